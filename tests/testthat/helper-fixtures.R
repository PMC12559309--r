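# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-site loops, textbook formulas) and share no code
# with the package internals they check.

toy_snps <- function(n, chrom = "1", span = 0.1,
                     ref = "A", alt = "C") {
  data.frame(snp_id = sprintf("rs%d", seq_len(n)),
             chrom = rep_len(chrom, n),
             genetic_pos = seq(0, span, length.out = n),
             physical_pos = seq_len(n) * 1000L,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             stringsAsFactors = FALSE)
}

toy_inds <- function(ids, pops = ids, ph = FALSE) {
  data.frame(ind_id = ids, sex = rep_len("U", length(ids)),
             population = pops,
             pseudo_haploid = rep_len(ph, length(ids)),
             stringsAsFactors = FALSE)
}

random_matrix <- function(n_snp, n_ind, seed, miss = 0.1, ph = FALSE) {
  set.seed(seed)
  calls <- matrix(sample(if (ph) c(0L, 2L) else 0:2, n_snp * n_ind,
                         replace = TRUE), n_snp, n_ind)
  calls[runif(length(calls)) < miss] <- NA_integer_
  pairs <- rbind(c("A", "C"), c("C", "T"), c("G", "A"), c("A", "T"),
                 c("G", "T"), c("C", "G"))
  pick <- pairs[sample(nrow(pairs), n_snp, replace = TRUE), , drop = FALSE]
  snps <- toy_snps(n_snp)
  snps$ref <- pick[, 1]; snps$alt <- pick[, 2]
  genotype_matrix(snps, toy_inds(paste0("I", seq_len(n_ind)), ph = ph),
                  calls)
}

# frequency table straight from a matrix of p values (all n = large)
freqs_from_p <- function(p, snps, n_alleles = 1000) {
  n <- matrix(n_alleles, nrow(p), ncol(p), dimnames = dimnames(p))
  n[is.na(p)] <- 0
  freq_table(p, n, snps)
}

# --- independent weighted-jackknife oracle (textbook Busing formula) ------
bf_jackknife <- function(est, loo, m) {
  g <- length(loo); n <- sum(m); h <- n / m
  tau <- h * est - (h - 1) * loo
  tj <- g * est - sum((1 - m / n) * loo)
  sqrt(sum((tau - tj)^2 / (h - 1)) / g)
}

# brute-force outgroup f3 with delete-one-block jackknife, per-site loops
bf_f3 <- function(p_out, p_a, p_b, block) {
  use <- which(!is.na(p_out + p_a + p_b))
  num <- vapply(use, function(s)
    (p_out[s] - p_a[s]) * (p_out[s] - p_b[s]), 0)
  blk <- block[use]
  est <- mean(num)
  ub <- sort(unique(blk))
  loo <- vapply(ub, function(b) mean(num[blk != b]), 0)
  m <- vapply(ub, function(b) sum(blk == b), 0)
  list(estimate = est, se = bf_jackknife(est, loo, m))
}

# brute-force D statistic (ratio of block-summed numerator/denominator)
bf_d <- function(pw, px, py, pz, block) {
  use <- which(!is.na(pw + px + py + pz))
  num <- (pw[use] - px[use]) * (py[use] - pz[use])
  den <- (pw[use] + px[use] - 2 * pw[use] * px[use]) *
    (py[use] + pz[use] - 2 * py[use] * pz[use])
  blk <- block[use]
  est <- sum(num) / sum(den)
  ub <- sort(unique(blk))
  loo <- vapply(ub, function(b)
    sum(num[blk != b]) / sum(den[blk != b]), 0)
  m <- vapply(ub, function(b) sum(blk == b), 0)
  list(estimate = est, se = bf_jackknife(est, loo, m))
}

# small deterministic frequency panel over several populations
toy_freq_panel <- function(n = 200, pops = c("Out", "A", "B", "C"),
                           seed = 42, chrom = rep("1", n)) {
  set.seed(seed)
  p <- matrix(runif(n * length(pops), 0.05, 0.95), n, length(pops),
              dimnames = list(NULL, pops))
  snps <- toy_snps(n, span = 0.3)
  snps$chrom <- chrom
  freqs_from_p(p, snps)
}
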