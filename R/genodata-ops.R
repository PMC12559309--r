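#' Pseudo-haploid genotype calling from read pileups
#'
#' At each site one read is drawn uniformly at random among the reads
#' matching the site's ref or alt allele and its allele is doubled
#' (ref -> 0, alt -> 2); sites with no matching reads are missing. This is
#' the random-haploid caller routinely applied to low-coverage ancient
#' genomes, where confident diploid genotypes cannot be obtained.
#'
#' @param pu A [pileup()].
#' @param seed Integer seed (one draw per site).
#' @return Integer vector of calls in \{0, 2, NA\}, one per site.
#' @export
pseudo_haploid_call <- function(pu, seed = NULL) {
  stopifnot(inherits(pu, "pileup"))
  n_ref <- pu$counts[cbind(seq_len(nrow(pu$snps)),
                           match(pu$snps$ref, colnames(pu$counts)))]
  n_alt <- pu$counts[cbind(seq_len(nrow(pu$snps)),
                           match(pu$snps$alt, colnames(pu$counts)))]
  tot <- n_ref + n_alt
  with_seed(seed, {
    u <- runif(length(tot))
    call <- ifelse(tot == 0L, NA_integer_,
                   ifelse(u < n_alt / pmax(tot, 1L), 2L, 0L))
    as.integer(call)
  })
}

#' Restrict a panel to transversion sites
#'
#' Drops sites whose ref/alt pair is C/T or G/A (either order), i.e. both
#' strand readings of a transition. Transition sites are confounded with
#' post-mortem cytosine deamination in ancient DNA, so analyses are
#' replicated on the remaining transversions as an authentication check.
#'
#' @param x A [genotype_matrix()] (or a SNP table / `pileup`).
#' @return Object of the same class restricted to transversion sites,
#'   site order preserved.
#' @export
filter_transversions <- function(x) {
  snps <- if (inherits(x, "geno_matrix") || inherits(x, "pileup")) x$snps
          else x
  keep <- !is_transition(snps$ref, snps$alt)
  if (inherits(x, "geno_matrix")) return(x[keep, ])
  if (inherits(x, "pileup"))
    return(pileup(x$snps[keep, , drop = FALSE],
                  x$counts[keep, , drop = FALSE]))
  snps[keep, , drop = FALSE]
}

is_transition <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

#' Binomial thinning of pileup coverage
#'
#' Retains each read independently with probability
#' `target_mean_cov / current_mean_cov`, so the expected mean coverage of the
#' result equals the target. Used to replicate analyses of a high-coverage
#' genome at the coverage of a low-coverage one.
#'
#' @param pu A [pileup()].
#' @param current_mean_cov Mean coverage of `pu` (computed if `NULL`).
#' @param target_mean_cov Desired mean coverage, `<= current_mean_cov`.
#' @param seed Integer seed.
#' @return A thinned [pileup()].
#' @export
downsample_pileups <- function(pu, target_mean_cov, current_mean_cov = NULL,
                               seed = NULL) {
  stopifnot(inherits(pu, "pileup"))
  if (is.null(current_mean_cov)) current_mean_cov <- mean(rowSums(pu$counts))
  if (target_mean_cov > current_mean_cov)
    stop(sprintf("target coverage %.3f exceeds current coverage %.3f",
                 target_mean_cov, current_mean_cov))
  p <- if (current_mean_cov == 0) 0 else target_mean_cov / current_mean_cov
  with_seed(seed, {
    thinned <- pu$counts
    thinned[] <- rbinom(length(pu$counts), pu$counts, p)
    pileup(pu$snps, thinned)
  })
}

#' Intersect and merge two genotype panels
#'
#' Site set is the intersection keyed by (chrom, physical position). When the
#' second panel records the alleles swapped, its genotypes are recoded
#' (0 <-> 2, 1 kept). Sites whose allele pairs cannot be reconciled are
#' dropped, as are strand-ambiguous (A/T, C/G) sites whose alleles disagree.
#' Individuals are concatenated.
#'
#' @param a,b [genotype_matrix()] panels sharing the coordinate convention.
#' @return A merged [genotype_matrix()] (site annotation taken from `a`).
#' @export
intersect_panels <- function(a, b) {
  stopifnot(inherits(a, "geno_matrix"), inherits(b, "geno_matrix"))
  dup <- intersect(a$individuals$ind_id, b$individuals$ind_id)
  if (length(dup))
    stop("duplicate individual ids across panels: ",
         paste(dup, collapse = ", "))
  ka <- paste(a$snps$chrom, a$snps$physical_pos)
  kb <- paste(b$snps$chrom, b$snps$physical_pos)
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  ra <- a$snps$ref[ia]; aa <- a$snps$alt[ia]
  rb <- b$snps$ref[ib]; ab <- b$snps$alt[ib]
  same <- ra == rb & aa == ab
  swapped <- ra == ab & aa == rb
  ambiguous <- (ra == "A" & aa == "T") | (ra == "T" & aa == "A") |
    (ra == "C" & aa == "G") | (ra == "G" & aa == "C")
  keep <- same | (swapped & !ambiguous)
  ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]
  calls_b <- b$calls[ib, , drop = FALSE]
  if (any(swapped))
    calls_b[swapped, ] <- 2L - calls_b[swapped, , drop = FALSE]
  genotype_matrix(a$snps[ia, , drop = FALSE],
                  rbind(a$individuals, b$individuals),
                  cbind(a$calls[ia, , drop = FALSE], calls_b))
}

#' Per-population alternate-allele frequencies
#'
#' Diploid individuals contribute two observed alleles per non-missing call;
#' pseudo-haploid individuals contribute one (their call is a single sampled
#' read, so counting two would understate the sampling variance). Frequency
#' is missing where the observed allele count is zero.
#'
#' @param x A [genotype_matrix()].
#' @param grouping Optional named factor/character assigning individuals to
#'   populations; defaults to the panel's `population` column. Values must
#'   cover every individual.
#' @return An `allele_freq_table`: list with `p` and `n` matrices
#'   (sites x populations; `p` alt-allele frequency, `n` allele count) plus
#'   the `snps` table.
#' @export
allele_frequencies <- function(x, grouping = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  pops <- grouping %||% x$individuals$population
  if (length(pops) != nrow(x$individuals))
    stop("grouping must assign every individual")
  if (anyNA(pops)) stop("unknown population label for some individuals")
  pops <- as.character(pops)
  upop <- unique(pops)
  g <- x$calls
  # alleles contributed per non-missing call
  w_ind <- ifelse(x$individuals$pseudo_haploid, 1, 2)
  alt_ind <- sweep(ifelse(is.na(g), 0, g), 2, w_ind / 2, `*`)
  obs_ind <- sweep(!is.na(g), 2, w_ind, `*`)
  alt <- matrix(0, nrow(g), length(upop), dimnames = list(NULL, upop))
  n <- alt
  for (p in upop) {
    j <- which(pops == p)
    alt[, p] <- rowSums(alt_ind[, j, drop = FALSE])
    n[, p] <- rowSums(obs_ind[, j, drop = FALSE])
  }
  p_mat <- alt / n
  p_mat[n == 0] <- NA_real_
  freq_table(p_mat, n, x$snps)
}

#' Construct an allele-frequency table directly
#'
#' Mostly used by the simulator, which can generate panel frequencies from
#' binomial allele counts without materialising individuals.
#'
#' @param p Sites x populations matrix of alt-allele frequencies (NA where
#'   unobserved).
#' @param n Matching matrix of observed allele counts.
#' @param snps SNP table.
#' @return An `allele_freq_table`.
#' @export
freq_table <- function(p, n, snps) {
  stopifnot(all(dim(p) == dim(n)), nrow(p) == nrow(snps),
            !is.null(colnames(p)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies outside [0, 1]")
  if (any(is.na(p) != (n == 0))) stop("p must be missing exactly when n = 0")
  structure(list(p = p, n = n, snps = snps), class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d sites x %d populations\n",
              nrow(x$p), ncol(x$p)))
  invisible(x)
}

pop_freq <- function(freqs, pop) {
  if (!pop %in% colnames(freqs$p)) stop("unknown population: ", pop)
  freqs$p[, pop]
}
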