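# Weighted delete-one-block jackknife (Busing-style), the standard-error
# machinery behind every f-statistic in the package. Blocks are contiguous
# genomic windows, so the SEs are robust to linkage disequilibrium between
# neighbouring sites.

#' Partition sites into contiguous jackknife blocks
#'
#' Greedy left-to-right blocks of genetic span at most `block_size` Morgans
#' per chromosome; a block's weight is its site count. Blocks never span
#' chromosomes.
#'
#' @param snps SNP table sorted by (chrom, genetic_pos); an error otherwise.
#' @param block_size Maximum genetic span per block in Morgans
#'   (default 0.05 M = 5 cM, the convention of the ADMIXTOOLS ecosystem).
#' @return A `block_partition`: list with `block` (per-site integer index)
#'   and `info` (data.frame: chrom, start, end, n_sites per block).
#' @export
make_blocks <- function(snps, block_size = 0.05) {
  ord <- order(match(snps$chrom, unique(snps$chrom)), snps$genetic_pos)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("snps must be sorted by (chrom, genetic_pos)")
  block <- integer(nrow(snps))
  b <- 0L
  cur_chrom <- NULL; cur_start <- -Inf
  for (i in seq_len(nrow(snps))) {
    if (!identical(snps$chrom[i], cur_chrom) ||
        snps$genetic_pos[i] - cur_start > block_size) {
      b <- b + 1L
      cur_chrom <- snps$chrom[i]
      cur_start <- snps$genetic_pos[i]
    }
    block[i] <- b
  }
  info <- data.frame(
    chrom = tapply(snps$chrom, block, `[`, 1),
    start = as.numeric(tapply(snps$genetic_pos, block, min)),
    end = as.numeric(tapply(snps$genetic_pos, block, max)),
    n_sites = as.integer(table(block)))
  structure(list(block = block, info = info, n_blocks = nrow(info)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block_partition: %d blocks over %d chromosomes, %d sites\n",
              x$n_blocks, length(unique(x$info$chrom)), length(x$block)))
  invisible(x)
}

#' Weighted delete-one-block jackknife for a scalar statistic
#'
#' Given the full-data estimate, the leave-one-block-out estimates and the
#' block weights (site counts), returns the Busing-style weighted jackknife
#' standard error. With equal block weights this reduces to the classic
#' delete-one jackknife.
#'
#' @param est Full-data estimate.
#' @param loo Numeric vector of leave-one-out estimates, one per block.
#' @param weights Block weights (site counts), same length as `loo`.
#' @return A `jackknife_estimate`: list with `estimate`, `se`, `z`,
#'   `n_blocks`, `loo`, `weights`.
#' @export
block_jackknife <- function(est, loo, weights) {
  g <- length(loo)
  stopifnot(length(weights) == g, g >= 2)
  n <- sum(weights)
  h <- n / weights
  tau <- h * est - (h - 1) * loo
  theta_j <- g * est - sum((1 - weights / n) * loo)
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(v)
  structure(list(estimate = est, se = se,
                 z = if (se > 0) est / se else NA_real_,
                 n_blocks = g, loo = loo, weights = weights),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("estimate %s +/- %s (Z = %s, %d blocks)\n",
              fmt_num(x$estimate, 6), fmt_num(x$se, 4), fmt_num(x$z, 3),
              x$n_blocks))
  invisible(x)
}

#' Weighted jackknife covariance of a vector statistic
#'
#' Multivariate analogue of [block_jackknife()]: rows of `loo` are
#' leave-one-block-out values of a vector estimate.
#'
#' @param est Full-data estimate (length d).
#' @param loo g x d matrix of leave-one-out estimates.
#' @param weights Block weights (length g).
#' @return d x d covariance matrix.
#' @export
block_jackknife_cov <- function(est, loo, weights) {
  g <- nrow(loo)
  stopifnot(length(weights) == g, g >= 2, ncol(loo) == length(est))
  n <- sum(weights)
  h <- n / weights
  # tau[j, ] = h_j * est - (h_j - 1) * loo[j, ]
  tau <- (h %o% est) - (h - 1) * loo
  theta_j <- g * est - colSums((1 - weights / n) * loo)
  d <- sweep(tau, 2, theta_j)
  crossprod(d / sqrt(h - 1)) / g
}

# Per-block sums of a per-site vector; returns length-g vector aligned with
# block ids 1..g (zeros for blocks with no usable site).
block_sums <- function(x, block, g) {
  out <- numeric(g)
  s <- rowsum(x, block)
  out[as.integer(rownames(s))] <- s
  out
}
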