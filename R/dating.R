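# Admixture-LD decay dating. After an admixture pulse t generations ago,
# recombination breaks ancestry into tracts whose association decays
# exponentially with genetic distance at rate t per Morgan. Weighting each
# site by the allele-frequency difference between the two source populations
# and correlating the weighted genotype residuals of the admixed target
# across site pairs therefore yields a curve A0 * exp(-t * d) + c whose
# decay rate estimates the time of admixture in generations.

#' Per-site source-differentiation weights for admixture dating
#'
#' Weight `w = p_A - p_B` per site plus the mid-frequency
#' `(p_A + p_B) / 2` used to centre the target's genotypes. Sites where
#' either source frequency is missing get `NA` and are skipped pairwise.
#'
#' @param freqs An `allele_freq_table`.
#' @param sourceA,sourceB Source population labels.
#' @return A `snp_weights` object: list with numeric `w`, `pbar`, and the
#'   source labels.
#' @export
snp_weights <- function(freqs, sourceA, sourceB) {
  pa <- pop_freq(freqs, sourceA)
  pb <- pop_freq(freqs, sourceB)
  structure(list(w = pa - pb, pbar = (pa + pb) / 2,
                 sourceA = sourceA, sourceB = sourceB),
            class = "snp_weights")
}

#' Weighted ancestry-covariance decay curve
#'
#' For every intra-chromosome site pair (s, s') at genetic distance
#' `d in (0, max_dist]`, accumulates the product of weighted genotype
#' residuals `r_s = w_s * (g_s / 2 - pbar_s)` into equally spaced distance
#' bins; the curve value per bin is the mean product. Per-chromosome partial
#' sums are retained for the delete-one-chromosome jackknife of
#' [fit_decay()]. Works on a single target individual, pseudo-haploid or
#' diploid; pairs involving a missing call are skipped.
#'
#' @param target_calls Integer vector of the target's calls (0/1/2/NA),
#'   aligned with `snps`.
#' @param weights A [snp_weights()] object.
#' @param snps SNP table with `chrom` and `genetic_pos` (Morgans), sorted
#'   within chromosomes.
#' @param bin_size Bin width in Morgans (default 0.001 M = 0.1 cM).
#' @param max_dist Maximum pair distance in Morgans (default 0.2 M = 20 cM).
#' @return An `ancestry_cov_curve`: `bin_mid` (Morgans), `cov`, `n_pairs`,
#'   plus per-chromosome partial sums/counts for the jackknife.
#' @export
ancestry_cov_curve <- function(target_calls, weights, snps,
                               bin_size = 0.001, max_dist = 0.2) {
  stopifnot(inherits(weights, "snp_weights"),
            length(target_calls) == nrow(snps),
            length(weights$w) == nrow(snps))
  r <- weights$w * (target_calls / 2 - weights$pbar)
  n_bins <- ceiling(max_dist / bin_size)
  chroms <- unique(snps$chrom)
  sums <- matrix(0, length(chroms), n_bins,
                 dimnames = list(chroms, NULL))
  cnts <- matrix(0, length(chroms), n_bins, dimnames = list(chroms, NULL))
  for (ci in seq_along(chroms)) {
    idx <- which(snps$chrom == chroms[ci])
    pos <- snps$genetic_pos[idx]
    if (is.unsorted(pos)) stop("genetic positions unsorted within chromosome")
    rc <- r[idx]
    ok <- !is.na(rc)
    m <- length(idx)
    for (lag in seq_len(m - 1)) {
      i <- seq_len(m - lag)
      d <- pos[i + lag] - pos[i]
      inrange <- d > 0 & d <= max_dist
      if (!any(inrange)) {
        if (min(d) > max_dist) break else next
      }
      sel <- which(inrange & ok[i] & ok[i + lag])
      if (!length(sel)) next
      b <- pmin(ceiling(d[sel] / bin_size), n_bins)
      prod <- rc[sel] * rc[sel + lag]
      sums[ci, ] <- sums[ci, ] + block_sums(prod, b, n_bins)
      cnts[ci, ] <- cnts[ci, ] + tabulate(b, n_bins)
    }
  }
  total_n <- colSums(cnts)
  if (all(total_n == 0)) stop("no site pairs in any distance bin")
  covv <- colSums(sums) / total_n
  covv[total_n == 0] <- NA_real_
  structure(list(bin_mid = (seq_len(n_bins) - 0.5) * bin_size,
                 cov = covv, n_pairs = total_n,
                 chrom_sums = sums, chrom_counts = cnts,
                 bin_size = bin_size, max_dist = max_dist),
            class = "ancestry_cov_curve")
}

#' @export
print.ancestry_cov_curve <- function(x, ...) {
  cat(sprintf(
    "ancestry covariance curve: %d bins of %.2f cM, %d chromosomes, %.0f pairs\n",
    length(x$bin_mid), 100 * x$bin_size, nrow(x$chrom_sums), sum(x$n_pairs)))
  invisible(x)
}

#' Export an ancestry-covariance curve as TSV
#' @param x An `ancestry_cov_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(x, path) {
  write.table(data.frame(bin_center_cM = 100 * x$bin_mid, cov = x$cov,
                         n_pairs = x$n_pairs),
              path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

decay_fit_once <- function(d, y, w) {
  keep <- is.finite(y) & w > 0
  d <- d[keep]; y <- y[keep]; w <- w[keep]
  if (length(d) < 5) stop("fewer than 5 usable bins in the fit range")
  c0 <- mean(y[d >= stats::quantile(d, 0.75)])
  a0 <- y[1] - c0
  if (abs(a0) < 1e-12) a0 <- 1e-8
  lam0 <- max(2 / diff(range(d)), 1)
  sw <- sqrt(w)
  out <- minpack.lm::nls.lm(
    par = c(A0 = a0, lam = lam0, c = c0),
    fn = function(par) sw * (y - (par[1] * exp(-par[2] * d) + par[3])),
    lower = c(-Inf, 0, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000))
  if (!out$info %in% 1:4)
    stop("Levenberg-Marquardt did not converge (info = ", out$info, ": ",
         out$message, ")")
  stats::setNames(out$par, c("A0", "lam", "c"))
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Nonlinear least squares of `A0 * exp(-lambda * d) + c` over bins in the
#' fit range, weighted by pair counts. The decay rate `lambda`, in per-Morgan
#' units, estimates the number of generations since admixture. The SE of the
#' estimate comes from refitting with each chromosome's contribution deleted
#' (weighted jackknife over chromosomes, the natural exchangeable unit since
#' pairs never span chromosomes). The affine term `c` absorbs background LD
#' and finite-panel bias and is always estimated.
#'
#' @param curve An [ancestry_cov_curve()].
#' @param fit_lo,fit_hi Fit range in Morgans (defaults 0.0045 and the
#'   curve's maximum distance, mirroring the conventions of admixture-LD
#'   dating tools, which exclude the shortest distances where background LD
#'   dominates).
#' @return A `date_fit`: `A0`, `t` (= lambda, generations), `c`, `se_t`,
#'   `lambda_at_bound` flag, fit range, `n_chromosomes`.
#' @export
fit_decay <- function(curve, fit_lo = 0.0045, fit_hi = NULL) {
  stopifnot(inherits(curve, "ancestry_cov_curve"))
  fit_hi <- fit_hi %||% curve$max_dist
  inr <- curve$bin_mid >= fit_lo & curve$bin_mid <= fit_hi
  if (sum(inr) < 5) stop("fewer than 5 bins in the fit range")
  d <- curve$bin_mid[inr]
  tot_s <- colSums(curve$chrom_sums)[inr]
  tot_n <- colSums(curve$chrom_counts)[inr]
  co <- tryCatch(decay_fit_once(d, tot_s / tot_n, tot_n),
                 error = function(e)
                   stop("decay fit did not converge: ", conditionMessage(e)))
  n_chr <- nrow(curve$chrom_sums)
  if (n_chr < 2) stop("chromosome jackknife needs at least 2 chromosomes")
  loo <- vapply(seq_len(n_chr), function(ci) {
    s <- tot_s - curve$chrom_sums[ci, inr]
    n <- tot_n - curve$chrom_counts[ci, inr]
    tryCatch(decay_fit_once(d, s / n, n)[["lam"]],
             error = function(e) NA_real_)
  }, 0)
  wts <- rowSums(curve$chrom_counts[, inr, drop = FALSE])
  okj <- !is.na(loo) & wts > 0
  jk <- block_jackknife(co[["lam"]], loo[okj], wts[okj])
  structure(list(A0 = co[["A0"]], t = co[["lam"]], c = co[["c"]],
                 se_t = jk$se, lambda_at_bound = co[["lam"]] <= 1e-8,
                 fit_lo = fit_lo, fit_hi = fit_hi,
                 n_chromosomes = n_chr, loo_t = loo),
            class = "date_fit")
}

#' @export
print.date_fit <- function(x, ...) {
  cat(sprintf(
    "admixture date: t = %.1f +/- %.1f generations (A0 = %.3g, c = %.3g)\n",
    x$t, x$se_t, x$A0, x$c))
  cat(sprintf("  fit range %.2f-%.1f cM, %d chromosomes%s\n",
              100 * x$fit_lo, 100 * x$fit_hi, x$n_chromosomes,
              if (x$lambda_at_bound) "  [decay rate at zero bound]" else ""))
  invisible(x)
}

#' Convert a generations-since-admixture estimate to calendar years BP
#'
#' `years BP = sample_age_BP + t * generation_time`; the SE scales by the
#' generation time. The sample age is an explicit parameter: dating is
#' relative to the sampled individual, not to the present.
#'
#' @param fit A [fit_decay()] result (or a list with `t` and `se_t`).
#' @param generation_time Years per generation (default 30).
#' @param sample_age_BP Age of the sampled individual in years BP (>= 0).
#' @return A `calendar_date`: `years_BP`, `se_years`, `generation_time`,
#'   `sample_age_BP`.
#' @export
to_calendar <- function(fit, generation_time = 30, sample_age_BP) {
  stopifnot(sample_age_BP >= 0)
  structure(list(years_BP = sample_age_BP + fit$t * generation_time,
                 se_years = fit$se_t * generation_time,
                 generation_time = generation_time,
                 sample_age_BP = sample_age_BP),
            class = "calendar_date")
}

#' @export
print.calendar_date <- function(x, ...) {
  cat(sprintf(
    "admixture date: %.0f +/- %.0f years BP (%g-yr generations, sample age %g BP)\n",
    x$years_BP, x$se_years, x$generation_time, x$sample_age_BP))
  invisible(x)
}
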