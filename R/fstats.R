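# f3 and D statistics with weighted block-jackknife errors.
#
# The outgroup f3 statistic E[(p_out - p_A)(p_out - p_B)] measures the drift
# shared by A and B relative to an outgroup: the larger the value, the closer
# the pair. The D statistic tests treeness of four populations; its sign
# says which pair shares excess drift. Both are computed from per-population
# allele frequencies, with sites dropped per statistic when any involved
# population has no observed alleles there, and standard errors from the
# weighted delete-one-block jackknife.

fstat_core <- function(num, den, block, blocks, ratio = TRUE) {
  use <- !is.na(num)
  if (ratio) use <- use & !is.na(den)
  if (!any(use)) stop("zero usable sites")
  num <- num[use]; block <- block[use]
  g <- blocks$n_blocks
  nsum <- block_sums(num, block, g)
  w <- block_sums(rep(1, length(num)), block, g)
  used_blocks <- w > 0
  if (sum(used_blocks) < 2) stop("fewer than 2 usable blocks")
  if (ratio) {
    den <- den[use]
    dsum <- block_sums(den, block, g)
    if (sum(dsum) == 0) stop("denominator is zero over all usable sites")
    est <- sum(nsum) / sum(dsum)
    loo <- (sum(nsum) - nsum[used_blocks]) / (sum(dsum) - dsum[used_blocks])
  } else {
    est <- sum(nsum) / sum(w)
    loo <- (sum(nsum) - nsum[used_blocks]) / (sum(w) - w[used_blocks])
  }
  jk <- block_jackknife(est, loo, w[used_blocks])
  list(jk = jk, n_sites = length(num), n_blocks = sum(used_blocks),
       block_num = nsum, block_w = w,
       block_den = if (ratio) dsum else NULL)
}

#' Outgroup f3 statistic
#'
#' `f3(out; A, B)` = mean over usable sites of
#' `(p_out - p_A)(p_out - p_B)`, in outgroup mode (no heterozygosity
#' normalisation, no inbreeding correction), with SE and Z from the weighted
#' block jackknife. Symmetric in A and B.
#'
#' @param freqs An `allele_freq_table` (see [allele_frequencies()]).
#' @param out,A,B Population labels.
#' @param blocks A [make_blocks()] partition over `freqs$snps`.
#' @return An `f3_result`: populations, `estimate`, `se`, `z`, `n_sites`,
#'   `n_blocks`, plus per-block sums used by [pairwise_f3_regression()].
#' @export
f3_outgroup <- function(freqs, out, A, B, blocks) {
  po <- pop_freq(freqs, out); pa <- pop_freq(freqs, A); pb <- pop_freq(freqs, B)
  num <- (po - pa) * (po - pb)
  core <- fstat_core(num, NULL, blocks$block, blocks, ratio = FALSE)
  structure(c(list(out = out, A = A, B = B), core["jk"],
              core[c("n_sites", "n_blocks", "block_num", "block_w")],
              list(estimate = core$jk$estimate, se = core$jk$se,
                   z = core$jk$z)),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.4f +/- %.4f  (Z = %.2f, %d sites, %d blocks)\n",
              x$out, x$A, x$B, x$estimate, x$se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' D statistic (ABBA-BABA)
#'
#' `D(W, X; Y, Z)` = sum of `(w - x)(y - z)` over sum of
#' `(w + x - 2wx)(y + z - 2yz)` across usable sites. A positive value means
#' X shares excess drift with Z (equivalently W with Y); swapping Y and Z
#' flips the sign. SE and Z by weighted block jackknife on the ratio.
#'
#' @param freqs An `allele_freq_table`.
#' @param W,X,Y,Z Population labels.
#' @param blocks A [make_blocks()] partition.
#' @return A `d_result` with `estimate`, `se`, `z`, `n_sites`, `n_blocks`.
#' @export
d_stat <- function(freqs, W, X, Y, Z, blocks) {
  w <- pop_freq(freqs, W); x <- pop_freq(freqs, X)
  y <- pop_freq(freqs, Y); z <- pop_freq(freqs, Z)
  num <- (w - x) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  core <- fstat_core(num, den, blocks$block, blocks, ratio = TRUE)
  structure(list(W = W, X = X, Y = Y, Z = Z, jk = core$jk,
                 estimate = core$jk$estimate, se = core$jk$se,
                 z = core$jk$z, n_sites = core$n_sites,
                 n_blocks = core$n_blocks),
            class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s, %s) = %.5f +/- %.5f  (Z = %.2f, %d sites)\n",
              x$W, x$X, x$Y, x$Z, x$estimate, x$se, x$z, x$n_sites))
  invisible(x)
}

#' Outgroup-f3 scan of a target against candidate populations
#'
#' One [f3_outgroup()] per candidate, sorted descending by estimate (ties
#' broken lexicographically by candidate label): the standard shared-drift
#' ranking of reference populations against an ancient target. Candidates
#' whose statistic cannot be computed are kept as rows with `NA` values and
#' the failure reason.
#'
#' @param freqs An `allele_freq_table`.
#' @param target Target population label.
#' @param candidates Character vector of candidate labels.
#' @param out Outgroup label.
#' @param blocks A [make_blocks()] partition.
#' @return An `f3_scan`: data.frame (candidate, estimate, se, z, n_sites,
#'   n_blocks, reason) with the per-candidate `f3_result`s in
#'   `attr(, "results")`.
#' @export
outgroup_f3_scan <- function(freqs, target, candidates, out, blocks) {
  stopifnot(length(candidates) >= 1)
  res <- lapply(candidates, function(cand) {
    tryCatch(f3_outgroup(freqs, out, target, cand, blocks),
             error = function(e) conditionMessage(e))
  })
  names(res) <- candidates
  ok <- vapply(res, inherits, logical(1), "f3_result")
  tab <- data.frame(
    candidate = candidates,
    estimate = ifelse(ok, vapply(res, function(r)
      if (inherits(r, "f3_result")) r$estimate else NA_real_, 0), NA_real_),
    se = vapply(res, function(r)
      if (inherits(r, "f3_result")) r$se else NA_real_, 0),
    z = vapply(res, function(r)
      if (inherits(r, "f3_result")) r$z else NA_real_, 0),
    n_sites = vapply(res, function(r)
      if (inherits(r, "f3_result")) r$n_sites else NA_integer_, 0L),
    n_blocks = vapply(res, function(r)
      if (inherits(r, "f3_result")) r$n_blocks else NA_integer_, 0L),
    reason = ifelse(ok, "", vapply(res, function(r)
      if (is.character(r)) r else "", "")),
    stringsAsFactors = FALSE)
  ord <- order(-tab$estimate, tab$candidate, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, results = res[ord], target = target, out = out,
            class = c("f3_scan", "data.frame"))
}

#' Pairwise-f3 regression with block-jackknife deviation test
#'
#' Regresses `f3(out; refB, X)` on `f3(out; refA, X)` across candidate
#' populations X by ordinary least squares and tests each candidate's
#' residual against zero. The residual SE comes from a delete-one-block
#' jackknife in which both f3 vectors *and* the regression are recomputed
#' for every deleted block, so uncertainty in the fitted line is propagated.
#' Candidates with |Z| >= `z_threshold` are flagged as deviating
#' significantly from the line.
#'
#' @param scanA,scanB [outgroup_f3_scan()] results over the same candidates
#'   (x axis: scanA, y axis: scanB).
#' @param blocks The [make_blocks()] partition both scans were computed with.
#' @param z_threshold Flagging threshold on |residual Z| (default 3).
#' @return A `pairwise_f3_reg`: data.frame (candidate, x, y, residual,
#'   residual_se, residual_z, significant) with `slope` and `intercept`
#'   attributes.
#' @export
pairwise_f3_regression <- function(scanA, scanB, blocks, z_threshold = 3) {
  ra <- attr(scanA, "results"); rb <- attr(scanB, "results")
  cand <- intersect(names(ra), names(rb))
  cand <- cand[vapply(ra[cand], inherits, logical(1), "f3_result") &
                 vapply(rb[cand], inherits, logical(1), "f3_result")]
  if (length(cand) < 3)
    stop("pairwise-f3 regression needs at least 3 candidates")
  g <- blocks$n_blocks
  # per-candidate per-block numerator sums and site counts for both axes
  numA <- vapply(ra[cand], function(r) r$block_num, numeric(g))
  wA <- vapply(ra[cand], function(r) r$block_w, numeric(g))
  numB <- vapply(rb[cand], function(r) r$block_num, numeric(g))
  wB <- vapply(rb[cand], function(r) r$block_w, numeric(g))

  f3_of <- function(nums, ws, drop = 0L) {
    if (drop > 0L) colSums(nums[-drop, , drop = FALSE]) /
      colSums(ws[-drop, , drop = FALSE])
    else colSums(nums) / colSums(ws)
  }
  resid_of <- function(drop = 0L) {
    x <- f3_of(numA, wA, drop); y <- f3_of(numB, wB, drop)
    fit <- stats::lm.fit(cbind(1, x), y)
    list(x = x, y = y, coef = fit$coefficients, resid = fit$residuals)
  }
  full <- resid_of()
  w_blk <- rowSums(wA) + rowSums(wB)
  used <- which(w_blk > 0)
  loo <- t(vapply(used, function(b) resid_of(b)$resid, numeric(length(cand))))
  res_se <- vapply(seq_along(cand), function(k)
    block_jackknife(full$resid[k], loo[, k], w_blk[used])$se, 0)
  tab <- data.frame(candidate = cand, x = full$x, y = full$y,
                    residual = full$resid, residual_se = res_se,
                    residual_z = full$resid / res_se,
                    stringsAsFactors = FALSE)
  tab$significant <- abs(tab$residual_z) >= z_threshold
  rownames(tab) <- NULL
  structure(tab, slope = unname(full$coef[2]),
            intercept = unname(full$coef[1]),
            class = c("pairwise_f3_reg", "data.frame"))
}

#' Spearman rank concordance between paired statistics
#'
#' Used to compare a statistic computed on all sites with its
#' transversion-only replication: high rank concordance indicates the
#' all-site ranking is not driven by deamination artefacts.
#'
#' @param a,b Equal-length paired numeric vectors, `n >= 3`.
#' @return Spearman's rho (average ranks for ties); `NA` if either vector
#'   is constant.
#' @export
rank_concordance <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3 || length(unique(a)) == 1 || length(unique(b)) == 1)
    return(NA_real_)
  unname(stats::cor(a, b, method = "spearman"))
}
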