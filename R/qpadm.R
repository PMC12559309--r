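# qpAdm-style admixture modelling. A target population is modelled as a
# mixture of "left" source populations such that every f4 relation between
# the target and a set of "right" reference populations is satisfied by the
# same mixture of the sources' f4 relations. Estimation is generalized least
# squares on f4 profiles with the mixture weights constrained to sum to one;
# the weighted block jackknife supplies both the residual covariance and the
# weight standard errors, and model fit is judged by an upper-tail chi-square
# on the GLS minimum.

#' Specify a qpAdm admixture model
#'
#' @param target Target population label.
#' @param sources Ordered source labels (length >= 1; 2 or 3 in typical use).
#' @param rights Right (reference) population labels; the first is the base
#'   right against which f4 profiles are formed. Needs
#'   `length(rights) >= length(sources) + 1` so the fit has at least one
#'   degree of freedom.
#' @return An `admixture_model`.
#' @export
admixture_model <- function(target, sources, rights) {
  stopifnot(length(target) == 1, length(sources) >= 1,
            length(rights) >= length(sources) + 1)
  if (target %in% c(sources, rights))
    stop("target must not appear among sources or rights")
  if (length(intersect(sources, rights)))
    stop("sources and rights must be disjoint")
  if (anyDuplicated(c(sources, rights)))
    stop("duplicated population labels in model")
  structure(list(target = target, sources = sources, rights = rights),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("admixture model: %s ~ %s  | rights: %s\n", x$target,
              paste(x$sources, collapse = " + "),
              paste(x$rights, collapse = ", ")))
  invisible(x)
}

#' f4 profile of a left population against the right set
#'
#' Component j is `f4(left, R1; R_(j+1), R1)` = mean over sites of
#' `(p_left - p_R1)(p_R(j+1) - p_R1)`, where R1 is the base right.
#' Per-block sums are retained for jackknife covariance.
#'
#' @param freqs An `allele_freq_table`.
#' @param left Left population label.
#' @param rights Right labels, base right first (length >= 2).
#' @param blocks A [make_blocks()] partition.
#' @param sites Optional logical site mask restricting the computation.
#' @return An `f4_profile`: list with `estimate` (length
#'   `length(rights) - 1`), per-block sums, block site counts, `n_sites`.
#' @export
f4_profile <- function(freqs, left, rights, blocks, sites = NULL) {
  stopifnot(length(rights) >= 2)
  prof <- f4_profiles(freqs, left, rights, blocks, sites)
  structure(list(left = left, rights = rights,
                 estimate = prof$est[1, ],
                 block_sums = matrix(prof$sums[, , 1],
                                     dim(prof$sums)[1], dim(prof$sums)[2],
                                     dimnames = dimnames(prof$sums)[1:2]),
                 block_n = prof$block_n, n_sites = prof$n_sites),
            class = "f4_profile")
}

# Shared-site f4 profiles for several left populations at once.
# Returns est (lefts x comps), sums (blocks x comps x lefts), block_n,
# n_sites and the site mask used.
f4_profiles <- function(freqs, lefts, rights, blocks, sites = NULL) {
  pops <- c(lefts, rights)
  miss <- setdiff(pops, colnames(freqs$p))
  if (length(miss)) stop("unknown population: ", paste(miss, collapse = ", "))
  p <- freqs$p[, pops, drop = FALSE]
  use <- rowSums(is.na(p)) == 0
  if (!is.null(sites)) use <- use & sites
  if (!any(use)) stop("no usable sites shared by all model populations")
  p <- p[use, , drop = FALSE]
  blk <- blocks$block[use]
  g <- blocks$n_blocks
  r1 <- p[, rights[1]]
  dR <- p[, rights[-1], drop = FALSE] - r1
  k1 <- length(rights) - 1
  sums <- array(0, dim = c(g, k1, length(lefts)),
                dimnames = list(NULL, rights[-1], lefts))
  for (li in seq_along(lefts)) {
    prod <- (p[, lefts[li]] - r1) * dR
    for (j in seq_len(k1))
      sums[, j, li] <- block_sums(prod[, j], blk, g)
  }
  block_n <- block_sums(rep(1, sum(use)), blk, g)
  n <- sum(block_n)
  est <- t(vapply(seq_along(lefts),
                  function(li) colSums(matrix(sums[, , li], g, k1)) / n,
                  numeric(k1)))
  rownames(est) <- lefts
  list(est = est, sums = sums, block_n = block_n, n_sites = n,
       sites = use)
}

solve_spd <- function(C, b = NULL, ridge_note = NULL) {
  eps_seq <- c(0, 10^(-10:-4))
  tr <- max(mean(diag(C)), .Machine$double.eps)
  for (eps in eps_seq) {
    Cr <- C + diag(eps * tr, nrow(C))
    ch <- tryCatch(chol(Cr), error = function(e) NULL)
    if (!is.null(ch)) {
      if (eps > 0 && !is.null(ridge_note))
        warning(sprintf("%s: covariance singular, ridge %.1e applied",
                        ridge_note, eps * tr))
      inv <- chol2inv(ch)
      return(if (is.null(b)) inv else inv %*% b)
    }
  }
  stop("covariance matrix could not be inverted even with ridge")
}

# GLS solve of e(a) = y - X a with sum(a) = 1 given C inverse action.
gls_weights <- function(Ft, Fs, Cinv) {
  m <- nrow(Fs)
  if (m == 1) return(1)
  y <- Ft - Fs[m, ]
  Xt <- t(Fs[-m, , drop = FALSE]) - Fs[m, ]   # comps x (m-1)
  A <- t(Xt) %*% Cinv %*% Xt
  b <- t(Xt) %*% Cinv %*% y
  bb <- solve(A, b)
  c(as.numeric(bb), 1 - sum(bb))
}

#' Fit a qpAdm admixture model
#'
#' Estimates mixture weights `a` minimising
#' `T(a) = e(a)' C^-1 e(a)` where `e(a)` is the target's f4 profile minus
#' the weighted sum of the sources' profiles and `C` is the weighted
#' block-jackknife covariance of `e` (re-estimated at the current weights;
#' a few fixed-point iterations suffice). Weights are constrained to sum to
#' one but may leave [0, 1]; feasibility is reported, never enforced. Model
#' fit: `P = upper tail of chi-square(T, df)` with
#' `df = length(rights) - length(sources)`. Weight SEs come from refitting
#' with each block deleted. Only sites non-missing in the target, all
#' sources and all rights are used.
#'
#' @param model An [admixture_model()].
#' @param freqs An `allele_freq_table`.
#' @param blocks A [make_blocks()] partition.
#' @param sites Optional logical mask forcing a site set (used to fit a
#'   nested submodel on exactly the full model's sites).
#' @param maxit,tol Fixed-point iteration controls for the covariance.
#' @return A `qpadm_fit`: `weights`, `se`, `vcov_w`, `statistic` (T), `df`,
#'   `p_value`, `feasible`, `n_sites`, `n_blocks`, plus internals
#'   (`sites`, covariance) reused by [nested_model_test()].
#' @export
fit_admixture <- function(model, freqs, blocks, sites = NULL,
                          maxit = 10, tol = 1e-9) {
  stopifnot(inherits(model, "admixture_model"))
  m <- length(model$sources)
  k1 <- length(model$rights) - 1
  df <- k1 - (m - 1)
  prof <- f4_profiles(freqs, c(model$target, model$sources), model$rights,
                      blocks, sites)
  used <- which(prof$block_n > 0)
  if (length(used) < df + 1)
    stop(sprintf("only %d usable blocks for %d degrees of freedom",
                 length(used), df))
  nb <- prof$block_n[used]
  n <- prof$n_sites
  tot <- apply(prof$sums, c(2, 3), sum)          # comps x lefts
  # leave-one-out profiles: (tot - block)/(n - nb), blocks x comps x lefts
  loo <- array(NA_real_, c(length(used), k1, m + 1))
  for (li in seq_len(m + 1))
    loo[, , li] <- (rep(1, length(used)) %o% tot[, li] -
                      matrix(prof$sums[used, , li], length(used), k1)) /
      (n - nb)
  Ft <- prof$est[1, ]
  Fs <- prof$est[-1, , drop = FALSE]
  a <- rep(1 / m, m)
  C <- NULL
  for (it in seq_len(maxit)) {
    e_full <- Ft - as.numeric(a %*% Fs)
    e_loo <- loo[, , 1, drop = FALSE][, , 1] -
      apply(loo[, , -1, drop = FALSE], c(1, 2),
            function(v) sum(v * a))
    if (k1 == 1) e_loo <- matrix(e_loo, ncol = 1)
    C <- block_jackknife_cov(e_full, e_loo, nb)
    Cinv <- solve_spd(C, ridge_note = "fit_admixture")
    a_new <- gls_weights(Ft, Fs, Cinv)
    if (max(abs(a_new - a)) < tol) { a <- a_new; break }
    a <- a_new
  }
  e_full <- Ft - as.numeric(a %*% Fs)
  Cinv <- solve_spd(C, ridge_note = NULL)
  Tstat <- max(0, as.numeric(t(e_full) %*% Cinv %*% e_full))
  # an exactly interpolating model leaves e and C both at rounding noise;
  # their ratio is then meaningless and the fit is perfect by construction
  prof_norm <- sqrt(mean(prof$est^2))
  if (sqrt(sum(e_full^2)) <= 1e-9 * max(prof_norm, 1e-30)) Tstat <- 0
  p <- stats::pchisq(Tstat, df, lower.tail = FALSE)
  # weight SEs: refit with each block deleted (same covariance)
  if (m > 1) {
    a_loo <- t(vapply(seq_along(used), function(b) {
      Ftb <- loo[b, , 1]
      Fsb <- t(loo[b, , -1, drop = FALSE][1, , ])
      if (m == 2 && nrow(Fsb) != 2) Fsb <- t(Fsb)
      gls_weights(Ftb, Fsb, Cinv)
    }, numeric(m)))
    se <- vapply(seq_len(m), function(i)
      block_jackknife(a[i], a_loo[, i], nb)$se, 0)
    vcov_w <- block_jackknife_cov(a, a_loo, nb)
  } else {
    se <- 0; vcov_w <- matrix(0, 1, 1)
  }
  weights <- stats::setNames(a, model$sources)
  structure(list(model = model, weights = weights,
                 se = stats::setNames(se, model$sources), vcov_w = vcov_w,
                 statistic = Tstat, df = df, p_value = p,
                 feasible = all(a >= 0 & a <= 1),
                 n_sites = n, n_blocks = length(used),
                 sites = prof$sites, cov_e = C, profiles = prof$est),
            class = "qpadm_fit")
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat(sprintf("qpAdm fit: %s ~ %s\n", x$model$target,
              paste(x$model$sources, collapse = " + ")))
  w <- rbind(weight = x$weights, se = x$se)
  print(round(w, 4))
  cat(sprintf("T = %.3f on df = %d, P = %.4g  (%s; %d sites, %d blocks)\n",
              x$statistic, x$df, x$p_value,
              if (x$feasible) "feasible" else "INFEASIBLE weights",
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' @export
coef.qpadm_fit <- function(object, ...) object$weights

#' @export
vcov.qpadm_fit <- function(object, ...) object$vcov_w

#' @export
summary.qpadm_fit <- function(object, ...) {
  out <- data.frame(source = object$model$sources,
                    weight = as.numeric(object$weights),
                    se = as.numeric(object$se))
  out$z <- out$weight / out$se
  attr(out, "fit") <- c(T = object$statistic, df = object$df,
                        P = object$p_value)
  out
}

#' Nested-model comparison of two qpAdm fits
#'
#' Likelihood-ratio-style test of whether dropping sources worsens the fit:
#' `dT = T_reduced - T_full` referred to a chi-square with one degree of
#' freedom per dropped source. Requires the reduced model's sources to be a
#' subset of the full model's, with identical target, rights and site set
#' (fit the reduced model with `sites = full_fit$sites`). Both statistics
#' are evaluated under the full model's covariance, where the reduced
#' constraint set is genuinely nested inside the full one, so `dT >= 0`
#' holds by construction and the chi-square reference is valid; tiny
#' negative values from floating point are clamped to zero.
#'
#' @param full,reduced `qpadm_fit` objects.
#' @return A `qpadm_nested`: `delta_T`, `df`, `p_value` plus both fits.
#' @export
nested_model_test <- function(full, reduced) {
  stopifnot(inherits(full, "qpadm_fit"), inherits(reduced, "qpadm_fit"))
  if (!all(reduced$model$sources %in% full$model$sources))
    stop("reduced model sources are not a subset of the full model's")
  if (!identical(full$model$target, reduced$model$target) ||
      !identical(full$model$rights, reduced$model$rights))
    stop("nested comparison requires identical target and rights")
  if (full$n_sites != reduced$n_sites)
    stop("nested comparison requires the same site set; refit the reduced ",
         "model with sites = full$sites")
  df <- length(full$model$sources) - length(reduced$model$sources)
  if (df < 1) stop("models are identical or reversed")
  # re-minimise the reduced model under the full model's covariance: its
  # profiles on the shared site set are the corresponding rows of the
  # full model's
  Cinv <- solve_spd(full$cov_e)
  Ft <- full$profiles[1, ]
  Fs_red <- full$profiles[reduced$model$sources, , drop = FALSE]
  a_red <- gls_weights(Ft, Fs_red, Cinv)
  e_red <- Ft - as.numeric(a_red %*% Fs_red)
  T_red <- as.numeric(t(e_red) %*% Cinv %*% e_red)
  dT <- max(T_red - full$statistic, 0)
  p <- stats::pchisq(dT, df, lower.tail = FALSE)
  structure(list(full = full, reduced = reduced, delta_T = dT,
                 df = df, p_value = p),
            class = "qpadm_nested")
}

#' @export
print.qpadm_nested <- function(x, ...) {
  cat(sprintf(
    "nested qpAdm test: [%s] vs [%s]\n  dT = %.3f on df = %d, P = %.4g\n",
    paste(x$full$model$sources, collapse = "+"),
    paste(x$reduced$model$sources, collapse = "+"),
    x$delta_T, x$df, x$p_value))
  invisible(x)
}

#' Coverage-downsampling robustness experiment
#'
#' Replicates the admixture modelling of a target after binomial thinning of
#' its read pileups to a lower mean coverage: per replicate, thin, re-call
#' pseudo-haploid genotypes, fit the reduced and full models (the reduced on
#' the full model's site set) and run the nested test. Used to check that a
#' model choice is not an artefact of low coverage.
#'
#' @param target_pileups [pileup()] for the target individual.
#' @param panel_freqs `allele_freq_table` of the reference panel (must not
#'   already contain the target).
#' @param model_reduced,model_full [admixture_model()]s sharing target and
#'   rights, `model_reduced$sources` a subset of `model_full$sources`.
#' @param target_cov Coverage to thin to.
#' @param blocks A [make_blocks()] partition over the panel's sites (must
#'   match the pileup site list).
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate i uses `derive_seed(seed, i)`.
#' @param alpha Fit-adequacy threshold on P (default 0.05).
#' @return A `downsampling_report`: per-rep data.frame (`reps`) and summary
#'   counts of adequately fitting replicates per model and of significant
#'   nested tests.
#' @export
downsampling_experiment <- function(target_pileups, panel_freqs,
                                    model_reduced, model_full, target_cov,
                                    blocks, n_reps = 100, seed = 1,
                                    alpha = 0.05) {
  stopifnot(inherits(target_pileups, "pileup"),
            inherits(panel_freqs, "allele_freq_table"))
  target <- model_full$target
  if (target %in% colnames(panel_freqs$p))
    stop("panel_freqs must not already contain the target population")
  cur <- mean(rowSums(target_pileups$counts))
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- derive_seed(seed, r)
    rows[[r]] <- tryCatch({
      thin <- downsample_pileups(target_pileups, target_cov, cur, seed = s)
      calls <- pseudo_haploid_call(thin, seed = derive_seed(s, 1))
      fr <- add_target_freqs(panel_freqs, target, calls)
      fit_full <- fit_admixture(model_full, fr, blocks)
      fit_red <- fit_admixture(model_reduced, fr, blocks,
                               sites = fit_full$sites)
      nested <- nested_model_test(fit_full, fit_red)
      data.frame(rep = r, seed = s, error = "",
                 p_reduced = fit_red$p_value, p_full = fit_full$p_value,
                 p_nested = nested$p_value,
                 t(stats::setNames(as.numeric(fit_full$weights),
                                   paste0("w_", model_full$sources))),
                 n_sites = fit_full$n_sites)
    }, error = function(e) {
      data.frame(rep = r, seed = s, error = conditionMessage(e),
                 p_reduced = NA_real_, p_full = NA_real_,
                 p_nested = NA_real_, n_sites = NA_integer_)
    })
  }
  reps <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (n_reps == 0)
    reps <- data.frame(rep = integer(), seed = integer(),
                       error = character(), p_reduced = numeric(),
                       p_full = numeric(), p_nested = numeric(),
                       n_sites = integer())
  structure(list(
    reps = reps, n_reps = n_reps, alpha = alpha, target_cov = target_cov,
    n_adequate_reduced = sum(reps$p_reduced >= alpha, na.rm = TRUE),
    n_adequate_full = sum(reps$p_full >= alpha, na.rm = TRUE),
    n_nested_significant = sum(reps$p_nested < alpha, na.rm = TRUE),
    n_failed = sum(reps$error != "")),
    class = "downsampling_report")
}

#' @export
print.downsampling_report <- function(x, ...) {
  cat(sprintf("downsampling experiment: %d replicates at %.2fx\n",
              x$n_reps, x$target_cov))
  cat(sprintf("  reduced model adequate (P >= %.2f): %d/%d\n", x$alpha,
              x$n_adequate_reduced, x$n_reps))
  cat(sprintf("  full model adequate:    %d/%d\n", x$n_adequate_full,
              x$n_reps))
  cat(sprintf("  nested test significant (P < %.2f): %d/%d\n", x$alpha,
              x$n_nested_significant, x$n_reps))
  if (x$n_failed) cat(sprintf("  failed replicates: %d\n", x$n_failed))
  invisible(x)
}

# Append a single pseudo-haploid target individual to a frequency table.
add_target_freqs <- function(freqs, target, calls) {
  p <- cbind(freqs$p, calls / 2)
  n <- cbind(freqs$n, as.numeric(!is.na(calls)))
  colnames(p)[ncol(p)] <- colnames(n)[ncol(n)] <- target
  p[, target][is.na(calls)] <- NA_real_
  freq_table(p, n, freqs$snps)
}
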