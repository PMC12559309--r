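# Desk-scale authentication summaries for ancient samples: chromosomal sex
# from the fraction of sex-chromosome reads mapping to Y, and the terminal
# C->T / G->A deamination profile that distinguishes degraded ancient DNA
# from modern contamination.

#' Chromosomal sex assignment from X/Y read counts
#'
#' `ry = nY / (nX + nY)` with a normal-approximation 95% CI. A sample is
#' called female when the whole CI lies below `female_max` and male when it
#' lies above `male_min` (defaults 0.016 and 0.075, the conventional
#' thresholds for this ratio); anything else is ambiguous. The ratio is
#' scale-invariant in the counts; only the CI tightens with depth.
#'
#' @param nY,nX Read counts mapped to Y and X (sum > 0).
#' @param female_max,male_min Calling thresholds on the CI.
#' @return A `sex_assignment`: `nY`, `nX`, `ry`, `ci95` (lo, hi), `call`.
#' @export
ry_sex <- function(nY, nX, female_max = 0.016, male_min = 0.075) {
  stopifnot(nY >= 0, nX >= 0)
  n <- nX + nY
  if (n == 0) stop("no reads mapped to X or Y")
  ry <- nY / n
  half <- 1.96 * sqrt(ry * (1 - ry) / n)
  ci <- c(lo = max(0, ry - half), hi = min(1, ry + half))
  call <- if (ci["hi"] < female_max) "female"
          else if (ci["lo"] > male_min) "male" else "ambiguous"
  structure(list(nY = nY, nX = nX, ry = ry, ci95 = ci, call = call),
            class = "sex_assignment")
}

#' @export
print.sex_assignment <- function(x, ...) {
  cat(sprintf("R_Y = %.4g (95%% CI %.4g-%.4g) from %d Y / %d X reads: %s\n",
              x$ry, x$ci95["lo"], x$ci95["hi"], x$nY, x$nX, x$call))
  invisible(x)
}

#' Terminal deamination profile from aligned reads
#'
#' Post-mortem cytosine deamination inflates C->T mismatches at 5' read ends
#' (and, read complementarily, G->A at 3' ends). Given reads with their
#' aligned reference bases, computes the position-wise C->T rate from the 5'
#' end and G->A rate from the 3' end over the first `k` positions
#' (truncated at the read length).
#'
#' @param reads A list of `c(read, ref)` character pairs, or a data.frame
#'   with columns `read` and `ref` (equal-length aligned strings).
#' @param k Number of terminal positions to profile (default 25).
#' @return A `damage_profile`: vectors `ct_5p`, `ga_3p` (rates, `NA` where
#'   no opportunity), `n_c_5p`, `n_g_3p` (opportunity counts).
#' @export
damage_profile <- function(reads, k = 25) {
  if (is.data.frame(reads))
    reads <- Map(c, reads$read, reads$ref)
  if (!length(reads)) stop("empty read set")
  kk <- as.integer(min(k, max(vapply(reads, function(r) nchar(r[1]), 0L))))
  ct_hit <- ct_opp <- ga_hit <- ga_opp <- numeric(kk)
  for (r in reads) {
    s <- strsplit(r[1], "")[[1]]
    f <- strsplit(r[2], "")[[1]]
    stopifnot(length(s) == length(f))
    L <- length(s)
    m5 <- seq_len(min(kk, L))
    cc <- f[m5] == "C"
    ct_opp[m5] <- ct_opp[m5] + cc
    ct_hit[m5] <- ct_hit[m5] + (cc & s[m5] == "T")
    m3 <- L + 1 - m5
    gg <- f[m3] == "G"
    ga_opp[m5] <- ga_opp[m5] + gg
    ga_hit[m5] <- ga_hit[m5] + (gg & s[m3] == "A")
  }
  structure(list(ct_5p = ifelse(ct_opp > 0, ct_hit / ct_opp, NA_real_),
                 ga_3p = ifelse(ga_opp > 0, ga_hit / ga_opp, NA_real_),
                 n_c_5p = ct_opp, n_g_3p = ga_opp, k = kk),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("damage profile over %d terminal positions\n", x$k))
  cat(sprintf("  position-1 C->T (5'): %.3f   position-1 G->A (3'): %.3f\n",
              x$ct_5p[1], x$ga_3p[1]))
  invisible(x)
}
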