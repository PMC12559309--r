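#' Run an expression with a fixed RNG seed, restoring RNG state afterwards
#'
#' All stochastic operations in the package accept an integer `seed` and are
#' routed through this helper, so identical seeds give bit-identical output
#' and a call never disturbs the caller's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-replicate seed from a master seed
#'
#' Deterministic derivation used by the replicated experiments
#' (`downsampling_experiment()`, simulation studies): replicate `i` runs with
#' `derive_seed(seed, i)`. Kept below 2^31 so it is always a valid R integer.
#'
#' @param seed Master integer seed.
#' @param i Replicate index (1-based) or any small integer offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
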