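# PCA on a reference panel with least-squares projection of low-coverage
# samples, the standard way to place a damaged ancient genome on a modern
# variation map without letting its missingness distort the axes.

#' Fit a PCA model on a reference genotype panel
#'
#' Sites with reference-panel missing rate above `max_missing` or without
#' polymorphism are dropped; remaining missing entries are mean-imputed.
#' Genotypes are centred by `2 * p_hat` and scaled by
#' `sqrt(p_hat * (1 - p_hat))` (`p_hat` the panel allele frequency), then
#' decomposed by SVD. Each eigenvector is oriented so its largest-magnitude
#' site loading is positive, making signs reproducible. Pseudo-haploid
#' reference individuals are allowed (and counted in `n_pseudo_haploid`).
#'
#' @param panel A [genotype_matrix()].
#' @param n_components Number of components to retain.
#' @param max_missing Maximum per-site missing rate in the panel
#'   (default 0.05).
#' @return A `pca_model`: retained `sites` (indices into the panel),
#'   `p_hat`, `scale`, `loadings` (sites x components, orthonormal),
#'   `eigenvalues`, `coords` (reference individuals x components),
#'   `individuals`.
#' @export
fit_pca <- function(panel, n_components = 2, max_missing = 0.05) {
  stopifnot(inherits(panel, "geno_matrix"))
  g <- panel$calls
  miss <- rowMeans(is.na(g))
  p_hat <- rowMeans(g, na.rm = TRUE) / 2
  keep <- which(miss <= max_missing & p_hat > 0 & p_hat < 1)
  if (n_components > min(length(keep), ncol(g)))
    stop(sprintf("n_components = %d exceeds usable dimensions (%d sites, %d individuals)",
                 n_components, length(keep), ncol(g)))
  g <- g[keep, , drop = FALSE]
  ph <- p_hat[keep]
  sc <- sqrt(ph * (1 - ph))
  z <- (g - 2 * ph) / sc
  z[is.na(z)] <- 0                      # mean imputation after centring
  sv <- svd(z, nu = n_components, nv = n_components)
  U <- sv$u
  flip <- vapply(seq_len(n_components), function(k) {
    j <- which.max(abs(U[, k])); sign(U[j, k])
  }, 0)
  U <- sweep(U, 2, flip, `*`)
  V <- sweep(sv$v, 2, flip, `*`)
  coords <- sweep(V, 2, sv$d[seq_len(n_components)], `*`)
  rownames(coords) <- panel$individuals$ind_id
  colnames(coords) <- paste0("PC", seq_len(n_components))
  colnames(U) <- colnames(coords)
  structure(list(sites = keep, snps = panel$snps[keep, , drop = FALSE],
                 p_hat = ph, scale = sc, loadings = U,
                 eigenvalues = sv$d[seq_len(n_components)]^2 / length(keep),
                 coords = coords, individuals = panel$individuals,
                 n_pseudo_haploid = sum(panel$individuals$pseudo_haploid)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components on %d sites x %d individuals\n",
              ncol(x$loadings), length(x$sites), nrow(x$coords)))
  cat("eigenvalues:", fmt_num(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Project a (possibly heavily missing) sample onto fitted components
#'
#' Least-squares regression of the sample's centred and scaled non-missing
#' genotypes onto the eigenvector rows at those sites -- the projection that
#' smartpca-style analyses use for low-coverage samples, which is unbiased
#' by missingness patterns in a way that naive imputation is not.
#'
#' @param model A [fit_pca()] model.
#' @param sample_calls Integer vector of calls (0/1/2/NA) aligned with the
#'   *original* panel's site list (the model records which sites it kept).
#' @return Named numeric vector of coordinates (PC1..PCk). Projecting a
#'   complete reference individual returns its fitted coordinates.
#' @export
project_sample <- function(model, sample_calls) {
  stopifnot(inherits(model, "pca_model"))
  gg <- sample_calls[model$sites]
  obs <- which(!is.na(gg))
  k <- ncol(model$loadings)
  if (length(obs) < k)
    stop(sprintf("sample has %d non-missing model sites but %d components",
                 length(obs), k))
  z <- (gg[obs] - 2 * model$p_hat[obs]) / model$scale[obs]
  U <- model$loadings[obs, , drop = FALSE]
  stats::setNames(as.numeric(solve(crossprod(U), crossprod(U, z))),
                  colnames(model$loadings))
}

#' Export PCA coordinates as TSV
#' @param model A `pca_model`.
#' @param path Output path.
#' @param extra Optional named list of projected samples (named numeric
#'   vectors from [project_sample()]) appended with population "projected".
#' @return Invisibly, `path`.
#' @export
write_pca_tsv <- function(model, path, extra = NULL) {
  tab <- data.frame(individual = rownames(model$coords),
                    population = model$individuals$population,
                    model$coords, check.names = FALSE)
  if (length(extra)) {
    et <- data.frame(individual = names(extra), population = "projected",
                     do.call(rbind, extra), check.names = FALSE)
    tab <- rbind(tab, et)
  }
  write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
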