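#' Construct a genotype matrix for pseudo-haploid / diploid panels
#'
#' The central container of the package: biallelic sites in rows, individuals
#' in columns, entries counting copies of the alternate allele (0, 1, 2) with
#' `NA` for missing.  Pseudo-haploid individuals -- genotypes formed by
#' sampling a single sequencing read and doubling its allele, the standard
#' representation for low-coverage ancient genomes -- may only carry calls in
#' \{0, 2, NA\}, which is enforced here.
#'
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `genetic_pos`
#'   (Morgans, >= 0), `physical_pos` (1-based bp), `ref`, `alt`
#'   (single characters in A/C/G/T, `ref != alt`).
#' @param individuals `data.frame` with columns `ind_id` (unique), `sex`
#'   (one of "M", "F", "U"), `population`, and logical `pseudo_haploid`.
#' @param calls Integer matrix, `nrow(snps)` x `nrow(individuals)`, entries
#'   in \{0, 1, 2, NA\}.
#' @return An object of class `geno_matrix`: a list with elements `snps`,
#'   `individuals` and `calls` (dimnames set to snp ids / individual ids).
#' @seealso [read_eigenstrat()], [allele_frequencies()],
#'   [filter_transversions()]
#' @export
genotype_matrix <- function(snps, individuals, calls) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  need_s <- c("snp_id", "chrom", "genetic_pos", "physical_pos", "ref", "alt")
  if (!all(need_s %in% names(snps)))
    stop("snps must have columns: ", paste(need_s, collapse = ", "))
  need_i <- c("ind_id", "sex", "population", "pseudo_haploid")
  if (!all(need_i %in% names(individuals)))
    stop("individuals must have columns: ", paste(need_i, collapse = ", "))
  if (anyDuplicated(individuals$ind_id))
    stop("duplicate individual ids: ",
         paste(unique(individuals$ind_id[duplicated(individuals$ind_id)]),
               collapse = ", "))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(snps) || ncol(calls) != nrow(individuals))
    stop(sprintf("calls is %d x %d but there are %d snps and %d individuals",
                 nrow(calls), ncol(calls), nrow(snps), nrow(individuals)))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (any(snps$physical_pos < 1)) stop("physical_pos must be >= 1")
  if (any(snps$genetic_pos < 0)) stop("genetic_pos must be >= 0")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(snps$ref) || !ok_allele(snps$alt))
    stop("alleles must be single characters in {A,C,G,T}")
  ph <- which(individuals$pseudo_haploid)
  if (length(ph)) {
    het <- calls[, ph, drop = FALSE] == 1L
    if (any(het, na.rm = TRUE))
      stop("pseudo-haploid individuals may only carry calls in {0, 2, NA}")
  }
  dimnames(calls) <- list(snps$snp_id, individuals$ind_id)
  structure(list(snps = snps, individuals = individuals, calls = calls),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  np <- length(unique(x$individuals$population))
  cat(sprintf(
    "geno_matrix: %d sites x %d individuals (%d populations, %d pseudo-haploid)\n",
    nrow(x$snps), nrow(x$individuals), np, sum(x$individuals$pseudo_haploid)))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sites and/or individuals
#'
#' @param x A `geno_matrix`.
#' @param i Site index (logical or integer).
#' @param j Individual index (logical, integer or character ind ids).
#' @param ... Ignored.
#' @return A `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$snps))
  if (missing(j)) j <- seq_len(nrow(x$individuals))
  if (is.character(j)) j <- match(j, x$individuals$ind_id)
  genotype_matrix(x$snps[i, , drop = FALSE],
                  x$individuals[j, , drop = FALSE],
                  x$calls[i, j, drop = FALSE])
}

#' Combine two panels that share an identical site list
#' @keywords internal
cbind_geno <- function(a, b) {
  stopifnot(nrow(a$snps) == nrow(b$snps))
  genotype_matrix(a$snps, rbind(a$individuals, b$individuals),
                  cbind(a$calls, b$calls))
}
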