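# EIGENSTRAT triplet I/O. The .snp file has six whitespace-separated columns
# (id, chrom, genetic position in Morgans, physical position, ref, alt), the
# .ind file three (id, sex, population), and the .geno file one row per SNP
# of digit characters per individual: the count of the alternate allele, with
# 9 for missing. The packed binary dialect (PACKEDANCESTRYMAP-style, 2 bits
# per genotype, value 3 = missing) is supported for reading.

GENO_MISSING_CHAR <- "9"

#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' @param prefix Path prefix: `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   are read. Alternatively give the three paths explicitly.
#' @param geno_path,snp_path,ind_path Explicit file paths (override `prefix`).
#' @param pseudo_haploid Character vector of individual ids (or `TRUE` for
#'   all) to flag as pseudo-haploid. The `.ind` format has no such column, so
#'   the flag is supplied at read time; individuals whose calls contain a
#'   heterozygote cannot be flagged.
#' @return A [genotype_matrix()] with rows and columns ordered as in the
#'   files; `9` is decoded as `NA`.
#' @export
read_eigenstrat <- function(prefix = NULL, geno_path = NULL, snp_path = NULL,
                            ind_path = NULL, pseudo_haploid = character()) {
  if (!is.null(prefix)) {
    geno_path <- geno_path %||% paste0(prefix, ".geno")
    snp_path <- snp_path %||% paste0(prefix, ".snp")
    ind_path <- ind_path %||% paste0(prefix, ".ind")
  }
  snp <- utils::read.table(snp_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  if (ncol(snp) != 6)
    stop(".snp file must have 6 columns, found ", ncol(snp))
  names(snp) <- c("snp_id", "chrom", "genetic_pos", "physical_pos",
                  "ref", "alt")
  bad <- which(!(snp$ref %in% c("A", "C", "G", "T")) |
                 !(snp$alt %in% c("A", "C", "G", "T")) | snp$ref == snp$alt)
  if (length(bad))
    stop("malformed allele column in ", snp_path, " at line ", bad[1])
  ind <- utils::read.table(ind_path, header = FALSE,
                           colClasses = "character")
  if (ncol(ind) != 3)
    stop(".ind file must have 3 columns, found ", ncol(ind))
  names(ind) <- c("ind_id", "sex", "population")
  ph <- if (isTRUE(pseudo_haploid)) rep(TRUE, nrow(ind))
        else ind$ind_id %in% pseudo_haploid
  ind$pseudo_haploid <- ph
  ind <- ind[, c("ind_id", "sex", "population", "pseudo_haploid")]

  calls <- if (is_packed_geno(geno_path))
    read_geno_packed(geno_path, nrow(snp), nrow(ind))
  else
    read_geno_ascii(geno_path, nrow(snp), nrow(ind))
  genotype_matrix(snp, ind, calls)
}

is_packed_geno <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 4)
  identical(rawToChar(head), "GENO")
}

read_geno_ascii <- function(path, n_snp, n_ind) {
  lines <- readLines(path)
  if (length(lines) != n_snp)
    stop(sprintf("geno file has %d lines but snp file has %d records",
                 length(lines), n_snp))
  wid <- nchar(lines)
  if (any(wid != n_ind))
    stop(sprintf(
      "geno line %d has %d characters but ind file has %d individuals",
      which(wid != n_ind)[1], wid[which(wid != n_ind)[1]], n_ind))
  m <- matrix(utf8ToInt("0"), nrow = n_snp, ncol = n_ind)
  for (i in seq_len(n_snp)) m[i, ] <- utf8ToInt(lines[i])
  g <- m - utf8ToInt("0")
  g[g == 9L] <- NA_integer_
  if (any(!(g %in% c(0L, 1L, 2L) | is.na(g))))
    stop("geno file contains characters other than 0/1/2/9")
  g
}

read_geno_packed <- function(path, n_snp, n_ind) {
  rlen <- max(48L, ceiling(n_ind / 4))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < rlen * (n_snp + 1))
    stop(sprintf("packed geno too short: %d bytes for %d snps x %d inds",
                 length(raw), n_snp, n_ind))
  # one header record, then one rlen-byte record per SNP; 2 bits per
  # genotype, most significant pair first, 3 = missing
  g <- matrix(NA_integer_, n_snp, n_ind)
  shifts <- c(6L, 4L, 2L, 0L)
  for (i in seq_len(n_snp)) {
    rec <- as.integer(raw[(i * rlen + 1):(i * rlen + ceiling(n_ind / 4))])
    vals <- integer(4 * length(rec))
    for (k in 1:4)
      vals[seq(k, by = 4, length.out = length(rec))] <-
        bitwAnd(bitwShiftR(rec, shifts[k]), 3L)
    g[i, ] <- vals[seq_len(n_ind)]
  }
  g[g == 3L] <- NA_integer_
  g
}

#' Write a genotype matrix as an EIGENSTRAT triplet
#'
#' Writes the ASCII dialect by default; `packed = TRUE` writes the binary
#' 2-bit geno encoding instead (snp/ind files are identical either way).
#'
#' @param x A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param packed Write packed binary geno instead of ASCII digits.
#' @return Invisibly, the three paths written.
#' @export
write_eigenstrat <- function(x, prefix, packed = FALSE) {
  stopifnot(inherits(x, "geno_matrix"))
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  dirs <- unique(dirname(paths))
  if (!all(dir.exists(dirs)))
    stop("output directory does not exist: ", dirs[!dir.exists(dirs)][1])
  snp <- x$snps
  write.table(
    data.frame(snp$snp_id, snp$chrom, format(snp$genetic_pos, digits = 10,
                                             scientific = FALSE, trim = TRUE),
               snp$physical_pos, snp$ref, snp$alt),
    paths[2], quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  write.table(x$individuals[, c("ind_id", "sex", "population")],
              paths[3], quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  g <- x$calls
  if (packed) {
    write_geno_packed(g, paths[1])
  } else {
    gg <- g
    gg[is.na(gg)] <- 9L
    lines <- apply(gg, 1, paste0, collapse = "")
    if (nrow(gg) == 0) lines <- character()
    writeLines(lines, paths[1])
  }
  invisible(paths)
}

write_geno_packed <- function(g, path) {
  n_ind <- ncol(g); n_snp <- nrow(g)
  rlen <- max(48L, ceiling(n_ind / 4))
  g[is.na(g)] <- 3L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("GENO %d %d 0 0", n_ind, n_snp))
  writeBin(c(hdr, rep(as.raw(0), rlen - length(hdr))), con)
  pad <- 4 * ceiling(n_ind / 4) - n_ind
  for (i in seq_len(n_snp)) {
    v <- c(g[i, ], rep(3L, pad))
    b <- bitwShiftL(v[seq(1, length(v), 4)], 6L) +
      bitwShiftL(v[seq(2, length(v), 4)], 4L) +
      bitwShiftL(v[seq(3, length(v), 4)], 2L) + v[seq(4, length(v), 4)]
    rec <- as.raw(c(b, rep(0L, rlen - length(b))))
    writeBin(rec, con)
  }
  invisible(path)
}

#' Read per-site read pileup counts from TSV
#'
#' Expected columns: `chrom`, `pos`, `countA`, `countC`, `countG`, `countT`
#' (header optional, detected). Sites are matched to `snps` by
#' (chrom, physical position); unmatched pileup rows are dropped.
#'
#' @param path TSV path.
#' @param snps SNP table as in [genotype_matrix()].
#' @return A `pileup` object: list with `snps` and an integer `counts`
#'   matrix (sites x 4, columns A/C/G/T; zero rows for sites with no reads).
#' @export
read_pileup_tsv <- function(path, snps) {
  first <- readLines(path, n = 1)
  hdr <- grepl("chrom", first, fixed = TRUE)
  tab <- utils::read.table(path, header = hdr, sep = "\t",
                           col.names = c("chrom", "pos", "countA", "countC",
                                         "countG", "countT"))
  counts <- matrix(0L, nrow(snps), 4,
                   dimnames = list(snps$snp_id, c("A", "C", "G", "T")))
  key <- paste(snps$chrom, snps$physical_pos)
  idx <- match(paste(tab$chrom, tab$pos), key)
  keep <- !is.na(idx)
  counts[idx[keep], ] <- as.matrix(tab[keep, 3:6])
  pileup(snps, counts)
}

#' Construct a pileup object
#'
#' @param snps SNP table (see [genotype_matrix()]).
#' @param counts Integer matrix sites x 4 (A, C, G, T read counts).
#' @return A `pileup` object.
#' @export
pileup <- function(snps, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(ncol(counts) == 4, nrow(counts) == nrow(snps),
            all(counts >= 0L))
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(snps = snps, counts = counts), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d sites, mean coverage %.3fx, %.1f%% sites covered\n",
              nrow(x$counts), mean(rowSums(x$counts)),
              100 * mean(rowSums(x$counts) > 0)))
  invisible(x)
}

#' Write pileup counts as TSV
#' @param x A `pileup`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pileup_tsv <- function(x, path) {
  stopifnot(inherits(x, "pileup"))
  tab <- data.frame(chrom = x$snps$chrom, pos = x$snps$physical_pos,
                    countA = x$counts[, "A"], countC = x$counts[, "C"],
                    countG = x$counts[, "G"], countT = x$counts[, "T"])
  write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
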