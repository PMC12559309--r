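test_that("EIGENSTRAT ASCII round-trip is the identity, byte for byte", {
  tmp <- withr::local_tempdir()
  # 3-site x 2-individual toy, including a "029"-style missing code
  snps <- toy_snps(3)
  inds <- toy_inds(c("a", "b"), pops = c("P1", "P2"))
  calls <- matrix(c(0L, 2L, NA, 1L, 0L, 2L), 3, 2)
  gm <- genotype_matrix(snps, inds, calls)
  write_eigenstrat(gm, file.path(tmp, "toy"))
  back <- read_eigenstrat(file.path(tmp, "toy"))
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_equal(back$snps$genetic_pos, gm$snps$genetic_pos)
  expect_identical(back$individuals$population, c("P1", "P2"))

  # geno line "029" decodes as (0, 2, missing)
  writeLines("029", file.path(tmp, "one.geno"))
  write.table(data.frame("s1", "1", 0.01, 100L, "A", "C"),
              file.path(tmp, "one.snp"), col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(c("x", "y", "z"), "U", "P"),
              file.path(tmp, "one.ind"), col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  one <- read_eigenstrat(file.path(tmp, "one"))
  expect_identical(unname(one$calls[1, ]), c(0L, 2L, NA_integer_))

  # generated 100 x 10 fixture: write(read(write(x))) byte-compares equal
  gm2 <- random_matrix(100, 10, seed = 7)
  write_eigenstrat(gm2, file.path(tmp, "big"))
  back2 <- read_eigenstrat(file.path(tmp, "big"))
  write_eigenstrat(back2, file.path(tmp, "big2"))
  for (ext in c(".geno", ".snp", ".ind"))
    expect_identical(readLines(file.path(tmp, paste0("big2", ext))),
                     readLines(file.path(tmp, paste0("big", ext))))
})

test_that("packed geno round-trips and degenerate writes behave", {
  tmp <- withr::local_tempdir()
  gm <- random_matrix(60, 9, seed = 11)
  write_eigenstrat(gm, file.path(tmp, "pk"), packed = TRUE)
  back <- read_eigenstrat(file.path(tmp, "pk"))
  expect_identical(unname(back$calls), unname(gm$calls))

  # empty matrix -> three empty-body files
  empty <- genotype_matrix(toy_snps(0), toy_inds(character()),
                           matrix(integer(), 0, 0))
  write_eigenstrat(empty, file.path(tmp, "empty"))
  expect_identical(readLines(file.path(tmp, "empty.geno")), character(0))
  # 1-site matrix -> 1-line geno
  one <- genotype_matrix(toy_snps(1), toy_inds("a"),
                         matrix(1L, 1, 1))
  write_eigenstrat(one, file.path(tmp, "one"))
  expect_length(readLines(file.path(tmp, "one.geno")), 1L)
})

test_that("malformed inputs fail loudly with counts or line numbers", {
  tmp <- withr::local_tempdir()
  gm <- random_matrix(10, 3, seed = 1)
  write_eigenstrat(gm, file.path(tmp, "x"))
  # drop a geno line: dimension mismatch must name the counts
  gl <- readLines(file.path(tmp, "x.geno"))
  writeLines(gl[-1], file.path(tmp, "x.geno"))
  expect_error(read_eigenstrat(file.path(tmp, "x")), "9 lines.*10 records")
  writeLines(gl, file.path(tmp, "x.geno"))
  # corrupt an allele column: error cites the line
  sl <- readLines(file.path(tmp, "x.snp"))
  sl[4] <- sub("\t[ACGT]\t[ACGT]$", "\tA\tA", sl[4])
  writeLines(sl, file.path(tmp, "x.snp"))
  expect_error(read_eigenstrat(file.path(tmp, "x")), "line 4")
})

test_that("pseudo-haploid calling follows the read proportions", {
  snps <- toy_snps(1)
  # single-allele pileups are deterministic
  pu_ref <- pileup(snps, matrix(c(5L, 0L, 0L, 0L), 1))   # 5 x A(ref)
  expect_identical(pseudo_haploid_call(pu_ref, seed = 1), 0L)
  pu_none <- pileup(snps, matrix(c(0L, 0L, 3L, 0L), 1))  # only G: no match
  expect_identical(pseudo_haploid_call(pu_none, seed = 1), NA_integer_)

  # balanced ref/alt: alt-call fraction is binomial around 0.5
  n <- 10000
  pu <- pileup(toy_snps(n), matrix(rep(c(1L, 1L, 0L, 0L), each = n), n))
  calls <- pseudo_haploid_call(pu, seed = 99)
  expect_true(abs(mean(calls == 2L) - 0.5) < 0.015)

  # chi-square goodness of fit at unbalanced proportions (3:1)
  pu2 <- pileup(toy_snps(n), matrix(rep(c(3L, 1L, 0L, 0L), each = n), n))
  calls2 <- pseudo_haploid_call(pu2, seed = 5)
  gof <- chisq.test(table(calls2), p = c(0.75, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("transversion filtering drops both strand readings of transitions", {
  snps <- toy_snps(4)
  snps$ref <- c("A", "C", "G", "A"); snps$alt <- c("C", "T", "A", "T")
  gm <- genotype_matrix(snps, toy_inds("a"), matrix(0L, 4, 1))
  kept <- filter_transversions(gm)
  expect_identical(kept$snps$snp_id, snps$snp_id[c(1, 4)])

  # all-transversion panel is untouched; idempotence; brute-force set check
  gm2 <- random_matrix(1000, 2, seed = 3)
  tv <- filter_transversions(gm2)
  expect_identical(filter_transversions(tv)$snps, tv$snps)
  brute <- !(paste0(gm2$snps$ref, gm2$snps$alt) %in%
               c("CT", "TC", "GA", "AG"))
  expect_identical(tv$snps$snp_id, gm2$snps$snp_id[brute])
  all_tv <- gm2[brute, ]
  expect_identical(filter_transversions(all_tv)$snps, all_tv$snps)
})

test_that("binomial thinning hits the target coverage in expectation", {
  n <- 10000
  set.seed(2)
  cnt <- matrix(0L, n, 4)
  cnt[, 1] <- rpois(n, 2); cnt[, 2] <- rpois(n, 2)
  pu <- pileup(toy_snps(n), cnt)                    # ~4x
  cur <- mean(rowSums(pu$counts))
  expect_error(downsample_pileups(pu, cur + 1), "exceeds")
  same <- downsample_pileups(pu, cur, seed = 1)
  expect_identical(same$counts, pu$counts)
  zero <- downsample_pileups(pu, 0, seed = 1)
  expect_true(all(zero$counts == 0L))
  thin <- downsample_pileups(pu, 1, seed = 8)
  expect_lt(abs(mean(rowSums(thin$counts)) - 1), 0.03)
  # thinning preserves per-base proportions in expectation
  props <- colSums(thin$counts) / sum(thin$counts)
  expect_lt(max(abs(props - colSums(pu$counts) / sum(pu$counts))), 0.02)
})

test_that("panel intersection reconciles alleles and recodes swaps", {
  gm <- random_matrix(300, 3, seed = 21)
  # disjoint site sets -> empty merge
  other <- random_matrix(300, 2, seed = 22)
  other$snps$physical_pos <- other$snps$physical_pos + 1L
  other$individuals$ind_id <- paste0("o", other$individuals$ind_id)
  other$calls <- matrix(other$calls, 300, 2,
                        dimnames = list(other$snps$snp_id,
                                        other$individuals$ind_id))
  merged0 <- intersect_panels(gm, genotype_matrix(other$snps,
                                                  other$individuals,
                                                  other$calls))
  expect_identical(nrow(merged0$snps), 0L)

  # identical panels: sites unchanged, individuals doubled
  dup <- gm
  dup$individuals$ind_id <- paste0("d", dup$individuals$ind_id)
  dup <- genotype_matrix(dup$snps, dup$individuals, dup$calls)
  merged <- intersect_panels(gm, dup)
  expect_identical(nrow(merged$snps), nrow(gm$snps))
  expect_identical(nrow(merged$individuals), 6L)
  expect_error(intersect_panels(gm, gm), "duplicate individual ids")

  # allele-swapped copy: recoded calls equal the originals at every site
  sw <- gm
  sw$snps$ref <- gm$snps$alt; sw$snps$alt <- gm$snps$ref
  sw$individuals$ind_id <- paste0("s", sw$individuals$ind_id)
  sw <- genotype_matrix(sw$snps, sw$individuals, 2L - gm$calls)
  msw <- intersect_panels(gm, sw)
  ambiguous <- paste0(gm$snps$ref, gm$snps$alt) %in%
    c("AT", "TA", "CG", "GC")
  expect_identical(nrow(msw$snps), sum(!ambiguous))
  expect_identical(unname(msw$calls[, 4:6]), unname(msw$calls[, 1:3]))
})

test_that("allele frequencies weight pseudo-haploids as one allele", {
  snps <- toy_snps(2)
  inds <- toy_inds(c("dip", "ph1", "ph2"), pops = c("P", "P", "Q"),
                   ph = c(FALSE, TRUE, TRUE))
  calls <- matrix(c(1L, 2L,   2L, NA,   2L, 0L), 2, 3)
  gm <- genotype_matrix(snps, inds, calls)
  fr <- allele_frequencies(gm)
  # P at site 1: diploid het (1/2) + pseudo-haploid alt (1/1) -> 2/3 of n=3
  expect_equal(unname(fr$p[1, "P"]), 2 / 3)
  expect_equal(unname(fr$n[1, "P"]), 3)
  # P at site 2: only the diploid observed -> p = 1, n = 2
  expect_equal(unname(fr$p[2, "P"]), 1)
  expect_equal(unname(fr$n[2, "P"]), 2)
  # Q: single pseudo-haploid, call 2 -> p = 1 with n = 1; call 0 -> p = 0
  expect_equal(unname(fr$p[1, "Q"]), 1)
  expect_equal(unname(fr$n[1, "Q"]), 1)
  expect_equal(unname(fr$p[2, "Q"]), 0)
  expect_error(allele_frequencies(gm, c("P", NA, "Q")), "unknown population")
})

test_that("pileup TSV round-trips through read/write", {
  tmp <- withr::local_tempdir()
  n <- 50
  set.seed(4)
  pu <- pileup(toy_snps(n), matrix(rpois(n * 4, 1), n, 4))
  path <- file.path(tmp, "p.tsv")
  write_pileup_tsv(pu, path)
  back <- read_pileup_tsv(path, pu$snps)
  expect_identical(unname(back$counts), unname(pu$counts))
})
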