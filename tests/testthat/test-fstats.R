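blocks_for <- function(freqs, size = 0.05) make_blocks(freqs$snps, size)

test_that("outgroup f3 matches its definition and the brute-force jackknife", {
  fr <- toy_freq_panel(200, seed = 1)
  bl <- blocks_for(fr)
  # A = B = Out at every site -> f3 = 0
  fr0 <- fr; fr0$p[, "A"] <- fr0$p[, "B"] <- fr0$p[, "Out"]
  expect_equal(f3_outgroup(fr0, "Out", "A", "B", bl)$estimate, 0)
  # p_out = 0, p_A = p_B = 1 -> f3 = 1
  fr1 <- fr
  fr1$p[, "Out"] <- 0; fr1$p[, "A"] <- fr1$p[, "B"] <- 1
  expect_equal(f3_outgroup(fr1, "Out", "A", "B", bl)$estimate, 1)

  # 200-site 5-block panel equals the per-site brute force incl. SE
  bl5 <- make_blocks(fr$snps, 0.3 / 5 + 1e-9)
  expect_identical(bl5$n_blocks, 5L)
  got <- f3_outgroup(fr, "Out", "A", "B", bl5)
  want <- bf_f3(fr$p[, "Out"], fr$p[, "A"], fr$p[, "B"], bl5$block)
  expect_equal(got$estimate, want$estimate, tolerance = 1e-14)
  expect_equal(got$se, want$se, tolerance = 1e-14)
  # symmetry is exact
  swap <- f3_outgroup(fr, "Out", "B", "A", bl5)
  expect_identical(swap$estimate, got$estimate)
  expect_identical(swap$se, got$se)
})

test_that("D statistic symmetries and brute-force equality hold", {
  fr <- toy_freq_panel(500, pops = c("W", "X", "Y", "Z"), seed = 2)
  bl <- blocks_for(fr)
  # Y = Z everywhere -> D = 0
  fr0 <- fr; fr0$p[, "Z"] <- fr0$p[, "Y"]
  expect_equal(d_stat(fr0, "W", "X", "Y", "Z", bl)$estimate, 0)
  # swapping Y and Z flips the sign exactly; so does swapping W and X
  d1 <- d_stat(fr, "W", "X", "Y", "Z", bl)
  d2 <- d_stat(fr, "W", "X", "Z", "Y", bl)
  d3 <- d_stat(fr, "X", "W", "Y", "Z", bl)
  d4 <- d_stat(fr, "X", "W", "Z", "Y", bl)
  expect_equal(d2$estimate, -d1$estimate, tolerance = 1e-14)
  expect_equal(d3$estimate, -d1$estimate, tolerance = 1e-14)
  expect_equal(d4$estimate, d1$estimate, tolerance = 1e-14)
  expect_equal(d2$se, d1$se, tolerance = 1e-12)
  # brute-force value and jackknife SE
  want <- bf_d(fr$p[, "W"], fr$p[, "X"], fr$p[, "Y"], fr$p[, "Z"],
               bl$block)
  expect_equal(d1$estimate, want$estimate, tolerance = 1e-14)
  expect_equal(d1$se, want$se, tolerance = 1e-14)
  # degenerate: all sites fixed -> denominator 0 -> error
  frf <- fr; frf$p[] <- 1
  expect_error(d_stat(frf, "W", "X", "Y", "Z", bl), "denominator")
})

test_that("X attracted to Z gives a significantly positive D", {
  # simulate excess sharing between X and Z on 500 sites
  set.seed(33)
  n <- 500
  anc <- runif(n, 0.2, 0.8)
  drift <- function(p, f) pmin(pmax(p + rnorm(n, 0, sqrt(f * p * (1 - p))),
                                    0.01), 0.99)
  shared <- drift(anc, 0.05)
  p <- cbind(W = drift(anc, 0.02), X = drift(shared, 0.02),
             Y = drift(anc, 0.05), Z = drift(shared, 0.02))
  snps <- toy_snps(n, span = 0.5)
  fr <- freqs_from_p(p, snps)
  d <- d_stat(fr, "W", "X", "Y", "Z", blocks_for(fr))
  expect_gt(d$estimate, 0)
  expect_gt(d$z, 3)
})

test_that("f3 scans rank candidates by shared drift", {
  fr <- toy_freq_panel(400, pops = c("Out", "T", "Close", "Far"), seed = 3)
  # Close is a noisy copy of the target, Far tracks the outgroup
  set.seed(9)
  fr$p[, "Close"] <- pmin(pmax(fr$p[, "T"] + rnorm(400, 0, 0.02), 0), 1)
  fr$p[, "Far"] <- pmin(pmax(fr$p[, "Out"] + rnorm(400, 0, 0.02), 0), 1)
  bl <- blocks_for(fr)
  scan <- outgroup_f3_scan(fr, "T", c("Far", "Close"), "Out", bl)
  expect_identical(scan$candidate, c("Close", "Far"))
  # single candidate -> single-row table
  expect_identical(nrow(outgroup_f3_scan(fr, "T", "Close", "Out", bl)), 1L)
  # a failing candidate is kept as a row with a reason
  fr2 <- fr; fr2$p[, "Far"] <- NA; fr2$n[, "Far"] <- 0
  scan2 <- outgroup_f3_scan(fr2, "T", c("Far", "Close"), "Out", bl)
  expect_identical(scan2$reason[scan2$candidate == "Far"],
                   "zero usable sites")

  # candidates branching at staggered depths along the target's lineage
  # recover the true proximity order (deeper branch point = higher f3)
  chain <- admixture_graph(data.frame(
    child = c("Out", "A1", "A2", "A3", "A4", "T",
              "C1", "C2", "C3", "C4"),
    parent = c("root", "root", "A1", "A2", "A3", "A4",
               "A1", "A2", "A3", "A4"),
    f = c(0.1, rep(0.05, 4), 0.02, rep(0.05, 4))), outgroup = "Out")
  p4 <- simulate_frequencies(chain, 4000, seed = 14)
  fr3 <- freqs_from_p(p4[, c("Out", "T", paste0("C", 1:4))],
                      toy_snps(4000, span = 1))
  scan3 <- outgroup_f3_scan(fr3, "T", paste0("C", 1:4), "Out",
                            blocks_for(fr3))
  expect_identical(scan3$candidate, paste0("C", 4:1))
})

test_that("pairwise-f3 regression flags constructed deviations only", {
  fr <- toy_freq_panel(600, pops = c("Out", "RA", "RB", paste0("C", 1:8)),
                       seed = 4)
  # make RB's f3 vector a linear transform of RA's by construction:
  # every candidate equally related to both axes
  bl <- blocks_for(fr)
  scanA <- outgroup_f3_scan(fr, "RA", paste0("C", 1:8), "Out", bl)
  # scanB identical to scanA -> slope 1, intercept 0, zero residuals
  reg0 <- pairwise_f3_regression(scanA, scanA, bl)
  expect_equal(attr(reg0, "slope"), 1, tolerance = 1e-10)
  expect_equal(attr(reg0, "intercept"), 0, tolerance = 1e-12)
  expect_true(all(abs(reg0$residual) < 1e-12))
  expect_equal(sum(reg0$residual), 0, tolerance = 1e-12)

  scanB <- outgroup_f3_scan(fr, "RB", paste0("C", 1:8), "Out", bl)
  reg <- pairwise_f3_regression(scanA, scanB, bl)
  expect_equal(sum(reg$residual), 0, tolerance = 1e-12)

  # perturb one candidate upward on the y axis only: largest + residual
  frp <- fr
  frp$p[, "C3"] <- pmin(frp$p[, "C3"] + 0.1 * (frp$p[, "RB"] - 0.5) + 0.05,
                        1)
  scanBp <- outgroup_f3_scan(frp, "RB", paste0("C", 1:8), "Out", bl)
  scanAp <- outgroup_f3_scan(frp, "RA", paste0("C", 1:8), "Out", bl)
  regp <- pairwise_f3_regression(scanAp, scanBp, bl)
  expect_lt(nrow(regp[regp$residual > regp$residual[regp$candidate == "C3"], ]),
            1)
  expect_error(pairwise_f3_regression(scanA, scanA, bl, z_threshold = 3),
               NA)
  expect_error(
    pairwise_f3_regression(
      outgroup_f3_scan(fr, "RA", c("C1", "C2"), "Out", bl),
      outgroup_f3_scan(fr, "RB", c("C1", "C2"), "Out", bl), bl),
    "at least 3")
})

test_that("jackknife residual SE tracks a site-bootstrap SE", {
  fr <- toy_freq_panel(800, pops = c("Out", "RA", "RB", paste0("C", 1:6)),
                       seed = 6)
  bl <- blocks_for(fr, 0.003)
  scanA <- outgroup_f3_scan(fr, "RA", paste0("C", 1:6), "Out", bl)
  scanB <- outgroup_f3_scan(fr, "RB", paste0("C", 1:6), "Out", bl)
  reg <- pairwise_f3_regression(scanA, scanB, bl)

  # independent oracle: bootstrap sites, recompute both scans + regression
  set.seed(77)
  nboot <- 200
  res_boot <- matrix(NA_real_, nboot, 6)
  for (b in seq_len(nboot)) {
    idx <- sample.int(800, replace = TRUE)
    x <- vapply(paste0("C", 1:6), function(cc)
      mean((fr$p[idx, "Out"] - fr$p[idx, "RA"]) *
             (fr$p[idx, "Out"] - fr$p[idx, cc])), 0)
    y <- vapply(paste0("C", 1:6), function(cc)
      mean((fr$p[idx, "Out"] - fr$p[idx, "RB"]) *
             (fr$p[idx, "Out"] - fr$p[idx, cc])), 0)
    res_boot[b, ] <- stats::lm.fit(cbind(1, x), y)$residuals
  }
  boot_se <- apply(res_boot, 2, sd)
  m <- match(paste0("C", 1:6), reg$candidate)
  ratio <- reg$residual_se[m] / boot_se
  expect_true(all(ratio > 0.75 & ratio < 1.35))
})

test_that("rank concordance handles ties and degenerate input", {
  expect_equal(rank_concordance(1:5, 1:5), 1)
  expect_equal(rank_concordance(1:5, 5:1), -1)
  # 10-element vector with one tie, against hand-ranked Spearman
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  b <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  ra <- rank(a); rb <- rank(b)
  hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(rank_concordance(a, b), hand, tolerance = 1e-12)
  expect_true(is.na(rank_concordance(rep(1, 5), 1:5)))
})
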