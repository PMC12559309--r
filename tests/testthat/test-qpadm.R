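# Small frequency panels with enough structure for admixture modelling:
# a drifted chain plus two or three sources mixed into a target.
qp_panel <- function(n = 4000, seed = 5, alpha = c(0.6, 0.4),
                     third = 0, noise = 0) {
  graph <- admixture_graph(data.frame(
    child = c("Out", "E", "R1", "R2", "R3", "R4", "S1anc", "S2anc",
              "S3anc", "S1", "S2", "S3"),
    parent = c("root", "root", "E", "E", "E", "E", "R1", "R3",
               "R4", "S1anc", "S2anc", "S3anc"),
    f = c(0.2, 0.02, 0.05, 0.05, 0.05, 0.05, 0.03, 0.03,
          0.03, 0.04, 0.04, 0.04)), outgroup = "Out")
  p <- simulate_frequencies(graph, n, seed = seed)
  w <- c((1 - third) * alpha, third)
  tgt <- as.numeric(p[, c("S1", "S2", "S3")] %*% w)
  if (noise > 0) {
    set.seed(seed + 1)
    tgt <- pmin(pmax(tgt + rnorm(n, 0, noise), 0.001), 0.999)
  }
  p <- cbind(p, Target = tgt)
  fr <- freqs_from_p(p[, c("Out", "R1", "R2", "R3", "R4",
                           "S1", "S2", "S3", "Target")],
                     toy_snps(n, span = 2))
  list(freqs = fr, blocks = make_blocks(fr$snps, 0.05), truth = w)
}

test_that("model specification enforces label disjointness", {
  expect_error(admixture_model("T", c("A", "T"), c("R1", "R2", "R3")),
               "target")
  expect_error(admixture_model("T", c("A", "R1"), c("R1", "R2", "R3")),
               "disjoint")
  expect_error(admixture_model("T", c("A", "B"), c("R1", "R2")),
               "length")
})

test_that("f4 profiles match brute force and are linear in frequencies", {
  pan <- qp_panel()
  fr <- pan$freqs
  # left = base right -> zero vector
  pr0 <- f4_profile(fr, "R1", c("R1", "R2", "R3"), pan$blocks)
  expect_true(all(abs(pr0$estimate) < 1e-15))
  # 2 rights -> the single f4 by per-site brute force
  pr <- f4_profile(fr, "S1", c("R1", "R2"), pan$blocks)
  bf <- mean((fr$p[, "S1"] - fr$p[, "R1"]) *
               (fr$p[, "R2"] - fr$p[, "R1"]))
  expect_equal(unname(pr$estimate), bf, tolerance = 1e-14)
  # linearity: profile of a frequency mixture = mixture of profiles
  frm <- fr
  frm$p <- cbind(fr$p, Mix = 0.3 * fr$p[, "S1"] + 0.7 * fr$p[, "S2"])
  frm$n <- cbind(fr$n, Mix = fr$n[, "S1"])
  rights <- c("R1", "R2", "R3", "R4")
  pm <- f4_profile(frm, "Mix", rights, pan$blocks)$estimate
  p1 <- f4_profile(fr, "S1", rights, pan$blocks)$estimate
  p2 <- f4_profile(fr, "S2", rights, pan$blocks)$estimate
  expect_equal(pm, 0.3 * p1 + 0.7 * p2, tolerance = 1e-12)
})

test_that("a target identical to one source is recovered degenerately", {
  pan <- qp_panel()
  fr <- pan$freqs
  fr$p <- cbind(fr$p, Self = fr$p[, "S1"])
  fr$n <- cbind(fr$n, Self = fr$n[, "S1"])
  # the degenerate covariance is expected to need the ridge here
  expect_warning(
    fit <- fit_admixture(admixture_model("Self", c("S1", "S2"),
                                         c("R1", "R2", "R3", "R4")),
                         fr, pan$blocks),
    "ridge")
  expect_lt(abs(fit$weights[["S1"]] - 1), 1e-6)
  expect_lt(fit$statistic, 1e-10)
  expect_gt(fit$p_value, 0.999)
})

test_that("weights sum to one exactly and transform with the model", {
  pan <- qp_panel(alpha = c(0.55, 0.45), third = 0.25, noise = 0.02)
  rights <- c("R1", "R2", "R3", "R4", "Out")
  m <- admixture_model("Target", c("S1", "S2", "S3"), rights)
  fit <- fit_admixture(m, pan$freqs, pan$blocks)
  expect_identical(sum(fit$weights), 1)          # constraint, exact
  # permuting sources permutes weights identically
  mp <- admixture_model("Target", c("S3", "S1", "S2"), rights)
  fitp <- fit_admixture(mp, pan$freqs, pan$blocks)
  expect_equal(fitp$weights[names(fit$weights)], fit$weights,
               tolerance = 1e-8)
  # T invariant to reordering the non-base rights
  mr <- admixture_model("Target", c("S1", "S2", "S3"),
                        c("R1", "Out", "R4", "R2", "R3"))
  fitr <- fit_admixture(mr, pan$freqs, pan$blocks)
  expect_equal(fitr$statistic, fit$statistic, tolerance = 1e-8)
  expect_equal(fitr$weights, fit$weights, tolerance = 1e-8)
})

test_that("noise-free mixtures are recovered to high precision", {
  pan <- qp_panel(alpha = c(0.6, 0.4))
  fit <- fit_admixture(admixture_model("Target", c("S1", "S2"),
                                       c("R1", "R2", "R3", "R4")),
                       pan$freqs, pan$blocks)
  # the target is an exact frequency mixture: weights recovered closely
  # and the model fits essentially perfectly
  # exact interpolation: truth recovered and the fit is perfect
  expect_lt(abs(fit$weights[["S1"]] - 0.6), 1e-6)
  expect_true(fit$feasible)
  expect_identical(fit$statistic, 0)
  expect_identical(fit$p_value, 1)
})

test_that("nested comparisons are structural: dT >= 0, trivial cases exact", {
  pan <- qp_panel(alpha = c(0.55, 0.45), third = 0.25, noise = 0.02)
  rights <- c("R1", "R2", "R3", "R4", "Out")
  full <- fit_admixture(admixture_model("Target", c("S1", "S2", "S3"),
                                        rights), pan$freqs, pan$blocks)
  red <- fit_admixture(admixture_model("Target", c("S1", "S2"), rights),
                       pan$freqs, pan$blocks, sites = full$sites)
  nst <- nested_model_test(full, red)
  expect_gte(nst$delta_T, 0)
  expect_identical(nst$df, 1L)
  # a noise-free 25% third source is decisively detected
  expect_lt(nst$p_value, 1e-6)
  # non-nested and mismatched models error
  other <- fit_admixture(admixture_model("Target", c("S1", "S3"), rights),
                         pan$freqs, pan$blocks, sites = full$sites)
  expect_error(nested_model_test(red, other), "subset")
  red2 <- fit_admixture(admixture_model("Target", c("S1", "S2"), rights),
                        pan$freqs, pan$blocks)
  expect_error(nested_model_test(full, full), "identical")
})

test_that("downsampling experiment runs per-rep and summarises counts", {
  sc <- okhotsk_scenario(n_snps = 8000, chrom_lengths_M = rep(1, 8),
                         alpha = c(Jomon = 0.2, Kamchatka = 0.2,
                                   Amur = 0.6),
                         coverage = 4, panel_size = 20)
  ds <- simulate_dataset(sc, seed = 31)
  m2 <- admixture_model("Target", c("Jomon", "Kamchatka"), sc$rights)
  m3 <- admixture_model("Target", c("Jomon", "Kamchatka", "Amur"),
                        sc$rights)
  rep0 <- downsampling_experiment(ds$target_pileups, ds$panel_freqs,
                                  m2, m3, target_cov = 1, ds$blocks,
                                  n_reps = 0, seed = 1)
  expect_identical(nrow(rep0$reps), 0L)
  rep3 <- downsampling_experiment(ds$target_pileups, ds$panel_freqs,
                                  m2, m3, target_cov = 1, ds$blocks,
                                  n_reps = 3, seed = 1)
  expect_identical(nrow(rep3$reps), 3L)
  expect_true(all(rep3$reps$error == ""))
  expect_true(all(rep3$reps$p_nested >= 0 & rep3$reps$p_nested <= 1))
  expect_lte(rep3$n_adequate_full, 3L)
  # per-rep seeds are recorded and derived deterministically
  expect_identical(rep3$reps$seed,
                   vapply(1:3, function(i) derive_seed(1, i), 0L))
  # thinning to the original coverage reproduces fits up to recall noise
  cur <- mean(rowSums(ds$target_pileups$counts))
  repid <- downsampling_experiment(ds$target_pileups, ds$panel_freqs,
                                   m2, m3, target_cov = cur, ds$blocks,
                                   n_reps = 2, seed = 2)
  base3 <- fit_admixture(m3, ds$freqs, ds$blocks)
  expect_lt(max(abs(repid$reps$w_Amur - base3$weights[["Amur"]])),
            6 * base3$se[["Amur"]])
})
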