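# End-to-end orchestration: the standard analysis scaffold for placing an
# ancient target against reference panels -- outgroup-f3 scan, PCA
# projection, D scans, pairwise-f3 regression, qpAdm models with nested
# tests, transversion-only replication, the coverage-downsampling
# experiment and admixture dating -- with per-stage error containment and a
# machine-readable summary.

#' Assemble an analysis configuration
#'
#' @param data Either a [simulate_dataset()] result or a list with
#'   `geno_prefix` (EIGENSTRAT triplet), optional `pseudo_haploid`
#'   (individual ids) and optional `pileup_tsv` for the target.
#' @param target Target population label.
#' @param outgroup Outgroup label.
#' @param candidates Candidate labels for the f3/D scans.
#' @param rights Right populations for qpAdm (base right first).
#' @param models Named list of source-label vectors, e.g.
#'   `list(two_way = c("Jomon", "Kamchatka"), three_way = c(...))`. Nested
#'   tests are run for every pair where one source set contains another.
#' @param d_pair Optional length-2 labels (A, B) for D(out, X; A, B) scans.
#' @param f3_pair Optional length-2 labels for the pairwise-f3 regression
#'   axes.
#' @param dating_sources Length-2 source labels for admixture dating, or
#'   `NULL` to skip.
#' @param generation_time,sample_age_BP Calendar conversion parameters.
#' @param downsampling `NULL`, or list(target_cov, n_reps).
#' @param site_filter "all" or "transversions" for the primary pass.
#' @param block_size Jackknife block size in Morgans.
#' @param seed Master seed for the stochastic stages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(data, target, outgroup, candidates, rights,
                            models, d_pair = NULL, f3_pair = NULL,
                            dating_sources = NULL, generation_time = 30,
                            sample_age_BP = 0, downsampling = NULL,
                            site_filter = c("all", "transversions"),
                            block_size = 0.05, seed = 1) {
  structure(list(data = data, target = target, outgroup = outgroup,
                 candidates = candidates, rights = rights, models = models,
                 d_pair = d_pair, f3_pair = f3_pair,
                 dating_sources = dating_sources,
                 generation_time = generation_time,
                 sample_age_BP = sample_age_BP,
                 downsampling = downsampling,
                 site_filter = match.arg(site_filter),
                 block_size = block_size, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' File-based configs reference data on disk: keys `geno_prefix`,
#' `pseudo_haploid`, `pileup_tsv` under `data`, plus the scalar/list fields
#' of [analysis_config()].
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, c(list(data = y$data),
                             y[setdiff(names(y), "data")]))
}

resolve_data <- function(config) {
  d <- config$data
  if (inherits(d, "sim_dataset")) {
    return(list(freqs = d$freqs, snps = d$snps,
                blocks = make_blocks(d$snps, config$block_size),
                pileups = d$target_pileups, p_true = d$p_true,
                panel_freqs = d$panel_freqs))
  }
  gm <- read_eigenstrat(d$geno_prefix,
                        pseudo_haploid = d$pseudo_haploid %||% character())
  pileups <- if (!is.null(d$pileup_tsv)) read_pileup_tsv(d$pileup_tsv, gm$snps)
  freqs <- allele_frequencies(gm)
  panel <- gm[, gm$individuals$population != config$target]
  list(freqs = freqs, snps = gm$snps,
       blocks = make_blocks(gm$snps, config$block_size),
       pileups = pileups, matrix = gm,
       panel_freqs = allele_frequencies(panel))
}

stage_run <- function(stages, name, expr) {
  stages[[name]] <- tryCatch(
    c(list(status = "ok"), expr),
    error = function(e) list(status = "error",
                             message = conditionMessage(e)))
  stages
}

stage_skip <- function(stages, name, why) {
  stages[[name]] <- list(status = "skipped", message = why)
  stages
}

#' Run the full analysis scaffold
#'
#' Executes, in order: (1) outgroup-f3 scan of the target; (2) PCA fit and
#' least-squares projection of the target; (3) D(out, X; A, B) scan;
#' (4) pairwise-f3 regression; (5) qpAdm model fits with nested tests;
#' (6) transversion-only replication of the scans and models plus rank
#' concordance with the all-site results; (7) the coverage-downsampling
#' experiment (if pileups and settings are available); (8) admixture-LD
#' dating with calendar conversion. Stage failures are recorded and later
#' independent stages still run.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory for TSV tables and the JSON summary.
#' @return An `analysis_report`: list of stage blocks plus the config echo.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  dat <- resolve_data(config)
  freqs <- dat$freqs; blocks <- dat$blocks
  if (config$site_filter == "transversions") {
    keep <- !is_transition(dat$snps$ref, dat$snps$alt)
    freqs <- subset_freqs(freqs, keep)
    blocks <- make_blocks(freqs$snps, config$block_size)
  }
  st <- list()

  st <- stage_run(st, "f3_scan", {
    scan <- outgroup_f3_scan(freqs, config$target, config$candidates,
                             config$outgroup, blocks)
    list(table = as.data.frame(scan), scan = scan)
  })

  st <- stage_run(st, "pca", {
    pc <- pipeline_pca(dat, config)
    list(coords = pc$coords, target_coords = pc$target,
         eigenvalues = pc$eigenvalues)
  })

  if (is.null(config$d_pair)) {
    st <- stage_skip(st, "d_scan", "no d_pair configured")
  } else st <- stage_run(st, "d_scan", {
    tab <- d_scan(freqs, config$outgroup, config$candidates,
                  config$d_pair[1], config$d_pair[2], blocks)
    list(table = tab)
  })

  if (is.null(config$f3_pair)) {
    st <- stage_skip(st, "pairwise_f3", "no f3_pair configured")
  } else st <- stage_run(st, "pairwise_f3", {
    sa <- outgroup_f3_scan(freqs, config$f3_pair[1], config$candidates,
                           config$outgroup, blocks)
    sb <- outgroup_f3_scan(freqs, config$f3_pair[2], config$candidates,
                           config$outgroup, blocks)
    reg <- pairwise_f3_regression(sa, sb, blocks)
    list(table = as.data.frame(reg), slope = attr(reg, "slope"),
         intercept = attr(reg, "intercept"))
  })

  st <- stage_run(st, "qpadm", {
    fit_models(freqs, blocks, config)
  })

  st <- stage_run(st, "transversion_replication", {
    keep <- !is_transition(freqs$snps$ref, freqs$snps$alt)
    ftv <- subset_freqs(freqs, keep)
    btv <- make_blocks(ftv$snps, config$block_size)
    scan_tv <- outgroup_f3_scan(ftv, config$target, config$candidates,
                                config$outgroup, btv)
    rho <- if (identical(st$f3_scan$status, "ok")) {
      full <- st$f3_scan$table
      m <- match(full$candidate, scan_tv$candidate)
      rank_concordance(full$estimate, scan_tv$estimate[m])
    } else NA_real_
    out <- list(f3_table = as.data.frame(scan_tv),
                spearman_rho_f3 = rho,
                qpadm = fit_models(ftv, btv, config))
    if (!is.null(config$d_pair)) {
      dtv <- d_scan(ftv, config$outgroup, config$candidates,
                    config$d_pair[1], config$d_pair[2], btv)
      rho_d <- if (identical(st$d_scan$status, "ok"))
        rank_concordance(st$d_scan$table$estimate,
                         dtv$estimate[match(st$d_scan$table$candidate,
                                            dtv$candidate)])
      else NA_real_
      out$d_table <- dtv
      out$spearman_rho_d <- rho_d
    }
    out
  })

  if (is.null(dat$pileups) || is.null(config$downsampling)) {
    st <- stage_skip(st, "downsampling",
                     "no pileups or downsampling settings provided")
  } else st <- stage_run(st, "downsampling", {
    ms <- config$models
    sizes <- lengths(ms)
    full_name <- names(ms)[which.max(sizes)]
    red_name <- names(ms)[which.min(sizes)]
    rep_ <- downsampling_experiment(
      dat$pileups, dat$panel_freqs,
      admixture_model(config$target, ms[[red_name]], config$rights),
      admixture_model(config$target, ms[[full_name]], config$rights),
      target_cov = config$downsampling$target_cov, blocks = dat$blocks,
      n_reps = config$downsampling$n_reps, seed = config$seed)
    list(report = rep_, n_adequate_full = rep_$n_adequate_full,
         n_adequate_reduced = rep_$n_adequate_reduced,
         n_nested_significant = rep_$n_nested_significant)
  })

  if (is.null(config$dating_sources)) {
    st <- stage_skip(st, "dating", "no dating sources configured")
  } else st <- stage_run(st, "dating", {
    tc <- target_calls_from(dat, config)
    w <- snp_weights(freqs, config$dating_sources[1],
                     config$dating_sources[2])
    curve <- ancestry_cov_curve(tc, w, freqs$snps)
    fit <- fit_decay(curve)
    cal <- to_calendar(fit, config$generation_time, config$sample_age_BP)
    list(t = fit$t, se_t = fit$se_t, A0 = fit$A0, c = fit$c,
         years_BP = cal$years_BP, se_years = cal$se_years,
         fit = fit, calendar = cal)
  })

  report <- structure(list(stages = st, seed = config$seed,
                           target = config$target),
                      class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis report for target %s (seed %d)\n", x$target,
              x$seed))
  for (nm in names(x$stages))
    cat(sprintf("  %-26s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}

# D(out, X; A, B) over candidates, errors kept as rows.
d_scan <- function(freqs, out, candidates, A, B, blocks) {
  rows <- lapply(setdiff(candidates, c(A, B)), function(x) {
    r <- tryCatch(d_stat(freqs, out, x, A, B, blocks),
                  error = function(e) conditionMessage(e))
    if (is.character(r))
      data.frame(candidate = x, estimate = NA_real_, se = NA_real_,
                 z = NA_real_, n_sites = NA_integer_, reason = r)
    else data.frame(candidate = x, estimate = r$estimate, se = r$se,
                    z = r$z, n_sites = r$n_sites, reason = "")
  })
  do.call(rbind, rows)
}

fit_models <- function(freqs, blocks, config) {
  fits <- list()
  for (nm in names(config$models)) {
    fits[[nm]] <- tryCatch(
      fit_admixture(admixture_model(config$target, config$models[[nm]],
                                    config$rights), freqs, blocks),
      error = function(e) list(status = "error",
                               message = conditionMessage(e)))
  }
  nested <- list()
  nms <- names(config$models)
  for (i in nms) for (j in nms) {
    if (i == j || !inherits(fits[[i]], "qpadm_fit") ||
        !inherits(fits[[j]], "qpadm_fit")) next
    si <- config$models[[i]]; sj <- config$models[[j]]
    if (length(sj) < length(si) && all(sj %in% si)) {
      red <- fit_admixture(admixture_model(config$target, sj,
                                           config$rights),
                           freqs, blocks, sites = fits[[i]]$sites)
      nested[[paste(i, "vs", j)]] <-
        tryCatch(nested_model_test(fits[[i]], red),
                 error = function(e) list(status = "error",
                                          message = conditionMessage(e)))
    }
  }
  summ <- lapply(fits, function(f)
    if (inherits(f, "qpadm_fit"))
      list(weights = as.list(f$weights), se = as.list(f$se),
           T = f$statistic, df = f$df, P = f$p_value,
           feasible = f$feasible, n_sites = f$n_sites)
    else f)
  list(fits = fits, nested = nested, summary = summ,
       nested_p = lapply(nested, function(x)
         if (inherits(x, "qpadm_nested")) x$p_value else NA_real_))
}

pipeline_pca <- function(dat, config) {
  if (!is.null(dat$matrix)) {
    panel <- dat$matrix[, dat$matrix$individuals$population != config$target]
    model <- fit_pca(panel, n_components = 2)
    ti <- which(dat$matrix$individuals$population == config$target)
    tcoords <- lapply(ti, function(j)
      project_sample(model, dat$matrix$calls[model_sites_full(model,
                                                              panel), j]))
    names(tcoords) <- dat$matrix$individuals$ind_id[ti]
  } else {
    pops <- colnames(dat$p_true)
    pops <- setdiff(pops, c("root", grep("^N[0-9]|^C", pops, value = TRUE)))
    np <- stats::setNames(rep(10L, length(pops)), pops)
    panel <- simulate_panel_matrix(dat$p_true, dat$snps, np,
                                   seed = derive_seed(config$seed, 90))
    model <- fit_pca(panel, n_components = 2)
    tc <- target_calls_from(dat, config)
    tcoords <- list(Target = project_sample(model, tc))
  }
  list(coords = model$coords, target = tcoords,
       eigenvalues = model$eigenvalues, model = model)
}

# project_sample indexes into the full site list the model was fit on; for
# a matrix-based pipeline the panel and sample share that list already.
model_sites_full <- function(model, panel) seq_len(nrow(panel$snps))

target_calls_from <- function(dat, config) {
  if (!is.null(dat$freqs) && config$target %in% colnames(dat$freqs$p)) {
    p <- dat$freqs$p[, config$target]
    n <- dat$freqs$n[, config$target]
    if (all(n %in% c(0, 1))) return(as.integer(round(p * 2)))
  }
  if (!is.null(dat$matrix)) {
    j <- which(dat$matrix$individuals$population == config$target)[1]
    return(dat$matrix$calls[, j])
  }
  stop("cannot recover per-site target calls from the configured data")
}

subset_freqs <- function(freqs, keep) {
  freq_table(freqs$p[keep, , drop = FALSE], freqs$n[keep, , drop = FALSE],
             freqs$snps[keep, , drop = FALSE])
}

#' Write an analysis report to disk
#'
#' TSV tables per stage plus `summary.json` with every statistic, SE, Z and
#' P the run produced. The JSON's top-level shape is described by the
#' schema shipped under `inst/schema/report-schema.json`.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary JSON path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  if (identical(st$f3_scan$status, "ok"))
    write.table(st$f3_scan$table, file.path(out_dir, "f3_scan.tsv"),
                quote = FALSE, row.names = FALSE, sep = "\t")
  if (identical(st$d_scan$status, "ok"))
    write.table(st$d_scan$table, file.path(out_dir, "d_scan.tsv"),
                quote = FALSE, row.names = FALSE, sep = "\t")
  json <- summarize_report(report)
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# JSON-safe stage summary (drops heavyweight fit objects).
summarize_report <- function(report) {
  st <- report$stages
  strip <- function(x) {
    if (inherits(x, c("qpadm_fit", "qpadm_nested", "downsampling_report",
                      "date_fit", "calendar_date", "f3_scan", "pca_model",
                      "ancestry_cov_curve")))
      return(NULL)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) {
      out <- lapply(x, strip)
      return(out[!vapply(out, is.null, TRUE)])
    }
    x
  }
  list(target = report$target, seed = report$seed,
       stages = lapply(st, strip))
}

#' Check a summary-JSON report for the required stage blocks
#'
#' Lightweight structural validation against the shipped schema: the
#' summary must contain every stage key, each with a `status` field.
#'
#' @param json Parsed summary (list) or a path to `summary.json`.
#' @return `TRUE` (invisibly) or an error describing the missing pieces.
#' @export
validate_report <- function(json) {
  if (is.character(json)) json <- jsonlite::read_json(json)
  need <- c("f3_scan", "pca", "d_scan", "pairwise_f3", "qpadm",
            "transversion_replication", "downsampling", "dating")
  miss <- setdiff(need, names(json$stages))
  if (length(miss))
    stop("summary is missing stage blocks: ", paste(miss, collapse = ", "))
  nost <- need[!vapply(json$stages[need], function(s)
    !is.null(s$status), TRUE)]
  if (length(nost))
    stop("stage blocks without status: ", paste(nost, collapse = ", "))
  invisible(TRUE)
}
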