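# A ready-made study scenario: an outgroup, six right-like reference
# populations, three admixture sources (a Jomon-like island lineage, a
# Kamchatka-like northeast lineage and an Amur-like continental lineage)
# and a low-coverage pseudo-haploid target admixed a couple of dozen
# generations before sampling. Drift amounts are set so outgroup-f3 values
# land on the few-percent scale typical of deep-outgroup human panels.

#' The default northeast-Asia-shaped simulation scenario
#'
#' Encodes the population structure the package's inference machinery
#' assumes: `Outgroup` is a deep African-like outgroup; `Ami`, `Dai`
#' (southern East Asians), `Aleut` (Beringian, sharing drift with the
#' Kamchatka lineage), `Yakut` (Siberian, sharing drift with the Amur
#' lineage), `Mixe` and `Papuan` serve as right populations; `Jomon`,
#' `Kamchatka` and `Amur` are the admixture sources; `Target` is a
#' two-ancestry Jomon/Kamchatka tract mosaic with an optional Amur
#' frequency-mixture component, sequenced to low Poisson coverage with
#' terminal deamination and called pseudo-haploid.
#'
#' @param n_snps Number of sites (default 50000).
#' @param chrom_lengths_M Chromosome lengths in Morgans
#'   (default 22 x 1 M).
#' @param alpha Named length-3 proportions for Jomon, Kamchatka, Amur
#'   (default c(0.46, 0.40, 0.14); set the third to 0 for a two-way
#'   target).
#' @param t_admix Generations since the Jomon/Kamchatka admixture
#'   (default 25).
#' @param coverage Target mean sequencing coverage (default 1).
#' @param damage Terminal deamination rate delta (default 0.02; transition
#'   sites carry the artefact, which is what transversion replication
#'   guards against).
#' @param panel_size Diploid individuals per reference population whose
#'   allele counts form the panel frequencies (default 15).
#' @param read_len Read length in bp (default 70).
#' @param block_size Jackknife block size in Morgans (default 0.05).
#' @return A `scenario` list (graph, rights, sources, outgroup and all
#'   parameters) for [simulate_dataset()].
#' @export
okhotsk_scenario <- function(n_snps = 50000, chrom_lengths_M = rep(1, 22),
                             alpha = c(Jomon = 0.46, Kamchatka = 0.40,
                                       Amur = 0.14),
                             t_admix = 25, coverage = 1, damage = 0.02,
                             panel_size = 15, read_len = 70,
                             block_size = 0.05) {
  stopifnot(length(alpha) == 3, abs(sum(alpha) - 1) < 1e-12,
            all(alpha >= 0))
  names(alpha) <- names(alpha) %||% c("Jomon", "Kamchatka", "Amur")
  edges <- data.frame(
    child  = c("Outgroup", "N1", "Papuan", "N2", "Mixe", "N3", "N4",
               "Csouth", "Cnorth", "Ami", "Dai", "Jomon", "N6", "Amur",
               "Yakut", "N5", "Kamchatka", "Aleut"),
    parent = c("root", "root", "N1", "N1", "N2", "N2", "N3",
               "N4", "N4", "Csouth", "Csouth", "Csouth", "Cnorth", "N6",
               "N6", "Cnorth", "N5", "N5"),
    f      = c(0.20, 0.02, 0.15, 0.02, 0.08, 0.01, 0.01,
               0.02, 0.02, 0.05, 0.05, 0.10, 0.04, 0.05,
               0.04, 0.03, 0.07, 0.06),
    stringsAsFactors = FALSE)
  graph <- admixture_graph(edges, outgroup = "Outgroup")
  structure(list(
    graph = graph, n_snps = n_snps, chrom_lengths_M = chrom_lengths_M,
    alpha = alpha, t_admix = t_admix, coverage = coverage, damage = damage,
    panel_size = panel_size, read_len = read_len, block_size = block_size,
    outgroup = "Outgroup",
    rights = c("Ami", "Dai", "Aleut", "Mixe", "Yakut", "Papuan"),
    sources = names(alpha), target = "Target"),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: %d snps on %d chromosomes; target = %s at t = %g gen, %gx coverage\n",
    x$n_snps, length(x$chrom_lengths_M),
    paste(sprintf("%.2f %s", x$alpha, names(x$alpha)), collapse = " + "),
    x$t_admix, x$coverage))
  invisible(x)
}

#' Simulate a full dataset from a scenario
#'
#' Runs the whole generator: graph frequencies, finite reference panels
#' (binomial allele counts of `panel_size` diploids per population -- the
#' sufficient statistic of simulating the individuals), the admixed
#' target's tract mosaic and diploid genotypes, Poisson-coverage damaged
#' reads and the pseudo-haploid recall. Identical seeds give bit-identical
#' datasets; the truth record carries everything needed to regenerate.
#'
#' @param scenario An [okhotsk_scenario()]-style scenario.
#' @param seed Integer master seed; internal stages use seeds derived with
#'   [derive_seed()].
#' @return A `sim_dataset` list: `snps`, `blocks`, `p_true` (node
#'   frequencies), `panel_freqs` (reference `allele_freq_table`), `tracts`,
#'   `target_genotype` (diploid truth), `target_pileups`, `target_calls`
#'   (pseudo-haploid), `freqs` (panel plus the called target), `truth`.
#' @export
simulate_dataset <- function(scenario, seed = 1) {
  sc <- scenario
  snps <- uniform_snp_map(sc$n_snps, sc$chrom_lengths_M)
  p_true <- simulate_frequencies(sc$graph, sc$n_snps,
                                 seed = derive_seed(seed, 1))
  ref_pops <- c(sc$outgroup, sc$rights, sc$sources)
  panel_freqs <- with_seed(derive_seed(seed, 2), {
    cnt <- vapply(ref_pops, function(pop)
      rbinom(sc$n_snps, 2L * sc$panel_size, p_true[, pop]), numeric(sc$n_snps))
    n <- matrix(2 * sc$panel_size, sc$n_snps, length(ref_pops),
                dimnames = list(NULL, ref_pops))
    freq_table(cnt / n, n, snps)
  })
  a <- sc$alpha
  jk <- a[1] + a[2]
  tract_alpha <- if (jk > 0) c(a[1], a[2]) / jk else c(0.5, 0.5)
  tracts <- list(
    simulate_tracts(tract_alpha, sc$t_admix, sc$chrom_lengths_M,
                    seed = derive_seed(seed, 3)),
    simulate_tracts(tract_alpha, sc$t_admix, sc$chrom_lengths_M,
                    seed = derive_seed(seed, 4)))
  geno <- simulate_individual(
    p_true, snps, ancestry = tracts, sources = names(a)[1:2], ploidy = 2,
    mix_with = if (a[3] > 0) names(a)[3] else NULL, mix_beta = a[3],
    seed = derive_seed(seed, 5))
  pup <- simulate_reads(geno, snps, sc$coverage, delta = sc$damage,
                        read_len = sc$read_len, seed = derive_seed(seed, 6))
  calls <- pseudo_haploid_call(pup, seed = derive_seed(seed, 7))
  freqs <- add_target_freqs(panel_freqs, sc$target, calls)
  structure(list(
    snps = snps, blocks = make_blocks(snps, sc$block_size),
    p_true = p_true, panel_freqs = panel_freqs, tracts = tracts,
    target_genotype = geno, target_pileups = pup, target_calls = calls,
    freqs = freqs,
    truth = list(alpha = a, t_admix = sc$t_admix, seed = seed,
                 coverage = sc$coverage, damage = sc$damage,
                 panel_size = sc$panel_size)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d sites, %d reference populations + target (%.1f%% called)\n",
    nrow(x$snps), ncol(x$panel_freqs$p),
    100 * mean(!is.na(x$target_calls))))
  invisible(x)
}

#' Materialise simulated individuals as a genotype matrix
#'
#' Draws diploid individuals per population from simulated frequencies;
#' used where the analysis needs a real panel (PCA, EIGENSTRAT round-trips,
#' the pipeline) rather than just frequencies.
#'
#' @param p_true Frequency matrix from [simulate_frequencies()].
#' @param snps Matching SNP table.
#' @param pops Named integer vector: individuals per population.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] of unrelated diploid individuals.
#' @export
simulate_panel_matrix <- function(p_true, snps, pops, seed = NULL) {
  with_seed(seed, {
    cols <- list(); ids <- character(); popl <- character()
    for (pop in names(pops)) {
      for (i in seq_len(pops[[pop]])) {
        cols[[length(cols) + 1L]] <-
          as.integer(rbinom(nrow(snps), 2L, p_true[, pop]))
        ids <- c(ids, sprintf("%s_%d", pop, i))
        popl <- c(popl, pop)
      }
    }
    ind <- data.frame(ind_id = ids, sex = "U", population = popl,
                      pseudo_haploid = FALSE, stringsAsFactors = FALSE)
    genotype_matrix(snps, ind, do.call(cbind, cols))
  })
}

#' Append a pseudo-haploid individual to a genotype matrix
#'
#' @param panel A [genotype_matrix()].
#' @param ind_id Individual id.
#' @param population Population label.
#' @param calls Pseudo-haploid calls (0/2/NA) aligned with the panel sites.
#' @param sex Sex code (default "U").
#' @return A [genotype_matrix()].
#' @export
add_individual <- function(panel, ind_id, population, calls, sex = "U") {
  ind <- rbind(panel$individuals,
               data.frame(ind_id = ind_id, sex = sex,
                          population = population,
                          pseudo_haploid = all(calls %in% c(0L, 2L, NA)),
                          stringsAsFactors = FALSE))
  genotype_matrix(panel$snps, ind, cbind(panel$calls, calls))
}
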