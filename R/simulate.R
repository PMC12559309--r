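# Synthetic-data generator. Reference populations are simulated at the
# allele-frequency level on an admixture graph with Balding-Nichols drift
# per branch -- fast, deterministic and with analytic expectations, which is
# what f-statistic machinery needs. Admixed target genomes are built from a
# two-ancestry Markov tract mosaic (which is what creates dateable admixture
# LD) and sequenced into Poisson-coverage pileups with terminal deamination,
# so every stage of the package can be validated end to end without any
# external data.

#' Define an admixture graph for frequency simulation
#'
#' @param edges data.frame with columns `child`, `parent`, `f`: each branch
#'   applies Balding-Nichols drift `F in (0, 1)` to its parent's frequency.
#'   Exactly one node (the root) must appear only as a parent.
#' @param admixtures Optional list of events, each a list with `child`,
#'   `parents` (character), `alpha` (proportions summing to 1) and optional
#'   `f` (post-admixture drift, default 0): the child's frequency is the
#'   alpha-mixture of its parents'.
#' @param outgroup Label of the designated outgroup population.
#' @return An `admixture_graph` with a precomputed topological order.
#' @export
admixture_graph <- function(edges, admixtures = list(), outgroup) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "f") %in% names(edges)),
            all(edges$f > 0 & edges$f < 1))
  adm_children <- vapply(admixtures, `[[`, "", "child")
  for (ev in admixtures) {
    stopifnot(abs(sum(ev$alpha) - 1) < 1e-12, length(ev$alpha) >= 2,
              length(ev$parents) == length(ev$alpha))
  }
  if (anyDuplicated(c(edges$child, adm_children)))
    stop("a node may have only one incoming branch or admixture event")
  nodes <- unique(c(edges$parent, edges$child,
                    unlist(lapply(admixtures, function(e)
                      c(e$parents, e$child)))))
  parents_of <- function(nd) {
    i <- match(nd, edges$child)
    if (!is.na(i)) return(edges$parent[i])
    j <- match(nd, adm_children)
    if (!is.na(j)) return(admixtures[[j]]$parents)
    character()
  }
  roots <- nodes[vapply(nodes, function(nd) length(parents_of(nd)) == 0,
                        TRUE)]
  if (length(roots) != 1)
    stop("graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  # Kahn topological order; failure to place every node means a cycle
  order <- roots
  remaining <- setdiff(nodes, roots)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nd)
      all(parents_of(nd) %in% order), TRUE)]
    if (!length(ready)) stop("admixture graph contains a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (!outgroup %in% nodes) stop("outgroup not in graph")
  structure(list(edges = edges, admixtures = admixtures, root = roots,
                 nodes = nodes, order = order, outgroup = outgroup),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat(sprintf(
    "admixture_graph: %d nodes, %d drift branches, %d admixture events (outgroup %s)\n",
    length(x$nodes), nrow(x$edges), length(x$admixtures), x$outgroup))
  invisible(x)
}

balding_nichols <- function(p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  q <- rbeta(length(p), a, b)
  pmin(pmax(q, 0), 1)
}

#' Simulate per-population allele frequencies on an admixture graph
#'
#' Ancestral frequencies are Uniform(0.05, 0.95) per site; every branch
#' draws the child frequency from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `F p(1-p)`); admixed
#' nodes take the alpha-mixture of their parents, followed by their own
#' drift branch if one is specified.
#'
#' @param graph An [admixture_graph()].
#' @param n_snps Number of sites.
#' @param seed Integer seed.
#' @return Numeric matrix `n_snps` x nodes (all internal and leaf nodes).
#' @export
simulate_frequencies <- function(graph, n_snps, seed = NULL) {
  stopifnot(inherits(graph, "admixture_graph"))
  with_seed(seed, {
    p <- matrix(NA_real_, n_snps, length(graph$nodes),
                dimnames = list(NULL, graph$nodes))
    adm_children <- vapply(graph$admixtures, `[[`, "", "child")
    for (nd in graph$order) {
      if (nd == graph$root) {
        p[, nd] <- runif(n_snps, 0.05, 0.95)
      } else if (nd %in% adm_children) {
        ev <- graph$admixtures[[match(nd, adm_children)]]
        mix <- p[, ev$parents, drop = FALSE] %*% ev$alpha
        f <- ev$f %||% 0
        p[, nd] <- if (f > 0) balding_nichols(as.numeric(mix), f)
                   else as.numeric(mix)
      } else {
        i <- match(nd, graph$edges$child)
        p[, nd] <- balding_nichols(p[, graph$edges$parent[i]],
                                   graph$edges$f[i])
      }
    }
    p
  })
}

#' Uniform SNP map over a multi-chromosome genome
#'
#' Evenly spaced sites proportional to chromosome genetic length, with a
#' uniform 1 cM/Mb map (1 Morgan = 100 Mb). Allele pairs cycle through a
#' fixed half-transition, half-transversion set so transversion filtering
#' has something to do.
#'
#' @param n_snps Total number of sites.
#' @param chrom_lengths_M Named or unnamed vector of chromosome lengths in
#'   Morgans (default 22 chromosomes of 1 Morgan).
#' @return SNP table suitable for [genotype_matrix()] / [make_blocks()].
#' @export
uniform_snp_map <- function(n_snps, chrom_lengths_M = rep(1, 22)) {
  nch <- length(chrom_lengths_M)
  chrom_names <- names(chrom_lengths_M) %||% as.character(seq_len(nch))
  per <- floor(n_snps * chrom_lengths_M / sum(chrom_lengths_M))
  per[seq_len(n_snps - sum(per))] <- per[seq_len(n_snps - sum(per))] + 1
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T",
                    "G", "A", "T", "C", "A", "T", "C", "A"),
                  ncol = 2, byrow = TRUE)
  tabs <- lapply(seq_len(nch), function(ci) {
    m <- per[ci]
    gp <- (seq_len(m) - 0.5) / m * chrom_lengths_M[ci]
    data.frame(snp_id = sprintf("snp_%s_%d", chrom_names[ci], seq_len(m)),
               chrom = chrom_names[ci], genetic_pos = gp,
               physical_pos = as.integer(round(gp * 1e8)) + 1L,
               ref = pairs[(seq_len(m) - 1) %% nrow(pairs) + 1, 1],
               alt = pairs[(seq_len(m) - 1) %% nrow(pairs) + 1, 2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Simulate a two-ancestry tract mosaic along a genome
#'
#' Renewal process along each chromosome: ancestry-resampling events occur
#' at rate `t` per Morgan and each event draws the new ancestry from the
#' stationary proportions `alpha` (so adjacent segments may share ancestry).
#' This gives a stationary ancestry-1 fraction of `alpha[1]` and an ancestry
#' autocovariance decaying as `exp(-t d)` -- the admixture-LD signal that
#' [fit_decay()] inverts into generations since admixture.
#'
#' @param alpha Length-2 ancestry proportions summing to 1.
#' @param t Generations since admixture (event rate per Morgan), >= 1.
#' @param chrom_lengths_M Chromosome lengths in Morgans.
#' @param seed Integer seed.
#' @return data.frame (chrom, start, end, ancestry in \{1, 2\}); one row per
#'   renewal segment.
#' @export
simulate_tracts <- function(alpha, t, chrom_lengths_M = rep(1, 22),
                            seed = NULL) {
  stopifnot(length(alpha) == 2, abs(sum(alpha) - 1) < 1e-12, t >= 1)
  chrom_names <- names(chrom_lengths_M) %||%
    as.character(seq_along(chrom_lengths_M))
  with_seed(seed, {
    segs <- lapply(seq_along(chrom_lengths_M), function(ci) {
      L <- chrom_lengths_M[ci]
      if (alpha[1] %in% c(0, 1))
        return(data.frame(chrom = chrom_names[ci], start = 0, end = L,
                          ancestry = if (alpha[1] == 1) 1L else 2L))
      breaks <- 0
      while (TRUE) {
        nxt <- breaks[length(breaks)] + rexp(1, rate = t)
        if (nxt >= L) break
        breaks <- c(breaks, nxt)
      }
      anc <- 1L + (runif(length(breaks)) > alpha[1])
      data.frame(chrom = chrom_names[ci], start = breaks,
                 end = c(breaks[-1], L), ancestry = anc)
    })
    do.call(rbind, segs)
  })
}

# Ancestry index (1/2) of each site under a tract mosaic.
tract_ancestry <- function(tracts, snps) {
  anc <- integer(nrow(snps))
  for (ch in unique(snps$chrom)) {
    i <- which(snps$chrom == ch)
    tr <- tracts[tracts$chrom == ch, , drop = FALSE]
    seg <- findInterval(snps$genetic_pos[i], tr$start)
    anc[i] <- tr$ancestry[pmax(seg, 1)]
  }
  anc
}

#' Simulate an individual's genotypes from population frequencies
#'
#' Each of `ploidy` allele copies is an independent Bernoulli draw from the
#' frequency of the copy's local ancestry. Unadmixed individuals use a
#' single population's frequency everywhere; admixed individuals use a tract
#' mosaic per copy (diploids draw two independent mosaics). An optional
#' third-source frequency mixture (`mix_with`, `mix_beta`) blends every
#' draw's frequency with a third population's -- the construction used for
#' three-way admixed targets, whose third ancestry enters at the frequency
#' level rather than as tracts.
#'
#' @param p_true Sites x populations frequency matrix (from
#'   [simulate_frequencies()]).
#' @param snps SNP table aligned with `p_true`.
#' @param ancestry A population label, or a list of `ploidy` tract
#'   data.frames from [simulate_tracts()].
#' @param sources For tract ancestry: length-2 character mapping tract
#'   ancestries 1 and 2 to populations.
#' @param ploidy 1 or 2.
#' @param mix_with,mix_beta Optional third-source label and its proportion.
#' @param seed Integer seed.
#' @return Integer genotype vector (0..ploidy alt copies).
#' @export
simulate_individual <- function(p_true, snps, ancestry, sources = NULL,
                                ploidy = 2, mix_with = NULL, mix_beta = 0,
                                seed = NULL) {
  n <- nrow(snps)
  with_seed(seed, {
    g <- integer(n)
    for (copy in seq_len(ploidy)) {
      p <- if (is.character(ancestry)) {
        p_true[, ancestry]
      } else {
        anc <- tract_ancestry(ancestry[[copy]], snps)
        p_true[cbind(seq_len(n), match(sources[anc], colnames(p_true)))]
      }
      if (!is.null(mix_with) && mix_beta > 0)
        p <- (1 - mix_beta) * p + mix_beta * p_true[, mix_with]
      g <- g + (runif(n) < p)
    }
    as.integer(g)
  })
}

#' Simulate Poisson-coverage pileups with terminal deamination
#'
#' Per-site read depth is Poisson(`mean_cov`); each read carries one of the
#' individual's alleles uniformly at random and lands at a uniform position
#' within a read of length `read_len`. Cytosines are misread as thymines
#' with probability `delta * exp(-(i - 1)/5)` at distance `i` from the 5'
#' end, and guanines as adenines symmetrically from the 3' end -- the
#' geometric terminal damage profile of degraded ancient DNA.
#'
#' @param genotypes Integer vector of diploid genotypes (0/1/2) per site.
#' @param snps SNP table (supplies ref/alt bases).
#' @param mean_cov Mean coverage (> 0).
#' @param delta Terminal damage rate in [0, 0.5].
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return A [pileup()].
#' @export
simulate_reads <- function(genotypes, snps, mean_cov, delta = 0,
                           read_len = 70, seed = NULL) {
  stopifnot(mean_cov > 0, delta >= 0, delta <= 0.5,
            length(genotypes) == nrow(snps))
  n <- nrow(snps)
  with_seed(seed, {
    cov <- rpois(n, mean_cov)
    site <- rep.int(seq_len(n), cov)
    alt <- runif(length(site)) < genotypes[site] / 2
    base <- ifelse(alt, snps$alt[site], snps$ref[site])
    if (delta > 0) {
      pos5 <- sample.int(read_len, length(site), replace = TRUE)
      pos3 <- read_len - pos5 + 1
      u <- runif(length(site))
      ct <- base == "C" & u < delta * exp(-(pos5 - 1) / 5)
      ga <- base == "G" & u < delta * exp(-(pos3 - 1) / 5)
      base[ct] <- "T"
      base[ga] <- "A"
    }
    counts <- matrix(0L, n, 4, dimnames = list(snps$snp_id,
                                               c("A", "C", "G", "T")))
    tab <- table(factor(site, levels = seq_len(n)),
                 factor(base, levels = c("A", "C", "G", "T")))
    counts[] <- as.integer(tab)
    pileup(snps, counts)
  })
}

#' Simulate aligned read/reference pairs with terminal damage
#'
#' Random reference sequences with C->T substitutions at 5' distance `i`
#' with probability `delta * exp(-(i - 1)/5)` and symmetric G->A at 3' ends;
#' substrate for [damage_profile()].
#'
#' @param n_reads Number of reads.
#' @param read_len Read length.
#' @param delta Terminal damage rate.
#' @param seed Integer seed.
#' @return data.frame with `read` and `ref` character columns.
#' @export
simulate_damaged_reads <- function(n_reads, read_len = 70, delta = 0.3,
                                   seed = NULL) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    refm <- matrix(sample(bases, n_reads * read_len, replace = TRUE),
                   n_reads, read_len)
    readm <- refm
    p5 <- delta * exp(-(seq_len(read_len) - 1) / 5)
    p3 <- rev(p5)
    u <- matrix(runif(n_reads * read_len), n_reads, read_len)
    ct <- refm == "C" & sweep(u, 2, p5, `<`)
    u2 <- matrix(runif(n_reads * read_len), n_reads, read_len)
    ga <- refm == "G" & sweep(u2, 2, p3, `<`)
    readm[ct] <- "T"
    readm[ga] <- "A"
    data.frame(read = apply(readm, 1, paste0, collapse = ""),
               ref = apply(refm, 1, paste0, collapse = ""),
               stringsAsFactors = FALSE)
  })
}
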