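# Synthetic pooled bisulfite methylomes with planted ground truth.
#
# The generator emulates the statistical structure of pooled plasma WGBS:
# a bimodal per-CpG landscape (background near fully methylated, CpG islands
# near unmethylated), a tunable global hypomethylation shift in one pool,
# planted focal island hypermethylation in that pool, negative-binomial
# coverage, and beta-binomial methylated counts. Both strands of each CpG
# dyad are emitted (same underlying proportion, independent coverage draws)
# so destranding is exercised downstream.

#' Construct a simulation genome model
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param islands CpG-island intervals: data.frame with `chrom`, `start`,
#'   `end` (1-based closed) and `name`; islands must be non-overlapping and
#'   lie within the declared chromosome bounds.
#' @param cpg_spacing_mean mean distance (bp) between CpG dyads outside
#'   islands.
#' @param island_cpg_density_multiplier factor (>= 1) by which CpG density is
#'   increased inside islands.
#' @param genes optional gene table (`chrom`, `tss`, `end`, `strand`, `name`)
#'   used to derive context tracks.
#' @return a `sim_genome_model`.
#' @export
sim_genome_model <- function(chromosomes, islands,
                             cpg_spacing_mean = 125,
                             island_cpg_density_multiplier = 4,
                             genes = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  assert_scalar_number(cpg_spacing_mean, "cpg_spacing_mean", min = 4)
  assert_scalar_number(island_cpg_density_multiplier,
                       "island_cpg_density_multiplier", min = 1)
  if (cpg_spacing_mean / island_cpg_density_multiplier < 3) {
    stop("island CpG spacing (spacing/multiplier) must be >= 3 bp",
         call. = FALSE)
  }
  islands <- annotation_track("CPGI", islands)$intervals
  if (nrow(islands)) {
    lens <- stats::setNames(chromosomes$length, chromosomes$name)
    if (!all(islands$chrom %in% chromosomes$name)) {
      stop("island on undeclared chromosome", call. = FALSE)
    }
    if (any(islands$end > lens[islands$chrom])) {
      stop("island extends beyond chromosome bounds", call. = FALSE)
    }
    by_chr <- split(islands, islands$chrom)
    for (iv in by_chr) {
      if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
        stop("islands must be non-overlapping in the genome model",
             call. = FALSE)
      }
    }
  }
  structure(list(chromosomes = chromosomes, islands = islands,
                 cpg_spacing_mean = cpg_spacing_mean,
                 island_cpg_density_multiplier = island_cpg_density_multiplier,
                 genes = genes),
            class = "sim_genome_model")
}

#' Per-pool simulation parameters
#'
#' @param label pool identifier.
#' @param depth_mean mean read coverage per strand-cytosine (the destranded
#'   dyad coverage is about twice this).
#' @param depth_dispersion negative-binomial dispersion of coverage
#'   (variance = mu + dispersion * mu^2; 0 gives Poisson coverage).
#' @param background_beta `c(alpha, beta)` of the high-methylation background
#'   Beta distribution of true proportions.
#' @param island_beta `c(alpha, beta)` of the low-methylation island Beta.
#' @param global_hypo_shift subtractive shift (proportion units, in \[0, 1))
#'   applied to background methylation probabilities; islands are unaffected.
#' @param overdispersion_rho beta-binomial intra-pool correlation in \[0, 1);
#'   0 recovers binomial counts.
#' @return a `sim_pool_params`.
#' @export
sim_pool_params <- function(label,
                            depth_mean,
                            depth_dispersion = 0.25,
                            background_beta = c(12, 1.5),
                            island_beta = c(1, 19),
                            global_hypo_shift = 0,
                            overdispersion_rho = 0.02) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  assert_scalar_number(depth_mean, "depth_mean", min = .Machine$double.xmin)
  assert_scalar_number(depth_dispersion, "depth_dispersion", min = 0)
  stopifnot(length(background_beta) == 2L, all(background_beta > 0),
            length(island_beta) == 2L, all(island_beta > 0))
  assert_scalar_number(global_hypo_shift, "global_hypo_shift", min = 0,
                       max = 1 - 1e-12)
  assert_scalar_number(overdispersion_rho, "overdispersion_rho", min = 0,
                       max = 1 - 1e-12)
  structure(list(label = label, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 background_beta = as.numeric(background_beta),
                 island_beta = as.numeric(island_beta),
                 global_hypo_shift = global_hypo_shift,
                 overdispersion_rho = overdispersion_rho),
            class = "sim_pool_params")
}

#' Presets for the three study pools
#'
#' Depth means follow the reported per-pool sequencing depths (7.4 healthy,
#' 9.6 disease-free survivor, 16.9 metastatic); the metastatic-like pool
#' carries the global hypomethylation shift (default 0.25, a free parameter
#' of the simulation chosen so the shifted pool reproduces the expected
#' structure: a visibly left-shifted percent methylation histogram and a
#' strong excess of hypomethylated DML).
#'
#' @param label one of `"H"`, `"DFS"`, `"MBC"`.
#' @param global_hypo_shift shift applied to the MBC-like pool.
#' @param ... overrides passed to [sim_pool_params()].
#' @return a `sim_pool_params`.
#' @export
pool_params_preset <- function(label = c("H", "DFS", "MBC"),
                               global_hypo_shift = 0.25, ...) {
  label <- match.arg(label)
  depth <- c(H = 7.4, DFS = 9.6, MBC = 16.9)[[label]]
  shift <- if (label == "MBC") global_hypo_shift else 0
  args <- utils::modifyList(
    list(label = label, depth_mean = depth, global_hypo_shift = shift),
    list(...)
  )
  do.call(sim_pool_params, args)
}

#' Place CpG dyads along the simulated genome
#'
#' Inter-CpG gaps are 2 + Geometric, with mean spacing `cpg_spacing_mean`
#' outside islands and `cpg_spacing_mean / multiplier` inside, so the
#' configured density ratio holds exactly in expectation. Positions are the
#' plus-strand cytosine of each dyad (the G, i.e. the minus-strand cytosine,
#' sits at pos + 1). Deterministic given the seed.
#'
#' @param genome a [sim_genome_model()].
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos` (dyad plus-strand cytosine) and
#'   `island` (island name or `NA`).
#' @export
place_cpgs <- function(genome, seed) {
  stopifnot(inherits(genome, "sim_genome_model"))
  s_bg <- genome$cpg_spacing_mean
  s_isl <- genome$cpg_spacing_mean / genome$island_cpg_density_multiplier
  if (any(genome$chromosomes$length < s_bg)) {
    stop("chromosome shorter than one CpG spacing unit", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      chrom <- genome$chromosomes$name[ci]
      L <- genome$chromosomes$length[ci]
      isl <- genome$islands[genome$islands$chrom == chrom, , drop = FALSE]
      # non-overlapping islands => alternating background/island segments
      bounds <- data.frame(start = 1L, end = as.integer(L) - 1L,
                           island = NA_character_)
      if (nrow(isl)) {
        segs <- list()
        cur <- 1L
        for (k in seq_len(nrow(isl))) {
          if (isl$start[k] > cur) {
            segs[[length(segs) + 1L]] <- data.frame(
              start = cur, end = isl$start[k] - 1L, island = NA_character_)
          }
          segs[[length(segs) + 1L]] <- data.frame(
            start = isl$start[k], end = isl$end[k], island = isl$name[k])
          cur <- isl$end[k] + 1L
        }
        if (cur <= L - 1L) {
          segs[[length(segs) + 1L]] <- data.frame(
            start = cur, end = as.integer(L) - 1L, island = NA_character_)
        }
        bounds <- do.call(rbind, segs)
      }
      pos_list <- lapply(seq_len(nrow(bounds)), function(si) {
        a <- bounds$start[si]; b <- bounds$end[si]
        len <- b - a + 1L
        ss <- if (is.na(bounds$island[si])) s_bg else s_isl
        if (len < 3L) return(integer(0))
        prob <- 1 / (ss - 1)  # gaps are 2 + Geom(prob), mean ss
        n_exp <- len / ss
        draws <- integer(0)
        last <- a - 1L
        while (last <= b - 1L) {
          k <- as.integer(ceiling(max(n_exp - length(draws), 10) +
                                    4 * sqrt(n_exp) + 10))
          g <- 2L + stats::rgeom(k, prob)
          draws <- c(draws, g)
          last <- a - 1L + sum(draws)
        }
        p <- a - 1L + cumsum(draws)
        p[p <= b - 1L]  # keep room for the G at pos + 1
      })
      n_per <- lengths(pos_list)
      data.frame(chrom = chrom, pos = unlist(pos_list),
                 island = rep(bounds$island, n_per),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$pos), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

#' Ground-truth manifest of a planted simulation
#'
#' @param planted_islands intervals (as in [annotation_track()]) of the
#'   islands planted as hypermethylation hotspots; must be a subset (by name)
#'   of the genome's islands.
#' @param planted_hyper_level target methylation proportion inside planted
#'   islands for the affected pool.
#' @param affected_pool_label label of the pool carrying the planted signal.
#' @param seed integer root seed of the simulation.
#' @param pool_params list of [sim_pool_params()] used.
#' @param planted_concentration Beta concentration of the planted draw
#'   (higher = tighter around `planted_hyper_level`).
#' @return a `simulation_truth`.
#' @export
simulation_truth <- function(planted_islands, planted_hyper_level,
                             affected_pool_label, seed, pool_params = NULL,
                             planted_concentration = 30) {
  planted_islands <- annotation_track("CPGI", planted_islands)$intervals
  assert_scalar_number(planted_hyper_level, "planted_hyper_level", min = 0,
                       max = 1)
  stopifnot(is.character(affected_pool_label),
            length(affected_pool_label) == 1L)
  structure(list(planted_hotspot_islands = planted_islands,
                 planted_hyper_level = planted_hyper_level,
                 affected_pool_label = affected_pool_label,
                 seed = as.integer(seed),
                 planted_concentration = planted_concentration,
                 pool_params = pool_params),
            class = "simulation_truth")
}

#' Write a simulation truth manifest as JSON
#' @param truth a [simulation_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  x <- unclass(truth)
  x$pool_params <- lapply(x$pool_params, unclass)
  write_summary_json(x, path)
}

#' Read a simulation truth manifest
#' @param path JSON path written by [write_truth()].
#' @return a `simulation_truth`.
#' @export
read_truth <- function(path) {
  x <- read_summary_json(path)
  planted <- as.data.frame(x$planted_hotspot_islands)
  if (!nrow(planted)) {
    planted <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0))
  }
  pp <- lapply(x$pool_params, function(p) do.call(sim_pool_params, p))
  simulation_truth(planted, x$planted_hyper_level, x$affected_pool_label,
                   as.integer(x$seed), pool_params = pp,
                   planted_concentration = x$planted_concentration)
}

# True per-dyad methylation proportions for one pool.
#' @keywords internal
#' @noRd
draw_true_proportions <- function(cpgs, genome, params, truth = NULL) {
  n <- nrow(cpgs)
  in_island <- !is.na(cpgs$island)
  p_bg <- stats::rbeta(n, params$background_beta[1L],
                       params$background_beta[2L]) - params$global_hypo_shift
  p_isl <- stats::rbeta(n, params$island_beta[1L], params$island_beta[2L])
  p <- ifelse(in_island, p_isl, pmin(pmax(p_bg, 0), 1))
  if (!is.null(truth) && identical(params$label, truth$affected_pool_label) &&
      nrow(truth$planted_hotspot_islands)) {
    planted_names <- truth$planted_hotspot_islands$name
    missing <- setdiff(planted_names, genome$islands$name)
    if (length(missing)) {
      stop("planted island(s) absent from the genome model: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
    hit <- !is.na(cpgs$island) & cpgs$island %in% planted_names
    kappa <- truth$planted_concentration
    lvl <- truth$planted_hyper_level
    p_hot <- stats::rbeta(n, lvl * kappa, (1 - lvl) * kappa)
    p[hit] <- p_hot[hit]
  }
  p
}

# Strand-level counts from per-dyad true proportions. Both strands of each
# dyad share the proportion; coverage draws are independent.
#' @keywords internal
#' @noRd
draw_strand_counts <- function(cpgs, p, params) {
  n <- nrow(cpgs)
  draw_cov <- function(n) {
    if (params$depth_dispersion > 0) {
      stats::rnbinom(n, mu = params$depth_mean,
                     size = 1 / params$depth_dispersion)
    } else {
      stats::rpois(n, params$depth_mean)
    }
  }
  draw_meth <- function(cov, p) {
    rho <- params$overdispersion_rho
    if (rho > 0) {
      conc <- 1 / rho - 1
      pp <- stats::rbeta(length(p), p * conc, (1 - p) * conc)
      edge <- p <= 0 | p >= 1
      pp[edge] <- p[edge]
    } else {
      pp <- p
    }
    stats::rbinom(length(cov), cov, pp)
  }
  cov_plus <- draw_cov(n); meth_plus <- draw_meth(cov_plus, p)
  cov_minus <- draw_cov(n); meth_minus <- draw_meth(cov_minus, p)
  df <- data.frame(
    chrom = rep(cpgs$chrom, 2L),
    pos = c(cpgs$pos, cpgs$pos + 1L),
    strand = rep(c("+", "-"), each = n),
    meth = c(meth_plus, meth_minus),
    unmeth = c(cov_plus - meth_plus, cov_minus - meth_minus),
    stringsAsFactors = FALSE
  )
  df
}

#' Simulate one pooled methylome
#'
#' True proportions are drawn from the island Beta inside islands and from
#' the (shifted, clamped) background Beta elsewhere; if `truth` names this
#' pool as affected, proportions inside planted islands are redrawn around
#' `planted_hyper_level`. Coverage is negative binomial; methylated counts
#' are beta-binomial. Deterministic given the seeds.
#'
#' The per-locus proportion draws come from their own RNG stream
#' (`prop_seed`). Pools of one study share that stream (see
#' [simulate_study()]), making the locus baseline a property of the genome:
#' two pools with identical parameters then differ only by measurement noise,
#' so at `overdispersion_rho = 0` every unplanted, unshifted locus is a sharp
#' null for the downstream exact test. Pass distinct `prop_seed` values to
#' draw independent landscapes instead.
#'
#' @param cpgs dyad positions from [place_cpgs()].
#' @param genome the [sim_genome_model()] the dyads were placed on.
#' @param params a [sim_pool_params()].
#' @param truth optional [simulation_truth()] for planted hotspots.
#' @param seed integer seed for the coverage and count draws.
#' @param prop_seed integer seed for the true-proportion draws (defaults to
#'   `seed`).
#' @param keep_truth if `TRUE`, attach the per-dyad true proportions as the
#'   `true_prop` attribute (data.frame `chrom`, `pos`, `prop`).
#' @return a [pool_methylome()] with both strands of every dyad.
#' @export
simulate_pool <- function(cpgs, genome, params, truth = NULL, seed,
                          prop_seed = seed, keep_truth = FALSE) {
  stopifnot(inherits(genome, "sim_genome_model"),
            inherits(params, "sim_pool_params"))
  p <- with_seed(prop_seed,
                 draw_true_proportions(cpgs, genome, params, truth))
  with_seed(seed, {
    df <- draw_strand_counts(cpgs, p, params)
    pool <- pool_methylome(df, label = params$label)
    if (keep_truth) {
      attr(pool, "true_prop") <- data.frame(chrom = cpgs$chrom,
                                            pos = cpgs$pos, prop = p,
                                            stringsAsFactors = FALSE)
    }
    pool
  })
}

#' Re-measure an existing simulated pool on a second platform
#'
#' Draws new coverage and counts for the same underlying true proportions,
#' restricted to `target_regions` when given — the structure of a targeted
#' deep-sequencing validation assay over the same biological material.
#'
#' @param pool a pool from [simulate_pool()] with `keep_truth = TRUE`.
#' @param params a [sim_pool_params()] for the second platform (typically a
#'   much larger `depth_mean`).
#' @param target_regions optional intervals (1-based closed data.frame or
#'   [annotation_track()]) to restrict to.
#' @param seed integer seed.
#' @return a [pool_methylome()].
#' @export
simulate_platform_replicate <- function(pool, params, target_regions = NULL,
                                        seed) {
  tp <- attr(pool, "true_prop")
  if (is.null(tp)) {
    stop("pool carries no true proportions; simulate with keep_truth = TRUE",
         call. = FALSE)
  }
  cpgs <- data.frame(chrom = tp$chrom, pos = tp$pos,
                     island = NA_character_, stringsAsFactors = FALSE)
  p <- tp$prop
  if (!is.null(target_regions)) {
    gr_t <- as_granges(target_regions)
    hit <- IRanges::overlapsAny(loci_granges(cpgs$chrom, cpgs$pos), gr_t)
    cpgs <- cpgs[hit, , drop = FALSE]
    p <- p[hit]
  }
  with_seed(seed, {
    df <- draw_strand_counts(cpgs, p, params)
    out <- pool_methylome(df, label = params$label)
    attr(out, "true_prop") <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                                         prop = p, stringsAsFactors = FALSE)
    out
  })
}

#' Build a randomized genome model with genes, islands and context tracks
#'
#' Genes are laid out on a jittered grid; a configurable fraction of islands
#' is centered on promoters and the rest placed intergenically without
#' overlap. Context tracks are derived from the gene models: TSS1500 (1500 bp
#' upstream of the TSS), UTR5 (first 300 bp), Exon1 (first 500 bp), GeneBody
#' (TSS to gene end).
#'
#' @param chrom_name,chrom_length chromosome to simulate.
#' @param n_islands number of CpG islands.
#' @param island_length_range min/max island length (bp).
#' @param n_genes number of gene models.
#' @param gene_length_range min/max gene length (bp).
#' @param prop_promoter_islands fraction of islands centered on a TSS.
#' @param cpg_spacing_mean,island_cpg_density_multiplier see
#'   [sim_genome_model()].
#' @param seed integer seed.
#' @return list with elements `genome` (a `sim_genome_model`) and `tracks`
#'   (named list of [annotation_track()]s: CPGI, TSS1500, UTR5, Exon1,
#'   GeneBody).
#' @export
simulate_genome <- function(chrom_name = "chr1", chrom_length = 2e6,
                            n_islands = 200,
                            island_length_range = c(400, 1200),
                            n_genes = 100,
                            gene_length_range = c(5000, 20000),
                            prop_promoter_islands = 0.3,
                            cpg_spacing_mean = 125,
                            island_cpg_density_multiplier = 4,
                            seed = 1L) {
  with_seed(seed, {
    slot <- chrom_length / n_genes
    tss <- as.integer(round((seq_len(n_genes) - 1) * slot +
                              stats::runif(n_genes, 0.15 * slot, 0.45 * slot)))
    glen <- as.integer(round(stats::runif(n_genes, gene_length_range[1L],
                                          gene_length_range[2L])))
    gend <- pmin(tss + glen, as.integer(chrom_length) - 2000L)
    genes <- data.frame(chrom = chrom_name, tss = tss, end = gend,
                        strand = "+", name = sprintf("GENE%03d", seq_len(n_genes)),
                        stringsAsFactors = FALSE)

    ilen <- as.integer(round(stats::runif(n_islands, island_length_range[1L],
                                          island_length_range[2L])))
    n_prom <- round(prop_promoter_islands * n_islands)
    prom_genes <- sort(sample.int(n_genes, min(n_prom, n_genes)))
    starts <- integer(0); ends <- integer(0)
    # promoter islands: centered on the TSS
    s_p <- pmax(2L, tss[prom_genes] - ilen[seq_along(prom_genes)] %/% 2L)
    e_p <- pmin(s_p + ilen[seq_along(prom_genes)] - 1L,
                as.integer(chrom_length) - 2L)
    starts <- s_p; ends <- e_p
    # intergenic islands: rejection-sample non-overlapping placements
    need <- n_islands - length(prom_genes)
    k <- length(prom_genes)
    guard <- 0L
    while (need > 0L && guard < 200L) {
      guard <- guard + 1L
      cand_s <- as.integer(round(stats::runif(2L * need, 2,
                                              chrom_length - max(ilen) - 2)))
      for (cs in cand_s) {
        if (need <= 0L) break
        ce <- cs + ilen[k + 1L] - 1L
        if (!any(cs <= ends + 200L & ce >= starts - 200L)) {
          starts <- c(starts, cs); ends <- c(ends, ce)
          k <- k + 1L; need <- need - 1L
        }
      }
    }
    if (need > 0L) {
      stop("could not place the requested number of non-overlapping islands",
           call. = FALSE)
    }
    ord <- order(starts)
    islands <- data.frame(chrom = chrom_name, start = starts[ord],
                          end = ends[ord],
                          name = sprintf("CGI%03d", seq_len(n_islands)),
                          stringsAsFactors = FALSE)
    genome <- sim_genome_model(
      chromosomes = data.frame(name = chrom_name, length = chrom_length),
      islands = islands,
      cpg_spacing_mean = cpg_spacing_mean,
      island_cpg_density_multiplier = island_cpg_density_multiplier,
      genes = genes
    )
    tracks <- list(
      CPGI = annotation_track("CPGI", islands),
      TSS1500 = annotation_track("TSS1500", data.frame(
        chrom = chrom_name, start = pmax(1L, tss - 1500L),
        end = pmax(1L, tss - 1L), name = paste0(genes$name, "_tss1500"))),
      UTR5 = annotation_track("UTR5", data.frame(
        chrom = chrom_name, start = tss, end = tss + 299L,
        name = paste0(genes$name, "_utr5"))),
      Exon1 = annotation_track("Exon1", data.frame(
        chrom = chrom_name, start = tss, end = tss + 499L,
        name = paste0(genes$name, "_exon1"))),
      GeneBody = annotation_track("GeneBody", data.frame(
        chrom = chrom_name, start = tss, end = gend,
        name = paste0(genes$name, "_body")))
    )
    list(genome = genome, tracks = tracks)
  })
}

#' Simulate the full three-pool study
#'
#' Generates a genome with context tracks, places CpGs, plants hotspot
#' islands in the affected pool, and simulates the pooled methylomes.
#' All randomness derives from `seed` through fixed per-stage substreams.
#' All pools share one per-locus proportion stream (the locus baseline is a
#' genome property); pools differ through their shift, planting, coverage and
#' count draws, so pools with identical parameters form a sharp null at
#' `overdispersion_rho = 0`.
#'
#' @param seed root integer seed.
#' @param n_planted number of islands planted as hotspots in the affected
#'   pool.
#' @param planted_hyper_level target methylation proportion in planted
#'   islands.
#' @param depth_means named vector of per-pool mean strand coverages.
#' @param global_hypo_shift background hypomethylation shift of the affected
#'   pool.
#' @param affected_pool label of the affected pool (default `"MBC"`).
#' @param overdispersion_rho beta-binomial correlation for all pools.
#' @param genome_args list of overrides passed to [simulate_genome()].
#' @param pool_args list of further overrides passed to [sim_pool_params()].
#' @return list with `genome`, `tracks`, `cpgs`, `pools` (named list of
#'   [pool_methylome()]s with true proportions attached) and `truth`.
#' @export
simulate_study <- function(seed,
                           n_planted = 10,
                           planted_hyper_level = 0.9,
                           depth_means = c(H = 7.4, DFS = 9.6, MBC = 16.9),
                           global_hypo_shift = 0.25,
                           affected_pool = "MBC",
                           overdispersion_rho = 0.02,
                           genome_args = list(),
                           pool_args = list()) {
  stopifnot(!is.null(names(depth_means)), affected_pool %in% names(depth_means))
  gen <- do.call(simulate_genome,
                 utils::modifyList(list(seed = derive_seed(seed, "genome")),
                                   genome_args))
  cpgs <- place_cpgs(gen$genome, seed = derive_seed(seed, "place_cpgs"))
  islands <- gen$genome$islands
  planted <- islands[sort(with_seed(derive_seed(seed, "plant"),
                                    sample.int(nrow(islands), n_planted))), ,
                     drop = FALSE]
  params <- lapply(names(depth_means), function(lab) {
    do.call(sim_pool_params, utils::modifyList(
      list(label = lab, depth_mean = unname(depth_means[[lab]]),
           global_hypo_shift = if (lab == affected_pool) global_hypo_shift else 0,
           overdispersion_rho = overdispersion_rho),
      pool_args))
  })
  names(params) <- names(depth_means)
  truth <- simulation_truth(planted, planted_hyper_level, affected_pool,
                            seed = as.integer(seed), pool_params = params)
  pools <- lapply(names(params), function(lab) {
    simulate_pool(cpgs, gen$genome, params[[lab]], truth = truth,
                  seed = derive_seed(seed, paste0("pool_", lab)),
                  prop_seed = derive_seed(seed, "proportions"),
                  keep_truth = TRUE)
  })
  names(pools) <- names(params)
  list(genome = gen$genome, tracks = gen$tracks, cpgs = cpgs, pools = pools,
       truth = truth)
}
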