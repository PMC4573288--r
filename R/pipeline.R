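# End-to-end orchestration: simulate (or load) -> differential methylation ->
# context annotation -> hotspots -> similarity, with deterministic seeding,
# per-stage logging, and a reproducible run manifest.

#' Build a pipeline configuration
#'
#' Either a `simulation` block (arguments for [simulate_study()]) or explicit
#' `inputs` (paths to per-pool cytosine reports / coverage files plus BED
#' tracks per category) must be provided. Defaults fill in the standard
#' calling thresholds (coverage 5, DMV 20, P 0.05; hotspot rule 8 loci at
#' DMV >= 50).
#'
#' @param seed non-negative integer root seed; every random stage draws from
#'   a substream derived from it (see [derive_seed()]).
#' @param outdir output directory (created if missing).
#' @param simulation named list of overrides for [simulate_study()], or
#'   `NULL` when reading real inputs.
#' @param inputs named list with `pools` (named paths; dialect inferred from
#'   extension: `.cov` for coverage files, otherwise cytosine report) and
#'   `tracks` (named BED paths, names drawn from the context categories).
#' @param comparisons list of `c(case, control)` label pairs; defaults to the
#'   three pairwise study comparisons.
#' @param diff a [diffmeth_params()].
#' @param hotspot a [hotspot_params()].
#' @param hotspot_cases labels whose comparisons enter hotspot calling
#'   (default: the affected/case pool `"MBC"`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("cfmeth_run_"),
                            simulation = list(),
                            inputs = NULL,
                            comparisons = list(c("H", "DFS"), c("MBC", "H"),
                                               c("MBC", "DFS")),
                            diff = diffmeth_params(),
                            hotspot = hotspot_params(),
                            hotspot_cases = "MBC") {
  structure(list(seed = seed, outdir = outdir, simulation = simulation,
                 inputs = inputs, comparisons = comparisons, diff = diff,
                 hotspot = hotspot, hotspot_cases = hotspot_cases),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks parameter invariants, and verifies that every
#' referenced input file exists. Errors name the offending key.
#'
#' @param config a [pipeline_config()] or plain named list.
#' @return the validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    config <- do.call(pipeline_config, config)
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed) || config$seed < 0 ||
      config$seed != floor(config$seed)) {
    stop("invalid 'seed': must be a non-negative integer", call. = FALSE)
  }
  if (!inherits(config$diff, "diffmeth_params")) {
    config$diff <- do.call(diffmeth_params, as.list(config$diff))
  }
  if (!inherits(config$hotspot, "hotspot_params")) {
    config$hotspot <- do.call(hotspot_params, as.list(config$hotspot))
  }
  if (is.null(config$simulation) && is.null(config$inputs)) {
    stop("config needs either a 'simulation' block or 'inputs'",
         call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    pools <- config$inputs$pools
    if (is.null(pools) || is.null(names(pools))) {
      stop("'inputs$pools' must be a named list of file paths",
           call. = FALSE)
    }
    missing <- unlist(pools)[!file.exists(unlist(pools))]
    if (length(missing)) {
      stop("missing input file(s) under 'inputs$pools': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tracks <- config$inputs$tracks
    if (!is.null(tracks)) {
      bad <- setdiff(names(tracks), TRACK_CATEGORIES)
      if (length(bad)) {
        stop("'inputs$tracks' has unknown categories: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      missing <- unlist(tracks)[!file.exists(unlist(tracks))]
      if (length(missing)) {
        stop("missing track file(s) under 'inputs$tracks': ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  labels <- unique(unlist(config$comparisons))
  if (!length(config$comparisons) ||
      !all(lengths(config$comparisons) == 2L)) {
    stop("'comparisons' must be a list of c(case, control) pairs",
         call. = FALSE)
  }
  config$hotspot_cases <- intersect(config$hotspot_cases, labels)
  config
}

#' Run the full analysis pipeline
#'
#' Stages: simulate or load the pools and tracks; call DML for every
#' configured comparison; annotate and summarize contexts; call island
#' hotspots for the case comparisons (plus their consensus intersection and,
#' when simulated truth is available, recovery metrics); compute the pool
#' similarity report; write a deterministic run manifest. Rerunning with the
#' same config and seed produces byte-identical tables; wall-clock timings go
#' to `run.log`, not to the manifest.
#'
#' @param config a [pipeline_config()] (validated on entry).
#' @param quiet suppress console messages (they are always appended to
#'   `run.log`).
#' @return the run manifest (a list), invisibly; all artifacts are written
#'   under `config$outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  note <- function(...) {
    msg <- sprintf(...)
    writeLines(sprintf("[%.2fs] %s",
                       as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       msg), log_con)
    if (!quiet) message(msg)
  }
  capture <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      writeLines(paste0("  ", trimws(conditionMessage(m))), log_con)
      if (quiet) invokeRestart("muffleMessage")
    })
  }
  manifest <- list(
    package = "cfmeth",
    version = tryCatch(as.character(utils::packageVersion("cfmeth")),
                       error = function(e) "dev"),
    seed = as.integer(config$seed),
    parameters = list(diff = unclass(config$diff),
                      hotspot = unclass(config$hotspot)),
    stages = list()
  )

  # --- stage 1: obtain pools and tracks ------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    note("stage simulate: generating synthetic study (seed %d)", config$seed)
    sim_args <- utils::modifyList(list(seed = derive_seed(config$seed,
                                                          "study")),
                                  config$simulation)
    study <- capture(do.call(simulate_study, sim_args))
    pools <- study$pools
    tracks <- study$tracks
    truth <- study$truth
    sim_dir <- file.path(outdir, "sim")
    dir.create(sim_dir, showWarnings = FALSE)
    for (lab in names(pools)) {
      write_cytosine_report(pools[[lab]],
                            file.path(sim_dir, paste0(lab, ".CpG_report.txt")))
    }
    for (cat in names(tracks)) {
      write_bed_track(tracks[[cat]],
                      file.path(sim_dir, paste0(cat, ".bed")))
    }
    write_truth(truth, file.path(sim_dir, "truth.json"))
    manifest$stages$simulate <- list(
      n_pools = length(pools),
      n_cpg_dyads = nrow(study$cpgs),
      n_islands = nrow(study$genome$islands),
      n_planted = nrow(truth$planted_hotspot_islands)
    )
  } else {
    note("stage load: reading %d pool file(s)", length(config$inputs$pools))
    pools <- lapply(names(config$inputs$pools), function(lab) {
      path <- config$inputs$pools[[lab]]
      if (grepl("\\.cov(\\.gz)?$", path)) {
        read_coverage_file(path, label = lab)
      } else {
        read_cytosine_report(path, label = lab)
      }
    })
    names(pools) <- names(config$inputs$pools)
    tracks <- lapply(names(config$inputs$tracks %||% list()), function(cat) {
      read_bed_track(config$inputs$tracks[[cat]], cat)
    })
    names(tracks) <- names(config$inputs$tracks %||% list())
    manifest$stages$load <- list(
      n_pools = length(pools),
      n_loci = vapply(pools, nrow, 0L)
    )
  }

  # --- stage 2-3: differential methylation + context annotation ------------
  dml_dir <- file.path(outdir, "dml")
  dir.create(dml_dir, showWarnings = FALSE)
  comparisons <- lapply(config$comparisons, function(cmp) {
    case <- cmp[[1L]]; control <- cmp[[2L]]
    if (!all(c(case, control) %in% names(pools))) {
      stop(sprintf("comparison %s vs %s references unknown pool label",
                   case, control), call. = FALSE)
    }
    note("stage diff: %s vs %s", case, control)
    rec <- capture(call_dml(pools[[case]], pools[[control]], config$diff))
    if (length(tracks)) {
      rec <- annotate_dml(rec, tracks)
      ctx <- summarize_contexts(rec)
    } else {
      ctx <- NULL
    }
    tag <- paste0(case, "_vs_", control)
    write_dml_table(rec, file.path(dml_dir, paste0(tag, ".dml.tsv")),
                    params = list(case = case, control = control,
                                  min_coverage = config$diff$min_coverage,
                                  dmv = config$diff$dmv_threshold,
                                  p = config$diff$p_threshold))
    if (!is.null(ctx)) {
      write_summary_json(ctx, file.path(dml_dir, paste0(tag, ".contexts.json")))
    }
    list(tag = tag, case = case, control = control, records = rec,
         contexts = ctx)
  })
  names(comparisons) <- vapply(comparisons, `[[`, "", "tag")
  manifest$stages$diffmeth <- lapply(comparisons, function(cm) {
    list(case = cm$case, control = cm$control,
         n_united = attr(cm$records, "n_united"),
         n_dml = attr(cm$records, "n_dml"),
         n_hyper = attr(cm$records, "n_hyper"),
         n_hypo = attr(cm$records, "n_hypo"))
  })

  # --- stage 4: hotspots ----------------------------------------------------
  hot_dir <- file.path(outdir, "hotspots")
  if ("CPGI" %in% names(tracks)) {
    dir.create(hot_dir, showWarnings = FALSE)
    hot_cmps <- Filter(function(cm) cm$case %in% config$hotspot_cases,
                       comparisons)
    hotspots <- lapply(hot_cmps, function(cm) {
      note("stage hotspots: %s", cm$tag)
      calls <- capture(call_hotspots(cm$records, tracks$CPGI,
                                     config$hotspot))
      write_hotspot_bed(calls, file.path(hot_dir,
                                         paste0(cm$tag, ".hotspots.bed")))
      calls
    })
    names(hotspots) <- names(hot_cmps)
    consensus <- if (length(hotspots) > 1L) {
      Reduce(intersect, lapply(hotspots, function(h) h$name))
    } else if (length(hotspots) == 1L) {
      hotspots[[1L]]$name
    } else character(0)
    manifest$stages$hotspots <- list(
      per_comparison = lapply(hotspots, function(h) {
        list(n_hotspots = nrow(h), islands = h$name)
      }),
      consensus = list(n_hotspots = length(consensus), islands = consensus)
    )
    if (!is.null(truth) && length(hotspots)) {
      recov <- lapply(hotspots, score_recovery, truth = truth)
      manifest$stages$hotspots$recovery <- recov
      write_summary_json(recov, file.path(hot_dir, "recovery.json"))
    }
  } else {
    note("stage hotspots: skipped (no CPGI track)")
  }

  # --- stage 5: similarity --------------------------------------------------
  note("stage similarity: %d pools", length(pools))
  pools_d <- if (config$diff$destrand) {
    capture(lapply(pools, destrand_merge))
  } else {
    pools
  }
  sim_rep <- capture(similarity_report(
    pools_d, min_coverage = config$diff$min_coverage,
    exclude_chromosomes = config$diff$exclude_chromosomes))
  write_summary_json(
    list(pearson = as.data.frame(sim_rep$pearson),
         clustering = sim_rep$clustering,
         pca = list(scores = as.data.frame(sim_rep$pca$scores),
                    explained = sim_rep$pca$explained),
         histograms = sim_rep$histograms,
         n_loci = sim_rep$n_loci),
    file.path(outdir, "similarity.json"))
  manifest$stages$similarity <- list(n_common_loci = sim_rep$n_loci)

  write_summary_json(manifest, file.path(outdir, "manifest.json"))
  note("pipeline complete: %s", outdir)
  invisible(manifest)
}
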