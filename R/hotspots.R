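# CpG-island hypermethylation hotspot calling: islands containing at least
# `min_dml` hypermethylated DML with DMV at or above `min_dmv` (the
# biomarker-selection rule), plus recovery scoring against planted truth.

#' Parameters of the island hotspot rule
#'
#' @param min_dml minimum number of qualifying loci in one island (default 8).
#' @param min_dmv minimum DMV of a qualifying locus, inclusive (default 50).
#' @param require_hyper restrict qualifying loci to hypermethylated DML
#'   (default `TRUE`).
#' @return a `hotspot_params`.
#' @export
hotspot_params <- function(min_dml = 8L, min_dmv = 50, require_hyper = TRUE) {
  assert_scalar_number(min_dml, "min_dml", min = 1)
  assert_scalar_number(min_dmv, "min_dmv", min = 1e-12, max = 100)
  structure(list(min_dml = as.integer(min_dml), min_dmv = min_dmv,
                 require_hyper = isTRUE(require_hyper)),
            class = "hotspot_params")
}

#' Call CpG-island hypermethylation hotspots
#'
#' For each island, qualifying loci are the input DML inside the island that
#' are hypermethylated (when `require_hyper`) with DMV >= `min_dmv`
#' (inclusive); an island is called iff it holds at least `min_dml` of them.
#' The call reports the full island interval; the minimal window spanning the
#' qualifying loci is emitted as auxiliary `span_start`/`span_end` columns.
#'
#' @param records called DML (from [call_dml()], i.e. already past the
#'   P/DMV filters).
#' @param islands the CPGI [annotation_track()].
#' @param params a [hotspot_params()].
#' @return a data.frame of calls (class `hotspot_calls`) sorted by
#'   (chrom, start), with columns `chrom`, `start`, `end`, `name`,
#'   `n_qualifying`, `mean_dmv`, `max_dmv`, `span_start`, `span_end`;
#'   the qualifying records of each call are kept in the `supporting`
#'   attribute (a named list of data.frames).
#' @export
call_hotspots <- function(records, islands, params = hotspot_params()) {
  stopifnot(inherits(params, "hotspot_params"))
  if (!inherits(islands, "annotation_track")) {
    stop("islands must be an annotation_track", call. = FALSE)
  }
  iv <- islands$intervals
  if (!nrow(iv)) {
    stop("empty island track: the hotspot rule is defined on CpG islands",
         call. = FALSE)
  }
  qual <- records[records$dmv >= params$min_dmv, , drop = FALSE]
  if (params$require_hyper) {
    qual <- qual[qual$direction == "hyper", , drop = FALSE]
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      n_qualifying = integer(0), mean_dmv = numeric(0),
                      max_dmv = numeric(0), span_start = integer(0),
                      span_end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(qual)) {
    return(structure(empty, supporting = list(), params = params,
                     class = c("hotspot_calls", "data.frame")))
  }
  check_chrom_namespace(qual$chrom, iv$chrom, "DML records", "island track")
  hits <- GenomicRanges::findOverlaps(loci_granges(qual$chrom, qual$pos),
                                      as_granges(islands))
  li <- S4Vectors::queryHits(hits)
  ii <- S4Vectors::subjectHits(hits)
  calls <- list(); supporting <- list()
  for (isl in unique(ii)) {
    rows <- li[ii == isl]
    if (length(rows) < params$min_dml) next
    sub <- qual[rows, , drop = FALSE]
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = iv$chrom[isl], start = iv$start[isl], end = iv$end[isl],
      name = iv$name[isl], n_qualifying = length(rows),
      mean_dmv = mean(sub$dmv), max_dmv = max(sub$dmv),
      span_start = min(sub$pos), span_end = max(sub$pos),
      stringsAsFactors = FALSE
    )
    supporting[[iv$name[isl]]] <- sub
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, supporting = supporting[out$name], params = params,
            class = c("hotspot_calls", "data.frame"))
}

#' Score hotspot recovery against planted truth
#'
#' Islands are matched by exact identity (name). Sensitivity is the fraction
#' of planted islands called; false positives are called islands that were
#' not planted.
#'
#' @param calls a `hotspot_calls` from [call_hotspots()].
#' @param truth a [simulation_truth()].
#' @return list with `n_planted`, `n_recovered`, `sensitivity`,
#'   `n_false_positive`, `recovered` and `false_positive` island names.
#' @export
score_recovery <- function(calls, truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  planted <- truth$planted_hotspot_islands
  if (nrow(calls) && nrow(planted)) {
    check_chrom_namespace(calls$chrom, planted$chrom, "hotspot calls",
                          "planted truth")
  }
  recovered <- intersect(planted$name, calls$name)
  fp <- setdiff(calls$name, planted$name)
  list(
    n_planted = nrow(planted),
    n_recovered = length(recovered),
    sensitivity = if (nrow(planted)) length(recovered) / nrow(planted)
                  else NA_real_,
    n_false_positive = length(fp),
    recovered = recovered,
    false_positive = fp
  )
}
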