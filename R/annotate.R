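# Genomic-context annotation of DML and per-context hyper/hypo summaries.

#' Annotate DML with genomic contexts
#'
#' Each record receives the set of categories whose intervals contain its
#' position (multi-label: a locus can be both CPGI and TSS1500). Membership
#' is point containment of the 1-based position; overlapping intervals of a
#' track are never merged.
#'
#' @param records DML records from [call_dml()] (or any data.frame with
#'   `chrom` and `pos`).
#' @param tracks list of [annotation_track()]s with distinct categories.
#' @return `records` with a `contexts` column (comma-separated category
#'   labels, `""` when in no track); the categories supplied are kept in the
#'   `context_categories` attribute.
#' @export
annotate_dml <- function(records, tracks) {
  if (!length(tracks)) stop("no annotation tracks supplied", call. = FALSE)
  ok <- vapply(tracks, inherits, TRUE, "annotation_track")
  if (!all(ok)) stop("tracks must be annotation_track objects", call. = FALSE)
  cats <- vapply(tracks, `[[`, "", "category")
  if (anyDuplicated(cats)) {
    stop("duplicate track categories: ",
         paste(cats[duplicated(cats)], collapse = ", "), call. = FALSE)
  }
  cats <- TRACK_CATEGORIES[TRACK_CATEGORIES %in% cats]
  tracks <- tracks[match(cats, vapply(tracks, `[[`, "", "category"))]
  if (nrow(records)) {
    track_chroms <- unlist(lapply(tracks, function(t) t$intervals$chrom))
    check_chrom_namespace(records$chrom, track_chroms, "DML records",
                          "annotation tracks")
    gr_loci <- loci_granges(records$chrom, records$pos)
    member <- vapply(tracks, function(t) {
      if (!nrow(t$intervals)) return(rep(FALSE, nrow(records)))
      IRanges::overlapsAny(gr_loci, as_granges(t))
    }, logical(nrow(records)))
    member <- matrix(member, nrow = nrow(records),
                     dimnames = list(NULL, cats))
    contexts <- apply(member, 1L, function(row) {
      paste(cats[row], collapse = ",")
    })
  } else {
    contexts <- character(0)
  }
  out <- records
  out$contexts <- contexts
  attr(out, "context_categories") <- cats
  for (at in c("n_united", "n_dml", "n_hyper", "n_hypo", "label_a",
               "label_b", "params")) {
    attr(out, at) <- attr(records, at)
  }
  class(out) <- unique(c("dml_records", class(out)))
  out
}

#' Per-context hyper/hypo summary
#'
#' One row per category (`genome_wide` first, then every annotated category,
#' including categories with zero DML). `genome_wide` counts every record
#' exactly once; a record contributes to every category it overlaps.
#'
#' @param annotated records from [annotate_dml()].
#' @return a data.frame with `category`, `n_dml`, `n_hyper`, `n_hypo`,
#'   `pct_hyper`, `pct_hypo`.
#' @export
summarize_contexts <- function(annotated) {
  if (is.null(annotated$contexts)) {
    stop("records carry no contexts; run annotate_dml() first", call. = FALSE)
  }
  cats <- attr(annotated, "context_categories")
  if (is.null(cats)) {
    cats <- TRACK_CATEGORIES[TRACK_CATEGORIES %in%
                               unlist(strsplit(annotated$contexts, ","))]
  }
  ctx_list <- strsplit(annotated$contexts, ",", fixed = TRUE)
  is_hyper <- annotated$direction == "hyper"
  one <- function(category, sel) {
    n <- sum(sel); nh <- sum(sel & is_hyper)
    data.frame(category = category, n_dml = n, n_hyper = nh,
               n_hypo = n - nh,
               pct_hyper = if (n > 0) 100 * nh / n else NA_real_,
               pct_hypo = if (n > 0) 100 * (n - nh) / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- c(list(one("genome_wide", rep(TRUE, nrow(annotated)))),
            lapply(cats, function(cc) {
              one(cc, vapply(ctx_list, function(v) cc %in% v, TRUE))
            }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
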