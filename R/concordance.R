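# Cross-platform validation analytics: per-locus agreement between two
# measurement platforms over target regions, depth summaries, and
# per-amplicon group tests.

#' Pair per-locus measurements from two platforms
#'
#' Loci inside the target regions measured (coverage >= 1) on both platforms
#' are paired by exact locus identity; both pools must share the same strand
#' convention (destrand both identically beforehand). Unpaired loci are
#' listed in the `drop_report` attribute.
#'
#' @param pool_p1,pool_p2 [pool_methylome()]s of the same biological pool on
#'   the two platforms.
#' @param target_regions intervals (1-based closed data.frame or
#'   [annotation_track()]) of the targeted amplicons.
#' @return data.frame with `chrom`, `pos`, `strand`, `amplicon`, `pct_p1`,
#'   `pct_p2`, `cov_p1`, `cov_p2`.
#' @export
pair_platforms <- function(pool_p1, pool_p2, target_regions) {
  iv <- if (inherits(target_regions, "annotation_track")) {
    target_regions$intervals
  } else {
    as.data.frame(target_regions)
  }
  if (!nrow(iv)) stop("no target regions supplied", call. = FALSE)
  if (is.null(iv$name)) iv$name <- paste0("amplicon_", seq_len(nrow(iv)))
  restrict <- function(pool) {
    hits <- GenomicRanges::findOverlaps(loci_granges(pool$chrom, pool$pos),
                                        as_granges(iv))
    qi <- S4Vectors::queryHits(hits)
    first <- !duplicated(qi)
    out <- as.data.frame(pool)[qi[first], , drop = FALSE]
    out$amplicon <- iv$name[S4Vectors::subjectHits(hits)[first]]
    out[coverage_of(out) >= 1L, , drop = FALSE]
  }
  d1 <- restrict(pool_p1); d2 <- restrict(pool_p2)
  m <- merge(d1, d2, by = c("chrom", "pos", "strand"),
             suffixes = c("_p1", "_p2"))
  if (!nrow(m)) {
    stop("no loci inside the target regions are covered on both platforms",
         call. = FALSE)
  }
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  drop1 <- d1[!key(d1) %in% key(m), c("chrom", "pos", "strand"), drop = FALSE]
  drop2 <- d2[!key(d2) %in% key(m), c("chrom", "pos", "strand"), drop = FALSE]
  drop_report <- rbind(
    if (nrow(drop1)) cbind(drop1, platform = "p1_only"),
    if (nrow(drop2)) cbind(drop2, platform = "p2_only")
  )
  pairs <- data.frame(
    chrom = m$chrom, pos = m$pos, strand = m$strand,
    amplicon = m$amplicon_p1,
    pct_p1 = 100 * m$meth_p1 / (m$meth_p1 + m$unmeth_p1),
    pct_p2 = 100 * m$meth_p2 / (m$meth_p2 + m$unmeth_p2),
    cov_p1 = m$meth_p1 + m$unmeth_p1,
    cov_p2 = m$meth_p2 + m$unmeth_p2,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$chrom, pairs$pos, pairs$strand), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, drop_report = drop_report,
            pool = attr(pool_p1, "label"),
            class = c("paired_measurements", "data.frame"))
}

#' Concordance statistics for paired platform measurements
#'
#' Pearson r over the pooled pairs and R^2 defined as its square, per-pool
#' mean depth per platform (raw and log10, as deep targeted assays are
#' usually displayed), and per-amplicon mean percent methylation per
#' platform. Zero variance on either axis flags the correlation undefined
#' (`NA`) rather than silently zero.
#'
#' @param pairs output of [pair_platforms()] (>= 3 pairs).
#' @return list with `n_loci`, `pearson_r`, `r_squared`, `depth`
#'   (per-platform mean and log10 mean), `per_amplicon`.
#' @export
concordance_stats <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 paired loci", call. = FALSE)
  v1 <- pairs$pct_p1; v2 <- pairs$pct_p2
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance on one platform; correlation undefined",
            call. = FALSE)
    r <- NA_real_
  } else {
    r <- stats::cor(v1, v2, method = "pearson")
  }
  per_amp <- do.call(rbind, lapply(split(pairs, pairs$amplicon),
                                   function(d) {
    data.frame(amplicon = d$amplicon[1L], n_loci = nrow(d),
               mean_pct_p1 = mean(d$pct_p1), mean_pct_p2 = mean(d$pct_p2),
               mean_cov_p1 = mean(d$cov_p1), mean_cov_p2 = mean(d$cov_p2),
               stringsAsFactors = FALSE)
  }))
  rownames(per_amp) <- NULL
  list(
    n_loci = nrow(pairs),
    pearson_r = r,
    r_squared = if (is.na(r)) NA_real_ else r^2,
    depth = list(
      mean_cov_p1 = mean(pairs$cov_p1),
      mean_cov_p2 = mean(pairs$cov_p2),
      mean_log10_cov_p1 = mean(log10(pairs$cov_p1)),
      mean_log10_cov_p2 = mean(log10(pairs$cov_p2))
    ),
    per_amplicon = per_amp
  )
}

#' Aggregate pool counts over target amplicons
#'
#' @param pool a [pool_methylome()].
#' @param target_regions amplicon intervals (1-based closed data.frame or
#'   [annotation_track()]).
#' @return data.frame with `amplicon`, `meth`, `unmeth` (summed counts).
#' @export
aggregate_amplicon_counts <- function(pool, target_regions) {
  iv <- if (inherits(target_regions, "annotation_track")) {
    target_regions$intervals
  } else {
    as.data.frame(target_regions)
  }
  if (is.null(iv$name)) iv$name <- paste0("amplicon_", seq_len(nrow(iv)))
  hits <- GenomicRanges::findOverlaps(loci_granges(pool$chrom, pool$pos),
                                      as_granges(iv))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(amplicon = iv$name, meth = 0L, unmeth = 0L,
                    stringsAsFactors = FALSE)
  if (length(qi)) {
    ms <- rowsum(pool$meth[qi], si)
    us <- rowsum(pool$unmeth[qi], si)
    idx <- as.integer(rownames(ms))
    out$meth[idx] <- ms[, 1L]
    out$unmeth[idx] <- us[, 1L]
  }
  out
}

#' Per-amplicon two-group exact test
#'
#' Two-sided Fisher exact test on the amplicon-aggregated 2x2 counts (case vs
#' control), with Benjamini-Hochberg q-values across amplicons.
#'
#' @param case_counts,control_counts data.frames from
#'   [aggregate_amplicon_counts()] over the same amplicons.
#' @return data.frame with per-amplicon counts, percent methylation, DMV,
#'   `p_value` and `q_value`.
#' @export
per_group_test <- function(case_counts, control_counts) {
  m <- merge(case_counts, control_counts, by = "amplicon",
             suffixes = c("_case", "_control"))
  if (!nrow(m)) stop("no shared amplicons", call. = FALSE)
  m <- m[order(m$amplicon), , drop = FALSE]
  p <- fisher_exact_2x2(m$meth_case, m$unmeth_case,
                        m$meth_control, m$unmeth_control)
  data.frame(
    amplicon = m$amplicon,
    meth_case = m$meth_case, unmeth_case = m$unmeth_case,
    meth_control = m$meth_control, unmeth_control = m$unmeth_control,
    pct_case = 100 * m$meth_case / (m$meth_case + m$unmeth_case),
    pct_control = 100 * m$meth_control /
      (m$meth_control + m$unmeth_control),
    dmv = compute_dmv(m$meth_case, m$unmeth_case, m$meth_control,
                      m$unmeth_control),
    p_value = p,
    q_value = bh_qvalues(p),
    stringsAsFactors = FALSE
  )
}
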