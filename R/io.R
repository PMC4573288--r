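# Containers and file formats.
#
# Internal coordinate convention: 1-based cytosine positions everywhere;
# interval containers are 1-based closed. BED's 0-based half-open convention
# is applied exactly once, at read/write time.

TRACK_CATEGORIES <- c("CPGI", "TSS1500", "UTR5", "Exon1", "GeneBody")

#' Construct a pool methylome
#'
#' A pool methylome holds per-cytosine methylated/unmethylated read counts for
#' one pooled sample (e.g. the H, DFS or MBC plasma pool). Rows are sorted by
#' (chrom, pos, strand) and keys are unique.
#'
#' @param df data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`"+"`/`"-"`), `meth`, `unmeth` (non-negative integer read counts).
#' @param label pool identifier (e.g. `"H"`).
#' @param destranded logical; `TRUE` once CpG dyad counts have been merged.
#' @param strand_known logical; `FALSE` for dialects that do not record strand.
#' @return a `pool_methylome` (a classed data.frame).
#' @export
pool_methylome <- function(df, label = NA_character_, destranded = FALSE,
                           strand_known = TRUE) {
  req <- c("chrom", "pos", "strand", "meth", "unmeth")
  if (!all(req %in% names(df))) {
    stop("pool_methylome requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, req]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$strand <- as.character(df$strand)
  df$meth <- as.integer(df$meth)
  df$unmeth <- as.integer(df$unmeth)
  if (nrow(df)) {
    if (any(df$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
    if (!all(df$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
    if (any(df$meth < 0L) || any(df$unmeth < 0L)) {
      stop("read counts must be non-negative", call. = FALSE)
    }
    df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
    if (anyDuplicated(df[c("chrom", "pos", "strand")])) {
      stop("duplicate (chrom, pos, strand) keys in pool", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, label = label, destranded = isTRUE(destranded),
            strand_known = isTRUE(strand_known),
            class = c("pool_methylome", "data.frame"))
}

#' Per-locus coverage of a pool methylome
#' @param pool a `pool_methylome`.
#' @return integer vector `meth + unmeth`.
#' @export
coverage_of <- function(pool) pool$meth + pool$unmeth

#' Per-locus percent methylation
#'
#' Defined only where coverage is positive; zero-coverage loci yield `NA`.
#'
#' @param pool a `pool_methylome`.
#' @return numeric vector in \[0, 100\] (or `NA`).
#' @export
percent_methylation <- function(pool) {
  cov <- coverage_of(pool)
  ifelse(cov > 0L, 100 * pool$meth / cov, NA_real_)
}

#' @export
print.pool_methylome <- function(x, ...) {
  cat(sprintf("pool_methylome '%s': %d loci on %d chromosome(s)%s%s\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom)),
              if (isTRUE(attr(x, "destranded"))) ", destranded" else "",
              if (!isTRUE(attr(x, "strand_known"))) ", strand unknown" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Construct an annotation track
#'
#' A named set of genomic intervals for one context category. Intervals are
#' stored 1-based closed and may overlap (no merging is performed; context
#' membership is "overlaps any interval of the track").
#'
#' @param category one of `"CPGI"`, `"TSS1500"`, `"UTR5"`, `"Exon1"`,
#'   `"GeneBody"`.
#' @param intervals data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and optionally `name`.
#' @return an `annotation_track`.
#' @export
annotation_track <- function(category, intervals) {
  if (!is.character(category) || length(category) != 1L ||
      !category %in% TRACK_CATEGORIES) {
    stop("unknown annotation category: ", paste(category, collapse = ","),
         "; must be one of ", paste(TRACK_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  intervals <- as.data.frame(intervals)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    stop("intervals require columns chrom, start, end", call. = FALSE)
  }
  if (is.null(intervals$name)) {
    intervals$name <- if (nrow(intervals)) {
      paste0(category, "_", seq_len(nrow(intervals)))
    } else character(0)
  }
  intervals <- intervals[c("chrom", "start", "end", "name")]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$name <- as.character(intervals$name)
  if (nrow(intervals)) {
    if (any(intervals$start < 1L) || any(intervals$end < intervals$start)) {
      stop("invalid interval: need 1 <= start <= end", call. = FALSE)
    }
    intervals <- intervals[order(intervals$chrom, intervals$start,
                                 intervals$end), , drop = FALSE]
  }
  rownames(intervals) <- NULL
  structure(list(category = category, intervals = intervals),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("annotation_track '%s': %d interval(s)\n",
              x$category, nrow(x$intervals)))
  invisible(x)
}

# GRanges view of a track or interval data.frame (1-based closed in, out).
#' @keywords internal
#' @noRd
as_granges <- function(x) {
  if (inherits(x, "annotation_track")) x <- x$intervals
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}

#' @keywords internal
#' @noRd
loci_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, end = pos))
}

# Chromosome namespaces are never silently coerced; disjoint namespaces are a
# configuration error (e.g. "1" vs "chr1").
#' @keywords internal
#' @noRd
check_chrom_namespace <- function(chroms_a, chroms_b, what_a, what_b) {
  a <- unique(as.character(chroms_a))
  b <- unique(as.character(chroms_b))
  if (length(a) && length(b) && !length(intersect(a, b))) {
    stop(sprintf(paste0("chromosome namespace mismatch between %s (%s) and ",
                        "%s (%s); no shared chromosome names"),
                 what_a, paste(utils::head(a, 3), collapse = ","),
                 what_b, paste(utils::head(b, 3), collapse = ",")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
#' @noRd
writer_header <- function(kind, params = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("cfmeth")),
                  error = function(e) "dev")
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=",
                      collapse = " "))
  } else ""
  sprintf("#cfmeth %s version=%s%s", kind, ver, extra)
}

#' @keywords internal
#' @noRd
read_tsv_lines <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], line_no = which(keep))
}

#' @keywords internal
#' @noRd
split_fields <- function(lines, line_no, n_fields, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_fields)
  if (length(bad)) {
    stop(sprintf("malformed %s row at line %d: expected %d tab-separated fields, got %d",
                 what, line_no[bad[1L]], n_fields, nf[bad[1L]]), call. = FALSE)
  }
  fields
}

#' @keywords internal
#' @noRd
parse_int_col <- function(x, line_no, what, col) {
  ok <- grepl("^[0-9]+$", x)
  if (!all(ok)) {
    stop(sprintf("malformed %s row at line %d: non-integer %s '%s'",
                 what, line_no[which(!ok)[1L]], col, x[which(!ok)[1L]]),
         call. = FALSE)
  }
  as.integer(x)
}

#' Read a Bismark cytosine report
#'
#' Seven tab-separated columns: chrom, 1-based position, strand, count
#' methylated, count unmethylated, context, trinucleotide. Rows whose context
#' differs from `context_filter` are skipped; zero-coverage rows are retained
#' (they carry position information) and their number is recorded in the
#' `n_zero_coverage` attribute.
#'
#' @param path file path.
#' @param context_filter cytosine context to retain (default `"CpG"`).
#' @param label pool label to attach.
#' @return a [pool_methylome()].
#' @export
read_cytosine_report <- function(path, context_filter = "CpG",
                                 label = NA_character_) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) {
    return(pool_methylome(data.frame(chrom = character(0), pos = integer(0),
                                     strand = character(0), meth = integer(0),
                                     unmeth = integer(0)), label = label))
  }
  fields <- split_fields(tl$lines, tl$line_no, 7L, "cytosine-report")
  m <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7L, byrow = TRUE)
  keep <- m[, 6L] == context_filter
  m <- m[keep, , drop = FALSE]
  ln <- tl$line_no[keep]
  if (!nrow(m)) {
    return(pool_methylome(data.frame(chrom = character(0), pos = integer(0),
                                     strand = character(0), meth = integer(0),
                                     unmeth = integer(0)), label = label))
  }
  bad_strand <- which(!m[, 3L] %in% c("+", "-"))
  if (length(bad_strand)) {
    stop(sprintf("malformed cytosine-report row at line %d: invalid strand '%s'",
                 ln[bad_strand[1L]], m[bad_strand[1L], 3L]), call. = FALSE)
  }
  pos <- parse_int_col(m[, 2L], ln, "cytosine-report", "position")
  meth <- parse_int_col(m[, 4L], ln, "cytosine-report", "methylated count")
  unmeth <- parse_int_col(m[, 5L], ln, "cytosine-report", "unmethylated count")
  pool <- pool_methylome(
    data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
               meth = meth, unmeth = unmeth, stringsAsFactors = FALSE),
    label = label
  )
  attr(pool, "n_zero_coverage") <- sum(meth + unmeth == 0L)
  pool
}

#' Write a Bismark-style cytosine report
#'
#' @param pool a [pool_methylome()].
#' @param path output path.
#' @param context cytosine context written in column 6 (default `"CpG"`).
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(pool, path, context = "CpG") {
  lines <- c(writer_header("cytosine-report",
                           list(pool = attr(pool, "label"))),
             if (nrow(pool)) {
               paste(pool$chrom, pool$pos, pool$strand, pool$meth,
                     pool$unmeth, context, "CGN", sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Six tab-separated columns: chrom, start, end (1-based inclusive), percent
#' methylation, count methylated, count unmethylated. Counts are taken from
#' columns 5-6 and percent methylation is recomputed; a row whose recorded
#' percentage deviates from the recomputed value by more than 0.5 points
#' triggers a warning (not an error). Strand is not recorded in this dialect:
#' loci are stored as `"+"` and the pool is flagged `strand_known = FALSE`.
#'
#' @param path file path.
#' @param label pool label to attach.
#' @return a [pool_methylome()].
#' @export
read_coverage_file <- function(path, label = NA_character_) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) {
    p <- pool_methylome(data.frame(chrom = character(0), pos = integer(0),
                                   strand = character(0), meth = integer(0),
                                   unmeth = integer(0)),
                        label = label, strand_known = FALSE)
    return(p)
  }
  fields <- split_fields(tl$lines, tl$line_no, 6L, "coverage")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  pos <- parse_int_col(m[, 2L], tl$line_no, "coverage", "position")
  meth <- parse_int_col(m[, 5L], tl$line_no, "coverage", "methylated count")
  unmeth <- parse_int_col(m[, 6L], tl$line_no, "coverage", "unmethylated count")
  pct_file <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(pct_file)) {
    stop(sprintf("malformed coverage row at line %d: non-numeric %% methylation",
                 tl$line_no[which(is.na(pct_file))[1L]]), call. = FALSE)
  }
  cov <- meth + unmeth
  pct_new <- ifelse(cov > 0L, 100 * meth / cov, 0)
  off <- which(abs(pct_new - pct_file) > 0.5)
  if (length(off)) {
    warning(sprintf(paste0("%d coverage row(s) with recorded %% methylation ",
                           "differing from counts by > 0.5 (first at line %d: ",
                           "recorded %.4g, recomputed %.4g); counts were kept"),
                    length(off), tl$line_no[off[1L]], pct_file[off[1L]],
                    pct_new[off[1L]]), call. = FALSE)
  }
  pool <- pool_methylome(
    data.frame(chrom = m[, 1L], pos = pos, strand = "+",
               meth = meth, unmeth = unmeth, stringsAsFactors = FALSE),
    label = label, strand_known = FALSE
  )
  attr(pool, "n_zero_coverage") <- sum(cov == 0L)
  pool
}

#' Write a Bismark-style coverage file
#'
#' @param pool a [pool_methylome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(pool, path) {
  cov <- coverage_of(pool)
  pct <- ifelse(cov > 0L, 100 * pool$meth / cov, 0)
  lines <- c(writer_header("coverage", list(pool = attr(pool, "label"))),
             if (nrow(pool)) {
               paste(pool$chrom, pool$pos, pool$pos, fmt_num(pct),
                     pool$meth, pool$unmeth, sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED track of genomic-context intervals
#'
#' BED3+ input, 0-based half-open; converted once to the internal 1-based
#' closed convention. Overlapping intervals are retained, never merged.
#'
#' @param path BED file path.
#' @param category context category for the track (see [annotation_track()]).
#' @return an [annotation_track()].
#' @export
read_bed_track <- function(path, category) {
  tl <- read_tsv_lines(path)
  tl$lines <- tl$lines[!startsWith(tl$lines, "track")]
  if (!length(tl$lines)) {
    return(annotation_track(category,
                            data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       name = character(0))))
  }
  fields <- split_fields(tl$lines, tl$line_no, 3L, "BED")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- parse_int_col(vapply(fields, `[`, "", 2L), tl$line_no, "BED",
                          "start")
  end0 <- parse_int_col(vapply(fields, `[`, "", 3L), tl$line_no, "BED", "end")
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop(sprintf("malformed BED row at line %d: start (%d) >= end (%d)",
                 tl$line_no[bad[1L]], start0[bad[1L]], end0[bad[1L]]),
         call. = FALSE)
  }
  name <- vapply(fields, function(f) {
    if (length(f) >= 4L && nzchar(f[4L])) f[4L] else NA_character_
  }, "")
  iv <- data.frame(chrom = chrom, start = start0 + 1L, end = end0,
                   name = name, stringsAsFactors = FALSE)
  if (anyNA(iv$name)) {
    iv$name[is.na(iv$name)] <- paste0(category, "_",
                                      which(is.na(iv$name)))
  }
  annotation_track(category, iv)
}

#' Write an annotation track (or any 1-based interval table) as BED
#'
#' @param track an [annotation_track()] or data.frame with `chrom`, `start`,
#'   `end`, `name` (1-based closed).
#' @param path output path.
#' @param extra_cols optional data.frame of additional columns.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path, extra_cols = NULL) {
  iv <- if (inherits(track, "annotation_track")) track$intervals else
    as.data.frame(track)
  body <- if (nrow(iv)) {
    line <- paste(iv$chrom, iv$start - 1L, iv$end, iv$name, sep = "\t")
    if (!is.null(extra_cols) && nrow(iv)) {
      more <- apply(as.data.frame(extra_cols), 1L, paste, collapse = "\t")
      line <- paste(line, more, sep = "\t")
    }
    line
  }
  writeLines(c(writer_header("bed"), body), path)
  invisible(path)
}

DML_COLUMNS <- c("chrom", "pos", "strand", "meth_a", "unmeth_a", "meth_b",
                 "unmeth_b", "pct_a", "pct_b", "dmv", "p_value", "q_value",
                 "direction")

#' Write a table of differentially methylated loci
#'
#' Tab-separated, deterministic column order; an optional `contexts` column is
#' appended when present. A commented header records the calling parameters.
#'
#' @param records DML records (see [call_dml()]).
#' @param path output path.
#' @param params optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_dml_table <- function(records, path, params = NULL) {
  cols <- DML_COLUMNS
  if ("contexts" %in% names(records)) cols <- c(cols, "contexts")
  header <- paste(cols, collapse = "\t")
  body <- if (nrow(records)) {
    vals <- data.frame(
      records$chrom, records$pos, records$strand,
      records$meth_a, records$unmeth_a, records$meth_b, records$unmeth_b,
      fmt_num(records$pct_a), fmt_num(records$pct_b), fmt_num(records$dmv),
      fmt_num(records$p_value, 12), fmt_num(records$q_value, 12),
      records$direction, stringsAsFactors = FALSE
    )
    if ("contexts" %in% cols) vals$contexts <- records$contexts
    do.call(paste, c(unname(vals), sep = "\t"))
  }
  writeLines(c(writer_header("dml-table", params), header, body), path)
  invisible(path)
}

#' Read back a DML table written by [write_dml_table()]
#'
#' @param path file path.
#' @return a data.frame of DML records.
#' @export
read_dml_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         strand = "character",
                                         direction = "character"))
  df$pos <- as.integer(df$pos)
  for (cc in c("meth_a", "unmeth_a", "meth_b", "unmeth_b")) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  df
}

#' Write hotspot calls as BED
#'
#' Island coordinates are converted to the 0-based half-open BED convention;
#' columns are chrom, start, end, name, n_qualifying, mean_dmv, max_dmv,
#' span_start, span_end (the minimal 1-based window of qualifying loci).
#'
#' @param calls hotspot calls (see [call_hotspots()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_bed <- function(calls, path) {
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$start - 1L, calls$end, calls$name,
          calls$n_qualifying, fmt_num(calls$mean_dmv),
          fmt_num(calls$max_dmv), calls$span_start, calls$span_end,
          sep = "\t")
  }
  writeLines(c(writer_header("hotspot-bed"), body), path)
  invisible(path)
}

#' Read back a hotspot BED written by [write_hotspot_bed()]
#' @param path file path.
#' @return a data.frame with 1-based closed `start`/`end`.
#' @export
read_hotspot_bed <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      n_qualifying = integer(0), mean_dmv = numeric(0),
                      max_dmv = numeric(0), span_start = integer(0),
                      span_end = integer(0)))
  }
  f <- split_fields(tl$lines, tl$line_no, 9L, "hotspot BED")
  m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]) + 1L,
             end = as.integer(m[, 3L]), name = m[, 4L],
             n_qualifying = as.integer(m[, 5L]),
             mean_dmv = as.numeric(m[, 6L]), max_dmv = as.numeric(m[, 7L]),
             span_start = as.integer(m[, 8L]),
             span_end = as.integer(m[, 9L]), stringsAsFactors = FALSE)
}

#' Write a run summary (or any list) as JSON
#'
#' Full double precision is kept so that summaries round-trip losslessly.
#'
#' @param x a list or data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a JSON summary written by [write_summary_json()]
#' @param path file path.
#' @return the parsed object.
#' @export
read_summary_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
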