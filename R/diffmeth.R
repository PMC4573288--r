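# Per-base two-group differential methylation: destranding, uniting at a
# minimum coverage, Fisher's exact test, differential methylation values
# (DMV), Benjamini-Hochberg q-values, and DML calling.

#' Parameters for differential methylation calling
#'
#' Defaults follow the standard per-base calling rule for pooled bisulfite
#' comparisons: minimum coverage 5 in each group, |DMV| >= 20 percentage
#' points, P < 0.05, sex chromosomes removed. The q-value bound is off by
#' default (the genome-wide call uses P and DMV only) and is typically set to
#' 0.5 when emulating a targeted amplicon validation analysis.
#'
#' @param min_coverage minimum read coverage required in *both* groups.
#' @param dmv_threshold minimum |DMV| in percentage points (inclusive).
#' @param p_threshold significance level (inclusive).
#' @param q_threshold optional FDR bound; `NA` disables it.
#' @param exclude_chromosomes chromosome names removed before testing.
#' @param destrand merge CpG dyad strands before uniting (default `TRUE`).
#' @return a `diffmeth_params`.
#' @export
diffmeth_params <- function(min_coverage = 5L,
                            dmv_threshold = 20,
                            p_threshold = 0.05,
                            q_threshold = NA_real_,
                            exclude_chromosomes = c("X", "Y", "chrX", "chrY"),
                            destrand = TRUE) {
  assert_scalar_number(min_coverage, "min_coverage", min = 1)
  assert_scalar_number(dmv_threshold, "dmv_threshold", min = 1e-12, max = 100)
  assert_scalar_number(p_threshold, "p_threshold", min = 1e-300,
                       max = 1 - 1e-12)
  assert_scalar_number(q_threshold, "q_threshold", min = 0, max = 1,
                       allow_na = TRUE)
  structure(list(min_coverage = as.integer(min_coverage),
                 dmv_threshold = dmv_threshold, p_threshold = p_threshold,
                 q_threshold = q_threshold,
                 exclude_chromosomes = as.character(exclude_chromosomes),
                 destrand = isTRUE(destrand)),
            class = "diffmeth_params")
}

#' Merge CpG dyad strands
#'
#' Counts of the minus-strand cytosine at position p are added to the
#' plus-strand cytosine at p - 1 (the dyad position). Minus-strand loci with
#' no plus partner are emitted as their own plus-strand locus at the dyad
#' position (their number is reported in a message and in the
#' `n_orphan_minus` attribute).
#'
#' @param pool a [pool_methylome()].
#' @return a destranded [pool_methylome()] (all loci on `"+"`).
#' @export
destrand_merge <- function(pool) {
  stopifnot(inherits(pool, "pool_methylome"))
  if (isTRUE(attr(pool, "destranded"))) return(pool)
  minus <- pool$strand == "-"
  dyad <- ifelse(minus, pool$pos - 1L, pool$pos)
  if (any(dyad < 1L)) {
    stop("minus-strand locus at position 1 has no valid dyad position",
         call. = FALSE)
  }
  ord <- order(pool$chrom, dyad)
  chrom <- pool$chrom[ord]; dpos <- dyad[ord]
  new_grp <- !duplicated(data.frame(chrom, dpos))
  grp <- cumsum(new_grp)
  meth <- rowsum(pool$meth[ord], grp, reorder = FALSE)[, 1L]
  unmeth <- rowsum(pool$unmeth[ord], grp, reorder = FALSE)[, 1L]
  # orphans: dyad groups fed only by a minus-strand locus
  has_plus <- rowsum(as.integer(!minus[ord]), grp, reorder = FALSE)[, 1L] > 0L
  has_minus <- rowsum(as.integer(minus[ord]), grp, reorder = FALSE)[, 1L] > 0L
  n_orphan <- sum(has_minus & !has_plus)
  if (n_orphan > 0L) {
    message(sprintf(paste0("[destrand] %d minus-strand locus/loci without a ",
                           "plus partner kept at their dyad position"),
                    n_orphan))
  }
  out <- pool_methylome(
    data.frame(chrom = chrom[new_grp], pos = dpos[new_grp], strand = "+",
               meth = meth, unmeth = unmeth, stringsAsFactors = FALSE),
    label = attr(pool, "label"), destranded = TRUE,
    strand_known = attr(pool, "strand_known")
  )
  attr(out, "n_orphan_minus") <- n_orphan
  out
}

#' Unite two pools at a minimum per-group coverage
#'
#' Only loci with coverage >= `min_coverage` in *both* pools are retained.
#' Pool `a` is the case group (its percent methylation enters the DMV with a
#' positive sign).
#'
#' @param a,b [pool_methylome()]s on the same strand convention.
#' @param min_coverage minimum coverage per group (default 5).
#' @return a data.frame with per-locus paired counts (`meth_a`, `unmeth_a`,
#'   `meth_b`, `unmeth_b`); labels kept as attributes.
#' @export
unite_pools <- function(a, b, min_coverage = 5L) {
  stopifnot(inherits(a, "pool_methylome"), inherits(b, "pool_methylome"))
  if (!identical(isTRUE(attr(a, "destranded")),
                 isTRUE(attr(b, "destranded")))) {
    stop("pools differ in destranding status; normalize before uniting",
         call. = FALSE)
  }
  assert_scalar_number(min_coverage, "min_coverage", min = 1)
  da <- as.data.frame(a); db <- as.data.frame(b)
  names(da)[names(da) %in% c("meth", "unmeth")] <- c("meth_a", "unmeth_a")
  names(db)[names(db) %in% c("meth", "unmeth")] <- c("meth_b", "unmeth_b")
  m <- merge(da, db, by = c("chrom", "pos", "strand"))
  n_common <- nrow(m)
  keep <- (m$meth_a + m$unmeth_a) >= min_coverage &
    (m$meth_b + m$unmeth_b) >= min_coverage
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$chrom, m$pos, m$strand), , drop = FALSE]
  rownames(m) <- NULL
  log_filter("unite", n_common, nrow(m),
             sprintf("coverage >= %d in both groups", min_coverage))
  if (!nrow(m)) {
    warning("no loci shared at the required coverage; united table is empty",
            call. = FALSE)
  }
  structure(m, label_a = attr(a, "label"), label_b = attr(b, "label"),
            class = c("united_counts", "data.frame"))
}

#' Two-sided Fisher exact test for 2x2 methylation count tables
#'
#' Vectorised conditional-hypergeometric computation: with both group
#' coverages fixed as margins, the two-sided p-value is the total probability
#' of all tables whose point probability does not exceed that of the observed
#' table. P-values are exact, never zero, and capped at 1.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b non-negative integer count vectors
#'   (recycled to a common length); both group coverages must be positive.
#' @return numeric vector of two-sided p-values in (0, 1\].
#' @export
fisher_exact_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- max(length(meth_a), length(unmeth_a), length(meth_b),
           length(unmeth_b))
  if (n == 0L) return(numeric(0))
  ma <- rep_len(as.numeric(meth_a), n); ua <- rep_len(as.numeric(unmeth_a), n)
  mb <- rep_len(as.numeric(meth_b), n); ub <- rep_len(as.numeric(unmeth_b), n)
  if (anyNA(c(ma, ua, mb, ub)) || any(c(ma, ua, mb, ub) < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  ra <- ma + ua; rb <- mb + ub
  if (any(ra == 0) || any(rb == 0)) {
    stop("both group coverages must be positive", call. = FALSE)
  }
  cm <- ma + mb          # methylated-column margin
  tot <- ra + rb
  vapply(seq_len(n), function(i) {
    lo <- max(0, cm[i] - rb[i]); hi <- min(ra[i], cm[i])
    k <- lo:hi
    # log space: point probabilities underflow for deeply sequenced tables
    ld <- stats::dhyper(k, cm[i], tot[i] - cm[i], ra[i], log = TRUE)
    ld_obs <- ld[match(ma[i], k)]
    sel <- ld <= ld_obs + log1p(1e-7)
    m <- max(ld[sel])
    p <- exp(m) * sum(exp(ld[sel] - m))
    min(1, max(p, .Machine$double.xmin))
  }, numeric(1))
}

#' Differential methylation value (DMV)
#'
#' `100 * meth_a / cov_a - 100 * meth_b / cov_b`, in percentage points;
#' positive when the case group (a) is more methylated.
#'
#' @inheritParams fisher_exact_2x2
#' @return numeric vector in \[-100, 100\].
#' @export
compute_dmv <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  cov_a <- meth_a + unmeth_a; cov_b <- meth_b + unmeth_b
  if (any(cov_a <= 0) || any(cov_b <= 0)) {
    stop("DMV requires positive coverage in both groups", call. = FALSE)
  }
  100 * meth_a / cov_a - 100 * meth_b / cov_b
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values via [stats::p.adjust()]: monotone after sorting by p and
#' never below the corresponding p-value.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return numeric vector of q-values, same order as input.
#' @export
bh_qvalues <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated loci between two pools
#'
#' Excluded chromosomes are removed first; pools are destranded (unless
#' disabled), united at the coverage floor, tested per locus with the exact
#' test, and DMV and BH q-values computed over all united loci. A locus is a
#' DML iff |DMV| >= `dmv_threshold` AND p <= `p_threshold` AND (when set)
#' q <= `q_threshold`. Direction is `"hyper"` when the case pool (`a`) is
#' more methylated.
#'
#' @param a case pool (e.g. the MBC-like pool).
#' @param b control pool.
#' @param params a [diffmeth_params()].
#' @return a data.frame of DML records (class `dml_records`) with columns
#'   `chrom`, `pos`, `strand`, counts, `pct_a`, `pct_b`, `dmv`, `p_value`,
#'   `q_value`, `direction`; attributes record the united/tested/called
#'   counts, labels and parameters.
#' @export
call_dml <- function(a, b, params = diffmeth_params()) {
  stopifnot(inherits(params, "diffmeth_params"))
  drop_chroms <- function(pool) {
    n0 <- nrow(pool)
    out <- pool[!pool$chrom %in% params$exclude_chromosomes, , drop = FALSE]
    if (nrow(out) < n0) {
      log_filter("exclude-chromosomes", n0, nrow(out),
                 paste("removed", paste(params$exclude_chromosomes,
                                        collapse = ",")))
    }
    pool_methylome(out, label = attr(pool, "label"),
                   destranded = attr(pool, "destranded"),
                   strand_known = attr(pool, "strand_known"))
  }
  a <- drop_chroms(a); b <- drop_chroms(b)
  if (params$destrand) {
    a <- destrand_merge(a)
    b <- destrand_merge(b)
  }
  u <- unite_pools(a, b, min_coverage = params$min_coverage)
  if (!nrow(u)) {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), meth_a = integer(0),
                      unmeth_a = integer(0), meth_b = integer(0),
                      unmeth_b = integer(0), pct_a = numeric(0),
                      pct_b = numeric(0), dmv = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
    return(structure(rec, n_united = 0L, n_dml = 0L, n_hyper = 0L,
                     n_hypo = 0L, label_a = attr(u, "label_a"),
                     label_b = attr(u, "label_b"), params = params,
                     class = c("dml_records", "data.frame")))
  }
  p <- fisher_exact_2x2(u$meth_a, u$unmeth_a, u$meth_b, u$unmeth_b)
  q <- bh_qvalues(p)
  dmv <- compute_dmv(u$meth_a, u$unmeth_a, u$meth_b, u$unmeth_b)
  pass <- abs(dmv) >= params$dmv_threshold & p <= params$p_threshold
  if (!is.na(params$q_threshold)) pass <- pass & q <= params$q_threshold
  rule <- sprintf("|DMV| >= %g and p <= %g%s", params$dmv_threshold,
                  params$p_threshold,
                  if (!is.na(params$q_threshold)) {
                    sprintf(" and q <= %g", params$q_threshold)
                  } else "")
  log_filter("call-dml", nrow(u), sum(pass), rule)
  rec <- data.frame(
    chrom = u$chrom, pos = u$pos, strand = u$strand,
    meth_a = u$meth_a, unmeth_a = u$unmeth_a,
    meth_b = u$meth_b, unmeth_b = u$unmeth_b,
    pct_a = 100 * u$meth_a / (u$meth_a + u$unmeth_a),
    pct_b = 100 * u$meth_b / (u$meth_b + u$unmeth_b),
    dmv = dmv, p_value = p, q_value = q,
    direction = ifelse(dmv > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )[pass, , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec,
            n_united = nrow(u), n_dml = nrow(rec),
            n_hyper = sum(rec$direction == "hyper"),
            n_hypo = sum(rec$direction == "hypo"),
            p_values_united = p,
            label_a = attr(u, "label_a"), label_b = attr(u, "label_b"),
            params = params,
            class = c("dml_records", "data.frame"))
}

#' Hyper/hypo summary of a DML call
#'
#' @param records a `dml_records` from [call_dml()].
#' @return one-row data.frame with counts and percentages of hyper- and
#'   hypomethylated DML (direction relative to the case pool).
#' @export
dml_summary <- function(records) {
  n <- nrow(records)
  n_hyper <- sum(records$direction == "hyper")
  n_hypo <- n - n_hyper
  data.frame(
    case = attr(records, "label_a") %||% NA_character_,
    control = attr(records, "label_b") %||% NA_character_,
    n_united = attr(records, "n_united") %||% NA_integer_,
    n_dml = n, n_hyper = n_hyper, n_hypo = n_hypo,
    pct_hyper = if (n > 0) 100 * n_hyper / n else NA_real_,
    pct_hypo = if (n > 0) 100 * n_hypo / n else NA_real_,
    stringsAsFactors = FALSE
  )
}
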