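# Pool-level similarity analyses: pairwise Pearson correlation of percent
# methylation profiles, Ward hierarchical clustering on correlation distance,
# PCA of the profiles, and per-base percent methylation histograms.

#' Build common-locus percent methylation profiles
#'
#' Profiles are restricted to the loci covered at `min_coverage` or more in
#' *every* pool (the same floor used for DML calling), so all profiles share
#' one locus index.
#'
#' @param pools named list of two or more [pool_methylome()]s on the same
#'   strand convention.
#' @param min_coverage per-pool coverage floor (default 5).
#' @return a `meth_profiles`: list with `loci` (data.frame `chrom`, `pos`,
#'   `strand`) and `values` (numeric matrix, loci x pools, percent
#'   methylation in \[0, 100\]).
#' @export
build_profiles <- function(pools, min_coverage = 5L) {
  stopifnot(is.list(pools), length(pools) >= 2L)
  labels <- names(pools) %||% vapply(pools, function(p) {
    as.character(attr(p, "label"))
  }, "")
  if (is.null(names(pools))) names(pools) <- labels
  key <- function(p) paste(p$chrom, p$pos, p$strand, sep = "\r")
  covered <- lapply(pools, function(p) key(p)[coverage_of(p) >= min_coverage])
  common <- Reduce(intersect, covered)
  if (!length(common)) {
    stop(sprintf(paste0("no loci covered >= %d in all %d pools ",
                        "(per-pool covered-locus counts: %s)"),
                 min_coverage, length(pools),
                 paste(lengths(covered), collapse = ", ")), call. = FALSE)
  }
  first <- pools[[1L]]
  idx <- match(common, key(first))
  loci <- data.frame(chrom = first$chrom[idx], pos = first$pos[idx],
                     strand = first$strand[idx], stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos, loci$strand)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  common <- paste(loci$chrom, loci$pos, loci$strand, sep = "\r")
  values <- vapply(pools, function(p) {
    i <- match(common, key(p))
    100 * p$meth[i] / (p$meth[i] + p$unmeth[i])
  }, numeric(length(common)))
  values <- matrix(values, ncol = length(pools),
                   dimnames = list(NULL, names(pools)))
  structure(list(loci = loci, values = values), class = "meth_profiles")
}

#' Pairwise Pearson correlation of methylation profiles
#'
#' @param profiles a `meth_profiles` from [build_profiles()].
#' @return symmetric correlation matrix with unit diagonal; entries involving
#'   a zero-variance profile are `NA` (with a warning), never silently 0.
#' @export
pairwise_pearson <- function(profiles) {
  v <- profiles$values
  if (nrow(v) < 2L) stop("profiles need at least 2 loci", call. = FALSE)
  sds <- apply(v, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(v, method = "pearson"))
  if (any(sds == 0)) {
    warning("zero-variance profile(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Ward hierarchical clustering on correlation distance
#'
#' Distance is `1 - r`; linkage is Ward (`"ward.D2"`).
#'
#' @param pearson_matrix symmetric correlation matrix (as from
#'   [pairwise_pearson()]).
#' @return an [stats::hclust] object (merge order and heights).
#' @export
ward_cluster <- function(pearson_matrix) {
  m <- as.matrix(pearson_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - m), method = "ward.D2")
}

#' PCA of methylation profiles
#'
#' Profiles are centered per locus (column means removed) and decomposed with
#' [stats::prcomp()]. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so scores are reproducible.
#'
#' @param profiles a `meth_profiles`.
#' @param n_components number of components to return (default 2, at most
#'   `n_pools - 1`).
#' @return list with `scores` (pools x components), `explained` (variance
#'   fractions, non-increasing) and `loadings`.
#' @export
pca_profiles <- function(profiles, n_components = 2L) {
  x <- t(profiles$values)   # pools x loci
  n_pools <- nrow(x)
  max_comp <- n_pools - 1L
  if (ncol(x) < n_components) {
    stop("fewer loci than components requested", call. = FALSE)
  }
  if (n_components > max_comp) {
    stop(sprintf("at most %d component(s) available for %d pools",
                 max_comp, n_pools), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  list(scores = scores, explained = (ev / sum(ev))[k], loadings = loadings)
}

#' Histogram of per-base percent methylation
#'
#' Equal-width bins over \[0, 100\]; values at 100 fall in the top bin. The
#' counts always sum to the number of values.
#'
#' @param values numeric vector of percent methylation (one profile column),
#'   or a `meth_profiles` plus `pool` name.
#' @param n_bins number of bins (>= 2, default 20).
#' @param pool when `values` is a `meth_profiles`, which pool to bin.
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
methylation_histogram <- function(values, n_bins = 20L, pool = NULL) {
  if (inherits(values, "meth_profiles")) {
    stopifnot(!is.null(pool))
    values <- values$values[, pool]
  }
  assert_scalar_number(n_bins, "n_bins", min = 2)
  n_bins <- as.integer(n_bins)
  if (any(values < 0 | values > 100, na.rm = TRUE)) {
    stop("percent methylation values must lie in [0, 100]", call. = FALSE)
  }
  values <- values[!is.na(values)]
  width <- 100 / n_bins
  bin <- pmin(floor(values / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(bin_low = (seq_len(n_bins) - 1L) * width,
             bin_high = seq_len(n_bins) * width,
             count = counts)
}

#' Full pool-similarity report
#'
#' Pairwise Pearson matrix, Ward dendrogram, PCA scores, and per-pool
#' histograms on the common covered loci; optionally repeated per chromosome
#' (sex chromosomes excluded).
#'
#' @param pools named list of [pool_methylome()]s.
#' @param min_coverage coverage floor for the common-locus profiles.
#' @param n_bins histogram bins.
#' @param per_chromosome also compute per-chromosome histograms.
#' @param exclude_chromosomes chromosomes dropped from the per-chromosome
#'   analysis.
#' @return a list (`similarity_report`): `pearson`, `clustering` (merge,
#'   height, labels), `pca` (scores, explained), `histograms`, `n_loci`
#'   (and `per_chromosome` when requested).
#' @export
similarity_report <- function(pools, min_coverage = 5L, n_bins = 20L,
                              per_chromosome = FALSE,
                              exclude_chromosomes = c("X", "Y", "chrX",
                                                      "chrY")) {
  profiles <- build_profiles(pools, min_coverage = min_coverage)
  r <- pairwise_pearson(profiles)
  hc <- ward_cluster(r)
  pca <- pca_profiles(profiles, n_components = min(2L, length(pools) - 1L))
  hists <- lapply(colnames(profiles$values), function(lab) {
    methylation_histogram(profiles$values[, lab], n_bins = n_bins)
  })
  names(hists) <- colnames(profiles$values)
  rep <- list(pearson = r,
              clustering = list(merge = hc$merge, height = hc$height,
                                labels = hc$labels, order = hc$order),
              pca = pca, histograms = hists, n_loci = nrow(profiles$values))
  if (per_chromosome) {
    chroms <- setdiff(unique(profiles$loci$chrom), exclude_chromosomes)
    rep$per_chromosome <- lapply(stats::setNames(chroms, chroms),
                                 function(ch) {
      sel <- profiles$loci$chrom == ch
      lapply(stats::setNames(colnames(profiles$values),
                             colnames(profiles$values)), function(lab) {
        methylation_histogram(profiles$values[sel, lab], n_bins = n_bins)
      })
    })
  }
  structure(rep, class = "similarity_report")
}
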