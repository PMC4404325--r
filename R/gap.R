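# Histogram analysis of pairwise distances: natural breaks ("barcode
# gaps") between the intraspecific and interspecific distance
# distributions, and single-linkage threshold clustering of haplotypes
# into putative species.

#' Bin pairwise distances into a histogram
#'
#' Half-open bins `[k*w, (k+1)*w)` over the strict upper triangle of the
#' distance matrix; non-estimable (`NA`) distances are excluded from the
#' histogram and reported in the result.
#'
#' @param m A `"dist_matrix"`.
#' @param bin_width Bin width in substitutions/site (default 0.0025, i.e.
#'   0.25%, matching the one-decimal-percent resolution at which barcode
#'   gaps are conventionally reported).
#' @return Object of class `"gap_analysis"`: list with `bin_width`,
#'   `counts` (integer vector; element k is the bin `[(k-1)w, kw)`),
#'   `n_pairs`, `n_na`, and `breaks` (`NULL` until [detect_gaps()]).
#' @export
distance_histogram <- function(m, bin_width = 0.0025) {
  if (bin_width <= 0) stop_input("bin width must be positive")
  d <- m$values[upper.tri(m$values)]
  n_na <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (length(d) == 0) stop_input("no finite off-diagonal distances")
  idx <- floor(d / bin_width)      # bin k covers [k*w, (k+1)*w)
  counts <- tabulate(idx + 1, nbins = max(idx) + 1)
  out <- list(bin_width = bin_width, counts = counts,
              n_pairs = length(d), n_na = n_na, breaks = NULL)
  class(out) <- "gap_analysis"
  out
}

#' Detect natural breaks (barcode gaps) in a distance histogram
#'
#' A break is a maximal run of at least `min_gap_bins` consecutive empty
#' bins with occupied bins on both sides. Breaks are reported with their
#' lower/upper edges and midpoint, ordered by midpoint. This empty-bin-run
#' rule is this package's operationalization of histogram gap analysis;
#' the original method is descriptive and does not prescribe one.
#'
#' @param g A `"gap_analysis"` from [distance_histogram()].
#' @param min_gap_bins Minimum run length of empty bins (default 2).
#' @return `g` with `breaks` filled: data frame with columns `lower`,
#'   `upper`, `midpoint` (empty when no break exists).
#' @export
detect_gaps <- function(g, min_gap_bins = 2) {
  counts <- g$counts
  w <- g$bin_width
  occ <- which(counts > 0)
  breaks <- data.frame(lower = numeric(0), upper = numeric(0),
                       midpoint = numeric(0))
  if (length(occ) >= 2) {
    runs <- rle(counts[occ[1]:occ[length(occ)]] == 0)
    pos <- occ[1] - 1 + cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$values)) {
      if (runs$values[r] && runs$lengths[r] >= min_gap_bins) {
        first_empty <- pos[r]
        last_empty <- pos[r] + runs$lengths[r] - 1
        lower <- (first_empty - 1) * w   # upper edge of bin before the run
        upper <- last_empty * w          # lower edge of bin after the run
        breaks <- rbind(breaks,
                        data.frame(lower = lower, upper = upper,
                                   midpoint = (lower + upper) / 2))
      }
    }
  }
  g$breaks <- breaks[order(breaks$midpoint), , drop = FALSE]
  rownames(g$breaks) <- NULL
  g
}

#' @export
print.gap_analysis <- function(x, ...) {
  cat("Distance histogram:", x$n_pairs, "pairs, bin width", x$bin_width, "\n")
  if (!is.null(x$breaks)) {
    if (nrow(x$breaks) == 0) cat("No breaks detected\n")
    else {
      cat("Breaks (midpoints):",
          paste(sprintf("%.2f%%", 100 * x$breaks$midpoint), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

#' Cluster haplotypes into putative species at a distance threshold
#'
#' Single-linkage clustering: two haplotypes are co-specific iff they are
#' connected through a chain of pairs with distance strictly below `t`
#' ("cut-off" semantics). Non-estimable distances are treated as at or
#' above the threshold (conservative split). Cluster labels are the
#' lexicographically smallest member id.
#'
#' @param m A `"dist_matrix"`.
#' @param t Distance threshold (> 0); the barcode-gap species cut-off.
#' @return Object of class `"species_partition"`: data frame with columns
#'   `haplotype` and `species`, plus attributes `threshold` and
#'   `provenance`.
#' @export
cluster_at_threshold <- function(m, t) {
  if (!is.numeric(t) || t <= 0) stop_input("threshold must be positive")
  d <- m$values
  n <- nrow(d)
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(d[i, j]) && d[i, j] < t) parent <- uf_union(parent, i, j)
  }
  comp <- uf_components(parent)
  labels <- vapply(unique(comp), function(cc) min(m$ids[comp == cc]),
                   character(1))
  names(labels) <- unique(comp)
  out <- data.frame(haplotype = m$ids,
                    species = unname(labels[as.character(comp)]),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- t
  attr(out, "provenance") <- "gap"
  class(out) <- c("species_partition", "data.frame")
  out
}

#' Number of species in a partition
#'
#' @param p A `"species_partition"`.
#' @return Integer count of distinct species labels.
#' @export
n_species <- function(p) length(unique(p$species))
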