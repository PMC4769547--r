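# Peak-centered aggregation: profile matrices, metagenes, per-locus
# normalized MNase profiles, heatmap row ordering and group comparison.

#' Peak-centered profile matrix
#'
#' One row per peak: binned signal density (per bp) in a window of
#' `window_bp` centered on the peak midpoint. Bins span
#' `[-window/2, +window/2)`; windows overhanging chromosome ends are padded
#' with zeros.
#'
#' @param track a `signal_track`.
#' @param peaks a `peak_set`.
#' @param window_bp window width (divisible by `bin_bp`).
#' @param bin_bp bin width.
#' @return a `profile_matrix`: list with `values` (peaks x bins density
#'   matrix), `peak_ids`, `offsets` (bin centers, bp relative to midpoint),
#'   `bin_bp`, `window_bp`.
#' @export
profile_matrix <- function(track, peaks, window_bp = 10000, bin_bp = 100) {
  if (window_bp %% bin_bp != 0) stop("window_bp must be divisible by bin_bp")
  nb <- window_bp / bin_bp
  half <- window_bp / 2
  n <- nrow(peaks)
  vals <- matrix(0, nrow = n, ncol = nb)
  for (i in seq_len(n)) {
    L <- as.integer(track$genome[[peaks$chrom[i]]])
    lo0 <- peaks$midpoint[i] - half            # 0-based window start
    v <- numeric(window_bp)
    a <- max(lo0, 0L)
    b <- min(lo0 + window_bp, L)               # half-open end
    if (a < b) {
      r <- S4Vectors::window(track$data[[peaks$chrom[i]]], a + 1L, b)
      v[(a - lo0 + 1L):(b - lo0)] <- as.numeric(r)
    }
    vals[i, ] <- colSums(matrix(v, nrow = bin_bp)) / bin_bp
  }
  structure(list(values = vals, peak_ids = peaks$id,
                 offsets = -half + (seq_len(nb) - 0.5) * bin_bp,
                 bin_bp = bin_bp, window_bp = window_bp),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d peaks x %d bins (%d bp window, %d bp bins)\n",
              nrow(x$values), ncol(x$values), x$window_bp, x$bin_bp))
  invisible(x)
}

.metagene_obj <- function(offsets, density, n_peaks, bin_bp) {
  structure(list(offsets = offsets, density = density, n_peaks = n_peaks,
                 bin_bp = bin_bp),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d bins (%g bp), %d peaks, peak density %.4g at %+d bp\n",
              length(x$density), x$bin_bp, x$n_peaks,
              max(x$density), as.integer(x$offsets[which.max(x$density)])))
  invisible(x)
}

#' Metagene profile (column means of a profile matrix)
#'
#' @param matrix a `profile_matrix`.
#' @param peak_ids optional subset of peak ids (default all).
#' @return a `metagene_profile`.
#' @export
metagene <- function(matrix, peak_ids = NULL) {
  rows <- if (is.null(peak_ids)) seq_along(matrix$peak_ids) else
    match(peak_ids, matrix$peak_ids)
  if (!length(rows) || anyNA(rows)) {
    stop("empty or unknown peak subset", call. = FALSE)
  }
  .metagene_obj(matrix$offsets,
                colMeans(matrix$values[rows, , drop = FALSE]),
                length(rows), matrix$bin_bp)
}

#' Centered moving average with truncated edges
#'
#' @param v numeric vector.
#' @param n odd window length (<= `length(v)`).
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(v, n = 5) {
  if (n %% 2 == 0) stop("moving-average window must be odd", call. = FALSE)
  if (n > length(v)) stop("window longer than vector", call. = FALSE)
  h <- (n - 1) / 2
  L <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(L) - h, 1)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-locus normalized MNase metagene
#'
#' Tag density in the +/- `flank_window_bp` window around each peak is
#' divided by that peak's total count in the window (so every locus
#' contributes a unit-mass profile regardless of local coverage depth),
#' averaged over peaks, then smoothed with a moving average of
#' `moving_average_n` bins. Peaks with zero signal in the window are
#' dropped and reported via the `n_dropped` attribute.
#'
#' @param fragments an MNase `fragment_set` (full fragment spans).
#' @param peaks a `peak_set` (or a subset of one, e.g. one class).
#' @param genome named chromosome lengths.
#' @param params a [chrom_params()] object.
#' @param mode `"coverage"` (full-fragment tag density, default) or
#'   `"midpoint"` (dyad-centric density).
#' @param smooth apply the moving average (default TRUE).
#' @return a `metagene_profile` (attributes `n_dropped`, `dropped_ids`).
#' @export
mnase_metagene <- function(fragments, peaks, genome,
                           params = chrom_params(),
                           mode = c("coverage", "midpoint"),
                           smooth = TRUE) {
  mode <- match.arg(mode)
  track <- fragment_track(fragments, genome, mode = mode)
  pm <- profile_matrix(track, peaks,
                       window_bp = 2 * params$flank_window_bp,
                       bin_bp = params$metagene_bin_bp)
  totals <- rowSums(pm$values) * pm$bin_bp
  keep <- totals > 0
  if (!any(keep)) stop("all peaks have zero signal in the flank window",
                       call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " peak(s) with zero local signal dropped from ",
            "normalized metagene")
  }
  norm <- pm$values[keep, , drop = FALSE] / totals[keep]
  dens <- colMeans(norm)
  if (smooth) dens <- moving_average(dens, params$moving_average_n)
  out <- .metagene_obj(pm$offsets, dens, sum(keep), pm$bin_bp)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dropped_ids") <- pm$peak_ids[!keep]
  out
}

#' Order heatmap rows by weighted central signal within class blocks
#'
#' Rows are grouped into class blocks (G1, G2, G3, G4) and, within each
#' block, sorted by decreasing weighted signal: a Gaussian-weighted
#' (`order_sigma_bp`) sum of track density within +/- `flank_window_bp` of
#' the peak midpoint. Ties are broken by peak id.
#'
#' @param peaks a `peak_set`.
#' @param track the `signal_track` supplying the ordering signal
#'   (typically the treated-condition ATAC track).
#' @param classes named character vector mapping peak id to class.
#' @param params a [chrom_params()] object.
#' @return data frame (`peak_id`, `class`, `weighted_signal`) in heatmap
#'   row order.
#' @export
order_rows <- function(peaks, track, classes, params = chrom_params()) {
  cls <- classes[peaks$id]
  if (anyNA(cls)) stop("every peak must have a class", call. = FALSE)
  pm <- profile_matrix(track, peaks,
                       window_bp = 2 * params$flank_window_bp,
                       bin_bp = params$metagene_bin_bp)
  w <- exp(-pm$offsets^2 / (2 * params$order_sigma_bp^2))
  sig <- as.numeric(pm$values %*% w) * pm$bin_bp
  df <- data.frame(peak_id = peaks$id, class = unname(cls),
                   weighted_signal = sig, stringsAsFactors = FALSE)
  ord <- order(factor(df$class, levels = c("G1", "G2", "G3", "G4")),
               -df$weighted_signal, df$peak_id)
  out <- df[ord, ]
  rownames(out) <- NULL
  out
}

#' Per-peak windowed signal, split by class
#'
#' Convenience for enrichment comparisons: the normalized track signal in
#' a +/- `halfwidth` window around each peak midpoint, returned as one
#' numeric vector per class.
#'
#' @param track a normalized `signal_track`.
#' @param peaks a `peak_set`.
#' @param classes named character vector mapping peak id to class.
#' @param halfwidth window half-width in bp.
#' @return named list of numeric vectors (names are classes); each vector
#'   is named by peak id.
#' @export
signal_by_class <- function(track, peaks, classes, halfwidth = 100) {
  cls <- classes[peaks$id]
  if (anyNA(cls)) stop("every peak must have a class", call. = FALSE)
  v <- vapply(seq_len(nrow(peaks)), function(i) {
    count_in_window(track, peaks$chrom[i], peaks$midpoint[i], halfwidth)
  }, numeric(1))
  names(v) <- peaks$id
  split(v, unname(cls))
}

#' Compare signal distributions between groups
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests with box
#' statistics per group (median, mean, 5th/95th percentiles). P-values are
#' exact (complete enumeration) when both groups have at most
#' `exact_limit` observations and no ties, otherwise the tie-corrected
#' normal approximation is used.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param exact_limit largest per-group n for exact enumeration.
#' @return a `group_comparison`: list with `stats` (per group) and `tests`
#'   (pairwise p-values).
#' @export
compare_groups <- function(groups, exact_limit = 8) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named")
  }
  ns <- lengths(groups)
  if (any(ns < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  stats_df <- data.frame(
    group = names(groups), n = as.integer(ns),
    median = vapply(groups, stats::median, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    p05 = vapply(groups, stats::quantile, numeric(1), probs = 0.05,
                 names = FALSE),
    p95 = vapply(groups, stats::quantile, numeric(1), probs = 0.95,
                 names = FALSE),
    stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  pairs <- utils::combn(names(groups), 2L)
  tests <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                      p_value = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- groups[[pairs[1L, k]]]
    y <- groups[[pairs[2L, k]]]
    use_exact <- length(x) <= exact_limit && length(y) <= exact_limit &&
      !anyDuplicated(c(x, y))
    pv <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact,
                         correct = !use_exact)$p.value)
    # fully tied data leaves the normal approximation 0/0: no evidence
    tests$p_value[k] <- if (is.finite(pv)) pv else 1
  }
  structure(list(stats = stats_df, tests = tests),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison\n")
  print(x$stats)
  cat("pairwise Mann-Whitney:\n")
  print(x$tests)
  invisible(x)
}
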