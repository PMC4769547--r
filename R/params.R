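#' Pipeline parameters
#'
#' Bundles the tunable constants used throughout the classification and
#' profiling pipeline. The defaults follow the published analysis this
#' package formalizes: differential accessibility is called at FDR < 0.1
#' with fold change > 2, counts are collected in a 200 bp window centered
#' on each peak, the open/closed sub-split uses a 20-count cutoff in the
#' +/- 1 kb flank window, tracks are normalized to 30 million total reads,
#' MNase metagenes are smoothed with a moving average of N = 5 bins, heatmap
#' rows span 10 kb, and peaks within 1 kb of a TSS are called proximal.
#'
#' All genomic coordinates in this package are 0-based, half-open (BED
#' convention).
#'
#' @param fdr_threshold FDR below which a peak is called differential.
#' @param fold_change_threshold fold change (on pseudocounted normalized
#'   counts) that must be strictly exceeded for a differential call.
#' @param count_window_bp width (bp) of the central counting window.
#' @param flank_window_bp half-width (bp) of the flank window used for the
#'   open/closed sub-split and for per-locus MNase normalization.
#' @param open_count_cutoff normalized control-condition count in the flank
#'   window at or above which a conserved peak is called open (G2).
#' @param normalization_target total count each track is scaled to.
#' @param moving_average_n moving-average window (bins, odd) for MNase
#'   metagene smoothing.
#' @param heatmap_window_bp width (bp) of heatmap rows.
#' @param tss_proximal_bp distance (bp) at or below which a peak is
#'   TSS-proximal.
#' @param metagene_bin_bp bin size (bp) for metagene profiles.
#' @param heatmap_bin_bp bin size (bp) for heatmap rows.
#' @param dispersion negative-binomial dispersion of the exact rate test;
#'   0 gives the conditional binomial test.
#' @param max_slide_lag_bp largest lag (bp) searched when estimating array
#'   sliding; kept below one nucleosome spacing to avoid period ambiguity.
#' @param pseudocount added to each side of the fold-change ratio.
#' @param order_sigma_bp Gaussian sigma (bp) of the weighted-signal kernel
#'   used to order heatmap rows.
#' @param tn5_shift_plus,tn5_shift_minus Tn5 cut-site offsets applied to
#'   plus-strand 5' ends and minus-strand 5' ends.
#'
#' @return An object of class `chrom_params` (a validated list).
#' @examples
#' p <- chrom_params()
#' p$fdr_threshold
#' @export
chrom_params <- function(fdr_threshold = 0.1,
                         fold_change_threshold = 2,
                         count_window_bp = 200,
                         flank_window_bp = 1000,
                         open_count_cutoff = 20,
                         normalization_target = 3e7,
                         moving_average_n = 5,
                         heatmap_window_bp = 10000,
                         tss_proximal_bp = 1000,
                         metagene_bin_bp = 10,
                         heatmap_bin_bp = 100,
                         dispersion = 0.1,
                         max_slide_lag_bp = 150,
                         pseudocount = 0.5,
                         order_sigma_bp = 250,
                         tn5_shift_plus = 4L,
                         tn5_shift_minus = 5L) {
  p <- list(
    fdr_threshold = fdr_threshold,
    fold_change_threshold = fold_change_threshold,
    count_window_bp = count_window_bp,
    flank_window_bp = flank_window_bp,
    open_count_cutoff = open_count_cutoff,
    normalization_target = normalization_target,
    moving_average_n = moving_average_n,
    heatmap_window_bp = heatmap_window_bp,
    tss_proximal_bp = tss_proximal_bp,
    metagene_bin_bp = metagene_bin_bp,
    heatmap_bin_bp = heatmap_bin_bp,
    dispersion = dispersion,
    max_slide_lag_bp = max_slide_lag_bp,
    pseudocount = pseudocount,
    order_sigma_bp = order_sigma_bp,
    tn5_shift_plus = as.integer(tn5_shift_plus),
    tn5_shift_minus = as.integer(tn5_shift_minus)
  )
  pos <- c("fdr_threshold", "fold_change_threshold", "count_window_bp",
           "flank_window_bp", "open_count_cutoff", "normalization_target",
           "moving_average_n", "heatmap_window_bp", "tss_proximal_bp",
           "metagene_bin_bp", "heatmap_bin_bp", "max_slide_lag_bp",
           "order_sigma_bp")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (p$pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (p$moving_average_n %% 2 == 0) {
    stop("moving_average_n must be odd", call. = FALSE)
  }
  if (p$heatmap_window_bp %% p$heatmap_bin_bp != 0) {
    stop("heatmap_window_bp must be divisible by heatmap_bin_bp",
         call. = FALSE)
  }
  structure(p, class = "chrom_params")
}

#' @export
print.chrom_params <- function(x, ...) {
  cat("chrom_params:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
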