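# Binding-site classification from two-condition ATAC counts.
#
# G1: accessibility gained (pioneer sites), G4: accessibility lost,
# G2/G3: conserved sites sub-split into open/closed by the control-condition
# flank count.

#' Collect windowed ATAC counts per peak
#'
#' For each peak, counts track signal in the central window
#' (`count_window_bp` wide, midpoint-centered) for both conditions and in
#' the +/- `flank_window_bp` flank window for the control condition. Both
#' tracks must be normalized to the same target before counting.
#'
#' @param peaks a `peak_set`.
#' @param atac_control,atac_treated normalized cut-site `signal_track`s.
#' @param params a [chrom_params()] object.
#' @return data frame with `peak_id`, `count_control`, `count_treated`,
#'   `flank_control` (one row per peak, input order preserved).
#' @export
build_count_matrix <- function(peaks, atac_control, atac_treated,
                               params = chrom_params()) {
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids", call. = FALSE)
  hw <- params$count_window_bp / 2
  fw <- params$flank_window_bp
  n <- nrow(peaks)
  cc <- numeric(n); ct <- numeric(n); fc <- numeric(n)
  for (i in seq_len(n)) {
    cc[i] <- count_in_window(atac_control, peaks$chrom[i],
                             peaks$midpoint[i], hw)
    ct[i] <- count_in_window(atac_treated, peaks$chrom[i],
                             peaks$midpoint[i], hw)
    fc[i] <- count_in_window(atac_control, peaks$chrom[i],
                             peaks$midpoint[i], fw)
  }
  data.frame(peak_id = peaks$id, count_control = cc, count_treated = ct,
             flank_control = fc, stringsAsFactors = FALSE)
}

#' Classify peaks into accessibility classes G1-G4
#'
#' A peak is `G1` when its accessibility increases significantly
#' (FDR < `fdr_threshold` and fold change strictly > `fold_change_threshold`
#' with treated > control), `G4` when it decreases by the same criteria,
#' and otherwise conserved: `G2` (pre-open) when the normalized
#' control-condition flank count is at or above `open_count_cutoff`, `G3`
#' (bound but closed) when below. Fold change uses a pseudocount of
#' `pseudocount` on each side; ties at either threshold are conserved
#' (strict inequalities). Every peak receives exactly one class.
#'
#' @param counts output of [build_count_matrix()].
#' @param params a [chrom_params()] object.
#' @param n_control,n_treated library totals for the exact test; default
#'   the normalization target, which equals the post-normalization total.
#' @return a `peak_classes` data frame with `peak_id`, counts, `p_value`,
#'   `fdr`, `log2_fold_change`, `class`.
#' @seealso [exact_rate_test()], [bh_fdr()]
#' @export
classify_peaks <- function(counts, params = chrom_params(),
                           n_control = params$normalization_target,
                           n_treated = params$normalization_target) {
  stopifnot(all(c("peak_id", "count_control", "count_treated",
                  "flank_control") %in% names(counts)))
  if (anyDuplicated(counts$peak_id)) stop("duplicate peak ids")
  p <- exact_rate_test(counts$count_control, counts$count_treated,
                       n_control, n_treated,
                       dispersion = params$dispersion)
  fdr <- bh_fdr(p)
  ps <- params$pseudocount
  ratio <- (counts$count_treated + ps) / (counts$count_control + ps)
  l2fc <- log2(ratio)
  sig <- fdr < params$fdr_threshold
  up <- sig & ratio > params$fold_change_threshold
  down <- sig & (1 / ratio) > params$fold_change_threshold
  cls <- ifelse(up, "G1",
         ifelse(down, "G4",
         ifelse(counts$flank_control >= params$open_count_cutoff,
                "G2", "G3")))
  out <- data.frame(peak_id = counts$peak_id,
                    count_control = counts$count_control,
                    count_treated = counts$count_treated,
                    flank_control = counts$flank_control,
                    log2_fold_change = l2fc,
                    p_value = p, fdr = fdr, class = cls,
                    stringsAsFactors = FALSE)
  structure(out, params = params, class = c("peak_classes", "data.frame"))
}

#' @export
print.peak_classes <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("peak_classes: %d peaks\n", n))
  tab <- table(factor(x$class, levels = c("G1", "G2", "G3", "G4")))
  for (cl in names(tab)) {
    cat(sprintf("  %s: %6d (%5.1f%%)\n", cl, tab[[cl]],
                100 * tab[[cl]] / max(n, 1L)))
  }
  invisible(x)
}

#' @method summary peak_classes
#' @export
summary.peak_classes <- function(object, ...) {
  tab <- table(factor(object$class, levels = c("G1", "G2", "G3", "G4")))
  data.frame(class = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / max(nrow(object), 1L),
                             2),
             stringsAsFactors = FALSE)
}

# Deterministic TSV formatting shared by the pipeline writers: numeric
# columns are rendered with %.6g so reruns are byte-identical.
.fmt_col <- function(x) {
  if (is.double(x)) {
    ifelse(is.na(x), "NA", sprintf("%.6g", x))
  } else {
    x
  }
}

.write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a classification table as TSV
#'
#' Joins peak coordinates (and TSS annotation when given) onto the
#' classification and writes a deterministic TSV.
#'
#' @param classes a `peak_classes` object.
#' @param peaks the `peak_set` the classification was computed from.
#' @param path output path.
#' @param tss_annotation optional output of [annotate_tss()].
#' @export
write_classification <- function(classes, peaks, path,
                                 tss_annotation = NULL) {
  idx <- match(classes$peak_id, peaks$id)
  df <- data.frame(peak_id = classes$peak_id,
                   chrom = peaks$chrom[idx],
                   start = peaks$start[idx],
                   end = peaks$end[idx],
                   count_control = classes$count_control,
                   count_treated = classes$count_treated,
                   flank_control = classes$flank_control,
                   log2_fold_change = classes$log2_fold_change,
                   p_value = classes$p_value,
                   fdr = classes$fdr,
                   class = classes$class,
                   stringsAsFactors = FALSE)
  if (!is.null(tss_annotation)) {
    j <- match(classes$peak_id, tss_annotation$id)
    df$tss_distance <- tss_annotation$tss_distance[j]
    df$tss_label <- tss_annotation$tss_label[j]
  }
  .write_tsv(df, path)
}
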