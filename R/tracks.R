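# Signal tracks: per-base counts over a genome, stored as one Rle per
# chromosome (sparse in practice). External coordinates are 0-based
# half-open; Rle indices are 1-based internally.

.zero_rles <- function(genome) {
  lapply(genome, function(L) S4Vectors::Rle(0, as.integer(L)))
}

#' Construct a signal track
#' @param genome named numeric vector of chromosome lengths.
#' @param data optional named list of `Rle` vectors (one per chromosome,
#'   length equal to the chromosome); missing chromosomes are zero-filled.
#' @return a `signal_track`.
#' @export
signal_track <- function(genome, data = NULL) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named vector of chromosome lengths")
  }
  rles <- .zero_rles(genome)
  if (!is.null(data)) {
    for (nm in names(data)) {
      if (!nm %in% names(genome)) stop("unknown chromosome: ", nm)
      if (length(data[[nm]]) != genome[[nm]]) {
        stop("track length mismatch on ", nm)
      }
      rles[[nm]] <- data[[nm]]
    }
  }
  structure(list(genome = genome, data = rles), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %.4g bp, total signal %.6g\n",
              length(x$genome), sum(x$genome), track_total(x)))
  invisible(x)
}

#' Total signal in a track
#' @param track a `signal_track`.
#' @export
track_total <- function(track) {
  sum(vapply(track$data, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                           S4Vectors::runLength(r)),
             numeric(1)))
}

.positions_track <- function(pos_by_chrom, genome) {
  # pos_by_chrom: named list of 0-based integer positions (with repeats)
  rles <- .zero_rles(genome)
  for (nm in names(pos_by_chrom)) {
    p <- pos_by_chrom[[nm]]
    if (!length(p)) next
    rles[[nm]] <- S4Vectors::Rle(as.numeric(
      IRanges::coverage(IRanges::IRanges(p + 1L, width = 1L),
                        width = as.integer(genome[[nm]]))))
  }
  signal_track(genome, rles)
}

#' Tn5 cut-site track from ATAC fragments
#'
#' Applies the standard transposase offset correction: plus-strand 5' ends
#' are shifted +4 bp and minus-strand 5' ends (the half-open `end`
#' coordinate) -5 bp. For paired fragments both ends contribute one cut
#' site. Shifted positions outside the chromosome are clipped to its bounds
#' and counted in the `clip_report` attribute.
#'
#' @param fragments an ATAC `fragment_set`.
#' @param genome named numeric vector of chromosome lengths.
#' @param shift_plus,shift_minus offsets in bp.
#' @return a `signal_track` of cut-site counts (attribute `clip_report`).
#' @export
tn5_cut_sites <- function(fragments, genome, shift_plus = 4L,
                          shift_minus = 5L) {
  if (attr(fragments, "assay") != "ATAC") {
    stop("tn5_cut_sites expects an ATAC fragment set")
  }
  df <- as.data.frame(fragments)
  if (isTRUE(attr(fragments, "is_paired"))) {
    cuts <- data.frame(chrom = rep(df$chrom, 2L),
                       pos = c(df$start + shift_plus,
                               df$end - shift_minus))
  } else {
    if (any(!df$strand %in% c("+", "-"))) {
      stop("single-end ATAC reads require +/- strands")
    }
    cuts <- data.frame(chrom = df$chrom,
                       pos = ifelse(df$strand == "+",
                                    df$start + shift_plus,
                                    df$end - shift_minus))
  }
  n_clip <- 0L
  if (nrow(cuts)) {
    lim <- unname(genome[cuts$chrom]) - 1L
    clip <- cuts$pos < 0L | cuts$pos > lim
    n_clip <- sum(clip)
    cuts$pos <- pmin(pmax(cuts$pos, 0L), lim)
  }
  tr <- .positions_track(split(cuts$pos, cuts$chrom), genome)
  attr(tr, "clip_report") <- c(clipped = n_clip)
  tr
}

#' Tag-density track from fragments
#'
#' `mode = "coverage"` counts every base covered by a fragment (full-span
#' tag density, the default used for MNase and ChIP profiles);
#' `mode = "midpoint"` counts one tag at each fragment midpoint (dyad mode
#' for nucleosome-centric analyses).
#'
#' @param fragments a `fragment_set`.
#' @param genome named numeric vector of chromosome lengths.
#' @param mode `"coverage"` or `"midpoint"`.
#' @return a `signal_track`.
#' @export
fragment_track <- function(fragments, genome,
                           mode = c("coverage", "midpoint")) {
  mode <- match.arg(mode)
  df <- as.data.frame(fragments)
  df <- df[df$chrom %in% names(genome), , drop = FALSE]
  if (mode == "midpoint") {
    mids <- (df$start + df$end) %/% 2L
    lim <- unname(genome[df$chrom]) - 1L
    mids <- pmin(pmax(mids, 0L), lim)
    return(.positions_track(split(mids, df$chrom), genome))
  }
  rles <- .zero_rles(genome)
  for (nm in unique(df$chrom)) {
    d <- df[df$chrom == nm, ]
    L <- as.integer(genome[[nm]])
    s <- pmax(d$start, 0L) + 1L
    e <- pmin(d$end, L)
    ok <- s <= e
    rles[[nm]] <- S4Vectors::Rle(as.numeric(
      IRanges::coverage(IRanges::IRanges(s[ok], e[ok]), width = L)))
  }
  signal_track(genome, rles)
}

#' Normalize a track to a target total count
#'
#' Scales every value by `target / total` so the track sums to `target`
#' (the published analyses scale libraries to a common total, by default
#' 30 million reads).
#'
#' @param track a `signal_track`.
#' @param target total count to scale to.
#' @return the scaled `signal_track`.
#' @export
normalize_track <- function(track, target = 3e7) {
  tot <- track_total(track)
  if (tot <= 0) stop("cannot normalize empty track", call. = FALSE)
  scale <- target / tot
  track$data <- lapply(track$data, function(r) r * scale)
  attr(track, "normalization_target") <- target
  track
}

#' Sum of track values in a window
#'
#' The window is the half-open interval
#' `[center - halfwidth, center + halfwidth)`; windows beyond the
#' chromosome end are truncated.
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name.
#' @param center window center (0-based bp).
#' @param halfwidth window half-width in bp (> 0).
#' @return numeric sum.
#' @export
count_in_window <- function(track, chrom, center, halfwidth) {
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  if (!chrom %in% names(track$genome)) stop("unknown chromosome: ", chrom)
  L <- as.integer(track$genome[[chrom]])
  lo <- max(center - halfwidth + 1, 1)       # 1-based inclusive
  hi <- min(center + halfwidth, L)           # window is [c-h, c+h) 0-based
  if (lo > hi) return(0)
  r <- S4Vectors::window(track$data[[chrom]], lo, hi)
  sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r))
}

#' Write a track as bedGraph
#' @param track a `signal_track`.
#' @param path output path.
#' @param digits significant digits used for values.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track$data)) {
    r <- track$data[[nm]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    end <- cumsum(len)
    start <- end - len
    keep <- v != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", nm, start[keep], end[keep],
                       formatC(v[keep], digits = digits, format = "g")),
               con)
  }
  invisible(path)
}
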