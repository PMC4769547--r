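# Peaks, TSS annotation and interval overlap. Coordinates are 0-based
# half-open throughout (BED convention).

.check_intervals <- function(chrom, start, end, where = "interval") {
  if (any(is.na(chrom) | !nzchar(chrom))) {
    stop(where, ": chromosome names must be non-empty", call. = FALSE)
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop(where, ": coordinates must be numeric", call. = FALSE)
  }
  if (any(start < 0)) stop(where, ": start must be >= 0", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad)) {
    stop(where, ": start >= end at record ", bad[1L], call. = FALSE)
  }
  invisible(TRUE)
}

.peak_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a peak set from a BED file
#'
#' Accepts BED3 or BED6. Missing name columns get generated ids
#' (`peak_00001`, ...). The peak midpoint is `floor((start + end) / 2)`.
#'
#' @param path path to a BED3/BED6 file.
#' @return A `peak_set` data frame with columns `chrom`, `start`, `end`,
#'   `id`, `strand`, `midpoint`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("no records in ", path, ": returning empty peak set")
    return(.peak_set(data.frame(chrom = character(), start = integer(),
                                end = integer(), id = character(),
                                strand = character(), midpoint = integer(),
                                stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]], " in ", path,
         ": fewer than 3 fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ",
         lineno[which(is.na(start) | is.na(end))[1L]], " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("invalid interval at BED line ", lineno[bad[1L]], " in ", path,
         ": need 0 <= start < end", call. = FALSE)
  }
  id <- if (all(nf >= 4L)) {
    vapply(fields, `[[`, "", 4L)
  } else {
    sprintf("peak_%05d", seq_along(lines))
  }
  if (anyDuplicated(id)) {
    stop("duplicate peak ids in ", path, call. = FALSE)
  }
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else
    rep(".", length(lines))
  .peak_set(data.frame(chrom = chrom, start = start, end = end, id = id,
                       strand = strand, midpoint = (start + end) %/% 2L,
                       stringsAsFactors = FALSE))
}

#' Write a peak set as BED6
#' @param peaks a `peak_set`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$id,
                   0L, peaks$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read TSS positions from a BED file
#'
#' The TSS is taken as the interval start for `+`/`.` strands and `end - 1`
#' for `-` strands (BED entries for TSS lists are typically width 1).
#'
#' @param path BED3/BED6 file of transcription start sites.
#' @return data frame with columns `chrom`, `pos`.
#' @export
read_tss <- function(path) {
  b <- read_peaks(path)
  pos <- ifelse(b$strand == "-", b$end - 1L, b$start)
  data.frame(chrom = b$chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Annotate peaks with distance to the nearest TSS
#'
#' Distance is the minimum over TSSs of |peak midpoint - TSS position|,
#' computed on the peak's chromosome; if the chromosome carries no TSS the
#' global list is used. Peaks at distance <= `proximal_bp` are labelled
#' `proximal`, otherwise `distal` (the published convention: proximal means
#' less than or equal to 1 kb).
#'
#' @param peaks a `peak_set`.
#' @param tss data frame with `chrom`, `pos` (see [read_tss()]).
#' @param proximal_bp proximal/distal boundary in bp.
#' @return data frame with `id`, `tss_distance`, `tss_label`.
#' @export
annotate_tss <- function(peaks, tss, proximal_bp = 1000) {
  if (is.null(tss) || !nrow(tss)) stop("TSS list is empty", call. = FALSE)
  by_chrom <- split(tss$pos, tss$chrom)
  all_pos <- sort(tss$pos)
  dist1 <- function(mid, pos) {
    pos <- sort(pos)
    i <- findInterval(mid, pos)
    cand <- c(if (i >= 1L) pos[i], if (i < length(pos)) pos[i + 1L])
    min(abs(cand - mid))
  }
  d <- vapply(seq_len(nrow(peaks)), function(i) {
    pos <- by_chrom[[peaks$chrom[i]]]
    if (is.null(pos)) pos <- all_pos
    dist1(peaks$midpoint[i], pos)
  }, numeric(1))
  data.frame(id = peaks$id, tss_distance = as.integer(d),
             tss_label = ifelse(d <= proximal_bp, "proximal", "distal"),
             stringsAsFactors = FALSE)
}

#' Overlap two peak sets
#'
#' A peak is shared iff its interval overlaps any peak of the other set by
#' at least 1 bp.
#'
#' @param set_a,set_b `peak_set` objects.
#' @return list with `shared_a`, `shared_b`, `unique_a`, `unique_b`
#'   (character vectors of peak ids) and a `counts` summary vector.
#' @export
overlap_peaks <- function(set_a, set_b) {
  gr <- function(p) {
    if (!nrow(p)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(p$chrom,
                           IRanges::IRanges(p$start + 1L, p$end))
  }
  ga <- gr(set_a)
  gb <- gr(set_b)
  hit_a <- IRanges::overlapsAny(ga, gb)
  hit_b <- IRanges::overlapsAny(gb, ga)
  out <- list(shared_a = set_a$id[hit_a], shared_b = set_b$id[hit_b],
              unique_a = set_a$id[!hit_a], unique_b = set_b$id[!hit_b])
  out$counts <- c(shared_a = sum(hit_a), shared_b = sum(hit_b),
                  unique_a = sum(!hit_a), unique_b = sum(!hit_b))
  out
}

#' Read a two-column chrom-sizes file
#' @param path tab-separated file of chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Write a chrom-sizes file
#' @param genome named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(names(genome), format(genome, scientific = FALSE,
                                     trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
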