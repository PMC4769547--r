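# Fragment-level data: the universal raw-signal carrier for ATAC, MNase and
# ChIP libraries. A fragment_set is a data.frame (chrom, start, end, strand)
# with assay/condition metadata attached.

#' Construct a fragment set
#'
#' @param fragments data frame with columns `chrom`, `start`, `end` and
#'   optionally `strand` (defaults to ".").
#' @param assay one of `"ATAC"`, `"MNASE"`, `"CHIP"`.
#' @param condition free-form condition label (e.g. `"control"`).
#' @param is_paired logical; TRUE when fragments are full spans derived
#'   from paired-end mates (both ends then carry cut-site information).
#' @return a `fragment_set`.
#' @export
fragment_set <- function(fragments, assay = c("ATAC", "MNASE", "CHIP"),
                         condition = "control", is_paired = FALSE) {
  assay <- match.arg(assay)
  if (is.null(fragments$strand)) fragments$strand <- "."
  fragments <- fragments[, c("chrom", "start", "end", "strand")]
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)
  if (nrow(fragments)) {
    .check_intervals(fragments$chrom, fragments$start, fragments$end,
                     "fragment")
  }
  rownames(fragments) <- NULL
  structure(fragments,
            assay = assay, condition = condition, is_paired = is_paired,
            class = c("fragment_set", "data.frame"))
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d %s fragments [%s]%s\n",
              nrow(x), attr(x, "assay"), attr(x, "condition"),
              if (isTRUE(attr(x, "is_paired"))) " paired" else ""))
  invisible(x)
}

#' Total fragment count
#' @param fragments a `fragment_set`.
#' @export
total_count <- function(fragments) nrow(fragments)

#' Read fragments from a BED6 or BEDPE file
#'
#' Paired-end BEDPE mates on the same chromosome are collapsed to a single
#' fragment spanning `min(start)` to `max(end)`; interchromosomal pairs are
#' skipped and counted in the `skip_report` attribute. BED6 single-end
#' records are kept as-is with their strand.
#'
#' @param path input file.
#' @param assay,condition metadata passed to [fragment_set()].
#' @param format `"auto"` (by file extension), `"bed"` or `"bedpe"`.
#' @return a `fragment_set`; attribute `skip_report` counts skipped records.
#' @export
read_fragments <- function(path, assay = "ATAC", condition = "control",
                           format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bedpe$", path, ignore.case = TRUE)) "bedpe"
              else "bed"
  }
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) NULL)
  if (is.null(df) || !nrow(df)) {
    fs <- fragment_set(data.frame(chrom = character(), start = integer(),
                                  end = integer(),
                                  strand = character()),
                       assay, condition, is_paired = (format == "bedpe"))
    attr(fs, "skip_report") <- c(interchromosomal = 0L)
    return(fs)
  }
  if (format == "bedpe") {
    if (ncol(df) < 6L) stop("BEDPE requires at least 6 columns: ", path)
    same <- df[[1L]] == df[[4L]] & df[[1L]] != "." & df[[4L]] != "."
    n_skip <- sum(!same)
    df <- df[same, , drop = FALSE]
    frags <- data.frame(chrom = df[[1L]],
                        start = pmin(df[[2L]], df[[5L]]),
                        end = pmax(df[[3L]], df[[6L]]),
                        strand = ".", stringsAsFactors = FALSE)
    fs <- fragment_set(frags, assay, condition, is_paired = TRUE)
    attr(fs, "skip_report") <- c(interchromosomal = n_skip)
  } else {
    if (ncol(df) < 3L) stop("BED requires at least 3 columns: ", path)
    strand <- if (ncol(df) >= 6L) df[[6L]] else "."
    frags <- data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
                        strand = strand, stringsAsFactors = FALSE)
    fs <- fragment_set(frags, assay, condition, is_paired = FALSE)
    attr(fs, "skip_report") <- c(interchromosomal = 0L)
  }
  fs
}

#' Write fragments to BED6 or BEDPE
#'
#' Paired fragment sets are written as BEDPE with synthetic mates covering
#' the outer `mate_bp` of each span (reading the file back through
#' [read_fragments()] reproduces the spans exactly); single-end sets are
#' written as BED6.
#'
#' @param fragments a `fragment_set`.
#' @param path output path.
#' @param mate_bp mate length used when writing BEDPE.
#' @export
write_fragments <- function(fragments, path, mate_bp = 36L) {
  if (isTRUE(attr(fragments, "is_paired"))) {
    m <- pmin(mate_bp, fragments$end - fragments$start)
    df <- data.frame(fragments$chrom, fragments$start,
                     fragments$start + m,
                     fragments$chrom, fragments$end - m, fragments$end,
                     sprintf("frag_%d", seq_len(nrow(fragments))), 0L,
                     "+", "-")
  } else {
    df <- data.frame(fragments$chrom, fragments$start, fragments$end,
                     sprintf("read_%d", seq_len(nrow(fragments))), 0L,
                     fragments$strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove duplicate fragments
#'
#' Fragments identical in (chrom, start, end, strand) are reduced to one
#' copy, mirroring coordinate-based duplicate marking.
#'
#' @param fragments a `fragment_set`.
#' @return deduplicated `fragment_set`; attribute `n_removed` records how
#'   many copies were dropped.
#' @export
deduplicate <- function(fragments) {
  dup <- duplicated(as.data.frame(fragments)[, c("chrom", "start", "end",
                                                 "strand")])
  out <- fragment_set(as.data.frame(fragments)[!dup, , drop = FALSE],
                      attr(fragments, "assay"), attr(fragments, "condition"),
                      attr(fragments, "is_paired"))
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Merge replicate fragment sets by concatenation
#'
#' Biological replicates are merged by simple concatenation before any
#' downstream analysis; all sets must share assay and condition.
#'
#' @param ... `fragment_set` objects.
#' @return a single merged `fragment_set`.
#' @export
merge_replicates <- function(...) {
  sets <- list(...)
  if (!length(sets)) stop("no fragment sets given")
  assay <- unique(vapply(sets, attr, "", "assay"))
  cond <- unique(vapply(sets, attr, "", "condition"))
  if (length(assay) != 1L || length(cond) != 1L) {
    stop("replicates must share assay and condition")
  }
  merged <- do.call(rbind, lapply(sets, as.data.frame))
  fragment_set(merged, assay, cond,
               is_paired = isTRUE(attr(sets[[1L]], "is_paired")))
}
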