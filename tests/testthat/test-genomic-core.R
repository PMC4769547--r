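test_that("read_peaks parses BED, computes floor midpoints, generates ids", {
  p <- read_peaks(write_bed_lines(c("chr1\t100\t300", "chr1\t100\t301")))
  expect_equal(p$midpoint, c(200L, 200L))
  expect_equal(p$id, c("peak_00001", "peak_00002"))

  p6 <- read_peaks(write_bed_lines("chr2\t10\t50\tmyPeak\t0\t+"))
  expect_equal(p6$id, "myPeak")
  expect_equal(p6$strand, "+")

  expect_warning(e <- read_peaks(write_bed_lines(character(0))), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("read_peaks rejects malformed input with line numbers", {
  expect_error(read_peaks(write_bed_lines(c("chr1\t1\t10", "chr1\t5"))),
               "line 2")
  expect_error(read_peaks(write_bed_lines("chr1\tfoo\t10")), "line 1")
  expect_error(read_peaks(write_bed_lines("chr1\t300\t100")), "line 1")
  expect_error(read_peaks(write_bed_lines(c("chr1\t1\t9\ta",
                                            "chr1\t2\t8\ta"))),
               "duplicate")
})

test_that("read_fragments collapses BEDPE mates and skips interchromosomal pairs", {
  path <- write_bed_lines(c(
    "chr1\t100\t150\tchr1\t220\t270\tp1\t0\t+\t-",
    "chr1\t500\t540\tchr2\t100\t140\tp2\t0\t+\t-"), ".bedpe")
  fs <- read_fragments(path, assay = "MNASE")
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$start, 100L)
  expect_equal(fs$end, 270L)
  expect_true(attr(fs, "is_paired"))
  expect_equal(unname(attr(fs, "skip_report")["interchromosomal"]), 1L)
})

test_that("read_fragments keeps single-end BED6 reads as-is", {
  fs <- read_fragments(write_bed_lines("chr1\t500\t550\tr1\t0\t-"),
                       assay = "ATAC")
  expect_equal(fs$start, 500L)
  expect_equal(fs$end, 550L)
  expect_equal(fs$strand, "-")
  expect_false(attr(fs, "is_paired"))
})

test_that("fragment round-trip through BED and BEDPE is lossless", {
  se <- fragment_set(data.frame(chrom = "chr1",
                                start = c(10L, 200L, 4000L),
                                end = c(46L, 236L, 4036L),
                                strand = c("+", "-", "+")),
                     "ATAC", "control", is_paired = FALSE)
  f <- tempfile(fileext = ".bed")
  write_fragments(se, f)
  back <- read_fragments(f, assay = "ATAC")
  expect_equal(back$start, se$start)
  expect_equal(back$end, se$end)
  expect_equal(back$strand, se$strand)

  pe <- fragment_set(data.frame(chrom = "chr1",
                                start = c(100L, 900L),
                                end = c(250L, 1047L)),
                     "MNASE", "treated", is_paired = TRUE)
  f2 <- tempfile(fileext = ".bedpe")
  write_fragments(pe, f2)
  back2 <- read_fragments(f2, assay = "MNASE", condition = "treated")
  expect_equal(back2$start, pe$start)
  expect_equal(back2$end, pe$end)
})

test_that("deduplicate keeps one copy per coordinate+strand and is idempotent", {
  fs <- fragment_set(data.frame(
    chrom = "chr1",
    start = c(10L, 10L, 10L, 50L, 10L),
    end = c(40L, 40L, 40L, 80L, 40L),
    strand = c("+", "+", "+", "+", "-")),
    "CHIP")
  d1 <- deduplicate(fs)
  expect_equal(nrow(d1), 3L)  # distinct + duplicate-collapsed + strand
  expect_equal(attr(d1, "n_removed"), 2L)
  d2 <- deduplicate(d1)
  expect_equal(d2$start, d1$start)
  expect_equal(d2$end, d1$end)
  expect_equal(d2$strand, d1$strand)
  uniq <- fragment_set(data.frame(chrom = "chr1", start = c(1L, 2L),
                                  end = c(5L, 6L)), "CHIP")
  expect_equal(nrow(deduplicate(uniq)), 2L)
})

test_that("tn5_cut_sites applies +4/-5 offsets and conserves counts", {
  genome <- c(chr1 = 5000)
  se <- fragment_set(data.frame(chrom = "chr1",
                                start = c(1000L, 1964L),
                                end = c(1036L, 2000L),
                                strand = c("+", "-")),
                     "ATAC")
  tr <- tn5_cut_sites(se, genome)
  expect_equal(count_in_window(tr, "chr1", 1004, 1), 1)  # [1004,1005)
  expect_equal(count_in_window(tr, "chr1", 1995, 1), 1)
  expect_equal(track_total(tr), 2)

  pe <- fragment_set(data.frame(chrom = "chr1", start = 1000L,
                                end = 1200L), "ATAC", is_paired = TRUE)
  trp <- tn5_cut_sites(pe, genome)
  expect_equal(count_in_window(trp, "chr1", 1004, 1), 1)
  expect_equal(count_in_window(trp, "chr1", 1195, 1), 1)

  # clipping at chromosome bounds is reported, counts conserved
  edge <- fragment_set(data.frame(chrom = "chr1", start = c(0L, 4990L),
                                  end = c(36L, 5000L),
                                  strand = c("-", "+")), "ATAC")
  tre <- tn5_cut_sites(edge, genome)
  expect_equal(track_total(tre), 2)
  # minus-strand cut 36-5=31 is in range; plus cut 4990+4=4994 in range
  expect_equal(unname(attr(tre, "clip_report")["clipped"]), 0L)
  over <- fragment_set(data.frame(chrom = "chr1", start = 4999L,
                                  end = 5000L, strand = "+"), "ATAC")
  tro <- tn5_cut_sites(over, genome)  # 4999+4 clips to 4999
  expect_equal(unname(attr(tro, "clip_report")["clipped"]), 1L)
  expect_equal(track_total(tro), 1)
})

test_that("normalize_track scales to target and is idempotent", {
  tr <- uniform_track(2, 1000)  # total 2000
  n1 <- normalize_track(tr, 1000)
  expect_equal(track_total(n1), 1000, tolerance = 1e-9)
  expect_equal(as.numeric(S4Vectors::runValue(n1$data$chr1)), 1)
  n2 <- normalize_track(n1, 1000)
  expect_equal(as.numeric(n2$data$chr1), as.numeric(n1$data$chr1),
               tolerance = 1e-9)
  # odd totals: sum recomputed independently of the scale factor
  tr2 <- delta_track(rep(c(3L, 7L, 9L), c(5, 4, 3)), len = 100)
  expect_equal(track_total(tr2), 12)
  n3 <- normalize_track(tr2, 3e7)
  ind <- sum(vapply(0:99, function(i) count_in_window(n3, "chr1", i, 0.5),
                    numeric(1)))
  expect_equal(ind, 3e7, tolerance = 1e-6)
  empty <- signal_track(c(chr1 = 100))
  expect_error(normalize_track(empty, 10), "empty track")
})

test_that("count_in_window uses half-open windows and is additive", {
  tr <- uniform_track(1, 1000)
  expect_equal(count_in_window(tr, "chr1", 500, 100), 200)
  expect_equal(count_in_window(signal_track(c(chr1 = 1000)), "chr1",
                               500, 100), 0)
  # single count just left of the window is excluded
  d <- delta_track(399L, len = 1000)
  expect_equal(count_in_window(d, "chr1", 500, 100), 0)
  expect_equal(count_in_window(d, "chr1", 499, 100), 1)
  # windows beyond the chromosome end truncate silently
  expect_equal(count_in_window(tr, "chr1", 990, 50), 60)
  # partition additivity over adjacent windows
  set.seed(42)
  tr2 <- delta_track(sample(0:999, 400, replace = TRUE), len = 1000)
  parts <- vapply(seq(50, 950, by = 100), function(c) {
    count_in_window(tr2, "chr1", c, 50)
  }, numeric(1))
  expect_equal(sum(parts), count_in_window(tr2, "chr1", 500, 500))
})

test_that("bedGraph output reproduces track values", {
  tr <- delta_track(c(10L, 10L, 50L), len = 100)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  df <- read.table(f, sep = "\t")
  expect_equal(df$V2, c(10L, 50L))
  expect_equal(df$V4, c(2, 1))
})

test_that("merge_replicates concatenates and enforces matching metadata", {
  a <- fragment_set(data.frame(chrom = "chr1", start = 1L, end = 10L),
                    "CHIP", "control")
  b <- fragment_set(data.frame(chrom = "chr1", start = 5L, end = 15L),
                    "CHIP", "control")
  m <- merge_replicates(a, b)
  expect_equal(nrow(m), 2L)
  c_ <- fragment_set(data.frame(chrom = "chr1", start = 1L, end = 2L),
                     "CHIP", "treated")
  expect_error(merge_replicates(a, c_), "share assay and condition")
})
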