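test_that("profile_matrix bins density around midpoints", {
  peaks <- make_peaks(c(3000, 6000), len = 12000)
  flat <- profile_matrix(uniform_track(2, 12000), peaks, 2000, 10)
  expect_true(all(abs(flat$values - 2) < 1e-12))
  expect_equal(length(flat$offsets), 200L)
  expect_equal(flat$offsets[1], -995)

  d <- profile_matrix(delta_track(rep(3000L, 5), len = 12000), peaks,
                      2000, 10)
  expect_equal(d$values[1, 101], 5 / 10)   # bin [3000,3010) holds w=5
  expect_equal(sum(d$values[1, ]), 0.5)
  expect_equal(sum(d$values[2, ]), 0)
})

test_that("profile rows integrate to the windowed count (cross-module)", {
  set.seed(5)
  tr <- delta_track(sample(0:11999, 2000, replace = TRUE), len = 12000)
  peaks <- make_peaks(c(2000, 7000), len = 12000)
  pm <- profile_matrix(tr, peaks, 2000, 10)
  for (i in 1:2) {
    expect_equal(sum(pm$values[i, ]) * pm$bin_bp,
                 count_in_window(tr, "chr1", peaks$midpoint[i], 1000))
  }
})

test_that("windows overhanging the chromosome are zero-padded", {
  peaks <- make_peaks(300, len = 10000)
  pm <- profile_matrix(uniform_track(1, 10000), peaks, 2000, 100)
  expect_equal(pm$values[1, 1:7], rep(0, 7))    # bins before base 0
  expect_equal(pm$values[1, 8:20], rep(1, 13))
})

test_that("metagene averages rows and ignores peak order", {
  peaks <- make_peaks(c(2000, 4000, 6000), len = 12000)
  tr <- delta_track(c(rep(2000L, 4), rep(4000L, 4)), len = 12000)
  pm <- profile_matrix(tr, peaks, 2000, 10)
  one <- metagene(pm, "pk_001")
  expect_equal(one$density, pm$values[1, ])
  two <- metagene(pm, c("pk_001", "pk_002"))
  expect_equal(two$density, metagene(pm, c("pk_002", "pk_001"))$density)
  all3 <- metagene(pm)
  # full metagene = class-size weighted mean of subset metagenes
  expect_equal(all3$density,
               (2 * two$density + metagene(pm, "pk_003")$density) / 3)
  expect_error(metagene(pm, character(0)), "empty")
  expect_error(metagene(pm, "nope"), "unknown")
})

test_that("moving_average is exact on closed-form cases", {
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  expect_equal(moving_average(c(0, 0, 5, 0, 0), 5),
               c(5 / 3, 5 / 4, 1, 5 / 4, 5 / 3))
  ramp <- moving_average(as.numeric(1:20), 5)
  expect_equal(ramp[3:18], as.numeric(3:18))  # interior unchanged
  expect_error(moving_average(1:10, 4), "odd")
  expect_error(moving_average(1:3, 5), "longer")
})

test_that("per-locus MNase normalization removes depth differences", {
  # two loci with the same dinucleosome shape, one at 10x coverage
  frag <- function(mid, n) {
    data.frame(chrom = "chr1",
               start = rep(c(mid - 250L, mid + 100L), each = n),
               end = rep(c(mid - 103L, mid + 247L), each = n))
  }
  peaks <- make_peaks(c(4000, 9000), len = 20000)
  p <- chrom_params()
  fs_equal <- fragment_set(rbind(frag(4000L, 3), frag(9000L, 3)),
                           "MNASE", is_paired = TRUE)
  fs_skew <- fragment_set(rbind(frag(4000L, 30), frag(9000L, 3)),
                          "MNASE", is_paired = TRUE)
  g <- c(chr1 = 20000)
  m1 <- mnase_metagene(fs_equal, peaks, g, p)
  m2 <- mnase_metagene(fs_skew, peaks, g, p)
  expect_equal(m1$density, m2$density, tolerance = 1e-12)
  # and a locus with zero coverage is dropped with a warning
  peaks3 <- make_peaks(c(4000, 9000, 15000), len = 20000)
  expect_warning(m3 <- mnase_metagene(fs_equal, peaks3, g, p), "dropped")
  expect_equal(attr(m3, "n_dropped"), 1L)
  expect_equal(m3$density, m1$density)
})

test_that("heatmap row ordering is a class-blocked permutation", {
  peaks <- make_peaks(c(2000, 4000, 6000, 8000), len = 20000)
  tr <- delta_track(c(rep(2000L, 2), rep(4000L, 9), rep(6000L, 5)),
                    len = 20000)
  classes <- c(pk_001 = "G2", pk_002 = "G1", pk_003 = "G1",
               pk_004 = "G1")
  ord <- order_rows(peaks, tr, classes)
  expect_equal(sort(ord$peak_id), sort(peaks$id))     # permutation
  expect_equal(ord$class, c("G1", "G1", "G1", "G2"))  # block order
  # within G1: signals 9 > 5 > 0, ties broken by id
  expect_equal(ord$peak_id[1:3], c("pk_002", "pk_003", "pk_004"))
  expect_error(order_rows(peaks, tr, classes[-1]), "class")
})

test_that("compare_groups matches exact rank-sum enumeration", {
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12))
  cmp <- compare_groups(g)
  expect_equal(cmp$tests$p_value, 0.1)  # 2/20 orderings as extreme
  expect_equal(cmp$stats$median, c(2, 11))
  same <- compare_groups(list(x = 1:6 + 0.5, y = 1:6 + 0.5))
  expect_gt(same$tests$p_value, 0.9)
  expect_error(compare_groups(list(a = 1, b = 1:5)), "at least 2")
  expect_error(compare_groups(list(1:3, 4:6)), "named")
})

test_that("normal approximation tracks the exact rank-sum p-value", {
  set.seed(9)
  for (i in 1:20) {
    x <- round(rnorm(8, 0, 2), 3)
    y <- round(rnorm(8, 1, 2), 3)
    p_ex <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    p_ap <- compare_groups(list(a = x, b = y),
                           exact_limit = 0)$tests$p_value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})
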