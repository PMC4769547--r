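# Closed-form profiles for the dynamics estimators.
mk_profile <- function(density, bin = 10, half = 1000) {
  nb <- 2 * half / bin
  structure(list(offsets = -half + (seq_len(nb) - 0.5) * bin,
                 density = density, n_peaks = 1L, bin_bp = bin),
            class = "metagene_profile")
}

gauss_bump <- function(offsets, mu = 0, sd = 40, h = 1) {
  h * exp(-(offsets - mu)^2 / (2 * sd^2))
}

test_that("eviction score recovers closed-form central losses", {
  off <- mk_profile(numeric(200))$offsets
  base <- 0.1 + gauss_bump(off)
  expect_equal(eviction_score(mk_profile(base), mk_profile(base)), 0)
  gone <- mk_profile(replace(base, abs(off) <= 90, 0))
  expect_equal(eviction_score(mk_profile(base), gone), 1)
  # common rescaling of both profiles cancels
  half_lost <- mk_profile(0.5 * base + 0.5 * 0.1)
  s1 <- eviction_score(mk_profile(base), half_lost)
  s2 <- eviction_score(mk_profile(3 * base),
                       mk_profile(3 * (0.5 * base + 0.5 * 0.1)))
  expect_equal(s1, s2)
  expect_warning(
    s <- eviction_score(mk_profile(numeric(200)), mk_profile(base)),
    "zero")
  expect_true(is.na(s))
})

test_that("phasing score is ~1 for a 190 bp cosine and 0 for flat input", {
  off <- mk_profile(numeric(200))$offsets
  cosine <- mk_profile(1 + cos(2 * pi * off / 190))
  expect_gt(phasing_score(cosine), 0.9)
  expect_equal(phasing_score(mk_profile(rep(2, 200))), 0)
  # adding a constant changes nothing
  expect_equal(phasing_score(mk_profile(5 + cos(2 * pi * off / 190))),
               phasing_score(cosine))
  # period outside the searched range scores much lower
  long_period <- mk_profile(1 + cos(2 * pi * off / 400))
  expect_lt(phasing_score(long_period), phasing_score(cosine))
})

test_that("slide estimate recovers exact grid shifts and is antisymmetric", {
  off <- mk_profile(numeric(200))$offsets
  arr <- function(shift) {
    mk_profile(0.05 + 0.8^(abs(off - shift) / 190) *
                 (1 + cos(2 * pi * (off - shift) / 190)))
  }
  expect_equal(slide_estimate(arr(0), arr(0)), 0)
  for (s in c(-80, 30, 50, 80)) {
    expect_equal(slide_estimate(arr(0), arr(s)), s)
    expect_equal(slide_estimate(arr(s), arr(0)), -s)
  }
  expect_warning(z <- slide_estimate(mk_profile(rep(1, 200)), arr(0)),
                 "flat")
  expect_equal(z, 0)
})

test_that("stability analysis reports ratios and class contrasts", {
  peaks <- make_peaks(seq(2000, 20000, by = 2000), len = 30000)
  classes <- setNames(rep(c("G1", "G3"), 5), peaks$id)
  pos <- unlist(lapply(peaks$midpoint, function(m) rep(m, 50)))
  tr <- delta_track(as.integer(pos), len = 30000)
  same <- stability_analysis(tr, tr, peaks, classes)
  expect_true(all(same$per_peak$stability_ratio == 1))
  halves <- tr
  halves$data$chr1 <- halves$data$chr1 * 0.5
  st <- stability_analysis(halves, tr, peaks, classes)
  expect_true(all(st$per_peak$stability_ratio < 1))
  expect_equal(unname(diff(st$class_stats$median_ratio)), 0)
  expect_gt(st$tests$tests$p_value, 0.9)  # no class separation
})

test_that("dynamics_table runs per class on constructed fragments", {
  # G1-like: central dinucleosome lost in treated; G3-like: shifted
  peaks <- make_peaks(c(5000, 15000), len = 20000)
  classes <- c(pk_001 = "G1", pk_002 = "G3")
  nuc <- function(mid, n = 20) {
    data.frame(chrom = "chr1", start = rep(mid - 73L, n),
               end = rep(mid + 74L, n))
  }
  array_at <- function(mid, shift = 0, n = 20) {
    do.call(rbind, lapply(mid + shift + c(-380, -190, 0, 190, 380),
                          nuc, n = n))
  }
  ctrl <- fragment_set(rbind(array_at(5000), array_at(15000)),
                       "MNASE", "control", is_paired = TRUE)
  treat <- fragment_set(rbind(array_at(5000)[-(41:60), ],  # center gone
                              array_at(15000, shift = 50)),
                        "MNASE", "treated", is_paired = TRUE)
  dt <- dynamics_table(ctrl, treat, peaks, classes, c(chr1 = 20000))
  expect_equal(dt$class, c("G1", "G3"))
  expect_gt(dt$eviction_score[1], 0.5)
  expect_lt(abs(dt$eviction_score[2]), 0.1)
  expect_equal(dt$slide_bp[2], 50)
  expect_true(all(dt$phasing_control > 0.2))
})
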