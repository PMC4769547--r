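cfg <- small_config()

test_that("plant_layout is deterministic and respects spacing constraints", {
  a <- plant_layout(cfg, seed = 5)
  b <- plant_layout(cfg, seed = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$peaks, b$peaks)
  expect_false(identical(a$truth$midpoint,
                         plant_layout(cfg, seed = 6)$truth$midpoint))
  expect_equal(as.integer(table(a$truth$class)), rep(12L, 4))
  expect_true(all(a$truth$midpoint >= 5000 &
                    a$truth$midpoint <= cfg$genome_length - 5000))
  expect_true(all(diff(sort(a$truth$midpoint)) >= 2000))
  # planted parameters follow the class architecture
  expect_true(all(a$truth$planted_slide_bp[a$truth$class == "G3"] == 50))
  expect_true(all(a$truth$planted_slide_bp[a$truth$class != "G3"] == 0))
  expect_true(all(is.na(
    a$truth$planted_eviction_fraction[a$truth$class %in% c("G2", "G3")])))
  expect_true(all(a$truth$open_treated[a$truth$class == "G1"]))
  expect_false(any(a$truth$open_control[a$truth$class == "G1"]))
})

test_that("an empty class and an overcrowded genome are handled", {
  cfg0 <- small_config(n_peaks_per_class = c(G1 = 5, G2 = 5, G3 = 5,
                                             G4 = 0))
  lay <- plant_layout(cfg0, seed = 1)
  expect_false("G4" %in% lay$truth$class)
  expect_equal(nrow(lay$truth), 15L)
  expect_error(simulation_config(genome_length = 1e5,
                                 n_peaks_per_class = 200),
               "too small")
})

test_that("MNase sampling follows the planted landscapes", {
  lay <- plant_layout(cfg, seed = 5)
  fs <- simulate_mnase(lay, "control", depth = 2e5, seed = 9)
  mids <- (fs$start + fs$end) %/% 2L
  # G2 loci: fragment-midpoint histogram dips at the peak center
  g2 <- lay$truth$midpoint[lay$truth$class == "G2"]
  rel <- unlist(lapply(g2, function(m) {
    d <- mids - m
    d[abs(d) <= 1000]
  }))
  h_center <- sum(abs(rel) <= 80)
  h_flank <- (sum(rel >= 110 & rel <= 270) +
                sum(rel <= -110 & rel >= -270)) / 4
  expect_lt(h_center, 0.5 * h_flank)
  # doubling depth doubles totals within 3 sigma of Poisson
  n1 <- nrow(simulate_mnase(lay, "control", depth = 5e4, seed = 10))
  n2 <- nrow(simulate_mnase(lay, "control", depth = 1e5, seed = 11))
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1))
})

test_that("simulated reads are reproducible for a fixed seed", {
  lay <- plant_layout(cfg, seed = 5)
  for (f in list(function(s) simulate_mnase(lay, "treated", seed = s),
                 function(s) simulate_atac(lay, "treated", seed = s),
                 function(s) simulate_chip(lay, "TF", "treated",
                                           seed = s))) {
    expect_identical(as.data.frame(f(33)), as.data.frame(f(33)))
  }
})

test_that("Tn5 offset correction inverts the ATAC read encoding exactly", {
  lay <- plant_layout(cfg, seed = 5)
  fs <- simulate_atac(lay, "treated", depth = 5000, seed = 12,
                      keep_cut_sites = TRUE)
  truth_cuts <- attr(fs, "cut_sites")
  # away from chromosome ends every read recovers its true cut site
  inner <- fs$start > 50 & fs$end < cfg$genome_length - 50
  rec <- ifelse(fs$strand == "+", fs$start + 4L, fs$end - 5L)
  expect_identical(rec[inner], truth_cuts[inner])
  tr <- tn5_cut_sites(fs, lay$genome)
  expect_equal(track_total(tr), nrow(fs))
})

test_that("planted accessibility contrasts appear in the cut-site rates", {
  lay <- plant_layout(cfg, seed = 5)
  ac <- simulate_atac(lay, "control", seed = 13, keep_cut_sites = TRUE)
  at <- simulate_atac(lay, "treated", seed = 14, keep_cut_sites = TRUE)
  central <- function(fs, cls) {
    cuts <- attr(fs, "cut_sites")
    mids <- lay$truth$midpoint[lay$truth$class == cls]
    sum(vapply(mids, function(m) sum(abs(cuts - m) <= 100), numeric(1)))
  }
  # G1: strong gain on treatment; G3: no gain
  expect_gt(central(at, "G1") / max(central(ac, "G1"), 1), 5)
  r_g3 <- central(at, "G3") / max(central(ac, "G3"), 1)
  expect_lt(abs(log2(r_g3)), 1.2)
  # cofactor is background-only at G3 peaks
  cof <- simulate_chip(lay, "cofactor", "treated", seed = 15)
  trc <- fragment_track(cof, lay$genome)
  g3c <- mean(vapply(lay$truth$midpoint[lay$truth$class == "G3"],
                     function(m) count_in_window(trc, cfg$chrom, m, 100),
                     numeric(1)))
  g1c <- mean(vapply(lay$truth$midpoint[lay$truth$class == "G1"],
                     function(m) count_in_window(trc, cfg$chrom, m, 100),
                     numeric(1)))
  expect_lt(g3c, 0.1 * g1c)
})

test_that("write_dataset emits a parseable, reproducible dataset", {
  tiny <- small_config(n_peaks_per_class = 5, depth_atac = 3000,
                       depth_mnase = 4000, depth_chip = 2000,
                       genome_length = 1.2e5, norm_target = 500,
                       n_background_tss = 5)
  lay <- plant_layout(tiny, seed = 2)
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(lay, d1, seed = 3)
  write_dataset(lay, d2, seed = 3)
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  expect_identical(readLines(file.path(d1, "mnase_control.bedpe")),
                   readLines(file.path(d2, "mnase_control.bedpe")))
  expect_error(write_dataset(lay, d1, seed = 3), "not empty")
  # round-trip through the readers
  pk <- read_peaks(file.path(d1, "peaks.bed"))
  expect_equal(pk$id, lay$peaks$id)
  expect_equal(pk$midpoint, lay$peaks$midpoint)
  g <- read_chrom_sizes(file.path(d1, "chrom.sizes"))
  expect_equal(unname(g), tiny$genome_length)
  mn <- read_fragments(file.path(d1, "mnase_control.bedpe"),
                       assay = "MNASE")
  ref <- simulate_mnase(lay, "control",
                        seed = chromdissect:::.derive_seed(3, 2))
  expect_equal(mn$start, ref$start)
  expect_equal(mn$end, ref$end)
})
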