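# Shared fixtures, all built in code.

# Down-scaled study conditions for fast unit tests: same architecture as
# the defaults, fewer peaks on a smaller chromosome, depths and
# normalization target scaled with genome size.
small_config <- function(...) {
  args <- list(genome_length = 2.5e5, n_peaks_per_class = 12,
               depth_atac = 28000, depth_mnase = 50000,
               depth_chip = 20000, norm_target = 2800,
               n_background_tss = 10)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

small_params <- function(cfg = small_config()) {
  chrom_params(normalization_target = cfg$norm_target)
}

# A uniform-density track: value per bp on a single small chromosome.
uniform_track <- function(value = 1, len = 10000, chrom = "chr1") {
  genome <- stats::setNames(len, chrom)
  signal_track(genome,
               stats::setNames(list(S4Vectors::Rle(value, len)), chrom))
}

# A track with unit counts at the given 0-based positions.
delta_track <- function(pos, len = 10000, chrom = "chr1") {
  genome <- stats::setNames(len, chrom)
  tr <- signal_track(genome)
  r <- as.numeric(IRanges::coverage(IRanges::IRanges(pos + 1L, width = 1L),
                                    width = len))
  signal_track(genome, stats::setNames(list(S4Vectors::Rle(r)), chrom))
}

make_peaks <- function(mids, len = 10000, chrom = "chr1", width = 200) {
  df <- data.frame(chrom = chrom, start = as.integer(mids - width / 2),
                   end = as.integer(mids + width / 2),
                   id = sprintf("pk_%03d", seq_along(mids)),
                   strand = ".", stringsAsFactors = FALSE)
  df$midpoint <- (df$start + df$end) %/% 2L
  structure(df, class = c("peak_set", "data.frame"))
}

write_bed_lines <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent brute-force oracle for the conditional binomial test:
# explicit tail sums of choose() terms, no pbinom.
binom_oracle <- function(xa, xb, na, nb) {
  xa <- round(xa); xb <- round(xb)
  t <- xa + xb
  if (t == 0) return(1)
  pa <- na / (na + nb)
  k <- 0:t
  pmf <- exp(lchoose(t, k) + k * log(pa) + (t - k) * log1p(-pa))
  min(1, 2 * min(sum(pmf[k <= xa]), sum(pmf[k >= xa])))
}

# Independent brute-force step-up FDR oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (j in rev(seq_len(m))) {
    running <- min(running, m * p[o[j]] / j)
    adj[o[j]] <- running
  }
  adj
}
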