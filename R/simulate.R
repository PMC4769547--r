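# Synthetic chromatin with planted architectures.
#
# Four peak classes over a single synthetic chromosome, two conditions
# (control vs. factor-expressing):
#   G1  closed -> open: occupied central nucleosome is evicted on factor
#       expression, with the evicted mass redistributed onto the phased
#       flanking array (mass-conserving eviction);
#   G2  pre-open: nucleosome-depleted region in both conditions;
#   G3  bound but closed: regular nucleosome array, translated by a fixed
#       offset on factor expression, never accessible;
#   G4  open -> closed: the reverse of G1.
# The per-peak generative parameters form the planted-truth table used as
# the acceptance oracle for the rest of the pipeline.

#' Simulation configuration
#'
#' Defaults define the study conditions the package's tests run under:
#' a 2 Mb single-chromosome genome with 200 peaks per class, 190 bp
#' nucleosome spacing, 147 bp footprints, eviction fraction 0.8, a 50 bp
#' planted slide, TF enrichment halved at G3, thermal destabilization
#' factor 0.4 at G3, and an accessibility fold of 30 at open loci.
#' The normalization target of 30,000 is the genome-scaled analogue of
#' normalizing 30 million reads on a ~3 Gb genome: it puts the normalized
#' closed-chromatin background insertion rate near 0.005/bp, so the
#' 20-count open/closed flank cutoff separates the planted states the way
#' it does on real data.
#'
#' @param genome_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param n_peaks_per_class single count or named vector
#'   `c(G1=,G2=,G3=,G4=)`.
#' @param nucleosome_spacing dyad-to-dyad spacing of the planted arrays.
#' @param footprint nucleosomal fragment length (bp).
#' @param fragment_length_sd MNase fragment-length jitter (sd, bp).
#' @param dyad_sd positional jitter of sampled dyads (sd, bp).
#' @param n_flank_nucleosomes phased nucleosomes per side.
#' @param center_weight MNase sampling weight of the central nucleosome
#'   relative to flanking ones (strongly positioned central nucleosomes
#'   recover more mononucleosomal fragments).
#' @param flank_decay geometric decay of flanking-nucleosome weight per
#'   position away from the anchor (phasing fades with distance).
#' @param flank_occ,treat_flank_occ fractional occupancy of flanking
#'   nucleosomes (control / after factor binding).
#' @param occ_sigma Gaussian half-width (bp) used to smooth dyads into a
#'   continuous occupancy landscape for accessibility.
#' @param eviction_fraction fraction of central occupancy lost at G1 (and
#'   gained at G4) on factor expression.
#' @param slide_bp planted array translation at G3 (bp).
#' @param accessibility_fold transposase insertion rate at fully open
#'   chromatin relative to the closed-chromatin background.
#' @param atac_read_length simulated single-end read length (bp).
#' @param mnase_background,chip_background fraction of fragments sampled
#'   uniformly from the genome.
#' @param tf_spread sd (bp) of TF/cofactor ChIP fragment centers around
#'   the peak midpoint.
#' @param chip_fragment_length,chip_fragment_sd ChIP fragment length
#'   distribution (bp).
#' @param tf_g3_multiplier TF ChIP enrichment at G3 relative to G1/G2.
#' @param thermal_factor multiplier applied to G3 TF enrichment under
#'   thermal treatment (37C); 1 elsewhere.
#' @param histone_weights named list of `c(control=, treated=)` flanking
#'   enhancer-mark weights per class.
#' @param depth_atac,depth_mnase,depth_chip expected fragments per
#'   library.
#' @param norm_target normalization target used by the synthetic pipeline.
#' @param tss_fraction fraction of peaks given a TSS within 1 kb.
#' @param n_background_tss additional TSSs placed uniformly.
#' @param end_margin minimum distance of peak midpoints from chromosome
#'   ends.
#' @param peak_width width of the written peak intervals (bp).
#' @return a `sim_config` list.
#' @export
simulation_config <- function(genome_length = 2e6,
                              chrom = "chrS",
                              n_peaks_per_class = 200,
                              nucleosome_spacing = 190,
                              footprint = 147,
                              fragment_length_sd = 10,
                              dyad_sd = 10,
                              n_flank_nucleosomes = 5,
                              center_weight = 3,
                              flank_decay = 0.8,
                              flank_occ = 0.85,
                              treat_flank_occ = 0.9,
                              occ_sigma = 55,
                              eviction_fraction = 0.8,
                              slide_bp = 50,
                              accessibility_fold = 30,
                              atac_read_length = 36,
                              mnase_background = 0.1,
                              chip_background = 0.1,
                              tf_spread = 40,
                              chip_fragment_length = 200,
                              chip_fragment_sd = 20,
                              tf_g3_multiplier = 0.5,
                              thermal_factor = 0.4,
                              histone_weights = list(
                                G1 = c(control = 0.5, treated = 2.0),
                                G2 = c(control = 1.2, treated = 1.5),
                                G3 = c(control = 0.3, treated = 0.3),
                                G4 = c(control = 2.0, treated = 0.5)),
                              depth_atac = 3e5,
                              depth_mnase = 1e6,
                              depth_chip = 2e5,
                              norm_target = 30000,
                              tss_fraction = 0.25,
                              n_background_tss = 50,
                              end_margin = 5000,
                              peak_width = 200) {
  if (length(n_peaks_per_class) == 1L && is.null(names(n_peaks_per_class))) {
    n_peaks_per_class <- stats::setNames(rep(n_peaks_per_class, 4L),
                                         c("G1", "G2", "G3", "G4"))
  }
  if (!all(c("G1", "G2", "G3", "G4") %in% names(n_peaks_per_class))) {
    stop("n_peaks_per_class needs entries for G1..G4")
  }
  cfg <- list(genome_length = genome_length, chrom = chrom,
              n_peaks_per_class = n_peaks_per_class[c("G1", "G2", "G3",
                                                      "G4")],
              nucleosome_spacing = nucleosome_spacing,
              footprint = footprint,
              fragment_length_sd = fragment_length_sd,
              dyad_sd = dyad_sd,
              n_flank_nucleosomes = n_flank_nucleosomes,
              center_weight = center_weight,
              flank_decay = flank_decay,
              flank_occ = flank_occ, treat_flank_occ = treat_flank_occ,
              occ_sigma = occ_sigma,
              eviction_fraction = eviction_fraction,
              slide_bp = slide_bp,
              accessibility_fold = accessibility_fold,
              atac_read_length = atac_read_length,
              mnase_background = mnase_background,
              chip_background = chip_background,
              tf_spread = tf_spread,
              chip_fragment_length = chip_fragment_length,
              chip_fragment_sd = chip_fragment_sd,
              tf_g3_multiplier = tf_g3_multiplier,
              thermal_factor = thermal_factor,
              histone_weights = histone_weights,
              depth_atac = depth_atac, depth_mnase = depth_mnase,
              depth_chip = depth_chip, norm_target = norm_target,
              tss_fraction = tss_fraction,
              n_background_tss = n_background_tss,
              end_margin = end_margin, peak_width = peak_width)
  if (eviction_fraction < 0 || eviction_fraction > 1) {
    stop("eviction_fraction must lie in [0, 1]")
  }
  n_total <- sum(cfg$n_peaks_per_class)
  if (n_total > 0) {
    span <- genome_length - 2 * end_margin
    spacing <- if (n_total > 1) span / (n_total - 1) else span
    # midpoints must stay far enough apart that the +/- 1 kb analysis
    # windows never overlap, even after +/- 200 bp placement jitter
    if (spacing < 2400) {
      stop("genome too small for ", n_total, " peaks: need >= 2.4 kb ",
           "between midpoints", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# Planted nucleosome architecture for one class+condition: dyad offsets
# relative to the peak midpoint, MNase sampling weights, and fractional
# occupancies used by the accessibility model. Phasing decays
# geometrically with distance from the anchor (flank_decay per
# nucleosome), as it does around real bound sites; without that envelope a
# planted array shift larger than spacing - max_slide_lag would be
# indistinguishable from its period alias.
.nuc_template <- function(class, condition, cfg) {
  s <- cfg$nucleosome_spacing
  J <- cfg$n_flank_nucleosomes
  fl <- c(-(J:1), 1:J) * s
  nf <- length(fl)
  fw <- cfg$flank_decay^(abs(fl) / s - 1)
  cw <- cfg$center_weight
  e <- cfg$eviction_fraction
  closed_arch <- data.frame(
    offset = c(0, fl),
    weight = c(cw, fw),
    occ = c(1, rep(cfg$flank_occ, nf)))
  open_arch <- data.frame(
    offset = c(0, fl),
    weight = c(cw * (1 - e), fw + cw * e * fw / sum(fw)),
    occ = c(1 - e, rep(cfg$treat_flank_occ, nf)))
  switch(class,
    G1 = if (condition == "control") closed_arch else open_arch,
    G2 = data.frame(offset = fl, weight = fw,
                    occ = rep(cfg$flank_occ, nf)),
    G3 = {
      d <- c(0, fl) + if (condition == "treated") cfg$slide_bp else 0
      data.frame(offset = d, weight = c(1, fw), occ = rep(1, nf + 1))
    },
    G4 = if (condition == "control") open_arch else closed_arch,
    stop("unknown class: ", class))
}

# Is this class+condition in the transposase-accessible state? Closed
# states expose only the uniform background rate regardless of linker
# geometry (higher-order compaction).
.open_state <- function(class, condition) {
  (class == "G1" & condition == "treated") |
    class == "G2" |
    (class == "G4" & condition == "control")
}

# Accessibility shape over the +/- 1 kb window: 1 - smoothed occupancy,
# clamped at 0; zero everywhere for closed states.
.openness_template <- function(class, condition, cfg, halfwidth = 1000) {
  x <- seq(-halfwidth, halfwidth)
  if (!.open_state(class, condition)) return(numeric(length(x)))
  t <- .nuc_template(class, condition, cfg)
  occ <- as.numeric(exp(-outer(x, t$offset, "-")^2 /
                          (2 * cfg$occ_sigma^2)) %*% t$occ)
  pmax(0, 1 - occ)
}

#' Plant the peak layout and ground-truth table
#'
#' Places peaks of the four classes (shuffled along the chromosome) at
#' deterministic-for-seed positions with at least 2.4 kb between midpoints
#' and at least `end_margin` from chromosome ends, draws TSSs near a
#' fraction of the peaks plus background TSSs, and records per-peak
#' generative parameters (class, planted slide, eviction fraction, TF
#' enrichment, open flags, thermal factor).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return a `chromatin_layout`: list with `config`, `genome`, `peaks`
#'   (a `peak_set`), `truth` (planted-truth data frame), `tss`, `seed`.
#' @export
plant_layout <- function(config = simulation_config(), seed = 1) {
  cfg <- config
  npc <- cfg$n_peaks_per_class
  n <- sum(npc)
  L <- cfg$genome_length
  .with_seed(seed, {
    classes <- sample(rep(names(npc), times = npc))
    base <- if (n > 1) {
      round(seq(cfg$end_margin, L - cfg$end_margin, length.out = n))
    } else if (n == 1) round(L / 2) else integer(0)
    mids <- base + sample(-200:200, n, replace = TRUE)
    pw <- cfg$peak_width
    peaks <- .peak_set(data.frame(
      chrom = rep(cfg$chrom, n),
      start = as.integer(mids - pw %/% 2L),
      end = as.integer(mids - pw %/% 2L + pw),
      id = sprintf("peak_%05d", seq_len(max(n, 0L))),
      strand = rep(".", n),
      midpoint = as.integer(mids),
      stringsAsFactors = FALSE))
    truth <- data.frame(
      peak_id = peaks$id,
      class = classes,
      midpoint = peaks$midpoint,
      planted_slide_bp = ifelse(classes == "G3", cfg$slide_bp, 0L),
      planted_eviction_fraction = ifelse(classes %in% c("G1", "G4"),
                                         cfg$eviction_fraction, NA_real_),
      tf_enrichment = ifelse(classes == "G3", cfg$tf_g3_multiplier, 1),
      open_control = .open_state(classes, "control"),
      open_treated = .open_state(classes, "treated"),
      thermal_factor = ifelse(classes == "G3", cfg$thermal_factor, 1),
      seed = seed,
      stringsAsFactors = FALSE)
    n_prox <- round(cfg$tss_fraction * n)
    prox_idx <- if (n_prox > 0) sample(n, n_prox) else integer(0)
    tss_pos <- c(
      pmax(0, mids[prox_idx] + sample(-1000:1000, n_prox, replace = TRUE)),
      floor(stats::runif(cfg$n_background_tss, 0, L)))
    tss <- data.frame(chrom = cfg$chrom, pos = as.integer(sort(tss_pos)),
                      stringsAsFactors = FALSE)
    structure(list(config = cfg,
                   genome = stats::setNames(L, cfg$chrom),
                   peaks = peaks, truth = truth, tss = tss, seed = seed),
              class = "chromatin_layout")
  })
}

#' @export
print.chromatin_layout <- function(x, ...) {
  cat(sprintf("chromatin_layout: %d peaks on %s (%.3g bp), seed %d\n",
              nrow(x$peaks), names(x$genome), x$genome[[1L]], x$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate an MNase-seq library
#'
#' Mononucleosome-sized fragments (length ~ `footprint` +/-
#' `fragment_length_sd`) are sampled with probability proportional to the
#' planted nucleosome landscape (dyads jittered by `dyad_sd`) plus a
#' uniform background fraction; the total is Poisson at the requested
#' depth.
#'
#' @param layout a `chromatin_layout`.
#' @param condition `"control"` or `"treated"`.
#' @param depth expected fragments (default `config$depth_mnase`).
#' @param seed integer seed.
#' @return an MNase `fragment_set` (paired spans).
#' @export
simulate_mnase <- function(layout, condition = c("control", "treated"),
                           depth = NULL, seed = 1) {
  condition <- match.arg(condition)
  cfg <- layout$config
  if (is.null(depth)) depth <- cfg$depth_mnase
  truth <- layout$truth
  L <- layout$genome[[1L]]
  .with_seed(seed, {
    n <- stats::rpois(1, depth)
    nbg <- stats::rbinom(1, n, cfg$mnase_background)
    npk <- n - nbg
    mids <- floor(stats::runif(nbg, 0, L))
    if (npk > 0 && nrow(truth) > 0) {
      tmpl <- lapply(stats::setNames(nm = unique(truth$class)),
                     .nuc_template, condition = condition, cfg = cfg)
      cmass <- vapply(tmpl, function(t) sum(t$weight), numeric(1))
      pk <- sample.int(nrow(truth), npk, replace = TRUE,
                       prob = cmass[truth$class])
      off <- numeric(npk)
      pkcls <- truth$class[pk]
      for (cl in names(tmpl)) {
        idx <- which(pkcls == cl)
        if (!length(idx)) next
        t <- tmpl[[cl]]
        j <- sample.int(nrow(t), length(idx), replace = TRUE,
                        prob = t$weight)
        off[idx] <- t$offset[j]
      }
      dyads <- truth$midpoint[pk] + off +
        round(stats::rnorm(npk, 0, cfg$dyad_sd))
      mids <- c(dyads, mids)
    }
    len <- pmax(100L, round(stats::rnorm(length(mids), cfg$footprint,
                                         cfg$fragment_length_sd)))
    start <- as.integer(mids - len %/% 2L)
    end <- as.integer(start + len)
    start <- pmax(start, 0L)
    end <- pmin(end, as.integer(L))
    keep <- end > start
    fragment_set(data.frame(chrom = rep(names(layout$genome), sum(keep)),
                            start = start[keep], end = end[keep],
                            stringsAsFactors = FALSE),
                 "MNASE", condition, is_paired = TRUE)
  })
}

#' Simulate an ATAC-seq library
#'
#' Transposase cut sites are sampled from a rate landscape equal to the
#' closed-chromatin background (1 unit/bp genome-wide) plus, within
#' +/- 1 kb of peaks in the transposase-accessible state,
#' `(accessibility_fold - 1) * openness(x)` where openness is one minus the
#' smoothed planted occupancy. Cut sites are emitted as single-end reads
#' with random strands, with raw coordinates pre-shifted -4/+5 so that the
#' standard Tn5 offset correction ([tn5_cut_sites()]) recovers the true
#' cut positions exactly.
#'
#' @param layout a `chromatin_layout`.
#' @param condition `"control"` or `"treated"`.
#' @param depth expected reads (default `config$depth_atac`).
#' @param seed integer seed.
#' @param keep_cut_sites attach the true cut positions as attribute
#'   `cut_sites` (for generative checks).
#' @return an ATAC `fragment_set` of stranded single-end reads.
#' @export
simulate_atac <- function(layout, condition = c("control", "treated"),
                          depth = NULL, seed = 1,
                          keep_cut_sites = FALSE) {
  condition <- match.arg(condition)
  cfg <- layout$config
  if (is.null(depth)) depth <- cfg$depth_atac
  truth <- layout$truth
  L <- layout$genome[[1L]]
  fold <- cfg$accessibility_fold
  .with_seed(seed, {
    tmpl <- lapply(stats::setNames(nm = unique(truth$class)),
                   .openness_template, condition = condition, cfg = cfg)
    omass <- vapply(tmpl, sum, numeric(1)) * (fold - 1)
    peak_mass <- if (nrow(truth)) unname(omass[truth$class]) else numeric(0)
    M <- L + sum(peak_mass)
    n <- stats::rpois(1, depth)
    nbg <- stats::rbinom(1, n, L / M)
    npk <- n - nbg
    cut <- floor(stats::runif(nbg, 0, L))
    if (npk > 0 && sum(peak_mass) > 0) {
      pk <- sample.int(nrow(truth), npk, replace = TRUE, prob = peak_mass)
      off <- integer(npk)
      pkcls <- truth$class[pk]
      for (cl in unique(pkcls)) {
        idx <- which(pkcls == cl)
        off[idx] <- sample.int(length(tmpl[[cl]]), length(idx),
                               replace = TRUE, prob = tmpl[[cl]]) -
          (length(tmpl[[cl]]) + 1L) / 2L
      }
      cut <- c(truth$midpoint[pk] + off, cut)
    }
    strand <- sample(c("+", "-"), length(cut), replace = TRUE)
    rl <- cfg$atac_read_length
    start <- ifelse(strand == "+", cut - 4L, cut + 5L - rl)
    end <- start + rl
    start <- pmax(as.integer(start), 0L)
    end <- pmin(as.integer(end), as.integer(L))
    keep <- end > start
    fs <- fragment_set(data.frame(chrom = rep(names(layout$genome),
                                              sum(keep)),
                                  start = start[keep], end = end[keep],
                                  strand = strand[keep],
                                  stringsAsFactors = FALSE),
                       "ATAC", condition, is_paired = FALSE)
    if (keep_cut_sites) attr(fs, "cut_sites") <- as.integer(cut[keep])
    fs
  })
}

#' Simulate a ChIP-seq library
#'
#' `factor = "TF"`: fragments centered on peak midpoints with per-class
#' enrichment (`tf_enrichment`, halved at G3 by default), present only in
#' the factor-expressing (treated) condition; under `thermal = "37C"` the
#' G3 enrichment is additionally multiplied by the planted thermal
#' destabilization factor. `"H3K4me1"` / `"H3K27ac"`: fragments centered
#' on the flanking nucleosomes with class- and condition-dependent weights
#' (gain at G1, loss at G4). `"cofactor"`: remodeler-like signal at G1
#' peaks in the treated condition only. A `chip_background` fraction of
#' fragments is uniform; libraries with no planted enrichment are pure
#' background.
#'
#' @param layout a `chromatin_layout`.
#' @param factor one of `"TF"`, `"H3K4me1"`, `"H3K27ac"`, `"cofactor"`.
#' @param condition `"control"` or `"treated"`.
#' @param thermal `"ice"` (native) or `"37C"` (thermal treatment).
#' @param depth expected fragments (default `config$depth_chip`).
#' @param seed integer seed.
#' @return a ChIP `fragment_set` (paired spans).
#' @export
simulate_chip <- function(layout,
                          factor = c("TF", "H3K4me1", "H3K27ac",
                                     "cofactor"),
                          condition = c("control", "treated"),
                          thermal = c("ice", "37C"),
                          depth = NULL, seed = 1) {
  factor <- match.arg(factor)
  condition <- match.arg(condition)
  thermal <- match.arg(thermal)
  cfg <- layout$config
  if (is.null(depth)) depth <- cfg$depth_chip
  truth <- layout$truth
  L <- layout$genome[[1L]]
  .with_seed(seed, {
    n <- stats::rpois(1, depth)
    if (factor %in% c("TF", "cofactor")) {
      w <- if (condition == "treated") {
        if (factor == "TF") {
          truth$tf_enrichment *
            (if (thermal == "37C") truth$thermal_factor else 1)
        } else {
          as.numeric(truth$class == "G1")
        }
      } else {
        rep(0, nrow(truth))
      }
    } else {
      hw <- cfg$histone_weights
      w <- vapply(truth$class, function(cl) hw[[cl]][[condition]],
                  numeric(1))
    }
    if (!length(w) || sum(w) == 0) {
      nbg <- n
      mids <- floor(stats::runif(nbg, 0, L))
    } else {
      nbg <- stats::rbinom(1, n, cfg$chip_background)
      npk <- n - nbg
      pk <- sample.int(nrow(truth), npk, replace = TRUE, prob = w)
      if (factor %in% c("TF", "cofactor")) {
        off <- round(stats::rnorm(npk, 0, cfg$tf_spread))
      } else {
        # enhancer marks sit on the flanking nucleosomes of the planted
        # architecture, never on the central dyad
        off <- integer(npk)
        pkcls <- truth$class[pk]
        for (cl in unique(pkcls)) {
          t <- .nuc_template(cl, condition, cfg)
          t <- t[abs(t$offset) >= cfg$nucleosome_spacing / 2, ,
                 drop = FALSE]
          idx <- which(pkcls == cl)
          j <- sample.int(nrow(t), length(idx), replace = TRUE,
                          prob = t$weight)
          off[idx] <- t$offset[j] +
            round(stats::rnorm(length(idx), 0, cfg$dyad_sd))
        }
      }
      mids <- c(truth$midpoint[pk] + off, floor(stats::runif(nbg, 0, L)))
    }
    len <- pmax(100L, round(stats::rnorm(length(mids),
                                         cfg$chip_fragment_length,
                                         cfg$chip_fragment_sd)))
    start <- as.integer(mids - len %/% 2L)
    end <- as.integer(start + len)
    start <- pmax(start, 0L)
    end <- pmin(end, as.integer(L))
    keep <- end > start
    fragment_set(data.frame(chrom = rep(names(layout$genome), sum(keep)),
                            start = start[keep], end = end[keep],
                            stringsAsFactors = FALSE),
                 "CHIP", condition, is_paired = TRUE)
  })
}

.write_config <- function(cfg, path) {
  flat <- lapply(cfg, function(v) {
    if (is.list(v)) {
      paste(vapply(names(v), function(nm) {
        paste0(nm, "=", paste(v[[nm]], collapse = ",")) }, ""),
        collapse = "; ")
    } else {
      paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
    }
  })
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `peaks.bed`, `tss.bed`, `chrom.sizes`, `truth.tsv`, the
#' configuration as `config.dcf`, ATAC reads as BED6 and MNase/ChIP
#' fragments as BEDPE for both conditions (plus TF ChIP under thermal
#' treatment, enhancer marks and the cofactor library). All libraries are
#' seeded from `seed` and byte-reproducible.
#'
#' @param layout a `chromatin_layout`.
#' @param dir output directory (created; must be empty unless `force`).
#' @param seed integer seed for the read sampling.
#' @param force overwrite a non-empty directory.
#' @param chip write the ChIP libraries too (TRUE; FALSE writes only
#'   peaks/TSS/ATAC/MNase, which the classification stages need).
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(layout, dir, seed = 1, force = FALSE,
                          chip = TRUE) {
  if (dir.exists(dir)) {
    if (length(list.files(dir)) && !force) {
      stop("output directory not empty (use force = TRUE): ", dir,
           call. = FALSE)
    }
  } else {
    if (!dir.create(dir, recursive = TRUE)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  p <- function(f) file.path(dir, f)
  paths <- c(peaks = p("peaks.bed"), tss = p("tss.bed"),
             chrom_sizes = p("chrom.sizes"), truth = p("truth.tsv"),
             config = p("config.dcf"))
  write_peaks(layout$peaks, paths[["peaks"]])
  utils::write.table(
    data.frame(layout$tss$chrom, layout$tss$pos, layout$tss$pos + 1L),
    paths[["tss"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_chrom_sizes(layout$genome, paths[["chrom_sizes"]])
  .write_tsv(layout$truth, paths[["truth"]])
  .write_config(layout$config, paths[["config"]])
  k <- 0L
  nxt <- function() {
    k <<- k + 1L
    .derive_seed(seed, k)
  }
  for (cond in c("control", "treated")) {
    f <- p(sprintf("atac_%s.bed", cond))
    write_fragments(simulate_atac(layout, cond, seed = nxt()), f)
    paths[[paste0("atac_", cond)]] <- f
    f <- p(sprintf("mnase_%s.bedpe", cond))
    write_fragments(simulate_mnase(layout, cond, seed = nxt()), f)
    paths[[paste0("mnase_", cond)]] <- f
  }
  if (chip) {
    specs <- list(
      c("chip_tf_control", "TF", "control", "ice"),
      c("chip_tf_treated", "TF", "treated", "ice"),
      c("chip_tf_treated_37c", "TF", "treated", "37C"),
      c("chip_h3k4me1_control", "H3K4me1", "control", "ice"),
      c("chip_h3k4me1_treated", "H3K4me1", "treated", "ice"),
      c("chip_h3k27ac_control", "H3K27ac", "control", "ice"),
      c("chip_h3k27ac_treated", "H3K27ac", "treated", "ice"),
      c("chip_cofactor_treated", "cofactor", "treated", "ice"))
    for (s in specs) {
      f <- p(paste0(s[1L], ".bedpe"))
      write_fragments(simulate_chip(layout, s[2L], s[3L], s[4L],
                                    seed = nxt()), f)
      paths[[s[1L]]] <- f
    }
  }
  invisible(paths)
}
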