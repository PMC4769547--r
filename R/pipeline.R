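# Pipeline stages: file-in, TSV-out wrappers chaining the core operations.
# Each stage is a pure function of its inputs and seed; reruns on identical
# inputs produce byte-identical primary TSV outputs. The thin command-line
# wrapper in inst/scripts/chromdissect.R maps subcommands onto these
# functions.

.ensure_outdir <- function(out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  invisible(out_dir)
}

.need_file <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for ", stage, ": ",
         if (is.null(path)) "(not given)" else path,
         " - run the upstream stage first", call. = FALSE)
  }
  invisible(path)
}

#' Simulate stage: write a synthetic dataset
#'
#' @param out_dir output directory.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param force overwrite a non-empty directory.
#' @param chip also write ChIP libraries.
#' @return file paths, invisibly.
#' @export
run_simulate <- function(out_dir, config = simulation_config(), seed = 1,
                         force = FALSE, chip = TRUE) {
  layout <- plant_layout(config, seed = seed)
  write_dataset(layout, out_dir, seed = .derive_seed(seed, 1000L),
                force = force, chip = chip)
}

# Shared loader: ATAC BED6 reads -> normalized cut-site track.
.atac_track <- function(path, genome, condition, params) {
  frags <- read_fragments(.need_file(path, "classify"), assay = "ATAC",
                          condition = condition)
  normalize_track(tn5_cut_sites(frags, genome,
                                shift_plus = params$tn5_shift_plus,
                                shift_minus = params$tn5_shift_minus),
                  target = params$normalization_target)
}

#' Classify stage: differential accessibility classes from two ATAC files
#'
#' Reads peaks and two single-end ATAC read files, builds normalized
#' cut-site tracks, classifies every peak into G1-G4 and writes
#' `classification.tsv` plus `classification_summary.tsv` (class counts
#' and percentages).
#'
#' @param peaks_file BED peaks.
#' @param atac_control_file,atac_treated_file BED6 ATAC reads.
#' @param chrom_sizes_file two-column chrom sizes.
#' @param out_dir output directory.
#' @param params a [chrom_params()]; for synthetic datasets set
#'   `normalization_target` to the value in the dataset's `config.dcf`.
#' @param tss_file optional TSS BED for proximal/distal annotation.
#' @param quiet suppress the class-count message.
#' @return the `peak_classes` object, invisibly.
#' @export
run_classify <- function(peaks_file, atac_control_file, atac_treated_file,
                         chrom_sizes_file, out_dir,
                         params = chrom_params(), tss_file = NULL,
                         quiet = FALSE) {
  .ensure_outdir(out_dir)
  genome <- read_chrom_sizes(.need_file(chrom_sizes_file, "classify"))
  peaks <- read_peaks(.need_file(peaks_file, "classify"))
  ctrl <- .atac_track(atac_control_file, genome, "control", params)
  treat <- .atac_track(atac_treated_file, genome, "treated", params)
  counts <- build_count_matrix(peaks, ctrl, treat, params)
  classes <- classify_peaks(counts, params)
  tss_ann <- if (!is.null(tss_file)) {
    annotate_tss(peaks, read_tss(tss_file), params$tss_proximal_bp)
  }
  write_classification(classes, peaks, file.path(out_dir,
                                                 "classification.tsv"),
                       tss_annotation = tss_ann)
  .write_tsv(summary(classes),
             file.path(out_dir, "classification_summary.tsv"))
  if (!quiet) {
    s <- summary(classes)
    message(paste(sprintf("%s: %d (%.1f%%)", s$class, s$n, s$percent),
                  collapse = "  "))
  }
  invisible(classes)
}

.read_classes <- function(classification_file, stage) {
  df <- utils::read.table(.need_file(classification_file, stage),
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$class, df$peak_id)
}

#' Profile stage: metagenes, heatmap matrices and enrichment box stats
#'
#' Writes per-class/condition ATAC metagenes (`metagene_atac.tsv`),
#' heatmap matrices for both conditions with rows ordered by decreasing
#' weighted treated-condition ATAC signal within class blocks
#' (`heatmap_atac_control.tsv`, `heatmap_atac_treated.tsv`,
#' `row_order.tsv`), and, when a ChIP file is given, per-class windowed
#' enrichment box statistics with pairwise Mann-Whitney p-values
#' (`chip_box_stats.tsv`, `chip_tests.tsv`).
#'
#' @param classification_file output of [run_classify()].
#' @param peaks_file,chrom_sizes_file dataset files.
#' @param atac_control_file,atac_treated_file BED6 ATAC reads.
#' @param out_dir output directory.
#' @param chip_file optional BEDPE ChIP fragments (e.g. the TF).
#' @param params a [chrom_params()].
#' @param classes_subset optional character vector restricting outputs to
#'   those classes.
#' @return invisibly, a list of the written paths.
#' @export
run_profile <- function(classification_file, peaks_file, chrom_sizes_file,
                        atac_control_file, atac_treated_file, out_dir,
                        chip_file = NULL, params = chrom_params(),
                        classes_subset = NULL) {
  .ensure_outdir(out_dir)
  genome <- read_chrom_sizes(.need_file(chrom_sizes_file, "profile"))
  peaks <- read_peaks(.need_file(peaks_file, "profile"))
  cls <- .read_classes(classification_file, "profile")
  if (!is.null(classes_subset)) {
    peaks <- peaks[cls[peaks$id] %in% classes_subset, , drop = FALSE]
  }
  ctrl <- .atac_track(atac_control_file, genome, "control", params)
  treat <- .atac_track(atac_treated_file, genome, "treated", params)
  w <- 2 * params$flank_window_bp
  pm_c <- profile_matrix(ctrl, peaks, w, params$metagene_bin_bp)
  pm_t <- profile_matrix(treat, peaks, w, params$metagene_bin_bp)
  mg <- do.call(rbind, lapply(sort(unique(unname(cls[peaks$id]))),
                              function(cl) {
    ids <- peaks$id[cls[peaks$id] == cl]
    rbind(
      data.frame(class = cl, condition = "control",
                 offset = pm_c$offsets,
                 density = metagene(pm_c, ids)$density),
      data.frame(class = cl, condition = "treated",
                 offset = pm_t$offsets,
                 density = metagene(pm_t, ids)$density))
  }))
  paths <- list(metagene = file.path(out_dir, "metagene_atac.tsv"))
  .write_tsv(mg, paths$metagene)
  ord <- order_rows(peaks, treat, cls, params)
  paths$row_order <- file.path(out_dir, "row_order.tsv")
  .write_tsv(ord, paths$row_order)
  hm_c <- profile_matrix(ctrl, peaks, params$heatmap_window_bp,
                         params$heatmap_bin_bp)
  hm_t <- profile_matrix(treat, peaks, params$heatmap_window_bp,
                         params$heatmap_bin_bp)
  ridx <- match(ord$peak_id, hm_c$peak_ids)
  for (nm in c("control", "treated")) {
    hm <- if (nm == "control") hm_c else hm_t
    df <- data.frame(peak_id = ord$peak_id, class = ord$class,
                     hm$values[ridx, , drop = FALSE])
    names(df) <- c("peak_id", "class",
                   sprintf("bp_%d", as.integer(hm$offsets)))
    paths[[paste0("heatmap_", nm)]] <-
      file.path(out_dir, sprintf("heatmap_atac_%s.tsv", nm))
    .write_tsv(df, paths[[paste0("heatmap_", nm)]])
  }
  if (!is.null(chip_file)) {
    chip <- read_fragments(chip_file, assay = "CHIP",
                           condition = "treated")
    chip_tr <- normalize_track(fragment_track(chip, genome),
                               target = params$normalization_target)
    groups <- signal_by_class(chip_tr, peaks, cls,
                              halfwidth = params$count_window_bp / 2)
    cmp <- compare_groups(groups)
    paths$chip_box <- file.path(out_dir, "chip_box_stats.tsv")
    paths$chip_tests <- file.path(out_dir, "chip_tests.tsv")
    .write_tsv(cmp$stats, paths$chip_box)
    .write_tsv(cmp$tests, paths$chip_tests)
  }
  invisible(paths)
}

#' Dynamics stage: nucleosome eviction, phasing, sliding and stability
#'
#' Computes per-class MNase metagenes in both conditions
#' (`mnase_metagene.tsv`), the per-class dynamics scores
#' (`dynamics.tsv`: eviction, phasing, sliding) and, when the
#' thermal-treatment ChIP pair is given, the per-class stability ratios
#' and pairwise tests (`stability.tsv`, `stability_tests.tsv`).
#'
#' @param classification_file output of [run_classify()].
#' @param peaks_file,chrom_sizes_file dataset files.
#' @param mnase_control_file,mnase_treated_file BEDPE MNase fragments.
#' @param out_dir output directory.
#' @param chip_ice_file,chip_37c_file optional BEDPE TF ChIP fragments
#'   without / with thermal treatment.
#' @param params a [chrom_params()].
#' @return invisibly, a list with the dynamics table and written paths.
#' @export
run_dynamics <- function(classification_file, peaks_file, chrom_sizes_file,
                         mnase_control_file, mnase_treated_file, out_dir,
                         chip_ice_file = NULL, chip_37c_file = NULL,
                         params = chrom_params()) {
  .ensure_outdir(out_dir)
  genome <- read_chrom_sizes(.need_file(chrom_sizes_file, "dynamics"))
  peaks <- read_peaks(.need_file(peaks_file, "dynamics"))
  cls <- .read_classes(classification_file, "dynamics")
  mn_c <- read_fragments(.need_file(mnase_control_file, "dynamics"),
                         assay = "MNASE", condition = "control")
  mn_t <- read_fragments(.need_file(mnase_treated_file, "dynamics"),
                         assay = "MNASE", condition = "treated")
  mg <- do.call(rbind, lapply(sort(unique(unname(cls[peaks$id]))),
                              function(cl) {
    sub <- peaks[cls[peaks$id] == cl, , drop = FALSE]
    pc <- mnase_metagene(mn_c, sub, genome, params)
    pt <- mnase_metagene(mn_t, sub, genome, params)
    rbind(data.frame(class = cl, condition = "control",
                     offset = pc$offsets, density = pc$density),
          data.frame(class = cl, condition = "treated",
                     offset = pt$offsets, density = pt$density))
  }))
  paths <- list(mnase_metagene = file.path(out_dir, "mnase_metagene.tsv"),
                dynamics = file.path(out_dir, "dynamics.tsv"))
  .write_tsv(mg, paths$mnase_metagene)
  dyn <- dynamics_table(mn_c, mn_t, peaks, cls, genome, params)
  .write_tsv(dyn, paths$dynamics)
  stab <- NULL
  if (!is.null(chip_ice_file) && !is.null(chip_37c_file)) {
    tr <- function(f, cond) {
      normalize_track(
        fragment_track(read_fragments(f, assay = "CHIP",
                                      condition = cond), genome),
        target = params$normalization_target)
    }
    stab <- stability_analysis(tr(chip_37c_file, "treated"),
                               tr(chip_ice_file, "treated"),
                               peaks, cls)
    paths$stability <- file.path(out_dir, "stability.tsv")
    paths$stability_tests <- file.path(out_dir, "stability_tests.tsv")
    .write_tsv(stab$class_stats, paths$stability)
    .write_tsv(stab$tests$tests, paths$stability_tests)
  }
  invisible(list(dynamics = dyn, stability = stab, paths = paths))
}

#' Report stage: plain-text summary of a completed run
#'
#' Collects the classification summary, dynamics table and stability/
#' enrichment tests from `out_dir` and writes `report.txt`.
#'
#' @param out_dir directory holding the stage outputs.
#' @return the report path, invisibly.
#' @export
run_report <- function(out_dir) {
  f <- function(name) file.path(out_dir, name)
  .need_file(f("classification_summary.tsv"), "report")
  lines <- c("chromatin-state dissection report", "")
  s <- utils::read.table(f("classification_summary.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  lines <- c(lines, "Accessibility classes:",
             sprintf("  %s  n=%-6d %5.1f%%", s$class, s$n, s$percent), "")
  if (file.exists(f("dynamics.tsv"))) {
    d <- utils::read.table(f("dynamics.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    lines <- c(lines, "Nucleosome dynamics (per class):",
               sprintf(paste0("  %s  eviction=%.3f  phasing(ctrl)=%.3f  ",
                              "phasing(treat)=%.3f  slide=%+d bp"),
                       d$class, d$eviction_score, d$phasing_control,
                       d$phasing_treated, as.integer(d$slide_bp)), "")
  }
  if (file.exists(f("stability.tsv"))) {
    st <- utils::read.table(f("stability.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    lines <- c(lines, "Thermal stability (37C/ice median ratio):",
               sprintf("  %s  %.3f", st$class, st$median_ratio), "")
  }
  if (file.exists(f("chip_tests.tsv"))) {
    ct <- utils::read.table(f("chip_tests.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    lines <- c(lines, "TF enrichment contrasts (Mann-Whitney):",
               sprintf("  %s vs %s  p=%.3g", ct$group_a, ct$group_b,
                       ct$p_value), "")
  }
  writeLines(lines, f("report.txt"))
  invisible(f("report.txt"))
}
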