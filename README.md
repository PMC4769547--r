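# chromdissect

Chromatin-state dissection of transcription-factor binding sites from
two-condition chromatin data.

When a pioneer transcription factor (a GATA-family factor, for example)
is introduced into cells that previously lacked it, its binding sites
split into distinct chromatin fates: loci that open de novo (pioneer
sites), loci that were already open, loci that stay bound-but-closed
inside nucleosomal arrays, and a small group that loses accessibility.
`chromdissect` implements this dissection as a reusable R package:

* **Peak classification (G1–G4).** Normalized ATAC-seq cut-site counts in
  a 200 bp window around each peak are compared between conditions with a
  conditional exact rate test: given the total *t* = *x*<sub>a</sub> +
  *x*<sub>b</sub>, *x*<sub>a</sub> is Binomial(*t*,
  *n*<sub>a</sub>/(*n*<sub>a</sub>+*n*<sub>b</sub>)) under the null (or
  the conditional negative-binomial law with size 1/φ when an
  overdispersion φ > 0 is set); the two-sided p-value doubles the smaller
  tail. After Benjamini–Hochberg adjustment, peaks with FDR < 0.1 and
  fold change > 2 are G1 (gained) or G4 (lost); conserved peaks are split
  into G2 (pre-open) and G3 (closed) by a 20-count cutoff on the
  control-condition ±1 kb flank signal.
* **Peak-centered profiling.** Metagene profiles and 10 kb read-density
  heatmap matrices (rows ordered by decreasing Gaussian-weighted ATAC
  signal within class blocks), per-locus normalized MNase metagenes
  (each locus scaled by its own ±1 kb total, smoothed with a moving
  average of N = 5 bins), and per-class enrichment contrasts with
  Mann–Whitney tests.
* **Nucleosome dynamics.** Quantitative scores for the three MNase
  phenomena: central-nucleosome **eviction**
  (O<sub>ctrl</sub> − O<sub>treat</sub>)/O<sub>ctrl</sub> over ±90 bp,
  flanking-array **phasing** (peak autocorrelation at 150–220 bp lags),
  and array **sliding** (cross-correlation argmax, bounded at ±150 bp),
  plus a thermal-stability contrast of TF ChIP signal (37 °C vs. ice)
  that singles out nucleosome-embedded binding.
* **Synthetic chromatin.** A seeded simulator plants the four
  architectures (eviction with phased flanks, NDR, sliding array,
  closing locus) on a synthetic genome, emits ATAC/MNase/ChIP fragment
  libraries with known ground truth, and backs every end-to-end test.

Genomic inputs are plain text: BED peaks/TSS/reads, BEDPE fragment
pairs, chrom.sizes; outputs are deterministic TSVs plus bedGraph tracks.
Coordinates are 0-based half-open throughout.

## Worked example

A complete round trip on a small synthetic dataset — simulate, classify,
quantify nucleosome dynamics:

```r
library(chromdissect)

cfg <- simulation_config(genome_length = 5e5, n_peaks_per_class = 25,
                         depth_atac = 56000, depth_mnase = 2e5,
                         norm_target = 5600)
dir <- file.path(tempdir(), "demo")
files <- run_simulate(dir, cfg, seed = 7, chip = FALSE)

params <- chrom_params(normalization_target = cfg$norm_target)
cl <- run_classify(files[["peaks"]], files[["atac_control"]],
                   files[["atac_treated"]], files[["chrom_sizes"]],
                   file.path(dir, "out"), params = params,
                   tss_file = files[["tss"]])
print(cl)
#> peak_classes: 100 peaks
#>   G1:     25 ( 25.0%)
#>   G2:     25 ( 25.0%)
#>   G3:     25 ( 25.0%)
#>   G4:     25 ( 25.0%)

res <- run_dynamics(file.path(dir, "out", "classification.tsv"),
                    files[["peaks"]], files[["chrom_sizes"]],
                    files[["mnase_control"]], files[["mnase_treated"]],
                    file.path(dir, "out"), params = params)
print(res$dynamics)
#>   class n_peaks eviction_score phasing_control phasing_treated slide_bp
#> 1    G1      25     0.78422496       0.7276804       0.7429884      150
#> 2    G2      25    -0.13232631       0.7423470       0.7232523        0
#> 3    G3      25     0.04632726       0.7339801       0.7779145       50
#> 4    G4      25    -3.64824643       0.7132707       0.7127789     -150
```

Reading the output: all 100 planted peaks recover their class (the four
25% blocks). The G1 eviction score of 0.78 reflects the planted eviction
fraction of 0.8 (a ~0.02 downward bias comes from the uniform background
in the score's ratio — see the vignette); G3 shows essentially no
eviction (0.05) but its nucleosome array is detected as slid by exactly
the planted 50 bp. Phasing scores near 0.73 indicate strong 190 bp
periodicity of the flanking arrays in every class; the slide value for
G1/G4 is not meaningful (the architecture changes rather than
translates; eviction is the statistic there).

A thin command-line wrapper over the same stages ships in
`inst/scripts/chromdissect.R`
(`simulate` / `classify` / `profile` / `dynamics` / `report`).

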