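#!/usr/bin/env Rscript
# Stage 3 — runs of homozygosity and FROH decomposition.
#
# For each species: low-het threshold at one-fifth of the genome-wide mean,
# ROH = >= 10 adjacent 50-kb windows (>= 500 kb) below threshold with
# per-window missingness <= 0.7; FROH decomposed into [0.5,1), [1,2), [2,5),
# [5,Inf) Mb length classes. Writes ROH BEDs and a FROH table, and compares
# recovered FROH with the planted truth.

suppressPackageStartupMessages({library(divscan); library(data.table)})

win_dir <- "results/windows"
cohort_dir <- "results/cohort"
out <- "results/roh"
wfiles <- list.files(win_dir, pattern = "^windows_.*\\.tsv$", full.names = TRUE)
if (!length(wfiles)) stop("no window tables in ", win_dir,
                          " - run analysis/02_diversity_windows.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

index <- read_genome_index(file.path(cohort_dir, "index.tsv"))
truth <- read_truth(file.path(cohort_dir, "truth.json"))

rows <- list()
for (f in wfiles) {
  sp <- sub("^windows_(.*)\\.tsv$", "\\1", basename(f))
  hw <- fread(f)
  thr <- roh_threshold(genome_mean_het(hw))
  segs <- call_roh(hw, thr)
  write_bed(segs, file.path(out, sprintf("roh_%s.bed", sp)))
  fr <- froh(segs, index)
  planted <- truth$expected_froh[[sp]]
  rows[[sp]] <- data.table(
    species = sp, n_segments = nrow(segs), froh_total = fr$froh_total,
    planted_froh = planted, abs_error = abs(fr$froh_total - planted),
    t(fr$froh_by_class))
  cat(sprintf("%s: %2d ROH, FROH %.4f (planted %.4f) by class: %s\n",
              sp, nrow(segs), fr$froh_total, planted,
              paste(sprintf("%s=%.3f", names(fr$froh_by_class), fr$froh_by_class),
                    collapse = " ")))
}
fwrite(rbindlist(rows), file.path(out, "froh.tsv"), sep = "\t")
jsonlite::write_json(lapply(rows, as.list), file.path(out, "froh.json"),
                     auto_unbox = TRUE, digits = NA)
write_sidecar(file.path(out, "roh_meta.json"),
              list(stage = "roh", het_threshold_fraction = 0.2,
                   min_windows = 10, min_length = 500000, max_missing_prop = 0.7))
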