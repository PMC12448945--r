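#!/usr/bin/env Rscript
# Stage 5 — joint diversity/divergence hotspot calling and cross-species
# consensus.
#
# A 50-kb window is flagged when normalized heterozygosity exceeds 4 AND an
# overlapping unmasked 10-kb window has normalized distance above 2; flagged
# windows merge within 100 kb into per-species regions; windows flagged in
# all species form the consensus. Compares the consensus against the planted
# hotspot intervals (Jaccard).

suppressPackageStartupMessages({library(divscan); library(data.table)})

win_dir <- "results/windows"
div_dir <- "results/divergence"
cohort_dir <- "results/cohort"
out <- "results/hotspots"
wfiles <- list.files(win_dir, pattern = "^windows_.*\\.tsv$", full.names = TRUE)
dfiles <- list.files(div_dir, pattern = "^distance_.*\\.tsv$", full.names = TRUE)
if (!length(wfiles)) stop("missing window tables - run stage 02 first")
if (!length(dfiles)) stop("missing divergence tables - run stage 04 first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

divs <- setNames(lapply(dfiles, fread),
                 sub("^distance_.*_(.*)\\.tsv$", "\\1", basename(dfiles)))
flagged <- list()
for (f in wfiles) {
  sp <- sub("^windows_(.*)\\.tsv$", "\\1", basename(f))
  hw <- fread(f)
  dw <- if (sp %in% names(divs)) divs[[sp]] else divs[[1]]  # reference species
  fl <- flag_windows(hw, dw, het_fold = 4, dist_fold = 2)
  flagged[[sp]] <- fl
  reg <- merge_flagged(fl, merge_gap = 100000)
  write_bed(fl[fl$flagged, c("chrom", "start", "end")],
            file.path(out, sprintf("flagged_%s.bed", sp)))
  cat(sprintf("%s: %d flagged windows -> %d regions on chromosomes %s\n",
              sp, sum(fl$flagged), nrow(reg),
              paste(unique(reg$chrom), collapse = ", ")))
}

cons <- consensus_hotspots(flagged, min_species = length(flagged), merge_gap = 100000)
write_bed(cons, file.path(out, "consensus_hotspots.bed"))
write_sidecar(file.path(out, "hotspots_meta.json"),
              list(stage = "hotspots", het_fold = 4, dist_fold = 2,
                   merge_gap = 100000, min_species = length(flagged)))

truth <- read_truth(file.path(cohort_dir, "truth.json"))
cat(sprintf("consensus: %d regions on chromosomes %s (planted: %s)\n",
            nrow(cons), paste(cons$chrom, collapse = ", "),
            paste(truth$hotspots$chrom, collapse = ", ")))
for (i in seq_len(nrow(cons))) {
  planted <- truth$hotspots[truth$hotspots$chrom == cons$chrom[i],
                            c("chrom", "start", "end")]
  cat(sprintf("  chr %s [%d,%d) Jaccard vs planted = %.3f\n", cons$chrom[i],
              cons$start[i], cons$end[i],
              iv_jaccard(cons[i, c("chrom", "start", "end")], planted)))
}
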