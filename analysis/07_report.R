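#!/usr/bin/env Rscript
# Stage 7 — aggregate report bundle.
#
# Collects the per-chromosome summaries, FROH decomposition, consensus
# hotspots and enrichment results into one results/report/ bundle with the
# three macro/micro contrasts, mirroring the headline analyses.

suppressPackageStartupMessages({library(divscan); library(data.table)})

need <- c(windows = "results/windows/chromosome_summary.tsv",
          froh = "results/roh/froh.tsv",
          hotspots = "results/hotspots/consensus_hotspots.bed",
          enrichment = "results/enrichment/enrichment.tsv")
missing <- need[!file.exists(need)]
if (length(missing)) stop("missing upstream outputs: ",
                          paste(missing, collapse = ", "))
out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

summary_dt <- fread(need["windows"])
froh_dt <- fread(need["froh"])
cons <- read_bed(need["hotspots"])
enr <- fread(need["enrichment"])

# distance means per chromosome from the first pair table
dfiles <- list.files("results/divergence", pattern = "^distance_.*\\.tsv$",
                     full.names = TRUE)
dist_cm <- suppressWarnings(chromosome_mean_distance(fread(dfiles[1])))
gd <- fread("results/enrichment/gene_density.tsv")

ref <- summary_dt[species == sort(unique(species))[1]]
ref <- merge(ref, dist_cm, by = "chrom", all.x = TRUE)
ref <- merge(ref, gd, by = "chrom")
fwrite(ref[, .(chrom, length, size_class, mean_het, mean_distance, gene_density)],
       file.path(out, "chromosome_report.tsv"), sep = "\t")
fwrite(froh_dt, file.path(out, "froh_report.tsv"), sep = "\t")
fwrite(enr, file.path(out, "enrichment_report.tsv"), sep = "\t")

contrasts <- list(
  het = compare_macro_micro(ref$mean_het, ref$size_class),
  gene_density = compare_macro_micro(ref$gene_density, ref$size_class),
  distance = compare_macro_micro(ref$mean_distance[!is.na(ref$mean_distance)],
                                 ref$size_class[!is.na(ref$mean_distance)])
)
jsonlite::write_json(list(
  n_consensus_hotspots = nrow(cons),
  consensus_chromosomes = cons$chrom,
  contrasts = lapply(contrasts, function(x)
    list(p_value = x$p_value, direction = x$direction)),
  froh = setNames(as.list(froh_dt$froh_total), froh_dt$species)
), file.path(out, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("report bundle written to", out, "\n")
cat(sprintf("  consensus hotspots: %d (%s)\n", nrow(cons),
            paste(cons$chrom, collapse = ", ")))
for (nm in names(contrasts)) {
  cat(sprintf("  macro/micro %s: direction %+d, p = %.2e\n", nm,
              contrasts[[nm]]$direction, contrasts[[nm]]$p_value))
}
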