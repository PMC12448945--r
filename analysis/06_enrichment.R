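#!/usr/bin/env Rscript
# Stage 6 — gene density and multicopy family enrichment in the consensus
# hotspots.
#
# Reads the gene annotation, classifies genes into multicopy families from
# their functional-term strings (precedence MHC > OR > GPCR > ZNF > IMMUNE),
# computes genes/Mb per chromosome, and tests each family for enrichment
# inside the consensus regions with a one-sided Fisher exact test and
# Benjamini-Hochberg correction across the family set.

suppressPackageStartupMessages({library(divscan); library(data.table)})

cohort_dir <- "results/cohort"
hot_dir <- "results/hotspots"
out <- "results/enrichment"
cons_bed <- file.path(hot_dir, "consensus_hotspots.bed")
if (!file.exists(cons_bed)) stop("missing ", cons_bed, " - run stage 05 first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

index <- read_genome_index(file.path(cohort_dir, "index.tsv"))
genes <- classify_genes(read_genes(file.path(cohort_dir, "genes.gff3")))
cons <- read_bed(cons_bed)

gd <- gene_density(genes, index)
fwrite(gd$per_chromosome, file.path(out, "gene_density.tsv"), sep = "\t")
cls <- classify_chromosomes(index, macro_threshold = 1e6)
j <- merge(cls, gd$per_chromosome, by = "chrom")
ct <- compare_macro_micro(j$gene_density, j$size_class)
cat(sprintf("gene density: macro/micro direction %+d, p = %.2e\n",
            ct$direction, ct$p_value))

enr <- fisher_enrichment(genes, cons)
fwrite(enr, file.path(out, "enrichment.tsv"), sep = "\t")
write_sidecar(file.path(out, "enrichment_meta.json"),
              list(stage = "enrich", scope = "genome", alternative = "greater"))
cat("family enrichment in consensus hotspots:\n")
for (i in seq_len(nrow(enr))) {
  cat(sprintf("  %-7s a=%3d b=%3d c=%3d d=%4d OR=%6.2f p=%.3e q=%.3e\n",
              enr$family[i], enr$a[i], enr$b[i], enr$c[i], enr$d[i],
              enr$odds_ratio[i], enr$p_value[i], enr$q_value[i]))
}
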