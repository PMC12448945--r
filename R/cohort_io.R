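#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits: `index.tsv` (chrom, length), `mask.bed`, one
#' `sites_<species>.tsv` per species, per pair
#' `track_<ref>_<sp>_variants.tsv` (chrom, pos) and
#' `track_<ref>_<sp>_aligned.bed`, `genes.gff3`, `truth.json`,
#' `config.yaml`, and a `cohort_meta.json` sidecar recording the package
#' version and seed. Outputs are byte-identical for identical
#' (config, seed).
#'
#' @param cohort from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cohort_write <- function(cohort, dir) {
  stopifnot(inherits(cohort, "divscan_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(cohort$index, file.path(dir, "index.tsv"), sep = "\t",
         col.names = FALSE, quote = FALSE)
  write_bed(cohort$mask, file.path(dir, "mask.bed"))
  for (sp in names(cohort$sites)) {
    write_sites(cohort$sites[[sp]], file.path(dir, sprintf("sites_%s.tsv", sp)))
  }
  ref <- cohort$config$species[1]
  for (sp in names(cohort$tracks)) {
    tr <- cohort$tracks[[sp]]
    fwrite(tr$variants, file.path(dir, sprintf("track_%s_%s_variants.tsv", ref, sp)),
           sep = "\t", quote = FALSE)
    write_bed(tr$aligned, file.path(dir, sprintf("track_%s_%s_aligned.bed", ref, sp)))
  }
  write_gff3(cohort$genes, file.path(dir, "genes.gff3"))
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  cfg <- cohort$config
  yaml::write_yaml(list(
    species = cfg$species,
    chromosomes = list(chrom = cfg$index$chrom, length = cfg$index$length),
    macro_threshold = cfg$macro_threshold, baseline_het = cfg$baseline_het,
    micro_het_multiplier = cfg$micro_het_multiplier,
    missing_rate = cfg$missing_rate,
    baseline_divergence = cfg$baseline_divergence,
    aligned_fraction = cfg$aligned_fraction, seed = cfg$seed
  ), file.path(dir, "config.yaml"))
  write_sidecar(file.path(dir, "cohort_meta.json"),
                list(stage = "simulate", seed = cfg$seed,
                     species = cfg$species))
  invisible(dir)
}

#' Write a run-parameter sidecar
#'
#' Every stage output gets a JSON sidecar naming the tool version, the
#' stage, and the parameters that produced it, so a run is reconstructible
#' from sidecars plus inputs.
#'
#' @param path sidecar path.
#' @param params named list of stage parameters.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(path, params) {
  meta <- c(list(tool = "divscan",
                 version = as.character(utils::packageVersion("divscan"))),
            params)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write gene records as GFF3
#'
#' One gene line per record with a `note` attribute carrying the functional
#' terms; a subset of genes (every tenth) additionally gets two mRNA
#' isoform children of different span so longest-isoform reduction is
#' exercised on re-read (the longest isoform always equals the gene span).
#'
#' @param genes gene table (gene_id, chrom, start, end, terms).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  g <- as.data.table(genes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    terms <- paste(unlist(g$terms[[i]]), collapse = " | ")
    gid <- g$gene_id[i]
    s1 <- g$start[i] + 1  # GFF3 is 1-based inclusive
    e1 <- g$end[i]
    writeLines(sprintf("%s\tdivscan\tgene\t%d\t%d\t.\t+\t.\tID=%s;note=%s",
                       g$chrom[i], s1, e1, gid, terms), con)
    writeLines(sprintf("%s\tdivscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                       g$chrom[i], s1, e1, gid, gid), con)
    if (i %% 10L == 0L && e1 - s1 > 1000) {
      writeLines(sprintf("%s\tdivscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t2;Parent=%s",
                         g$chrom[i], s1, e1 - 500, gid, gid), con)
    }
  }
  invisible(path)
}

#' Write / read the ground-truth ledger
#'
#' Plain JSON, full precision, so the ledger round-trips losslessly.
#'
#' @param truth ledger list from [simulate_cohort()].
#' @param path JSON path.
#' @return `path` invisibly / the ledger list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$hotspots <- as.data.frame(raw$hotspots)
  raw$expected_chrom_het <- as.data.frame(raw$expected_chrom_het)
  raw$roh <- lapply(raw$roh, as.data.frame)
  raw$family_counts <- as.data.frame(raw$family_counts)
  raw
}

#' Read a pairwise divergence track written by [cohort_write()]
#'
#' @param variants_path 2-column TSV (chrom, pos).
#' @param aligned_path BED3 of aligned intervals.
#' @param species_a,species_b species names (a = reference frame).
#' @return a [divergence_track()].
#' @export
read_track <- function(variants_path, aligned_path,
                       species_a = "ref", species_b = "qry") {
  v <- fread(variants_path, header = TRUE, sep = "\t")
  if (!all(c("chrom", "pos") %in% names(v))) {
    setnames(v, seq_len(2), c("chrom", "pos"))
  }
  divergence_track(species_a, species_b, v, read_bed(aligned_path))
}

#' Jaccard overlap between two interval sets
#' @param a,b interval sets.
#' @return overlap bp / union bp (0 when both empty).
#' @export
iv_jaccard <- function(a, b) {
  inter <- iv_overlap_bp(a, b)
  uni <- iv_total_bp(a) + iv_total_bp(b) - inter
  if (uni == 0) 0 else inter / uni
}
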