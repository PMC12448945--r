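#' Run the full diversity/divergence hotspot scan on a cohort
#'
#' One-call driver over the stage functions: per-species QC filtering and
#' repeat masking, 50-kb heterozygosity windows with chromosome
#' normalization, ROH calling and FROH decomposition, 10-kb divergence
#' windows per pairwise track, joint hotspot flagging, cross-species
#' consensus, gene density, family enrichment against the consensus
#' regions, and macro/micro contrasts for heterozygosity, gene density and
#' genetic distance.
#'
#' For hotspot flagging each non-reference species uses its own
#' (reference, species) track; the reference species, which has no track
#' against itself, uses the first track in the cohort.
#'
#' @param cohort from [simulate_cohort()] (or an equivalently shaped list
#'   read from files).
#' @param window_size heterozygosity window bp (default 50 kb).
#' @param div_window_size divergence window bp (default 10 kb).
#' @param het_fold,dist_fold hotspot fold thresholds (defaults 4 and 2).
#' @param merge_gap hotspot merge gap bp (default 100 kb).
#' @param min_species consensus vote threshold (default all species).
#' @param roh_fraction low-het threshold as a fraction of the genome mean
#'   (default 1/5).
#' @param min_roh_windows,min_roh_length,max_missing_prop ROH rule
#'   parameters (defaults 10 windows, 500 kb, 0.7).
#' @param apply_filters run [filter_sites()] / [apply_mask()] before
#'   windowing (default TRUE).
#' @return list with per-species window tables (`het_windows`), chromosome
#'   summaries (`chrom_summary`), `genome_mean_het`, `roh`, `froh`,
#'   divergence windows (`div_windows`), flagged windows (`flagged`),
#'   per-species regions (`regions`), `consensus`, `gene_density`,
#'   `enrichment`, `contrasts`, and the `params` used.
#' @export
analyze_cohort <- function(cohort,
                           window_size = 50000, div_window_size = 10000,
                           het_fold = 4, dist_fold = 2, merge_gap = 100000,
                           min_species = length(cohort$sites),
                           roh_fraction = 1/5, min_roh_windows = 10,
                           min_roh_length = 500000, max_missing_prop = 0.7,
                           apply_filters = TRUE) {
  index <- cohort$index
  check_index(index)
  macro_threshold <- if (!is.null(cohort$config$macro_threshold)) {
    cohort$config$macro_threshold
  } else 50e6
  mean_depth <- if (!is.null(cohort$config$mean_depth)) {
    cohort$config$mean_depth
  } else NULL
  chrom_class <- classify_chromosomes(index, macro_threshold)
  windows <- make_windows(index, size = window_size)
  species <- names(cohort$sites)

  het_windows <- list(); rohs <- list(); frohs <- list()
  gmeans <- setNames(numeric(length(species)), species)
  for (sp in species) {
    sites <- cohort$sites[[sp]]
    if (apply_filters) {
      sites <- filter_sites(sites, mean_depth = mean_depth)
      sites <- apply_mask(sites, cohort$mask)
    }
    hw <- window_heterozygosity(sites, windows, absent = "hom_ref")
    hw <- normalize_windows(hw)
    het_windows[[sp]] <- hw
    gmeans[sp] <- genome_mean_het(hw)
    thr <- roh_threshold(gmeans[sp], roh_fraction)
    rohs[[sp]] <- call_roh(hw, thr, min_windows = min_roh_windows,
                           min_length = min_roh_length,
                           max_missing_prop = max_missing_prop)
    frohs[[sp]] <- froh(rohs[[sp]], index)
  }

  div_windows <- list()
  for (sp in names(cohort$tracks)) {
    dw <- window_distance(cohort$tracks[[sp]], index, size = div_window_size)
    div_windows[[sp]] <- normalize_distance(dw)
  }

  track_for <- function(sp) {
    if (sp %in% names(div_windows)) div_windows[[sp]] else div_windows[[1]]
  }
  flagged <- setNames(lapply(species, function(sp) {
    flag_windows(het_windows[[sp]], track_for(sp),
                 het_fold = het_fold, dist_fold = dist_fold)
  }), species)
  regions <- lapply(flagged, merge_flagged, merge_gap = merge_gap)
  consensus <- consensus_hotspots(flagged, min_species = min_species,
                                  merge_gap = merge_gap)

  genes <- classify_genes(cohort$genes)
  gd <- gene_density(genes, index)
  enrichment <- if (nrow(consensus)) {
    fisher_enrichment(genes, consensus[, .(chrom, start, end)])
  } else NULL

  # per-chromosome summaries and macro/micro contrasts
  summaries <- rbindlist(lapply(species, function(sp) {
    cm <- chromosome_mean_het(het_windows[[sp]])
    s <- merge(chrom_class, cm, by = "chrom", sort = FALSE)
    s[, species := sp]
    s
  }))
  dist_means <- rbindlist(lapply(names(div_windows), function(sp) {
    dm <- suppressWarnings(chromosome_mean_distance(div_windows[[sp]]))
    dm[, species := sp]
    dm
  }))
  summaries <- merge(summaries, dist_means, by = c("chrom", "species"),
                     all.x = TRUE, sort = FALSE)
  summaries <- merge(summaries, gd$per_chromosome[, .(chrom, gene_density)],
                     by = "chrom", sort = FALSE)

  ref <- species[1]
  s_ref <- summaries[species == ref]
  contrasts <- list(
    het = compare_macro_micro(s_ref$mean_het, s_ref$size_class),
    gene_density = compare_macro_micro(s_ref$gene_density, s_ref$size_class),
    distance = if (nrow(dist_means)) {
      s1 <- summaries[species == names(div_windows)[1] & !is.na(mean_distance)]
      compare_macro_micro(s1$mean_distance, s1$size_class)
    } else NULL
  )

  list(het_windows = het_windows, chrom_summary = summaries,
       genome_mean_het = gmeans, roh = rohs, froh = frohs,
       div_windows = div_windows, flagged = flagged, regions = regions,
       consensus = consensus, gene_density = gd, enrichment = enrichment,
       contrasts = contrasts,
       params = list(window_size = window_size,
                     div_window_size = div_window_size, het_fold = het_fold,
                     dist_fold = dist_fold, merge_gap = merge_gap,
                     min_species = min_species, roh_fraction = roh_fraction,
                     min_roh_windows = min_roh_windows,
                     min_roh_length = min_roh_length,
                     max_missing_prop = max_missing_prop,
                     macro_threshold = macro_threshold))
}
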