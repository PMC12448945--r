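#' Build and validate a cohort simulation configuration
#'
#' Defines the statistical structure of a synthetic multi-species cohort on
#' one shared coordinate frame: per-bp baseline heterozygosity with a
#' microchromosome multiplier, planted hotspot intervals that elevate both
#' heterozygosity and interspecific variant density, planted ROH tracts per
#' species with a within-tract het factor, independent per-site missingness,
#' pairwise alignment coverage, a repeat mask, and gene annotations whose
#' clustered family concentrates in hotspots.
#'
#' @param species character vector of species names; the first is the
#'   reference coordinate frame.
#' @param chromosomes data.frame: chrom, length (bp).
#' @param macro_threshold bp cutoff separating macro/microchromosomes in
#'   this cohort's frame.
#' @param baseline_het per-bp heterozygous-site probability on
#'   macrochromosomes.
#' @param micro_het_multiplier het multiplier on microchromosomes.
#' @param hotspots data.frame: chrom, start, end, het_multiplier,
#'   dist_multiplier, shared (logical; unshared hotspots apply to the
#'   reference species only).
#' @param roh named list (species -> data.frame chrom, start, end) of
#'   planted ROH tracts.
#' @param roh_het_factor within-ROH het multiplier (default 1/50).
#' @param missing_rate independent per-site missing probability.
#' @param hom_alt_rate per-bp homozygous-alternate (fixed difference)
#'   probability.
#' @param mask data.frame chrom, start, end: repeat-mask intervals emitted
#'   with the cohort.
#' @param baseline_divergence per-bp interspecific variant probability per
#'   pair on macrochromosomes.
#' @param micro_dist_multiplier divergence multiplier on microchromosomes.
#' @param aligned_fraction fraction of each 10-kb unit covered by the
#'   alignment.
#' @param low_coverage_rate fraction of 10-kb units dropped to
#'   `low_coverage_fraction` alignment coverage.
#' @param low_coverage_fraction coverage of low-coverage units.
#' @param gene_density_macro,gene_density_micro genes per Mb by chromosome
#'   class.
#' @param family_sizes named integer vector of multicopy family sizes
#'   (families beyond these counts are "OTHER").
#' @param clustered_family family whose genes are placed with
#'   `cluster_weight`-fold per-bp density inside hotspots.
#' @param cluster_weight hotspot placement weight for the clustered family.
#' @param gene_length_range min/max simulated gene span (bp).
#' @param mean_depth mean simulated read depth (Poisson).
#' @param seed integer RNG seed; identical (config, seed) gives
#'   byte-identical outputs.
#' @return validated list of class "sim_config".
#' @export
sim_config <- function(species, chromosomes, macro_threshold,
                       baseline_het = 1e-3, micro_het_multiplier = 1,
                       hotspots = NULL, roh = list(), roh_het_factor = 1/50,
                       missing_rate = 0.05, hom_alt_rate = 1e-3, mask = NULL,
                       baseline_divergence = 2e-3, micro_dist_multiplier = 1,
                       aligned_fraction = 0.9, low_coverage_rate = 0.02,
                       low_coverage_fraction = 0.3,
                       gene_density_macro = 35, gene_density_micro = 70,
                       family_sizes = c(MHC = 20, OR = 300, GPCR = 90,
                                        ZNF = 80, IMMUNE = 60),
                       clustered_family = "OR", cluster_weight = 10,
                       gene_length_range = c(2000, 15000),
                       mean_depth = 30, seed = 1234) {
  index <- genome_index(chromosomes$chrom, chromosomes$length)
  stopifnot(length(species) >= 1, !anyDuplicated(species))
  rates <- c(baseline_het, missing_rate, hom_alt_rate, baseline_divergence,
             aligned_fraction, low_coverage_rate, low_coverage_fraction)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  mult <- c(micro_het_multiplier, roh_het_factor, micro_dist_multiplier,
            cluster_weight)
  if (any(mult <= 0)) stop("multipliers must be positive")

  check_intervals <- function(iv, what) {
    if (is.null(iv) || nrow(as.data.table(iv)) == 0L) return(interval_set(NULL))
    iv <- as.data.table(iv)
    lens <- setNames(index$length, index$chrom)
    if (!all(iv$chrom %in% index$chrom)) stop(what, " on unknown chromosome")
    if (any(iv$start < 0) || any(iv$end > lens[iv$chrom]) || any(iv$end <= iv$start)) {
      stop(what, " interval outside chromosome bounds")
    }
    iv
  }
  hotspots <- if (is.null(hotspots)) {
    data.table(chrom = character(), start = numeric(), end = numeric(),
               het_multiplier = numeric(), dist_multiplier = numeric(),
               shared = logical())
  } else as.data.table(check_intervals(hotspots, "hotspot"))
  roh <- lapply(roh, check_intervals, what = "ROH")
  if (length(roh) && !all(names(roh) %in% species)) stop("ROH plan for unknown species")
  mask <- interval_set(check_intervals(mask, "mask"))

  structure(list(
    species = species, index = index, macro_threshold = macro_threshold,
    baseline_het = baseline_het, micro_het_multiplier = micro_het_multiplier,
    hotspots = hotspots, roh = roh, roh_het_factor = roh_het_factor,
    missing_rate = missing_rate, hom_alt_rate = hom_alt_rate, mask = mask,
    baseline_divergence = baseline_divergence,
    micro_dist_multiplier = micro_dist_multiplier,
    aligned_fraction = aligned_fraction,
    low_coverage_rate = low_coverage_rate,
    low_coverage_fraction = low_coverage_fraction,
    gene_density_macro = gene_density_macro,
    gene_density_micro = gene_density_micro,
    family_sizes = family_sizes, clustered_family = clustered_family,
    cluster_weight = cluster_weight, gene_length_range = gene_length_range,
    mean_depth = mean_depth, seed = seed
  ), class = "sim_config")
}

#' Desk-scale default cohort configuration
#'
#' A scaled stand-in for a 7-species sea-turtle-like cohort on a 28-chromosome
#' frame: 11 macrochromosomes of 2 Mb and 17 microchromosomes of 0.5 Mb
#' (macro threshold 1 Mb; total 30.5 Mb), microchromosome het multiplier 3,
#' shared hotspots planted on chromosomes "13", "14" and "24" (one 50-kb
#' window each, het multiplier 8, distance multiplier 3), one species
#' ("sp02") with high planted FROH (0.228, tracts spanning all length
#' classes reachable at this scale) and one ("sp07") with near-zero FROH
#' (one minimum-length tract, 0.016).
#'
#' @param seed RNG seed (default 1234).
#' @return a [sim_config()].
#' @export
scaled_default_config <- function(seed = 1234) {
  chroms <- data.table(
    chrom = as.character(1:28),
    length = c(rep(2e6, 11), rep(5e5, 17))
  )
  hot <- data.table(
    chrom = c("13", "14", "24"),
    start = 200000, end = 250000,
    het_multiplier = 8, dist_multiplier = 3, shared = TRUE
  )
  roh <- list(
    sp02 = data.table(
      chrom = as.character(1:6),
      start = c(0,  4e5, 2e5, 1e5, 1e5, 5e5),
      end   = c(6e5, 13e5, 14e5, 16e5, 19e5, 145e4)
    ),
    sp07 = data.table(chrom = "7", start = 5e5, end = 1e6)
  )
  mask <- data.table(chrom = as.character(1:28), start = 10000, end = 20000)
  sim_config(
    species = sprintf("sp%02d", 1:7),
    chromosomes = chroms, macro_threshold = 1e6,
    baseline_het = 1e-3, micro_het_multiplier = 3,
    hotspots = hot, roh = roh, mask = mask,
    micro_dist_multiplier = 2,
    seed = seed
  )
}

# per-chromosome stratified segments with per-bp het prob for one species
.het_segments <- function(config, sp) {
  idx <- config$index
  micro <- idx$length <= config$macro_threshold
  base <- config$baseline_het * ifelse(micro, config$micro_het_multiplier, 1)
  roh_sp <- config$roh[[sp]]
  rbindlist(lapply(seq_len(nrow(idx)), function(ci) {
    ch <- idx$chrom[ci]
    L <- idx$length[ci]
    hs <- config$hotspots[chrom == ch &
                            (shared | sp == config$species[1])]
    rs <- if (!is.null(roh_sp)) as.data.table(roh_sp)[chrom == ch] else NULL
    cuts <- sort(unique(c(0, L, hs$start, hs$end,
                          if (!is.null(rs)) c(rs$start, rs$end))))
    seg <- data.table(chrom = ch, start = head(cuts, -1), end = tail(cuts, -1))
    seg[, p := base[ci]]
    for (i in seq_len(nrow(hs))) {
      seg[start >= hs$start[i] & end <= hs$end[i], p := p * hs$het_multiplier[i]]
    }
    if (!is.null(rs)) for (i in seq_len(nrow(rs))) {
      seg[start >= rs$start[i] & end <= rs$end[i], p := p * config$roh_het_factor]
    }
    seg
  }))
}

# draw positions: n sites uniform without replacement in [start, end) -> 1-based
.draw_pos <- function(start, end, n) {
  if (n == 0L) return(numeric(0))
  start + sample.int(end - start, n)
}

.simulate_sites_one <- function(config, sp) {
  seg <- .het_segments(config, sp)
  m <- config$missing_rate
  q <- config$hom_alt_rate
  parts <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    L <- seg$end[i] - seg$start[i]
    n_mis <- rbinom(1L, L, m)
    n_het <- rbinom(1L, L, seg$p[i])
    n_alt <- rbinom(1L, L, q)
    pos_mis <- .draw_pos(seg$start[i], seg$end[i], n_mis)
    pos_het <- .draw_pos(seg$start[i], seg$end[i], n_het)
    pos_alt <- .draw_pos(seg$start[i], seg$end[i], n_alt)
    pos_het <- setdiff(pos_het, pos_mis)
    pos_alt <- setdiff(pos_alt, c(pos_mis, pos_het))
    n <- length(pos_mis) + length(pos_het) + length(pos_alt)
    if (n == 0L) next
    parts[[i]] <- data.table(
      chrom = seg$chrom[i],
      pos = c(pos_mis, pos_het, pos_alt),
      gt = rep(c(NA_integer_, 1L, 2L),
               c(length(pos_mis), length(pos_het), length(pos_alt)))
    )
  }
  sites <- rbindlist(parts)
  if (nrow(sites) == 0L) {
    sites <- data.table(chrom = character(), pos = numeric(), gt = integer())
  }
  sites[, depth := rpois(.N, config$mean_depth)]
  sites[, mq := 60]
  sites[, biallelic := TRUE]
  sites[, chrom := factor(chrom, levels = config$index$chrom)]
  setorder(sites, chrom, pos)
  sites[, chrom := as.character(chrom)]
  sites[]
}

.simulate_track_one <- function(config, sp) {
  idx <- config$index
  micro <- idx$length <= config$macro_threshold
  unit <- 10000
  aligned_parts <- vector("list", nrow(idx))
  var_parts <- vector("list", nrow(idx))
  for (ci in seq_len(nrow(idx))) {
    ch <- idx$chrom[ci]
    L <- idx$length[ci]
    u0 <- seq(0, L - 1, by = unit)
    u1 <- pmin(u0 + unit, L)
    ulen <- u1 - u0
    frac <- ifelse(runif(length(u0)) < config$low_coverage_rate,
                   config$low_coverage_fraction, config$aligned_fraction)
    alen <- pmax(1, round(ulen * frac))
    off <- floor(runif(length(u0)) * (ulen - alen + 1))
    a0 <- u0 + off
    a1 <- a0 + alen
    aligned_parts[[ci]] <- data.table(chrom = ch, start = a0, end = a1)

    # split aligned pieces at hotspot bounds, apply per-piece variant rate
    p_base <- config$baseline_divergence *
      if (micro[ci]) config$micro_dist_multiplier else 1
    hs <- config$hotspots[chrom == ch]
    cuts <- sort(unique(c(hs$start, hs$end)))
    pieces <- data.table(start = a0, end = a1)
    for (cut in cuts) {
      hitl <- pieces$start < cut & pieces$end > cut
      if (any(hitl)) {
        pieces <- rbind(pieces[!hitl],
                        pieces[hitl, .(start, end = cut)],
                        pieces[hitl, .(start = cut, end)])
      }
    }
    pieces[, p := p_base]
    for (i in seq_len(nrow(hs))) {
      pieces[start >= hs$start[i] & end <= hs$end[i],
             p := p * hs$dist_multiplier[i]]
    }
    n <- rbinom(nrow(pieces), pieces$end - pieces$start, pieces$p)
    keep <- which(n > 0L)
    if (length(keep)) {
      var_parts[[ci]] <- data.table(
        chrom = ch,
        pos = unlist(lapply(keep, function(k)
          .draw_pos(pieces$start[k], pieces$end[k], n[k])))
      )
    }
  }
  variants <- rbindlist(var_parts)
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- data.table(chrom = character(), pos = numeric())
  }
  divergence_track(config$species[1], sp, variants,
                   interval_set(rbindlist(aligned_parts)))
}

.simulate_genes <- function(config) {
  idx <- config$index
  micro <- idx$length <= config$macro_threshold
  dens <- ifelse(micro, config$gene_density_micro, config$gene_density_macro)
  n_total <- round(sum(dens * idx$length / 1e6))
  fam_sizes <- config$family_sizes
  n_other <- n_total - sum(fam_sizes)
  if (n_other < 0) stop("family sizes exceed total gene budget")
  fam_of <- rep(c(names(fam_sizes), "OTHER"), c(fam_sizes, n_other))

  # placement strata: per-bp weight = class density, x cluster_weight inside
  # hotspots for the clustered family
  strata <- rbindlist(lapply(seq_len(nrow(idx)), function(ci) {
    ch <- idx$chrom[ci]
    L <- idx$length[ci]
    hs <- config$hotspots[chrom == ch]
    cuts <- sort(unique(c(0, L, hs$start, hs$end)))
    seg <- data.table(chrom = ch, start = head(cuts, -1), end = tail(cuts, -1))
    seg[, w := dens[ci]]
    seg[, hot := FALSE]
    for (i in seq_len(nrow(hs))) {
      seg[start >= hs$start[i] & end <= hs$end[i], hot := TRUE]
    }
    seg
  }))
  w_bg <- strata$w * (strata$end - strata$start)
  w_cl <- strata$w * ifelse(strata$hot, config$cluster_weight, 1) *
    (strata$end - strata$start)

  term_pool <- list(
    MHC = "major histocompatibility complex class I antigen presentation",
    OR = "olfactory receptor activity coupled to g protein-coupled receptor signaling",
    GPCR = "g protein-coupled receptor signal transduction",
    ZNF = "zinc finger c2h2-type nucleic acid binding",
    IMMUNE = "interleukin receptor immune response signaling",
    OTHER = c("protein kinase activity", "oxidoreductase metabolic process",
              "cytoskeleton organization", "membrane transport atpase",
              "rna processing spliceosome component")
  )
  lens <- setNames(idx$length, idx$chrom)
  n <- length(fam_of)
  stratum <- integer(n)
  clustered <- fam_of == config$clustered_family
  stratum[!clustered] <- sample.int(nrow(strata), sum(!clustered),
                                    replace = TRUE, prob = w_bg)
  stratum[clustered] <- sample.int(nrow(strata), sum(clustered),
                                   replace = TRUE, prob = w_cl)
  glen <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  s0 <- strata$start[stratum] +
    floor(runif(n) * (strata$end[stratum] - strata$start[stratum]))
  ch <- strata$chrom[stratum]
  genes <- data.table(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = ch, start = s0, end = pmin(s0 + glen, lens[ch]),
    family = fam_of
  )
  genes[, terms := lapply(family, function(f) {
    pool <- term_pool[[f]]
    pool[1 + (sample.int(length(pool), 1L) - 1L) * (f == "OTHER")]
  })]
  setorder(genes, chrom, start)
  genes[, gene_id := sprintf("g%05d", seq_len(.N))]
  genes[]
}

#' Simulate a full multi-species cohort with planted ground truth
#'
#' Each position of each species is heterozygous with probability
#' `baseline_het x (micro multiplier) x (hotspot multiplier) x (ROH
#' factor)`, missing independently with `missing_rate`, and homozygous
#' alternate with `hom_alt_rate`; only informative positions
#' (het/hom-alt/missing) are materialized (the site tables carry the
#' "hom_ref-absent" sparse convention, see [window_heterozygosity()]).
#' Pairwise tracks against the reference species draw variants with
#' probability `baseline_divergence x (micro multiplier) x (hotspot
#' distance multiplier)` inside the simulated aligned intervals. Genes are
#' placed with family-conditional weights concentrating the clustered
#' family in hotspots. All outputs are deterministic for identical
#' (config, seed).
#'
#' @param config a [sim_config()].
#' @return list of class "divscan_cohort": config, index, mask, sites
#'   (named list of site tables), tracks (named list of
#'   [divergence_track()] keyed by non-reference species), genes, truth
#'   (ground-truth ledger list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- setNames(
    lapply(config$species, function(sp) .simulate_sites_one(config, sp)),
    config$species
  )
  others <- config$species[-1]
  tracks <- setNames(lapply(others, function(sp) .simulate_track_one(config, sp)),
                     others)
  genes <- .simulate_genes(config)

  # ground truth: planted intervals plus analytic expectations
  mask <- config$mask
  exp_het <- rbindlist(lapply(config$species, function(sp) {
    seg <- .het_segments(config, sp)
    seg[, mask_bp := 0]
    if (nrow(mask)) {
      ov <- iv_intersect(seg[, .(chrom, start, end)], mask)
      if (nrow(ov)) {
        for (i in seq_len(nrow(seg))) {
          seg$mask_bp[i] <- iv_total_bp(
            ov[chrom == seg$chrom[i] & start >= seg$start[i] & end <= seg$end[i]])
        }
      }
    }
    agg <- seg[, .(expected_het = sum(p * (1 - config$missing_rate) *
                                        (end - start - mask_bp)) / sum(end - start)),
               by = chrom]
    agg[, species := sp]
    agg
  }))
  denom <- sum(config$index$length)
  exp_froh <- vapply(config$species, function(sp) {
    r <- config$roh[[sp]]
    if (is.null(r) || nrow(r) == 0L) 0 else sum(r$end - r$start) / denom
  }, numeric(1))
  fam_counts <- .family_truth_counts(genes, config$hotspots)

  truth <- list(
    hotspots = as.data.frame(config$hotspots),
    roh = lapply(config$roh, as.data.frame),
    expected_chrom_het = as.data.frame(exp_het),
    expected_froh = as.list(exp_froh),
    family_counts = fam_counts,
    seed = config$seed
  )
  structure(list(config = config, index = config$index, mask = mask,
                 sites = sites, tracks = tracks, genes = genes, truth = truth),
            class = "divscan_cohort")
}

.family_truth_counts <- function(genes, hotspots) {
  hs <- if (nrow(hotspots)) interval_set(hotspots[, .(chrom, start, end)]) else
    interval_set(NULL)
  in_hot <- rep(FALSE, nrow(genes))
  if (nrow(hs)) {
    ir <- .iv_by_chrom(hs)
    for (ch in unique(genes$chrom)) {
      if (is.null(ir[[ch]])) next
      gi <- which(genes$chrom == ch)
      in_hot[gi] <- IRanges::overlapsAny(
        IRanges::IRanges(start = genes$start[gi] + 1, end = genes$end[gi]),
        ir[[ch]])
    }
  }
  dt <- data.table(family = genes$family, in_hot = in_hot)
  agg <- dt[, .(n_total = .N, n_in_hotspot = sum(in_hot)), by = family]
  setorder(agg, family)
  as.data.frame(agg)
}
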