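#' Flag diversity/divergence hotspot windows for one species
#'
#' A heterozygosity window (50-kb grid) is flagged iff its normalized
#' heterozygosity strictly exceeds `het_fold` AND at least one overlapping
#' unmasked divergence window (10-kb grid) has normalized distance strictly
#' exceeding `dist_fold`. The joint rule is evaluated on the coarser
#' heterozygosity grid because the two metrics live on different window
#' sizes. Boundary values (norm exactly equal to the fold) are not flagged.
#'
#' @param het_windows normalized heterozygosity windows
#'   ([normalize_windows()]).
#' @param div_windows normalized divergence windows
#'   ([normalize_distance()]).
#' @param het_fold heterozygosity fold threshold (default 4).
#' @param dist_fold distance fold threshold (default 2).
#' @return het windows plus `flagged`, `max_norm_distance` (max over
#'   overlapping unmasked divergence windows; NA if none).
#' @export
flag_windows <- function(het_windows, div_windows, het_fold = 4, dist_fold = 2) {
  stopifnot(het_fold > 0, dist_fold > 0)
  hw <- copy(as.data.table(het_windows))
  dw <- as.data.table(div_windows)
  if (!all(unique(dw$chrom) %in% unique(hw$chrom))) {
    stop("divergence windows on chromosomes absent from the heterozygosity frame")
  }
  hw[, max_norm_distance := NA_real_]
  dwu <- dw[masked == FALSE & !is.na(norm_distance)]
  if (nrow(dwu)) {
    ir_d <- lapply(split(seq_len(nrow(dwu)), dwu$chrom), function(i)
      list(ir = IRanges::IRanges(start = dwu$start[i] + 1, end = dwu$end[i]),
           val = dwu$norm_distance[i]))
    for (ch in names(ir_d)) {
      wi <- which(hw$chrom == ch)
      if (!length(wi)) next
      ir_h <- IRanges::IRanges(start = hw$start[wi] + 1, end = hw$end[wi])
      hits <- IRanges::findOverlaps(ir_h, ir_d[[ch]]$ir)
      if (length(hits)) {
        mx <- tapply(ir_d[[ch]]$val[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), max)
        hw$max_norm_distance[wi[as.integer(names(mx))]] <- as.numeric(mx)
      }
    }
  }
  hw[, flagged := norm_het > het_fold &
       !is.na(max_norm_distance) & max_norm_distance > dist_fold]
  hw[]
}

#' Merge flagged windows into hotspot regions
#'
#' Flagged windows on one chromosome separated by at most `merge_gap` bp
#' are joined into maximal regions; bounds snap to window bounds.
#'
#' @param flagged_windows output of [flag_windows()].
#' @param merge_gap bp (default 100 kb), so one sub-threshold window does
#'   not split a region.
#' @return regions: chrom, start, end, n_windows, max_norm_het,
#'   max_norm_distance.
#' @export
merge_flagged <- function(flagged_windows, merge_gap = 100000) {
  fw <- as.data.table(flagged_windows)[flagged == TRUE]
  if (nrow(fw) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), max_norm_het = numeric(),
                      max_norm_distance = numeric()))
  }
  reg <- iv_merge(fw[, .(chrom, start, end)], gap = merge_gap)
  # attach per-region stats by window membership
  reg[, `:=`(n_windows = 0L, max_norm_het = NA_real_, max_norm_distance = NA_real_)]
  for (i in seq_len(nrow(reg))) {
    m <- fw[chrom == reg$chrom[i] & start >= reg$start[i] & end <= reg$end[i]]
    reg$n_windows[i] <- nrow(m)
    reg$max_norm_het[i] <- max(m$norm_het)
    reg$max_norm_distance[i] <- max(m$max_norm_distance)
  }
  reg[]
}

#' Consensus hotspots across species
#'
#' Window-level voting on the shared heterozygosity grid: a window enters
#' the consensus iff it is flagged in at least `min_species` species;
#' consensus windows are then merged with `merge_gap`, and each region
#' records the union of species flagging any member window.
#'
#' @param flagged_list named list (species -> [flag_windows()] output), all
#'   on the same window frame.
#' @param min_species vote threshold (default: all species).
#' @param merge_gap bp (default 100 kb).
#' @return regions: chrom, start, end, n_species, supporting_species
#'   (comma-separated), max_norm_het, max_norm_distance.
#' @export
consensus_hotspots <- function(flagged_list, min_species = length(flagged_list),
                               merge_gap = 100000) {
  if (length(flagged_list) == 0L) stop("empty cohort")
  stopifnot(min_species >= 1, min_species <= length(flagged_list))
  if (is.null(names(flagged_list)) || any(names(flagged_list) == "")) {
    stop("flagged_list must be named by species")
  }
  all_w <- rbindlist(lapply(names(flagged_list), function(sp) {
    fw <- as.data.table(flagged_list[[sp]])
    fw[flagged == TRUE, .(chrom, start, end, norm_het, max_norm_distance,
                          species = sp)]
  }))
  empty <- data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_species = integer(), supporting_species = character(),
                      max_norm_het = numeric(), max_norm_distance = numeric())
  if (nrow(all_w) == 0L) return(empty)
  votes <- all_w[, .(n_species = uniqueN(species)), by = .(chrom, start, end)]
  cons <- votes[n_species >= min_species]
  if (nrow(cons) == 0L) return(empty)
  reg <- iv_merge(cons[, .(chrom, start, end)], gap = merge_gap)
  reg[, `:=`(n_species = 0L, supporting_species = "",
             max_norm_het = NA_real_, max_norm_distance = NA_real_)]
  for (i in seq_len(nrow(reg))) {
    m <- all_w[chrom == reg$chrom[i] & start >= reg$start[i] & end <= reg$end[i]]
    sp <- sort(unique(m$species))
    reg$n_species[i] <- length(sp)
    reg$supporting_species[i] <- paste(sp, collapse = ",")
    reg$max_norm_het[i] <- max(m$norm_het)
    reg$max_norm_distance[i] <- suppressWarnings(max(m$max_norm_distance, na.rm = TRUE))
  }
  reg[]
}
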