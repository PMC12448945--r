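#' Low-heterozygosity threshold for ROH calling
#'
#' A window counts as low-heterozygosity when its per-bp het falls strictly
#' below `fraction` of the genome-wide mean heterozygosity (default
#' one-fifth).
#'
#' @param genome_mean_het per-bp genome-wide mean heterozygosity.
#' @param fraction multiplier (default 1/5).
#' @return per-bp threshold.
#' @export
roh_threshold <- function(genome_mean_het, fraction = 1/5) {
  stopifnot(genome_mean_het >= 0, fraction > 0)
  fraction * genome_mean_het
}

#' Call runs of homozygosity from the window table
#'
#' A window is eligible iff `het < threshold` (strict) and
#' `missing_prop <= max_missing_prop`; windows over the missingness cap
#' break runs rather than being bridged (`bridge_missing = TRUE` ignores
#' them instead, the non-default permissive reading). Maximal runs of
#' consecutive eligible windows on one chromosome are reported when they
#' contain at least `min_windows` windows AND span at least `min_length` bp
#' — both minima are enforced independently, so truncated terminal windows
#' cannot produce sub-length calls.
#'
#' @param windows window table (tiling, sorted; as from
#'   [window_heterozygosity()]).
#' @param threshold per-bp het threshold from [roh_threshold()].
#' @param min_windows minimum consecutive windows (default 10).
#' @param min_length minimum span in bp (default 500 kb).
#' @param max_missing_prop per-window missing-data cap (default 0.7).
#' @param bridge_missing if TRUE, over-cap windows are skipped without
#'   breaking a run (they still do not count toward `min_windows`).
#' @return ROH segments: chrom, start, end, n_windows, mean_het.
#' @export
call_roh <- function(windows, threshold, min_windows = 10, min_length = 500000,
                     max_missing_prop = 0.7, bridge_missing = FALSE) {
  stopifnot(threshold >= 0, min_windows >= 1, min_length >= 1,
            max_missing_prop >= 0, max_missing_prop <= 1)
  win <- copy(as.data.table(windows))
  setorder(win, chrom, start)
  gap_ok <- win[, all(start[-1] == end[-.N]) || .N == 1L, by = chrom]
  if (!all(gap_ok$V1)) stop("windows must tile each chromosome without gaps or overlaps")

  win[, eligible := het < threshold & missing_prop <= max_missing_prop]
  if (bridge_missing) {
    # over-cap windows are transparent: drop them before run detection
    win <- win[missing_prop <= max_missing_prop]
  }
  if (nrow(win) == 0L || !any(win$eligible)) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), mean_het = numeric()))
  }
  win[, run_id := rleid(chrom, eligible)]
  seg <- win[eligible == TRUE, .(
    chrom = chrom[1], start = min(start), end = max(end),
    n_windows = .N, mean_het = sum(n_het) / (max(end) - min(start))
  ), by = run_id][, run_id := NULL]
  seg <- seg[n_windows >= min_windows & (end - start) >= min_length]
  setorder(seg, chrom, start)
  seg[]
}

#' FROH: genome fraction in ROH, decomposed by segment length class
#'
#' The denominator is the summed length of the chromosomes in `index`
#' (the analyzed chromosome frame, not the full assembly). Each segment is
#' assigned to exactly one half-open length bin; the per-class fractions sum
#' exactly to the total.
#'
#' @param segments ROH segments from [call_roh()].
#' @param index genome index.
#' @param bins_mb lower bin edges in Mb (default `c(0.5, 1, 2, 5)`, giving
#'   bins \[0.5,1), \[1,2), \[2,5), \[5,Inf) Mb).
#' @return list with `froh_total`, `froh_by_class` (named numeric),
#'   `denominator` (bp), and `n_segments`.
#' @export
froh <- function(segments, index, bins_mb = c(0.5, 1, 2, 5)) {
  check_index(index)
  stopifnot(length(bins_mb) >= 1, !is.unsorted(bins_mb, strictly = TRUE))
  denom <- sum(index$length)
  edges <- c(bins_mb * 1e6, Inf)
  labels <- paste0("[", bins_mb, ",", c(bins_mb[-1], Inf), ")")
  seg <- as.data.table(segments)
  if (nrow(seg)) {
    setorder(seg, chrom, start)
    ovl <- seg[, any(start[-1] < end[-.N]), by = chrom]
    if (any(ovl$V1)) stop("overlapping ROH segments")
    seg_len <- seg$end - seg$start
    if (any(seg_len < edges[1])) {
      stop("segment shorter than the smallest FROH length bin")
    }
    cls <- cut(seg_len, breaks = edges, labels = labels, right = FALSE)
    by_class <- tapply(seg_len, cls, sum, default = 0) / denom
    by_class <- setNames(as.numeric(by_class), labels)
  } else {
    by_class <- setNames(rep(0, length(labels)), labels)
  }
  list(froh_total = sum(by_class), froh_by_class = by_class,
       denominator = denom, n_segments = nrow(seg))
}
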