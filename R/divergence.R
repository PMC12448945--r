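#' Construct and validate a pairwise divergence track
#'
#' Interspecific single-variant positions plus aligned-coverage intervals
#' for one species pair, both expressed on the shared reference coordinate
#' frame (the emulated output of a whole-genome-alignment SNP/coverage
#' extraction). Every variant must lie inside an aligned interval.
#'
#' @param species_a,species_b species names (a is the reference frame).
#' @param variants data.frame with columns chrom, pos (1-based).
#' @param aligned interval set of aligned regions (0-based half-open).
#' @return list of class "divergence_track".
#' @export
divergence_track <- function(species_a, species_b, variants, aligned) {
  variants <- data.table(chrom = as.character(variants$chrom),
                         pos = as.numeric(variants$pos))
  setorder(variants, chrom, pos)
  aligned <- interval_set(aligned)
  if (nrow(variants)) {
    ir <- .iv_by_chrom(aligned)
    for (ch in unique(variants$chrom)) {
      p <- variants[chrom == ch, pos]
      inside <- if (is.null(ir[[ch]])) rep(FALSE, length(p)) else
        IRanges::overlapsAny(IRanges::IRanges(start = p, width = 1L), ir[[ch]])
      if (!all(inside)) {
        stop("variant outside aligned intervals: ", ch, ":", p[which(!inside)[1]])
      }
    }
  }
  structure(list(species_a = species_a, species_b = species_b,
                 variants = variants, aligned = aligned),
            class = "divergence_track")
}

#' Windowed interspecific genetic distance
#'
#' Tiles each chromosome with fixed windows (default 10 kb; pass
#' `size = 30000` for the coarser genome-wide view), counts interspecific
#' variants per window, and divides by the aligned bp in the window.
#' Windows whose aligned coverage falls below
#' `min_aligned_fraction * window length` are reported MASKED
#' (`distance = NA`, `masked = TRUE`). `min_aligned_fraction = 0` together
#' with `raw_length_denominator = TRUE` reproduces a plain
#' variants-per-window-length rate.
#'
#' @param track a [divergence_track()].
#' @param index genome index.
#' @param size window width bp (default 10 kb).
#' @param min_aligned_fraction minimum aligned fraction for a defined
#'   distance (default 0.5).
#' @param raw_length_denominator divide by window length instead of
#'   aligned bp.
#' @return data.table: chrom, start, end, window_len, n_variants,
#'   aligned_bp, distance, masked.
#' @export
window_distance <- function(track, index, size = 10000,
                            min_aligned_fraction = 0.5,
                            raw_length_denominator = FALSE) {
  stopifnot(inherits(track, "divergence_track"),
            min_aligned_fraction >= 0, min_aligned_fraction <= 1)
  win <- make_windows(index, size = size)
  win[, win := seq_len(.N), by = chrom]

  # variant counts per window
  starts <- split(win$start, win$chrom)
  ends <- split(win$end, win$chrom)
  v <- track$variants[chrom %in% names(starts)]
  if (nrow(v) < nrow(track$variants)) {
    stop("track chromosome absent from genome index")
  }
  if (nrow(v)) {
    v <- copy(v)
    v[, win := {
      idx <- findInterval(pos - 1, starts[[.BY$chrom]])
      if (any(idx < 1L) || any(pos - 1 >= ends[[.BY$chrom]][idx])) {
        stop("variant position outside chromosome bounds on ", .BY$chrom)
      }
      idx
    }, by = chrom]
    cnt <- v[, .(n_variants = .N), by = .(chrom, win)]
    win <- merge(win, cnt, by = c("chrom", "win"), all.x = TRUE)
    win[is.na(n_variants), n_variants := 0L]
  } else {
    win[, n_variants := 0L]
  }

  # aligned bp per window via overlap with the window grid
  win[, aligned_bp := 0]
  al <- track$aligned
  if (nrow(al)) {
    ir_al <- .iv_by_chrom(al)
    for (ch in names(ir_al)) {
      wi <- which(win$chrom == ch)
      if (!length(wi)) next
      ir_win <- IRanges::IRanges(start = win$start[wi] + 1, end = win$end[wi])
      hits <- IRanges::findOverlaps(ir_win, ir_al[[ch]])
      if (length(hits)) {
        ov <- IRanges::pintersect(ir_win[S4Vectors::queryHits(hits)],
                                  ir_al[[ch]][S4Vectors::subjectHits(hits)])
        bp <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
        win$aligned_bp[wi[as.integer(names(bp))]] <- as.numeric(bp)
      }
    }
  }
  win[, masked := aligned_bp < min_aligned_fraction * window_len | aligned_bp == 0]
  denom <- if (raw_length_denominator) win$window_len else win$aligned_bp
  win[, distance := ifelse(masked, NA_real_, n_variants / denom)]
  win[, win := NULL]
  setorder(win, chrom, start)
  win[]
}

#' Per-chromosome mean genetic distance over unmasked windows
#'
#' Total variants over total aligned bp of the chromosome's unmasked
#' windows. Chromosomes with every window masked are excluded with a
#' warning (mean undefined).
#'
#' @param div_windows from [window_distance()].
#' @return data.table: chrom, mean_distance (masked-out chromosomes
#'   absent).
#' @export
chromosome_mean_distance <- function(div_windows) {
  win <- as.data.table(div_windows)
  means <- win[masked == FALSE,
               .(mean_distance = sum(n_variants) / sum(aligned_bp)), by = chrom]
  dropped <- setdiff(unique(win$chrom), means$chrom)
  if (length(dropped)) {
    warning("chromosome(s) with all windows masked excluded from distance means: ",
            paste(dropped, collapse = ", "))
  }
  means[]
}

#' Normalize window distances by the chromosomal mean
#'
#' `norm_distance = distance / chromosome mean`; zero-mean chromosomes get
#' 0 with a degenerate flag; MASKED windows stay NA.
#'
#' @param div_windows from [window_distance()].
#' @param chrom_means from [chromosome_mean_distance()]; computed if NULL.
#' @return windows with norm_distance and degenerate columns.
#' @export
normalize_distance <- function(div_windows, chrom_means = NULL) {
  win <- copy(as.data.table(div_windows))
  if (is.null(chrom_means)) {
    chrom_means <- suppressWarnings(chromosome_mean_distance(win))
  }
  win <- merge(win, as.data.table(chrom_means), by = "chrom",
               all.x = TRUE, sort = FALSE)
  win[, degenerate := !is.na(mean_distance) & mean_distance == 0]
  win[, norm_distance := ifelse(masked | is.na(mean_distance), NA_real_,
                                ifelse(degenerate, 0, distance / mean_distance))]
  win[, mean_distance := NULL]
  setorder(win, chrom, start)
  win[]
}
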