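#' Tile the genome with non-overlapping fixed-width windows
#'
#' Per chromosome, windows `[0,size), [size,2*size), ...` with the final
#' window truncated at the chromosome end, so every bp is covered exactly
#' once.
#'
#' @param index genome index.
#' @param size window width in bp (default 50 kb, the diversity-window
#'   width).
#' @return window data.table: chrom, start, end, window_len.
#' @export
make_windows <- function(index, size = 50000) {
  check_index(index)
  if (!is.finite(size) || size < 1) stop("window size must be >= 1")
  win <- index[, {
    starts <- seq(0, length - 1, by = size)
    .(start = starts, end = pmin(starts + size, length))
  }, by = chrom]
  win[, window_len := end - start]
  win[]
}

#' Count heterozygous and missing sites per window
#'
#' The per-bp heterozygosity denominator is the full window length (no
#' missing-data filter is applied at this stage); missingness is carried
#' alongside as `missing_prop` so the ROH caller can apply its own cap.
#'
#' Two sparse-table conventions are supported via `absent`:
#' \describe{
#'   \item{"missing"}{gVCF semantics: a position with no record is missing
#'     (conservative; the default for real data).}
#'   \item{"hom_ref"}{simulator semantics: only informative positions
#'     (het / hom-alt / missing) are materialized, every absent position is
#'     callable hom-ref. Exact denominators are reconstructed from the
#'     missing rows alone.}
#' }
#'
#' @param sites site table sorted by (chrom, pos).
#' @param windows window table from [make_windows()].
#' @param absent how to interpret positions with no record (see above).
#' @return windows with n_het, n_missing, het, missing_prop.
#' @export
window_heterozygosity <- function(sites, windows, absent = c("missing", "hom_ref")) {
  absent <- match.arg(absent)
  sites <- as.data.table(sites)
  win <- copy(as.data.table(windows))
  setorder(win, chrom, start)
  win[, win := seq_len(.N), by = chrom]

  starts <- split(win$start, win$chrom)
  ends <- split(win$end, win$chrom)
  if (nrow(sites)) {
    if (!all(unique(sites$chrom) %in% names(starts))) {
      stop("site chromosome absent from window frame")
    }
    sites <- copy(sites)
    sites[, win := {
      idx <- findInterval(pos - 1, starts[[.BY$chrom]])
      if (any(idx < 1L) || any(pos - 1 >= ends[[.BY$chrom]][idx])) {
        stop("site position outside any window on ", .BY$chrom)
      }
      idx
    }, by = chrom]
    agg <- sites[, .(
      n_het = sum(gt == 1L, na.rm = TRUE),
      n_rec_missing = sum(is.na(gt)),
      n_rec_called = sum(!is.na(gt))
    ), by = .(chrom, win)]
    win <- merge(win, agg, by = c("chrom", "win"), all.x = TRUE)
    for (col in c("n_het", "n_rec_missing", "n_rec_called")) {
      win[is.na(get(col)), (col) := 0]
    }
  } else {
    win[, `:=`(n_het = 0, n_rec_missing = 0, n_rec_called = 0)]
  }
  if (absent == "missing") {
    win[, n_missing := window_len - n_rec_called]
  } else {
    win[, n_missing := n_rec_missing]
  }
  win[, `:=`(n_rec_missing = NULL, n_rec_called = NULL)]
  win[, `:=`(het = n_het / window_len, missing_prop = n_missing / window_len)]
  setorder(win, chrom, start)
  win[]
}

#' Length-weighted per-chromosome mean heterozygosity
#'
#' Default is total het sites over total chromosome length (the truncated
#' final window enters with its true length); `weighted = FALSE` gives the
#' unweighted per-window mean instead.
#'
#' @param windows window table with n_het.
#' @param weighted length-weighted (default) or plain window mean.
#' @return data.table: chrom, mean_het.
#' @export
chromosome_mean_het <- function(windows, weighted = TRUE) {
  win <- as.data.table(windows)
  if (nrow(win) == 0L) stop("no windows")
  if (weighted) {
    win[, .(mean_het = sum(n_het) / sum(window_len)), by = chrom]
  } else {
    win[, .(mean_het = mean(het)), by = chrom]
  }
}

#' Genome-wide mean heterozygosity (total het sites / total length)
#' @param windows window table.
#' @return per-bp rate.
#' @export
genome_mean_het <- function(windows) {
  win <- as.data.table(windows)
  if (nrow(win) == 0L) stop("no windows")
  sum(win$n_het) / sum(win$window_len)
}

#' Normalize window heterozygosity by the chromosomal mean
#'
#' `norm_het = het / chromosome mean`; chromosomes with zero mean get
#' norm_het 0 and a `degenerate` flag. The normalization highlights
#' within-chromosome hotspots rather than overall diversity differences.
#'
#' @param windows window table with het.
#' @param chrom_means from [chromosome_mean_het()]; computed if NULL.
#' @return windows with norm_het and degenerate columns.
#' @export
normalize_windows <- function(windows, chrom_means = NULL) {
  win <- copy(as.data.table(windows))
  if (is.null(chrom_means)) chrom_means <- chromosome_mean_het(win)
  win <- merge(win, as.data.table(chrom_means), by = "chrom", all.x = TRUE, sort = FALSE)
  if (anyNA(win$mean_het)) stop("missing chromosome mean for some windows")
  win[, degenerate := mean_het == 0]
  win[, norm_het := ifelse(degenerate, 0, het / mean_het)]
  win[, mean_het := NULL]
  setorder(win, chrom, start)
  win[]
}

#' Classify chromosomes as macro- or microchromosomes
#'
#' MACRO iff length strictly exceeds the threshold (default 50 Mb);
#' exactly-threshold chromosomes are MICRO.
#'
#' @param index genome index.
#' @param macro_threshold bp cutoff (default 5e7).
#' @return data.table: chrom, length, size_class.
#' @export
classify_chromosomes <- function(index, macro_threshold = 50e6) {
  check_index(index)
  out <- as.data.table(index)[, .(chrom, length)]
  out[, size_class := ifelse(length > macro_threshold, "MACRO", "MICRO")]
  out[]
}

#' Exact rank-sum contrast between micro- and macrochromosome values
#'
#' Two-sided Wilcoxon rank-sum on per-chromosome values (exact when there
#' are no ties); `direction` is the sign of (micro median - macro median).
#' Degenerate all-identical input returns p = 1, direction 0.
#'
#' @param values numeric per-chromosome values (e.g. mean het, gene
#'   density, mean distance).
#' @param size_class character vector ("MACRO"/"MICRO") aligned with
#'   `values`.
#' @return list(statistic, p_value, direction).
#' @export
compare_macro_micro <- function(values, size_class) {
  stopifnot(length(values) == length(size_class))
  macro <- values[size_class == "MACRO"]
  micro <- values[size_class == "MICRO"]
  if (length(macro) == 0L || length(micro) == 0L) {
    stop("both chromosome size classes must be non-empty")
  }
  direction <- sign(median(micro) - median(macro))
  if (length(unique(c(macro, micro))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1, direction = 0))
  }
  wt <- suppressWarnings(wilcox.test(micro, macro, alternative = "two.sided",
                                     exact = TRUE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = direction)
}
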