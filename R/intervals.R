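#' Interval sets
#'
#' All intervals in the package share one convention: 0-based half-open
#' `[start, end)` coordinates on named chromosomes, stored as a data.table
#' with columns `chrom`, `start`, `end`, sorted, non-overlapping within each
#' chromosome. `interval_set()` validates and normalizes (sorts and merges
#' touching/overlapping input) so every consumer can rely on the invariants.
#' The arithmetic is backed by IRanges; the half-open convention is converted
#' at the boundary.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @return normalized interval data.table.
#' @export
interval_set <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  }
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop("interval set needs columns chrom, start, end")
  }
  dt <- data.table(chrom = as.character(x$chrom),
                   start = as.numeric(x$start), end = as.numeric(x$end))
  if (any(!is.finite(dt$start)) || any(!is.finite(dt$end))) {
    stop("non-finite interval bounds")
  }
  if (any(dt$start < 0) || any(dt$end <= dt$start)) {
    stop("intervals must satisfy 0 <= start < end")
  }
  iv_merge(dt, gap = 0)
}

# split into an IRangesList-like list of IRanges keyed by chromosome
.iv_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1, end = x$end[i]))
}

.iv_from_iranges <- function(ir_list) {
  if (length(ir_list) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- rbindlist(lapply(names(ir_list), function(ch) {
    ir <- ir_list[[ch]]
    if (length(ir) == 0L) return(NULL)
    data.table(chrom = ch, start = BiocGenerics::start(ir) - 1,
               end = BiocGenerics::end(ir))
  }))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric()))
  }
  setorder(out, chrom, start)[]
}

#' Merge intervals, joining any pair separated by at most `gap` bp
#'
#' @param x interval data.table (chrom, start, end), 0-based half-open.
#' @param gap maximum separation (bp) still merged; 0 merges only
#'   touching/overlapping intervals.
#' @return merged interval set.
#' @export
iv_merge <- function(x, gap = 0) {
  stopifnot(gap >= 0)
  if (nrow(x) == 0L) return(data.table(chrom = character(), start = numeric(), end = numeric()))
  ir <- .iv_by_chrom(x)
  .iv_from_iranges(lapply(ir, IRanges::reduce, min.gapwidth = gap + 1))
}

#' Intersect two interval sets exactly
#'
#' @param a,b interval sets.
#' @return interval set covering exactly the bp present in both.
#' @export
iv_intersect <- function(a, b) {
  empty <- data.table(chrom = character(), start = numeric(), end = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  ia <- .iv_by_chrom(a)
  ib <- .iv_by_chrom(b)
  common <- intersect(names(ia), names(ib))
  if (length(common) == 0L) return(empty)
  .iv_from_iranges(setNames(
    lapply(common, function(ch) IRanges::intersect(ia[[ch]], ib[[ch]])),
    common
  ))
}

#' Total overlap between two interval sets, in bp
#' @param a,b interval sets.
#' @return numeric, total length of `iv_intersect(a, b)`.
#' @export
iv_overlap_bp <- function(a, b) iv_total_bp(iv_intersect(a, b))

#' Total bp covered by an interval set
#' @param x interval set.
#' @return numeric.
#' @export
iv_total_bp <- function(x) if (nrow(x) == 0L) 0 else sum(x$end - x$start)

#' Read a BED3 file into an interval set
#'
#' Strand-agnostic; only the first three columns are used. Track/browser
#' header lines are rejected (the mask files this package consumes are plain
#' BED3).
#'
#' @param path BED file path.
#' @return interval set.
#' @export
read_bed <- function(path) {
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", select = 1:3,
          col.names = c("chrom", "start", "end")),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) return(interval_set(NULL))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 | dt$end <= dt$start)
  if (length(bad)) stop("malformed BED interval at line ", bad[1], " of ", path)
  interval_set(dt)
}

#' Write an interval set as BED3 (plus any extra columns given)
#' @param x interval-set-like data.table (chrom, start, end, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
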