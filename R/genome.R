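#' Construct a genome index
#'
#' The ordered chromosome frame every stage works on. Order is preserved and
#' defines output order; typically the analyzed chromosome set only (e.g. the
#' 28 assembled chromosomes), not the full assembly.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in bp, all >= 1.
#' @return data.table with columns `chrom`, `length`.
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (base::length(chrom) == 0L) stop("genome index must not be empty")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in genome index")
  if (any(!is.finite(length)) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  data.table(chrom = chrom, length = length)
}

#' Read a genome index from a file
#'
#' Accepts either a two-column TSV (name, length) or a samtools `.fai` index
#' (name, length in the first two columns).
#'
#' @param path file path.
#' @return data.table as from [genome_index()].
#' @export
read_genome_index <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("genome index file needs at least 2 columns: ", path)
  genome_index(dt[[1]], dt[[2]])
}

# cheap structural check used by consumers
check_index <- function(index) {
  if (!is.data.frame(index) || !all(c("chrom", "length") %in% names(index))) {
    stop("not a genome index (need columns chrom, length)")
  }
  invisible(genome_index(index$chrom, index$length))
}
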