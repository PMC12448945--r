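#' Read per-site genotype records
#'
#' Builds the base-pair-resolution site table all downstream stages consume,
#' from either a single-individual VCF/gVCF (plain or bgzipped) or the
#' package's per-site TSV dialect (columns chrom, pos, gt, depth, mq,
#' biallelic; gt coded 0/1/2/.). Records on contigs absent from `index` are
#' dropped with a warning carrying the dropped count. Positions never seen in
#' the file are not materialized; downstream they count as missing unless the
#' table's sparse convention says otherwise (see [window_heterozygosity()]).
#'
#' @param path input file.
#' @param index genome index from [genome_index()].
#' @param format "auto" (by extension), "vcf" or "tsv".
#' @return site data.table: `chrom`, `pos` (1-based), `gt`
#'   (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing), `depth`, `mq`,
#'   `biallelic`; sorted by (chrom, pos) in index order.
#' @export
read_sites <- function(path, index, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  check_index(index)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  sites <- if (format == "vcf") .read_sites_vcf(path) else .read_sites_tsv(path)
  .conform_sites(sites, index)
}

.conform_sites <- function(sites, index) {
  unknown <- !(sites$chrom %in% index$chrom)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) on contigs absent from the genome index were dropped")
    sites <- sites[!unknown]
  }
  lens <- setNames(index$length, index$chrom)
  bad <- which(sites$pos < 1 | sites$pos > lens[sites$chrom])
  if (length(bad)) {
    stop("site position outside chromosome bounds: ", sites$chrom[bad[1]], ":", sites$pos[bad[1]])
  }
  sites[, chrom := factor(chrom, levels = index$chrom)]
  setorder(sites, chrom, pos)
  sites[, chrom := as.character(chrom)]
  sites[]
}

.read_sites_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = "gt"))
  need <- c("chrom", "pos", "gt")
  if (!all(need %in% names(dt))) {
    stop("site TSV needs columns chrom, pos, gt: ", path)
  }
  gt_chr <- as.character(dt$gt)
  ok <- gt_chr %in% c("0", "1", "2", ".", NA_character_)
  if (!all(ok)) stop("bad gt code at line ", which(!ok)[1] + 1L, " of ", path)
  out <- data.table(
    chrom = as.character(dt$chrom),
    pos = as.numeric(dt$pos),
    gt = suppressWarnings(as.integer(gt_chr)),
    depth = if ("depth" %in% names(dt)) as.numeric(dt$depth) else NA_real_,
    mq = if ("mq" %in% names(dt)) as.numeric(dt$mq) else NA_real_,
    biallelic = if ("biallelic" %in% names(dt)) as.logical(dt$biallelic) else TRUE
  )
  out
}

.read_sites_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("unparseable VCF ", path, ": ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(data.table(chrom = character(), pos = numeric(), gt = integer(),
                      depth = numeric(), mq = numeric(), biallelic = logical()))
  }
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  # gVCF idiom: drop the symbolic <NON_REF> allele before counting alternates
  alt_clean <- vapply(strsplit(alt, ",", fixed = TRUE), function(a) {
    a <- a[!(a %in% c("<NON_REF>", "<*>", "."))]
    paste(a, collapse = ",")
  }, character(1))
  n_alt <- ifelse(alt_clean == "", 0L, lengths(strsplit(alt_clean, ",", fixed = TRUE)))
  biallelic <- n_alt <= 1L

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt_str <- if (is.null(gt_raw)) rep(NA_character_, nrow(fix)) else gt_raw[, 1]
  gt <- .parse_gt(gt_str)

  dp_raw <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                     error = function(e) NULL)
  depth <- if (is.null(dp_raw)) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "DP")))
  } else dp_raw[, 1]
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "MQ")))
  if (length(mq) == 0L) mq <- rep(NA_real_, nrow(fix))

  data.table(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]), gt = gt,
             depth = as.numeric(depth), mq = mq, biallelic = biallelic)
}

# "0/1", "0|1", "./.", NA -> 0/1/2/NA integer code
.parse_gt <- function(gt_str) {
  gt_str <- sub(":.*$", "", gt_str)
  alleles <- strsplit(gsub("|", "/", gt_str, fixed = TRUE), "/", fixed = TRUE)
  vapply(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) return(NA_integer_)
    if (all(a == 0L)) 0L else if (length(unique(a)) > 1L) 1L else 2L
  }, integer(1))
}

#' Apply genotype-quality filters, converting failing genotypes to missing
#'
#' Records are never removed, only their `gt` set to NA, so per-window
#' missingness accounting stays exact. A genotype is retained iff
#' `mq >= min_mq`, `min_depth <= depth <= max_depth_factor * mean_depth`
#' (boundaries inclusive: strictly-below-8 and strictly-above-2x fail), and
#' the site is biallelic or not a variant site. QC fields that are absent
#' (NA) do not fail a record.
#'
#' @param sites site table from [read_sites()].
#' @param min_mq minimum mapping quality kept (default 30).
#' @param min_depth minimum read depth kept (default 8).
#' @param max_depth_factor maximum depth as a multiple of `mean_depth`
#'   (default 2).
#' @param mean_depth average coverage; if NULL, computed as the mean depth
#'   over non-missing records with depth present.
#' @param require_biallelic if TRUE (default), variant sites flagged
#'   non-biallelic become missing.
#' @return new site table, same rows, filtered `gt`.
#' @export
filter_sites <- function(sites, min_mq = 30, min_depth = 8, max_depth_factor = 2,
                         mean_depth = NULL, require_biallelic = TRUE) {
  stopifnot(min_mq >= 0, min_depth >= 0, max_depth_factor > 0)
  out <- copy(as.data.table(sites))
  if (is.null(mean_depth)) {
    mean_depth <- out[!is.na(gt) & !is.na(depth), mean(depth)]
    if (!is.finite(mean_depth)) mean_depth <- NA_real_
  }
  if (!is.na(mean_depth) && mean_depth <= 0) stop("mean_depth must be positive")
  max_depth <- if (is.na(mean_depth)) Inf else max_depth_factor * mean_depth
  fail <- (!is.na(out$mq) & out$mq < min_mq) |
    (!is.na(out$depth) & (out$depth < min_depth | out$depth > max_depth)) |
    (require_biallelic & !is.na(out$gt) & out$gt %in% c(1L, 2L) & !out$biallelic)
  out[fail, gt := NA_integer_]
  out[]
}

#' Mask variant sites inside repeat regions
#'
#' Variant genotypes (het or hom-alt) whose position falls inside the mask
#' become missing; non-variant sites are untouched. Mask coordinates are
#' 0-based half-open, site positions 1-based.
#'
#' @param sites site table.
#' @param mask interval set (e.g. from [read_bed()]).
#' @return new site table, same rows.
#' @export
apply_mask <- function(sites, mask) {
  out <- copy(as.data.table(sites))
  mask <- interval_set(mask)
  if (nrow(mask) == 0L) return(out[])
  variant <- which(!is.na(out$gt) & out$gt %in% c(1L, 2L))
  if (length(variant) == 0L) return(out[])
  ir_mask <- .iv_by_chrom(mask)
  for (ch in unique(out$chrom[variant])) {
    if (is.null(ir_mask[[ch]])) next
    idx <- variant[out$chrom[variant] == ch]
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = out$pos[idx], width = 1L), ir_mask[[ch]])
    out[idx[hit], gt := NA_integer_]
  }
  out[]
}

#' Write the callable site table to TSV
#'
#' Bit-exact across runs; gt written as 0/1/2 with "." for missing.
#'
#' @param sites site table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  out <- as.data.table(sites)[, .(chrom, pos, gt, depth, mq, biallelic)]
  out[, gt := ifelse(is.na(gt), ".", as.character(gt))]
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
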