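#' Read gene records from GFF3, one record per gene
#'
#' Gene span is reduced to the longest isoform: for each gene the single
#' mRNA child with the largest span is kept; genes with no mRNA children
#' fall back to the gene line's own span. Functional-annotation term strings
#' are taken from the attribute named by `term_attribute` (semicolon- or
#' comma-free free text; multiple values joined with "; "), or merged from a
#' two-column TSV (gene id, term) given as `terms_tsv` — one row per term,
#' multiple rows per gene allowed.
#'
#' @param path GFF3 file.
#' @param term_attribute GFF3 attribute carrying functional terms (default
#'   "note").
#' @param terms_tsv optional TSV path with columns gene id, term.
#' @return gene data.table: gene_id, chrom, start, end (0-based half-open),
#'   terms (list column of character vectors).
#' @export
read_genes <- function(path, term_attribute = "note", terms_tsv = NULL) {
  gff <- tryCatch(rtracklayer::import(path, format = "gff3"),
                  error = function(e) stop("malformed GFF3 ", path, ": ",
                                           conditionMessage(e)))
  df <- as.data.table(as.data.frame(gff))
  if (nrow(df) == 0L) {
    return(data.table(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), terms = list()))
  }
  df[, chrom := as.character(seqnames)]
  genes <- df[type == "gene"]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  mrna <- df[type %in% c("mRNA", "transcript")]

  # longest-isoform span per gene; fall back to the gene line
  out <- genes[, .(gene_id = ID, chrom, start = start - 1, end = end)]
  if (nrow(mrna)) {
    parent <- vapply(mrna$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    mr <- data.table(gene_id = parent, start = mrna$start - 1, end = mrna$end,
                     span = mrna$end - mrna$start + 1)
    best <- mr[!is.na(gene_id)][order(-span), .SD[1], by = gene_id]
    out <- merge(out, best[, .(gene_id, mstart = start, mend = end)],
                 by = "gene_id", all.x = TRUE, sort = FALSE)
    out[!is.na(mstart), `:=`(start = mstart, end = mend)]
    out[, c("mstart", "mend") := NULL]
  }

  term_col <- if (term_attribute %in% names(df)) term_attribute else NULL
  tl <- vector("list", nrow(out))
  if (!is.null(term_col)) {
    gt_terms <- genes[[term_col]]
    key <- match(out$gene_id, genes$ID)
    tl <- lapply(key, function(i) {
      v <- gt_terms[[i]]
      if (is.null(v) || all(is.na(v))) character(0) else as.character(v)
    })
  } else {
    tl <- replicate(nrow(out), character(0), simplify = FALSE)
  }
  if (!is.null(terms_tsv)) {
    tt <- fread(terms_tsv, header = FALSE, col.names = c("gene_id", "term"))
    extra <- split(tt$term, tt$gene_id)
    tl <- lapply(seq_len(nrow(out)), function(i) {
      c(tl[[i]], extra[[out$gene_id[i]]])
    })
  }
  out[, terms := tl]
  setorder(out, chrom, start)
  out[]
}

#' Default multicopy gene-family keyword configuration
#'
#' Case-insensitive substring keywords mapping functional-term strings to
#' the multicopy families tested for hotspot enrichment. This shipped list
#' is a pragmatic stand-in assembled from the families' standard
#' InterPro/Pfam-style vocabulary; replace it with your own mapping (same
#' structure: named list family -> character keywords) for production
#' annotations. List order is the classification precedence.
#'
#' @return named list of keyword vectors, in precedence order
#'   MHC > OR > GPCR > ZNF > IMMUNE.
#' @export
default_family_keywords <- function() {
  list(
    MHC = c("major histocompatibility", "mhc class", "histocompatibility antigen"),
    OR = c("olfactory receptor"),
    GPCR = c("g protein-coupled receptor", "g-protein coupled receptor",
             "7 transmembrane receptor", "rhodopsin family"),
    ZNF = c("zinc finger", "zinc-finger"),
    IMMUNE = c("immunoglobulin", "interleukin", "t-cell receptor",
               "tumor necrosis factor", "interferon", "toll-like receptor",
               "immune response", "complement component")
  )
}

#' Classify a gene's functional terms into a multicopy family
#'
#' Families are tested in the fixed precedence order of the keyword config
#' (default MHC > OR > GPCR > ZNF > IMMUNE); the first family with any
#' case-insensitive keyword substring match wins. Olfactory receptors are
#' deliberately tested before GPCRs since every OR carries GPCR vocabulary.
#' No match gives "OTHER".
#'
#' @param terms character vector of functional-term strings for one gene.
#' @param keywords keyword config ([default_family_keywords()]).
#' @return single family label.
#' @export
classify_family <- function(terms, keywords = default_family_keywords()) {
  if (length(keywords) == 0L) stop("empty keyword config")
  if (length(terms) == 0L || all(is.na(terms))) return("OTHER")
  blob <- tolower(paste(terms, collapse = " ; "))
  for (fam in names(keywords)) {
    if (any(vapply(tolower(keywords[[fam]]),
                   function(k) grepl(k, blob, fixed = TRUE), logical(1)))) {
      return(fam)
    }
  }
  "OTHER"
}

#' Add a family column to a gene table
#' @param genes gene table from [read_genes()] (list column `terms`).
#' @param keywords keyword config.
#' @return genes with `family` column.
#' @export
classify_genes <- function(genes, keywords = default_family_keywords()) {
  out <- copy(as.data.table(genes))
  out[, family := vapply(terms, classify_family, character(1), keywords = keywords)]
  out[]
}

#' Gene density per Mb window and per chromosome
#'
#' Counts genes per fixed 1-Mb window (a gene is assigned to the window
#' containing its start) and reports the per-chromosome density
#' n_genes / (length in Mb).
#'
#' @param genes gene table.
#' @param index genome index.
#' @param window_mb window width in Mb (default 1).
#' @return list: `windows` (chrom, start, end, n_genes),
#'   `per_chromosome` (chrom, n_genes, gene_density in genes/Mb).
#' @export
gene_density <- function(genes, index, window_mb = 1) {
  check_index(index)
  g <- as.data.table(genes)
  win <- make_windows(index, size = window_mb * 1e6)
  win[, win := seq_len(.N), by = chrom]
  if (nrow(g)) {
    if (!all(unique(g$chrom) %in% index$chrom)) stop("gene on unknown chromosome")
    g <- copy(g)
    starts <- split(win$start, win$chrom)
    g[, win := findInterval(start, starts[[.BY$chrom]]), by = chrom]
    cnt <- g[, .(n_genes = .N), by = .(chrom, win)]
    win <- merge(win, cnt, by = c("chrom", "win"), all.x = TRUE)
    win[is.na(n_genes), n_genes := 0L]
  } else {
    win[, n_genes := 0L]
  }
  win[, win := NULL]
  setorder(win, chrom, start)
  per_chrom <- win[, .(n_genes = sum(n_genes)), by = chrom]
  per_chrom <- merge(per_chrom, as.data.table(index), by = "chrom", sort = FALSE)
  per_chrom[, gene_density := n_genes / (length / 1e6)]
  list(windows = win[], per_chromosome = per_chrom[, .(chrom, n_genes, gene_density)])
}

#' Fisher exact gene-family enrichment in a region set
#'
#' For each family, builds the 2x2 table (in-region & family, in-region &
#' other, out-of-region & family, out-of-region & other) over all genes in
#' scope and applies the one-sided (enrichment) Fisher exact test by
#' default. A gene is in-region iff its interval overlaps any region by at
#' least 1 bp. Degenerate tables (family absent, or no out-of-region genes)
#' give p = 1 with a flag. Benjamini-Hochberg q-values are computed jointly
#' across every test in the returned set.
#'
#' @param genes gene table with `family` (see [classify_genes()]).
#' @param regions interval set (e.g. consensus hotspot regions).
#' @param families families to test (default: every non-OTHER family
#'   present in the keyword precedence order).
#' @param region_set label for the output rows (default "hotspots").
#' @param scope "genome" (default) tests against all genes; "chromosome"
#'   runs one family set per chromosome carrying a region, each against
#'   that chromosome's genes only.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return data.table: region_set, family, a, b, c, d, odds_ratio
#'   (sample OR, Inf/0 on zero cells), p_value, q_value, degenerate.
#' @export
fisher_enrichment <- function(genes, regions, families = NULL,
                              region_set = "hotspots",
                              scope = c("genome", "chromosome"),
                              alternative = c("greater", "two.sided")) {
  scope <- match.arg(scope)
  alternative <- match.arg(alternative)
  g <- as.data.table(genes)
  if (nrow(g) == 0L) stop("zero genes")
  if (!"family" %in% names(g)) stop("genes need a family column (classify_genes)")
  regions <- interval_set(regions)
  if (is.null(families)) {
    families <- intersect(names(default_family_keywords()), unique(g$family))
  }

  g <- copy(g)
  g[, keep := FALSE]
  if (nrow(regions)) {
    ir_reg <- .iv_by_chrom(regions)
    for (ch in unique(g$chrom)) {
      if (is.null(ir_reg[[ch]])) next
      gi <- which(g$chrom == ch)
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(start = g$start[gi] + 1, end = g$end[gi]), ir_reg[[ch]])
      g$keep[gi[hit]] <- TRUE
    }
  }
  setnames(g, "keep", "in_region")

  one_scope <- function(gs, label) {
    rbindlist(lapply(families, function(fam) {
      a <- gs[, sum(in_region & family == fam)]
      b <- gs[, sum(in_region & family != fam)]
      cc <- gs[, sum(!in_region & family == fam)]
      d <- gs[, sum(!in_region & family != fam)]
      degenerate <- (a + cc) == 0L || (cc + d) == 0L || (a + b) == 0L
      p <- if (degenerate) 1 else
        fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                    alternative = alternative)$p.value
      or <- if (b == 0L || cc == 0L) {
        if (a == 0L || d == 0L) NaN else Inf
      } else (a * d) / (b * cc)
      data.table(region_set = label, family = fam, a = a, b = b, c = cc, d = d,
                 odds_ratio = or, p_value = p, degenerate = degenerate)
    }))
  }

  res <- if (scope == "genome") {
    one_scope(g, region_set)
  } else {
    chs <- unique(regions$chrom)
    rbindlist(lapply(chs, function(ch) {
      reg_ch <- regions[chrom == ch]
      gch <- copy(g[chrom == ch])
      one_scope(gch, paste0(region_set, ":", ch))
    }))
  }
  res[, q_value := bh_correct(p_value)]
  res[]
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin, named wrapper over `p.adjust(method = "BH")` so the correction
#' applied across a run's family-by-region tests is a single explicit
#' step.
#'
#' @param p numeric p-values.
#' @return q-values in the input order, capped at 1.
#' @export
bh_correct <- function(p) p.adjust(p, method = "BH")
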