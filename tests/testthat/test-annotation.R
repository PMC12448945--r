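gff_fixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "A\tsrc\tgene\t1001\t9000\t.\t+\t.\tID=gA;note=olfactory receptor activity",
    "A\tsrc\tmRNA\t1001\t4000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "A\tsrc\tmRNA\t1001\t6000\t.\t+\t.\tID=gA.t2;Parent=gA",
    "A\tsrc\tgene\t20001\t30000\t.\t-\t.\tID=gB;note=protein kinase activity",
    "B\tsrc\tgene\t501\t2500\t.\t+\t.\tID=gC;note=zinc finger c2h2-type"
  ), path)
  path
}

test_that("GFF3 genes reduce to the longest isoform with gene-line fallback", {
  path <- withr::local_tempfile(fileext = ".gff3")
  gff_fixture(path)
  genes <- read_genes(path)
  expect_equal(nrow(genes), 3L)
  gA <- genes[genes$gene_id == "gA", ]
  expect_equal(c(gA$start, gA$end), c(1000, 6000))  # longest isoform, 0-based
  gB <- genes[genes$gene_id == "gB", ]              # no mRNA children
  expect_equal(c(gB$start, gB$end), c(20000, 30000))
  expect_match(unlist(gA$terms), "olfactory receptor")
})

test_that("gene density counts per Mb and per chromosome", {
  idx <- genome_index(c("A", "B"), c(2e6, 1e6))
  set.seed(99)
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:160),
    chrom = rep(c("A", "B"), c(150, 10)),
    start = c(sample.int(2e6 - 1000, 150), sample.int(1e6 - 1000, 10)),
    family = "OTHER"
  )
  genes$end <- genes$start + 500
  gd <- gene_density(genes, idx)
  expect_equal(gd$per_chromosome[gd$per_chromosome$chrom == "A", ]$gene_density, 75)
  expect_equal(gd$per_chromosome[gd$per_chromosome$chrom == "B", ]$gene_density, 10)
  # window counts sum to the chromosome totals
  wins <- gd$windows
  expect_equal(sum(wins[wins$chrom == "A", ]$n_genes), 150)
  expect_equal(sum(wins[wins$chrom == "B", ]$n_genes), 10)
  # empty gene set
  gd0 <- gene_density(genes[0], idx)
  expect_true(all(gd0$per_chromosome$gene_density == 0))
})

test_that("family classification follows precedence with substring matching", {
  expect_equal(classify_family("olfactory receptor family 51"), "OR")
  # ORs are GPCRs: OR wins over GPCR vocabulary
  expect_equal(classify_family(c("G protein-coupled receptor",
                                 "olfactory receptor activity")), "OR")
  expect_equal(classify_family("MHC class II beta and zinc finger domain"), "MHC")
  expect_equal(classify_family("Zinc Finger C2H2"), "ZNF")
  expect_equal(classify_family("interleukin 6 receptor"), "IMMUNE")
  expect_equal(classify_family("unannotated hypothetical protein"), "OTHER")
  expect_equal(classify_family(character(0)), "OTHER")
  expect_error(classify_family("x", keywords = list()), "empty")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  genes <- data.table::data.table(
    gene_id = sprintf("g%d", 1:8), chrom = "A",
    start = c(100, 200, 300, 400, 5000, 6000, 7000, 8000),
    end = c(150, 250, 350, 450, 5050, 6050, 7050, 8050),
    family = c("OR", "OR", "OR", "OTHER", "OR", "OTHER", "OTHER", "OTHER")
  )
  region <- data.frame(chrom = "A", start = 0, end = 1000)
  res <- fisher_enrichment(genes, region, families = "OR")
  expect_equal(res$a, 3L); expect_equal(res$b, 1L)
  expect_equal(res$c, 1L); expect_equal(res$d, 3L)
  expect_equal(res$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_fisher_greater(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)

  # random tables vs enumeration, N <= 60
  set.seed(4242)
  for (i in 1:40) {
    a <- sample(0:12, 1); b <- sample(0:15, 1)
    cc <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + cc == 0 || a + b == 0 || cc + d == 0) next
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    expect_equal(p, oracle_fisher_greater(a, b, cc, d), tolerance = 1e-9)
  }

  # degenerate tables: family absent everywhere, or no out-of-region genes
  g2 <- data.table::copy(genes)[, family := "OTHER"]
  r2 <- fisher_enrichment(g2, region, families = "OR")
  expect_equal(r2$p_value, 1); expect_true(r2$degenerate)
  r3 <- fisher_enrichment(genes, data.frame(chrom = "A", start = 0, end = 10000),
                          families = "OR")
  expect_equal(r3$p_value, 1); expect_true(r3$degenerate)
  expect_error(fisher_enrichment(genes[0], region), "zero genes")
  # permutation of gene order never changes counts
  perm <- fisher_enrichment(genes[sample(8)], region, families = "OR")
  expect_equal(perm$a, res$a); expect_equal(perm$p_value, res$p_value)
})

test_that("BH correction reproduces the step-up formula", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(99)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    q <- bh_correct(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(q <= 1) && all(q >= p))
    # step-up hand formula
    m <- length(p)
    hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p, ties.method = "first")]
    expect_equal(q, pmin(1, hand))
  }
})
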