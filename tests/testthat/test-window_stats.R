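test_that("windows tile each chromosome exactly once", {
  idx <- genome_index(c("A", "B"), c(120000, 50000))
  win <- make_windows(idx, 50000)
  expect_equal(win[win$chrom == "A", ]$start, c(0, 50000, 100000))
  expect_equal(win[win$chrom == "A", ]$end, c(50000, 100000, 120000))
  expect_equal(nrow(win[win$chrom == "B", ]), 1L)
  # full coverage, no overlap
  for (ch in idx$chrom) {
    w <- win[win$chrom == ch, ]
    expect_equal(sum(w$window_len), idx$length[idx$chrom == ch])
    expect_true(all(w$start[-1] == w$end[-nrow(w)]))
  }
  expect_error(make_windows(idx, 0), "size")
  expect_error(genome_index("A", 0), "positive")
})

test_that("window het and missing counts match a per-site oracle scan", {
  set.seed(4242)
  idx <- genome_index("A", 200000)
  win <- make_windows(idx, 50000)
  pos <- sort(sample.int(200000, 3000))
  sites <- data.table::data.table(
    chrom = "A", pos = pos,
    gt = sample(c(0L, 1L, 2L, NA), 3000, replace = TRUE,
                prob = c(0.5, 0.25, 0.1, 0.15)),
    depth = 20, mq = 60, biallelic = TRUE
  )
  for (absent in c("missing", "hom_ref")) {
    hw <- window_heterozygosity(sites, win, absent = absent)
    orc <- oracle_window_counts(sites, as.data.frame(win), absent = absent)
    expect_equal(hw$n_het, orc$n_het)
    expect_equal(hw$n_missing, orc$n_missing)
    expect_equal(hw$het, hw$n_het / hw$window_len)
  }
  # counting conservation
  hw <- window_heterozygosity(sites, win)
  expect_equal(sum(hw$n_het), sum(sites$gt == 1L, na.rm = TRUE))
  # a window with every position missing
  allmiss <- data.table::data.table(chrom = "A", pos = 1:50000, gt = NA_integer_,
                                    depth = 20, mq = 60, biallelic = TRUE)
  hm <- window_heterozygosity(allmiss, win)
  expect_equal(hm$het[1], 0)
  expect_equal(hm$missing_prop[1], 1.0)
  # out-of-frame site errors
  bad <- data.table::data.table(chrom = "Q", pos = 1, gt = 1L, depth = 1,
                                mq = 1, biallelic = TRUE)
  expect_error(window_heterozygosity(bad, win), "chromosome")
})

test_that("chromosome and genome means are length-weighted totals", {
  win <- window_fixture(c(10, 20, 30))
  expect_equal(chromosome_mean_het(win)$mean_het, 60 / 150000)
  expect_equal(chromosome_mean_het(window_fixture(c(0, 0)))$mean_het, 0)
  # truncated terminal window enters with its true length
  tr <- window_fixture(c(10, 20))
  tr$end[2] <- 80000; tr$window_len[2] <- 30000
  expect_equal(chromosome_mean_het(tr)$mean_het, 30 / 80000)
  # genome mean over two chromosomes; invariant to chromosome order
  winB <- window_fixture(5, chrom = "B")
  both <- rbind(win, winB)
  expect_equal(genome_mean_het(both), 65 / 200000)
  expect_equal(genome_mean_het(both[c(4, 1, 3, 2), ]), 65 / 200000)
  expect_equal(genome_mean_het(win), chromosome_mean_het(win)$mean_het)
})

test_that("normalization is the ratio to the chromosome mean and invertible", {
  win <- rbind(window_fixture(c(10, 20, 30)), window_fixture(c(0, 0), chrom = "B"))
  nw <- normalize_windows(win)
  cm <- chromosome_mean_het(win)
  expect_equal(nw[nw$chrom == "A" & nw$start == 0, ]$norm_het,
               (10 / 50000) / (60 / 150000))
  # multiply back recovers het to representation tolerance
  mean_of <- setNames(cm$mean_het, cm$chrom)
  back <- nw$norm_het * mean_of[nw$chrom]
  expect_equal(unname(back), nw$het, tolerance = 1e-12)
  # degenerate zero-mean chromosome
  expect_true(all(nw[nw$chrom == "B", ]$degenerate))
  expect_true(all(nw[nw$chrom == "B", ]$norm_het == 0))
  # het equal to the mean normalizes to 1
  eq <- window_fixture(c(10, 10))
  expect_equal(normalize_windows(eq)$norm_het, c(1, 1))
})

test_that("macro/micro classification applies the strict length cutoff", {
  idx <- genome_index(c("m1", "m2", "m3"), c(50000001, 50000000, 1000))
  cls <- classify_chromosomes(idx)
  expect_equal(cls$size_class, c("MACRO", "MICRO", "MICRO"))
  # scaled threshold
  cls2 <- classify_chromosomes(genome_index(c("a", "b"), c(2e6, 5e5)),
                               macro_threshold = 1e6)
  expect_equal(cls2$size_class, c("MACRO", "MICRO"))
})

test_that("rank-sum contrast matches exact enumeration and handles degeneracy", {
  r <- compare_macro_micro(c(1, 2, 3, 4), c("MACRO", "MACRO", "MICRO", "MICRO"))
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$direction, 1)
  expect_equal(r$p_value, oracle_ranksum_two_sided(c(3, 4), c(1, 2)))
  # random small instances against full enumeration (n <= 10, no ties)
  set.seed(99)
  for (i in 1:20) {
    nm <- sample(2:5, 1); nn <- sample(2:5, 1)
    vals <- sample(1000, nm + nn) / 7
    cls <- rep(c("MACRO", "MICRO"), c(nm, nn))
    r <- compare_macro_micro(vals, cls)
    expect_equal(r$p_value,
                 oracle_ranksum_two_sided(vals[cls == "MICRO"],
                                          vals[cls == "MACRO"]),
                 tolerance = 1e-12)
  }
  # identical constant values: no evidence either way
  d <- compare_macro_micro(rep(1, 6), rep(c("MACRO", "MICRO"), 3))
  expect_equal(d$p_value, 1)
  expect_equal(d$direction, 0)
  expect_error(compare_macro_micro(1:3, rep("MACRO", 3)), "non-empty")
})
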