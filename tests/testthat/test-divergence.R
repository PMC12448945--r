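aligned_full <- function(len, chrom = "A") {
  data.frame(chrom = chrom, start = 0, end = len)
}

test_that("track validation rejects variants outside aligned intervals", {
  expect_error(
    divergence_track("r", "q",
                     data.frame(chrom = "A", pos = 5000),
                     data.frame(chrom = "A", start = 6000, end = 10000)),
    "outside aligned"
  )
  tr <- divergence_track("r", "q", data.frame(chrom = "A", pos = 6001),
                         data.frame(chrom = "A", start = 6000, end = 10000))
  expect_s3_class(tr, "divergence_track")
})

test_that("window distance uses aligned denominators and masks low coverage", {
  idx <- genome_index("A", 20000)
  tr <- divergence_track("r", "q",
                         data.frame(chrom = "A", pos = sort(sample(1:10000, 14))),
                         aligned_full(20000))
  dw <- window_distance(tr, idx, size = 10000)
  expect_equal(dw$distance[1], 14 / 10000)
  expect_false(any(dw$masked))

  # aligned fraction 0.4 < 0.5 masks the window
  tr2 <- divergence_track("r", "q", data.frame(chrom = "A", pos = 100),
                          data.frame(chrom = "A", start = c(0, 10000),
                                     end = c(4000, 20000)))
  dw2 <- window_distance(tr2, idx, size = 10000)
  expect_true(dw2$masked[1])
  expect_true(is.na(dw2$distance[1]))
  expect_false(dw2$masked[2])
  # raw-length denominator mode
  dw3 <- window_distance(tr2, idx, size = 10000, min_aligned_fraction = 0,
                         raw_length_denominator = TRUE)
  expect_equal(dw3$distance[1], 1 / 10000)
})

test_that("window variant counts match a per-position oracle", {
  set.seed(4242)
  idx <- genome_index("A", 200000)
  pos <- sort(sample.int(200000, 400))
  tr <- divergence_track("r", "q", data.frame(chrom = "A", pos = pos),
                         aligned_full(200000))
  dw <- window_distance(tr, idx, size = 10000)
  orc <- vapply(seq_len(nrow(dw)), function(i)
    sum(pos - 1 >= dw$start[i] & pos - 1 < dw$end[i]), numeric(1))
  expect_equal(as.numeric(dw$n_variants), orc)
  expect_equal(sum(dw$n_variants), length(pos))
  expect_equal(dw$aligned_bp, dw$window_len)
})

test_that("distance is invariant to splitting aligned intervals at window bounds", {
  idx <- genome_index("A", 30000)
  v <- data.frame(chrom = "A", pos = c(500, 15000, 29999))
  one <- divergence_track("r", "q", v, aligned_full(30000))
  split3 <- divergence_track("r", "q", v,
                             data.frame(chrom = "A", start = c(0, 10000, 20000),
                                        end = c(10000, 20000, 30000)))
  expect_equal(window_distance(one, idx), window_distance(split3, idx))
})

test_that("doubling every variant count doubles unmasked distances and means", {
  set.seed(99)
  idx <- genome_index("A", 100000)
  pos <- sort(sample(seq(1, 100000, by = 2), 120))
  tr1 <- divergence_track("r", "q", data.frame(chrom = "A", pos = pos),
                          aligned_full(100000))
  tr2 <- divergence_track("r", "q",
                          data.frame(chrom = "A", pos = sort(c(pos, pos + 1))),
                          aligned_full(100000))
  d1 <- window_distance(tr1, idx); d2 <- window_distance(tr2, idx)
  expect_equal(d2$distance, 2 * d1$distance)
  expect_equal(chromosome_mean_distance(d2)$mean_distance,
               2 * chromosome_mean_distance(d1)$mean_distance)
})

test_that("chromosome means cover unmasked windows only and mirror an oracle recount", {
  idx <- genome_index("A", 30000)
  # middle window poorly aligned -> masked; mean from the other two
  tr <- divergence_track(
    "r", "q",
    data.frame(chrom = "A", pos = c(sort(sample(1:10000, 14)), 12001,
                                    sort(sample(20001:30000, 6)))),
    data.frame(chrom = "A", start = c(0, 12000, 20000),
               end = c(10000, 14000, 30000))
  )
  dw <- window_distance(tr, idx)
  expect_equal(dw$masked, c(FALSE, TRUE, FALSE))
  cm <- chromosome_mean_distance(dw)
  expect_equal(cm$mean_distance, (14 + 6) / 20000)
  # normalization: ratio to chromosome mean, masked stays NA
  nd <- normalize_distance(dw)
  expect_equal(nd$norm_distance[1], (14 / 10000) / ((14 + 6) / 20000))
  expect_true(is.na(nd$norm_distance[2]))
  # all-masked chromosome excluded with a warning
  tr2 <- divergence_track("r", "q", data.frame(chrom = "A", pos = 100),
                          data.frame(chrom = "A", start = 0, end = 1000))
  dw2 <- window_distance(tr2, idx)
  expect_warning(cm2 <- chromosome_mean_distance(dw2), "masked")
  expect_equal(nrow(cm2), 0L)
})
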