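small_config <- function(seed = 77) {
  sim_config(
    species = c("s1", "s2", "s3"),
    chromosomes = data.frame(chrom = c("c1", "c2", "c3"),
                             length = c(8e5, 8e5, 2e5)),
    macro_threshold = 5e5,
    baseline_het = 1e-3, micro_het_multiplier = 2,
    hotspots = data.frame(chrom = "c3", start = 50000, end = 100000,
                          het_multiplier = 8, dist_multiplier = 3,
                          shared = TRUE),
    roh = list(s2 = data.frame(chrom = "c1", start = 1e5, end = 7e5)),
    mask = data.frame(chrom = "c1", start = 0, end = 10000),
    missing_rate = 0.05, micro_dist_multiplier = 2,
    gene_density_macro = 40, gene_density_micro = 80,
    family_sizes = c(MHC = 2, OR = 12, GPCR = 4, ZNF = 4, IMMUNE = 3),
    seed = seed
  )
}

test_that("the scaled default configuration encodes the cohort design", {
  cfg <- scaled_default_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$index$length), 30.5e6)  # 11 x 2 Mb + 17 x 0.5 Mb
  expect_equal(length(cfg$species), 7L)
  expect_equal(nrow(cfg$index), 28L)
  cls <- classify_chromosomes(cfg$index, cfg$macro_threshold)
  expect_equal(sum(cls$size_class == "MACRO"), 11L)
  expect_setequal(cfg$hotspots$chrom, c("13", "14", "24"))
  # planted FROH mirrors a high- and a near-zero-inbreeding individual
  froh_planted <- vapply(cfg$roh, function(r) sum(r$end - r$start), numeric(1)) / 30.5e6
  expect_equal(unname(froh_planted["sp02"]), 0.2279, tolerance = 1e-3)
  expect_equal(unname(froh_planted["sp07"]), 0.0164, tolerance = 1e-3)
  # invalid plans are rejected before anything is generated
  expect_error(sim_config(species = "s", chromosomes = data.frame(chrom = "c", length = 100),
                          macro_threshold = 50, hotspots = data.frame(
                            chrom = "c", start = 50, end = 200,
                            het_multiplier = 2, dist_multiplier = 2, shared = TRUE)),
               "bounds")
  expect_error(sim_config(species = "s", chromosomes = data.frame(chrom = "c", length = 100),
                          macro_threshold = 50, missing_rate = 1.5), "rates")
})

test_that("identical config and seed give byte-identical cohort files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cohort_write(simulate_cohort(small_config()), d1)
  cohort_write(simulate_cohort(small_config()), d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seed changes the draws
  d3 <- withr::local_tempdir()
  cohort_write(simulate_cohort(small_config(seed = 78)), d3)
  expect_false(identical(readLines(file.path(d1, "sites_s1.tsv")),
                         readLines(file.path(d3, "sites_s1.tsv"))))
})

test_that("observed marginal rates stay within 4 standard errors per stratum", {
  cohort <- default_cohort()
  cfg <- cohort$config
  m <- cfg$missing_rate
  check_rate <- function(n_obs, n_bp, p) {
    se <- sqrt(p * (1 - p) / n_bp)
    expect_lt(abs(n_obs / n_bp - p), 4 * se)
  }
  for (sp in c("sp01", "sp02")) {
    s <- cohort$sites[[sp]]
    # background macrochromosome stratum (chrom 8 carries no planted feature)
    bg <- s[s$chrom == "8", ]
    check_rate(sum(bg$gt == 1L, na.rm = TRUE), 2e6, cfg$baseline_het * (1 - m))
    check_rate(sum(is.na(bg$gt)), 2e6, m)
    # microchromosome multiplier (chrom 20, no hotspot)
    mi <- s[s$chrom == "20", ]
    check_rate(sum(mi$gt == 1L, na.rm = TRUE), 5e5,
               cfg$baseline_het * cfg$micro_het_multiplier * (1 - m))
    # hotspot stratum on chromosome 13
    hot <- s[s$chrom == "13" & s$pos > 200000 & s$pos <= 250000, ]
    check_rate(sum(hot$gt == 1L, na.rm = TRUE), 5e4,
               cfg$baseline_het * cfg$micro_het_multiplier * 8 * (1 - m))
  }
  # ROH stratum: het suppressed by the configured factor
  roh_sites <- cohort$sites$sp02[cohort$sites$sp02$chrom == "4", ]
  in_tract <- roh_sites[roh_sites$pos > 1e5 & roh_sites$pos <= 16e5, ]
  check_rate(sum(in_tract$gt == 1L, na.rm = TRUE), 15e5,
             cfg$baseline_het * cfg$roh_het_factor * (1 - m))
  # pairwise track: variant rate inside aligned regions, background macro
  tr <- cohort$tracks$sp03
  al_bp <- iv_total_bp(tr$aligned[tr$aligned$chrom == "8", ])
  nv <- nrow(tr$variants[tr$variants$chrom == "8", ])
  check_rate(nv, al_bp, cfg$baseline_divergence)
})

test_that("the truth ledger round-trips through JSON losslessly", {
  cohort <- simulate_cohort(small_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(cohort$truth, path)
  back <- read_truth(path)
  expect_equal(back$hotspots, as.data.frame(cohort$truth$hotspots))
  expect_equal(back$roh$s2, as.data.frame(cohort$truth$roh$s2))
  expect_equal(back$expected_froh, cohort$truth$expected_froh)
  expect_equal(back$expected_chrom_het, as.data.frame(cohort$truth$expected_chrom_het))
  expect_equal(back$family_counts, cohort$truth$family_counts)
  expect_equal(back$seed, cohort$truth$seed)
})

test_that("windowed heterozygosity tracks the ledger's analytic expectations", {
  res <- default_results()
  cohort <- default_cohort()
  exp_het <- data.table::as.data.table(cohort$truth$expected_chrom_het)
  obs <- res$chrom_summary
  j <- merge(obs, exp_het, by = c("species", "chrom"))
  expect_equal(nrow(j), 28L * 7L)
  # binomial noise at 2 Mb / 0.5 Mb scale: within 15% relative everywhere
  expect_true(all(abs(j$mean_het - j$expected_het) / j$expected_het < 0.15))
})
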