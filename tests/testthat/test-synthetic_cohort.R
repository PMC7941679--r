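small_config <- function(...) {
  synthetic_config(
    n_cases = 5, n_controls = 5,
    chromosomes = c(`1` = 1e6, `2` = 2e6),
    effect = c(`1` = 0.1),
    seed = 101, ...
  )
}

test_that("generator bookkeeping and validation hold", {
  expect_error(synthetic_config(n_cases = 0, n_controls = 5,
                                chromosomes = c(`1` = 1e6)))
  expect_error(synthetic_config(chromosomes = c(`1` = 1e6),
                                effect = c(`9` = 0.1)), "subset")

  sim <- generate_cohort(small_config())
  expect_equal(sum(sim$clinical$is_case), 5)
  expect_equal(nrow(sim$clinical), 10)
  expect_equal(sim$truth$is_case, sim$clinical$is_case)
  expect_true(all(sim$segments$chromosome %in% c("1", "2")))
  expect_true(all(sim$segments$end >= sim$segments$start))
  # barcodes mark every synthetic sample as blood-derived normal
  bc <- parse_sample_barcode(sim$clinical$sample_id)
  expect_true(all(bc$is_blood_normal))
})

test_that("identical config and seed give byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  generate_cohort(small_config(), dir = d1)
  generate_cohort(small_config(), dir = d2)
  generate_cohort(small_config(segment_noise_sd = 0.01 + 1e-9), dir = d3)
  for (f in c("segments.seg", "clinical.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  cfg_b <- small_config(); cfg_b$seed <- 102L
  d4 <- tempfile()
  generate_cohort(cfg_b, dir = d4)
  expect_false(identical(readLines(file.path(d1, "segments.seg")),
                         readLines(file.path(d4, "segments.seg"))))
})

test_that("noiseless single-segment generation recovers log2(cn/2) exactly", {
  cfg <- synthetic_config(n_cases = 10, n_controls = 10,
                          chromosomes = c(`1` = 1e6, `2` = 2e6),
                          effect = c(`1` = 0.2),
                          segment_noise_sd = 0, missing_prob = 0,
                          segments_per_chromosome = 1, seed = 103)
  sim <- generate_cohort(cfg)
  prof <- build_profiles(sim$segments, cfg$chromosomes)
  expect_equal(prof$sample_id, sim$truth$sample_id)
  expect_equal(prof$chr1, log2(sim$truth$cn_chr1 / 2), tolerance = 1e-12)
  expect_equal(prof$chr2, log2(sim$truth$cn_chr2 / 2), tolerance = 1e-12)
  # segmentation must tile each chromosome completely here
  cov <- attr(prof, "coverage")
  expect_equal(cov$chr1, rep(1, 20))
})

test_that("multi-segment noiseless CSLV still equals the latent value", {
  cfg <- synthetic_config(n_cases = 5, n_controls = 5,
                          chromosomes = c(`1` = 1e6),
                          effect = c(`1` = 0.1),
                          segment_noise_sd = 0, missing_prob = 0,
                          segments_per_chromosome = c(2, 5), seed = 104)
  sim <- generate_cohort(cfg)
  prof <- build_profiles(sim$segments, cfg$chromosomes)
  expect_equal(prof$chr1[match(sim$truth$sample_id, prof$sample_id)],
               log2(sim$truth$cn_chr1 / 2), tolerance = 1e-12)
})

test_that("chromosome dropout appears as missing values at the stated rate", {
  cfg <- synthetic_config(n_cases = 150, n_controls = 150,
                          chromosomes = c(`1` = 1e6, `2` = 1e6),
                          effect = NULL, missing_prob = 0.2, seed = 105)
  sim <- generate_cohort(cfg)
  prof <- build_profiles(sim$segments, cfg$chromosomes)
  miss <- mean(is.na(as.matrix(prof[, c("chr1", "chr2")])))
  expect_gt(miss, 0.12)  # binomial(600, 0.2), +/- 5 sd
  expect_lt(miss, 0.28)
})

test_that("the analytic Bayes AUC oracle matches its closed form", {
  expect_equal(analytic_auc(0, 1), 0.5)
  expect_equal(analytic_auc(sqrt(2) * 0.06, 0.06), pnorm(1))
  expect_equal(analytic_auc(100, 0.01), 1)
  expect_equal(analytic_auc(-0.1, 0.05), analytic_auc(0.1, 0.05))
  expect_error(analytic_auc(0.1, 0), "positive")
})

test_that("group CSLV means recover the generator's targets", {
  cfg <- synthetic_config(n_cases = 200, n_controls = 200,
                          chromosomes = c(`17` = 8e7),
                          effect = c(`17` = 0.06),
                          between_subject_sd = 0.06,
                          segment_noise_sd = 0, missing_prob = 0,
                          segments_per_chromosome = 1, seed = 106)
  sim <- generate_cohort(cfg)
  prof <- build_profiles(sim$segments, cfg$chromosomes)
  x <- prof$chr17[match(sim$truth$sample_id, prof$sample_id)]
  for (grp in c(TRUE, FALSE)) {
    v <- x[sim$truth$is_case == grp]
    target <- log2((2 + 0.06 * grp) / 2)
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 3 * se)
  }
})
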