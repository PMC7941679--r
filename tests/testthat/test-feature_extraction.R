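test_that("segment-mean conversions match their closed forms and invert", {
  expect_equal(segment_mean_to_copy_number(0), 2)
  expect_equal(segment_mean_to_copy_number(1), 4)
  expect_equal(round(segment_mean_to_copy_number(0.02), 3), 2.028)
  expect_equal(segment_mean_to_relative_length_change(0), 0)
  expect_equal(segment_mean_to_relative_length_change(-1), -0.5)
  expect_equal(round(segment_mean_to_relative_length_change(0.02), 3), 0.014)

  set.seed(7)
  sm <- rnorm(100)
  expect_equal(copy_number_to_segment_mean(segment_mean_to_copy_number(sm)),
               sm, tolerance = 1e-12)
})

test_that("chromosome-scale length is the length-weighted segment mean", {
  full <- data.frame(start = 1, end = 1000, segment_mean = 0.05)
  r <- chromosome_scale_length(full, 1000)
  expect_equal(r$value, 0.05)
  expect_equal(r$coverage, 1)

  two <- data.frame(start = c(1, 61), end = c(60, 100),
                    segment_mean = c(0.1, -0.1))
  expect_equal(chromosome_scale_length(two, 100)$value, 0.02)

  none <- chromosome_scale_length(two[0, ], 100)
  expect_true(is.na(none$value))
  expect_equal(none$coverage, 0)

  # low coverage suppresses the value but the coverage is still reported
  low <- chromosome_scale_length(full, 1e6, min_coverage = 0.9)
  expect_true(is.na(low$value))
  expect_equal(low$coverage, 0.001)

  overlap <- data.frame(start = c(1, 50), end = c(60, 100),
                        segment_mean = c(0.1, 0.2))
  expect_error(chromosome_scale_length(overlap, 100), "overlapping")
  past <- data.frame(start = 90, end = 120, segment_mean = 0)
  expect_error(chromosome_scale_length(past, 100), "past chromosome length")
})

test_that("probe-count weighting is available behind a flag", {
  seg <- data.frame(start = c(1, 61), end = c(60, 100),
                    segment_mean = c(0.1, -0.1), num_probes = c(10, 30))
  expect_equal(chromosome_scale_length(seg, 100, weight = "probes")$value,
               (10 * 0.1 - 30 * 0.1) / 40)
})

test_that("refining segments with equal means never changes the value", {
  set.seed(11)
  for (rep in 1:20) {
    seg <- random_segments(3, 5000)
    # split each segment at a random interior point, same mean
    split <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      if (s$end - s$start < 2) return(s)
      cut <- sample(seq(s$start, s$end - 1), 1)
      rbind(
        transform(s, end = cut),
        transform(s, start = cut + 1)
      )
    }))
    expect_equal(chromosome_scale_length(split, 5000)$value,
                 chromosome_scale_length(seg, 5000)$value, tolerance = 1e-12)
  }
})

test_that("closed-form CSLV equals the per-base-pair brute-force oracle", {
  set.seed(13)
  for (rep in 1:30) {
    L <- sample(100:10000, 1)
    seg <- random_segments(sample(1:4, 1), L)
    got <- chromosome_scale_length(seg, L)
    want <- per_base_cslv(seg, L)
    expect_equal(got$value, want$value, tolerance = 1e-9)
    expect_equal(got$coverage, want$coverage, tolerance = 1e-12)
  }
})

test_that("profiles are complete, bounded, and input-order invariant", {
  set.seed(17)
  lens <- c(`1` = 4000, `2` = 6000)
  rec <- rbind(
    random_segments(2, 4000, "A", "1"),
    random_segments(3, 6000, "A", "2"),
    random_segments(2, 4000, "B", "1")
    # B has no chromosome-2 segments
  )
  prof <- build_profiles(rec, lens)
  expect_equal(names(prof), c("sample_id", "chr1", "chr2"))
  expect_equal(prof$sample_id, c("A", "B"))
  expect_true(is.na(prof$chr2[prof$sample_id == "B"]))

  # weighted-mean boundedness
  a1 <- rec$segment_mean[rec$sample_id == "A" & rec$chromosome == "1"]
  expect_gte(prof$chr1[1], min(a1))
  expect_lte(prof$chr1[1], max(a1))

  perm <- rec[sample(nrow(rec)), ]
  prof2 <- build_profiles(perm, lens)
  prof2 <- prof2[match(prof$sample_id, prof2$sample_id), ]
  expect_equal(prof2$chr1, prof$chr1)
  expect_equal(prof2$chr2, prof$chr2)

  # coverage attribute: zero coverage for the missing chromosome
  cov <- attr(prof, "coverage")
  expect_equal(cov$chr2[cov$sample_id == "B"], 0)
})

test_that("profile matrices round-trip through their TSV form", {
  set.seed(19)
  lens <- c(`1` = 4000, `2` = 6000)
  rec <- rbind(random_segments(2, 4000, "A", "1"),
               random_segments(2, 6000, "A", "2"),
               random_segments(2, 4000, "B", "1"))
  rec$segment_mean <- rnorm(nrow(rec))
  prof <- build_profiles(rec, lens)
  path <- tempfile(fileext = ".tsv")
  write_profiles(prof, path)
  back <- read_profiles(path)
  expect_equal(back, prof, ignore_attr = TRUE)
})
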