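seg_header <- "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean"

test_that("well-formed masked segment files parse with fields and order intact", {
  path <- write_lines_fixture(c(
    seg_header,
    "TCGA-04-1331-10A\t1\t100\t5000\t40\t0.0213",
    "TCGA-04-1331-10A\tchr2\t1\t900\t12\t-0.104",
    "TCGA-04-1332-10A\tX\t50\t60\t\t1.5"
  ))
  rec <- read_segment_file(path, "gdc_masked")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$sample_id[1], "TCGA-04-1331-10A")
  expect_equal(rec$chromosome, c("1", "2", "X"))  # chr prefix stripped
  expect_equal(rec$start, c(100, 1, 50))
  expect_equal(rec$end, c(5000, 900, 60))
  expect_true(is.na(rec$num_probes[3]))
  expect_equal(rec$segment_mean, c(0.0213, -0.104, 1.5))

  # column order insensitivity and trailing blank lines
  path2 <- write_lines_fixture(c(
    "Segment_Mean\tEnd\tStart\tChromosome\tSample\tNum_Probes",
    "0.0213\t5000\t100\t1\tTCGA-04-1331-10A\t40",
    "", ""
  ))
  rec2 <- read_segment_file(path2, "gdc_masked")
  expect_equal(rec2$segment_mean, 0.0213)
  expect_equal(rec2$start, 100)
})

test_that("header and row errors are loud, named, and count-accurate", {
  no_mean <- write_lines_fixture(c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes",
    "S1\t1\t1\t10\t5"
  ))
  expect_error(read_segment_file(no_mean, "gdc_masked"), "Segment_Mean")

  bad_num <- write_lines_fixture(c(
    seg_header,
    "S1\t1\t1\t10\t5\t0.1",
    "S1\t2\tabc\t10\t5\t0.1"
  ))
  expect_error(read_segment_file(bad_num, "gdc_masked"), "line 3")
  expect_warning(rec <- read_segment_file(bad_num, "gdc_masked", lenient = TRUE),
                 "skipped")
  expect_equal(nrow(rec), 1)
  rej <- attr(rec, "rejected")
  expect_equal(nrow(rec) + sum(rej), 2)  # accepted + rejected = data rows

  inverted <- write_lines_fixture(c(seg_header, "S1\t1\t100\t10\t5\t0.1"))
  expect_error(read_segment_file(inverted, "gdc_masked"), "end < start")
})

test_that("masked dialect rejects chromosome-Y rows with a reported count", {
  path <- write_lines_fixture(c(
    seg_header,
    "S1\t1\t1\t10\t5\t0.1",
    "S1\tY\t1\t10\t5\t0.1",
    "S1\tchrY\t20\t30\t5\t0.2"
  ))
  expect_message(rec <- read_segment_file(path, "gdc_masked"), "2 chromosome-Y")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "rejected")[["chromosome_y"]], 2L)
  expect_equal(nrow(rec) + sum(attr(rec, "rejected")), 3)
})

test_that("TCGA barcodes split into patient and sample-type fields", {
  b <- parse_sample_barcode(c("TCGA-04-1331-10A", "TCGA-04-1331-01A"))
  expect_equal(b$patient_id, rep("TCGA-04-1331", 2))
  expect_equal(b$sample_type_code, c("10", "01"))
  expect_equal(b$is_blood_normal, c(TRUE, FALSE))
  expect_error(parse_sample_barcode("TCGA-04"), "malformed")
})

test_that("clinical tables label cases, reject duplicates, tolerate emptiness", {
  path <- write_lines_fixture(c(
    "sample_id\tgender\tdiagnosis\tage\trace",
    "S1\tFemale\tovarian serous carcinoma\t61\twhite",
    "S2\tfemale\tovarian serous carcinoma\t55\tblack",
    "S3\tF\tnormal\t58\twhite",
    "S4\tmale\tcolon adenocarcinoma\t\t",
    "S5\t\tnormal\t44\tasian"
  ))
  clin <- read_clinical_table(path, "ovarian serous carcinoma")
  expect_equal(sum(clin$is_case), 2)
  expect_equal(clin$sex, c("female", "female", "female", "male", "unknown"))
  expect_true(is.na(clin$age_years[4]))

  dup <- write_lines_fixture(c(
    "sample_id\tsex\tdiagnosis", "S1\tfemale\tnormal", "S1\tfemale\tnormal"
  ))
  expect_error(read_clinical_table(dup, "x"), "duplicate.*S1")

  empty <- write_lines_fixture("sample_id\tsex\tdiagnosis")
  expect_warning(clin0 <- read_clinical_table(empty, "x"), "no data rows")
  expect_equal(nrow(clin0), 0)
})

test_that("write-then-read is the identity on valid segment collections", {
  set.seed(42)
  rec <- do.call(rbind, lapply(1:5, function(i) {
    r <- random_segments(2, 10000, sample_id = paste0("S", i),
                         chromosome = as.character(i))
    r$segment_mean <- rnorm(2)  # full-precision doubles
    r
  }))
  for (dialect in c("gdc_masked", "generic_seg")) {
    path <- tempfile(fileext = ".seg")
    write_segment_file(rec, path, dialect)
    back <- read_segment_file(path, dialect)
    expect_equal(back, rec, ignore_attr = TRUE)
  }

  # empty collection -> header-only file
  path <- tempfile(fileext = ".seg")
  write_segment_file(rec[0, ], path, "gdc_masked")
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_segment_file(path, "gdc_masked")), 0)

  # Y refused under the masked dialect
  recy <- rec
  recy$chromosome[1] <- "Y"
  expect_error(write_segment_file(recy, tempfile(), "gdc_masked"), "Y")
})
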