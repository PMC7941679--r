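#' Read a copy-number segment table
#'
#' Parses a tab-separated segment table into a validated segment data frame.
#' Two dialects are supported: `"gdc_masked"`, the GDC "masked copy number
#' segment" layout (columns `Sample`/`GDC_Aliquot`, `Chromosome`, `Start`,
#' `End`, `Num_Probes`, `Segment_Mean`), and `"generic_seg"`, the classic
#' six-column SEG layout (`ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`). Header matching is case-insensitive and order-insensitive.
#'
#' Coordinates are 1-based and inclusive on both ends (the SEG convention)
#' and are never shifted internally. Chromosome labels are normalized by
#' stripping any `"chr"` prefix; the accepted set is `1..22` and `X`. Under
#' the `gdc_masked` dialect, rows on chromosome `Y` are dropped (the masking
#' process that produces this dialect removes the Y chromosome); the number
#' dropped is reported via the `"rejected"` attribute and a message.
#'
#' @param path Path to a tab-separated segment file with a header row.
#' @param dialect `"gdc_masked"` or `"generic_seg"`.
#' @param lenient If `FALSE` (default) any malformed row aborts the read with
#'   a row-level error carrying its line number. If `TRUE`, malformed rows
#'   are skipped with a warning and tallied in the `"rejected"` attribute.
#' @return A `data.frame` with columns `sample_id`, `chromosome`, `start`,
#'   `end`, `num_probes`, `segment_mean`, one row per accepted segment, in
#'   file order. Attribute `"rejected"` is a named integer vector of dropped
#'   row counts by reason; rejected + accepted rows equal the file's data
#'   rows.
#' @seealso [write_segment_file()] for the inverse operation.
#' @export
read_segment_file <- function(path, dialect = c("gdc_masked", "generic_seg"),
                              lenient = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA", "N/A"))
  syn <- segment_column_synonyms(dialect)
  cols <- vapply(names(syn), function(field) {
    match_column(names(raw), syn[[field]]$keys, syn[[field]]$label)
  }, integer(1))

  n <- nrow(raw)
  rejected <- c(bad_numeric = 0L, bad_interval = 0L, bad_chromosome = 0L,
                chromosome_y = 0L)
  if (n == 0) {
    out <- empty_segment_frame()
    attr(out, "rejected") <- rejected
    return(out)
  }

  sample_id <- raw[[cols[["sample_id"]]]]
  chromosome <- normalize_chromosome(raw[[cols[["chromosome"]]]])
  start <- suppressWarnings(as.numeric(raw[[cols[["start"]]]]))
  end <- suppressWarnings(as.numeric(raw[[cols[["end"]]]]))
  probes_raw <- raw[[cols[["num_probes"]]]]
  num_probes <- suppressWarnings(as.numeric(probes_raw))
  segment_mean <- suppressWarnings(as.numeric(raw[[cols[["segment_mean"]]]]))

  # Data row i sits on physical line i + 1 (header is line 1).
  line_no <- seq_len(n) + 1L

  bad_num <- (is.na(start) | is.na(end) | is.na(segment_mean)) |
    (!is.na(probes_raw) & is.na(num_probes))
  bad_int <- !bad_num & (end < start | start < 1)
  is_y <- chromosome == "Y"
  bad_chrom <- !is_y & !chromosome %in% c(as.character(1:22), "X")

  fail <- function(mask, what) {
    if (!any(mask)) return(invisible())
    if (lenient) {
      warning(sum(mask), " row(s) skipped (", what, "), e.g. line ",
              line_no[which(mask)[1]], call. = FALSE)
    } else {
      stop(what, " at line ", line_no[which(mask)[1]],
           if (sum(mask) > 1) paste0(" (and ", sum(mask) - 1L, " more row(s))"),
           call. = FALSE)
    }
  }
  fail(bad_num, "non-numeric start/end/segment_mean")
  fail(bad_int, "end < start or start < 1")
  if (dialect == "generic_seg") fail(is_y | bad_chrom, "unrecognized chromosome label")

  rejected["bad_numeric"] <- sum(bad_num)
  rejected["bad_interval"] <- sum(bad_int)
  if (dialect == "gdc_masked") {
    fail(bad_chrom, "unrecognized chromosome label")
    rejected["bad_chromosome"] <- sum(bad_chrom)
    rejected["chromosome_y"] <- sum(is_y)
    if (any(is_y)) {
      message(sum(is_y), " chromosome-Y row(s) rejected (masked dialect)")
    }
  } else {
    rejected["bad_chromosome"] <- sum(is_y | bad_chrom)
  }

  keep <- !(bad_num | bad_int | bad_chrom | is_y)
  out <- data.frame(
    sample_id = sample_id[keep],
    chromosome = chromosome[keep],
    start = start[keep],
    end = end[keep],
    num_probes = num_probes[keep],
    segment_mean = segment_mean[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

segment_column_synonyms <- function(dialect) {
  if (dialect == "gdc_masked") {
    list(
      sample_id = list(keys = c("sample", "sampleid", "gdcaliquot", "samplebarcode", "aliquotbarcode"), label = "Sample"),
      chromosome = list(keys = "chromosome", label = "Chromosome"),
      start = list(keys = "start", label = "Start"),
      end = list(keys = "end", label = "End"),
      num_probes = list(keys = "numprobes", label = "Num_Probes"),
      segment_mean = list(keys = "segmentmean", label = "Segment_Mean")
    )
  } else {
    list(
      sample_id = list(keys = c("id", "sample", "sampleid"), label = "ID"),
      chromosome = list(keys = c("chrom", "chromosome", "chr"), label = "chrom"),
      start = list(keys = c("locstart", "start", "chromstart"), label = "loc.start"),
      end = list(keys = c("locend", "end", "chromend"), label = "loc.end"),
      num_probes = list(keys = c("nummark", "numprobes"), label = "num.mark"),
      segment_mean = list(keys = c("segmean", "segmentmean"), label = "seg.mean")
    )
  }
}

normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
  toupper(x)
}

empty_segment_frame <- function() {
  data.frame(sample_id = character(), chromosome = character(),
             start = numeric(), end = numeric(), num_probes = numeric(),
             segment_mean = numeric(), stringsAsFactors = FALSE)
}

#' Write a copy-number segment table
#'
#' Inverse of [read_segment_file()]: writes a segment data frame in the
#' requested dialect such that reading the file back reproduces every field.
#' Missing `num_probes` values are written as empty cells. Under the
#' `gdc_masked` dialect, chromosome-Y records are refused (the dialect
#' excludes Y by construction).
#'
#' @param records Segment data frame as returned by [read_segment_file()].
#' @param path Output path.
#' @param dialect `"gdc_masked"` or `"generic_seg"`.
#' @return `path`, invisibly.
#' @export
write_segment_file <- function(records, path,
                               dialect = c("gdc_masked", "generic_seg")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("sample_id", "chromosome", "start", "end",
                  "num_probes", "segment_mean") %in% names(records)))
  if (dialect == "gdc_masked" && any(records$chromosome == "Y")) {
    stop("chromosome-Y records cannot be written in the gdc_masked dialect",
         call. = FALSE)
  }
  header <- if (dialect == "gdc_masked") {
    c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  } else {
    c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  }
  out <- data.frame(
    records$sample_id, records$chromosome,
    format_full(records$start), format_full(records$end),
    ifelse(is.na(records$num_probes), "", format_full(records$num_probes)),
    format_full(records$segment_mean),
    stringsAsFactors = FALSE
  )
  names(out) <- header
  write_tsv_plain(out, path)
  invisible(path)
}

#' Parse TCGA-style sample barcodes
#'
#' Splits barcodes of the form `project-TSS-participant-sample[vial]...`
#' (e.g. `"TCGA-04-1331-10A"`) into the patient identifier and the two-digit
#' sample-type code. Code `"10"` denotes a blood-derived normal sample, i.e.
#' germ line DNA.
#'
#' @param barcode Character vector of barcodes.
#' @return A `data.frame` with columns `barcode`, `patient_id`,
#'   `sample_type_code`, `is_blood_normal`.
#' @export
#' @examples
#' parse_sample_barcode("TCGA-04-1331-10A")
parse_sample_barcode <- function(barcode) {
  parts <- strsplit(as.character(barcode), "-", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed barcode (fewer than four dash-separated fields): ",
         paste(barcode[nf < 4], collapse = ", "), call. = FALSE)
  }
  patient_id <- vapply(parts, function(p) paste(p[1:3], collapse = "-"), character(1))
  sample_field <- vapply(parts, function(p) p[4], character(1))
  code <- substr(sample_field, 1, 2)
  if (any(!grepl("^[0-9]{2}", sample_field))) {
    stop("malformed sample-type field in barcode: ",
         paste(barcode[!grepl("^[0-9]{2}", sample_field)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(barcode = as.character(barcode), patient_id = patient_id,
             sample_type_code = code, is_blood_normal = code == "10",
             stringsAsFactors = FALSE)
}

#' Read a clinical table
#'
#' Reads a tab- or comma-separated clinical table with at least sample
#' identifier, sex and diagnosis columns (age and race are optional) and
#' labels each record as case or control by matching the diagnosis against
#' `case_label`.
#'
#' @param path Path to the clinical table. Files ending in `.csv` are read as
#'   comma-separated, anything else as tab-separated.
#' @param case_label Diagnosis string identifying cases (exact match by
#'   default).
#' @param ignore_case Match the diagnosis label case-insensitively.
#' @return A `data.frame` with columns `sample_id`, `patient_id`, `sex`
#'   (`"female"`, `"male"` or `"unknown"`), `diagnosis`, `is_case`,
#'   `age_years`, `race`. Unknown sex is preserved, not dropped; cohort
#'   filtering happens later in [assemble_cohort()].
#' @export
read_clinical_table <- function(path, case_label, ignore_case = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA", "N/A"))
  id_col <- match_column(names(raw), c("sampleid", "sample", "samplebarcode", "barcode"), "sample_id")
  sex_col <- match_column(names(raw), c("sex", "gender"), "sex")
  dx_col <- match_column(names(raw), c("diagnosis", "disease", "ovariancancerstatus", "status"), "diagnosis")
  age_col <- match_column(names(raw), c("ageyears", "age", "ageatdiagnosis"), "age", required = FALSE)
  race_col <- match_column(names(raw), c("race", "ethnicity"), "race", required = FALSE)
  pid_col <- match_column(names(raw), c("patientid", "participant", "casebarcode"), "patient_id", required = FALSE)

  if (nrow(raw) == 0) {
    warning("clinical table has no data rows", call. = FALSE)
    return(data.frame(sample_id = character(), patient_id = character(),
                      sex = character(), diagnosis = character(),
                      is_case = logical(), age_years = numeric(),
                      race = character(), stringsAsFactors = FALSE))
  }

  sample_id <- raw[[id_col]]
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id in clinical table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  patient_id <- if (!is.na(pid_col)) {
    raw[[pid_col]]
  } else {
    # Fall back to the barcode convention; non-barcode identifiers map to
    # themselves.
    vapply(sample_id, function(s) {
      p <- strsplit(s, "-", fixed = TRUE)[[1]]
      if (length(p) >= 4) paste(p[1:3], collapse = "-") else s
    }, character(1), USE.NAMES = FALSE)
  }

  sex <- tolower(trimws(raw[[sex_col]]))
  sex <- ifelse(sex %in% c("female", "f"), "female",
                ifelse(sex %in% c("male", "m"), "male", "unknown"))
  sex[is.na(sex)] <- "unknown"

  diagnosis <- raw[[dx_col]]
  is_case <- if (ignore_case) {
    !is.na(diagnosis) & tolower(diagnosis) == tolower(case_label)
  } else {
    !is.na(diagnosis) & diagnosis == case_label
  }

  data.frame(
    sample_id = sample_id,
    patient_id = patient_id,
    sex = sex,
    diagnosis = diagnosis,
    is_case = is_case,
    age_years = if (!is.na(age_col)) suppressWarnings(as.numeric(raw[[age_col]])) else NA_real_,
    race = if (!is.na(race_col)) raw[[race_col]] else NA_character_,
    stringsAsFactors = FALSE
  )
}
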