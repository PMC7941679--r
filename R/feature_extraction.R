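#' Segment-mean unit conversions
#'
#' A segment mean is the log base 2 of one-half the copy number, so a diploid
#' region has segment mean 0. `segment_mean_to_copy_number()` inverts this to
#' an absolute copy number (2 * 2^sm); `copy_number_to_segment_mean()` is its
#' inverse; `segment_mean_to_relative_length_change()` expresses the same
#' quantity as a signed fractional deviation from the diploid chromosome
#' length (2^sm - 1), e.g. a segment mean of 0.02 corresponds to 2.028 copies,
#' about 1.4% longer than the average chromosome.
#'
#' @param segment_mean Numeric vector of segment means (log2 scale).
#' @param copy_number Numeric vector of copy numbers (>= 0).
#' @return Numeric vector of the converted quantity.
#' @export
segment_mean_to_copy_number <- function(segment_mean) {
  stopifnot(is.numeric(segment_mean))
  2 * 2^segment_mean
}

#' @rdname segment_mean_to_copy_number
#' @export
copy_number_to_segment_mean <- function(copy_number) {
  stopifnot(is.numeric(copy_number), all(copy_number >= 0, na.rm = TRUE))
  log2(copy_number / 2)
}

#' @rdname segment_mean_to_copy_number
#' @export
segment_mean_to_relative_length_change <- function(segment_mean) {
  stopifnot(is.numeric(segment_mean))
  2^segment_mean - 1
}

#' GRCh38 chromosome lengths
#'
#' Total lengths in base pairs of the GRCh38 primary-assembly chromosomes,
#' shipped so that coverage fractions can be computed without downloads. The
#' default feature set is the 22 autosomes; X can be included by flag.
#'
#' @param include_x Include chromosome X.
#' @return Named numeric vector of lengths (names `"1"`..`"22"`, optionally
#'   `"X"`).
#' @export
grch38_chromosome_lengths <- function(include_x = FALSE) {
  len <- c(
    `1` = 248956422, `2` = 242193529, `3` = 198295559, `4` = 190214555,
    `5` = 181538259, `6` = 170805979, `7` = 159345973, `8` = 145138636,
    `9` = 138394717, `10` = 133797422, `11` = 135086622, `12` = 133275309,
    `13` = 114364328, `14` = 107043718, `15` = 101991189, `16` = 90338345,
    `17` = 83257441, `18` = 80373285, `19` = 58617616, `20` = 64444167,
    `21` = 46709983, `22` = 50818468, X = 156040895
  )
  if (include_x) len else len[as.character(1:22)]
}

#' Chromosome-scale length for one sample and chromosome
#'
#' Aggregates the segment means reported for one chromosome of one sample
#' into a single chromosome-scale length variation (CSLV) value: the
#' length-weighted mean of the segment means, together with the fraction of
#' the chromosome covered by the reported segments. The weighted mean is the
#' unique aggregator that is invariant under refining a segment into
#' contiguous sub-segments with the same mean. Unreported regions contribute
#' nothing (they are not imputed as diploid); when nothing is reported, or
#' coverage falls below `min_coverage`, the value is `NA`.
#'
#' @param segments Data frame with columns `start`, `end`, `segment_mean`
#'   (and `num_probes` if probe weighting is requested), all on one
#'   chromosome of one sample. Segments must not overlap.
#' @param chrom_length Chromosome length in base pairs.
#' @param min_coverage Minimum covered fraction for the value to be reported.
#' @param weight `"length"` (default) weights each segment mean by its span
#'   in base pairs; `"probes"` weights by `num_probes`.
#' @return List with elements `value` (CSLV, or `NA` if missing) and
#'   `coverage` (fraction of `chrom_length` covered).
#' @export
chromosome_scale_length <- function(segments, chrom_length, min_coverage = 0,
                                    weight = c("length", "probes")) {
  weight <- match.arg(weight)
  stopifnot(is.numeric(chrom_length), chrom_length > 0)
  if (nrow(segments) == 0) {
    return(list(value = NA_real_, coverage = 0))
  }
  o <- order(segments$start, segments$end)
  s <- segments[o, , drop = FALSE]
  if (any(s$end > chrom_length)) {
    bad <- which(s$end > chrom_length)[1]
    stop("segment [", s$start[bad], ", ", s$end[bad],
         "] extends past chromosome length ", chrom_length, call. = FALSE)
  }
  if (nrow(s) > 1) {
    ov <- which(s$start[-1] <= s$end[-nrow(s)])
    if (length(ov) > 0) {
      i <- ov[1]
      stop("overlapping segments: [", s$start[i], ", ", s$end[i], "] and [",
           s$start[i + 1], ", ", s$end[i + 1], "]", call. = FALSE)
    }
  }
  span <- s$end - s$start + 1
  w <- if (weight == "length") span else s$num_probes
  coverage <- sum(span) / chrom_length
  value <- if (coverage < min_coverage || sum(w) <= 0) {
    NA_real_
  } else {
    sum(w * s$segment_mean) / sum(w)
  }
  list(value = value, coverage = coverage)
}

#' Build per-sample chromosome profiles
#'
#' Converts a segment table into one row per sample of per-chromosome CSLV
#' values, with explicit missingness: a chromosome with no reported segments
#' (or coverage below `min_coverage`) is `NA`. Input row order does not
#' affect the result.
#'
#' @param records Segment data frame from [read_segment_file()] (or
#'   [generate_cohort()]).
#' @param lengths Named chromosome length table; defaults to
#'   [grch38_chromosome_lengths()]. Its names define the feature columns.
#' @param min_coverage Per-chromosome minimum covered fraction below which
#'   the CSLV value is reported as missing.
#' @param weight Passed to [chromosome_scale_length()].
#' @return A `data.frame` with column `sample_id` followed by one numeric
#'   CSLV column per chromosome, named `chr1`, `chr2`, ... Samples are in
#'   order of first appearance. The matching coverage fractions are attached
#'   as the `"coverage"` attribute (a data frame of the same shape).
#' @export
build_profiles <- function(records, lengths = grch38_chromosome_lengths(),
                           min_coverage = 0, weight = c("length", "probes")) {
  weight <- match.arg(weight)
  chroms <- names(lengths)
  stopifnot(!is.null(chroms), all(lengths > 0))
  samples <- unique(records$sample_id)

  keep <- records$chromosome %in% chroms
  rec <- records[keep, , drop = FALSE]

  cslv <- matrix(NA_real_, nrow = length(samples), ncol = length(chroms),
                 dimnames = list(samples, chroms))
  cov <- matrix(0, nrow = length(samples), ncol = length(chroms),
                dimnames = list(samples, chroms))

  if (nrow(rec) > 0) {
    grp <- split(seq_len(nrow(rec)),
                 list(sample = factor(rec$sample_id, levels = samples),
                      chrom = factor(rec$chromosome, levels = chroms)),
                 drop = TRUE)
    for (g in names(grp)) {
      idx <- grp[[g]]
      sm <- rec$sample_id[idx[1]]
      ch <- rec$chromosome[idx[1]]
      res <- tryCatch(
        chromosome_scale_length(rec[idx, , drop = FALSE], lengths[[ch]],
                                min_coverage = min_coverage, weight = weight),
        error = function(e) {
          stop("sample ", sm, ", chromosome ", ch, ": ", conditionMessage(e),
               call. = FALSE)
        }
      )
      cslv[sm, ch] <- res$value
      cov[sm, ch] <- res$coverage
    }
  }

  out <- data.frame(sample_id = samples, cslv, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c("sample_id", paste0("chr", chroms))
  rownames(out) <- NULL
  covdf <- data.frame(sample_id = samples, cov, stringsAsFactors = FALSE,
                      check.names = FALSE)
  names(covdf) <- names(out)
  rownames(covdf) <- NULL
  attr(out, "coverage") <- covdf
  out
}

#' Read/write profile matrices
#'
#' Profiles are exchanged as a tab-separated matrix: one row per sample, a
#' `sample_id` column followed by per-chromosome CSLV columns, empty cells
#' for missing values.
#'
#' @param profiles Profile data frame from [build_profiles()].
#' @param path File path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns the profile data frame.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_full)
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- read_tsv_plain(path)
  if (!"sample_id" %in% names(df)) {
    stop("profile table lacks a sample_id column", call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  for (cn in setdiff(names(df), "sample_id")) df[[cn]] <- as.numeric(df[[cn]])
  df
}
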