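#' Configuration for the synthetic copy-number cohort generator
#'
#' The generator emulates the statistical structure a chromosome-scale
#' length-variation analysis assumes in germline SNP-array copy-number data:
#' each subject carries a latent per-chromosome copy number near 2, cases are
#' shifted on specific chromosomes, chromosomes are reported as a few
#' segments whose means carry measurement noise, and whole chromosomes
#' occasionally drop out (coded as missing downstream).
#'
#' For subject i and chromosome c the latent copy number is
#' `cn = 2 + is_case * effect_c + e`, with `e ~ N(0, between_subject_sd)`
#' truncated below at 0.1. The chromosome is split at uniform random
#' breakpoints into `k` segments (`k` drawn uniformly over
#' `segments_per_chromosome`), each reported with segment mean
#' `log2(cn / 2) + n`, `n ~ N(0, segment_noise_sd)`; with probability
#' `missing_prob` the whole chromosome is withheld for that subject.
#'
#' Defaults mirror the ovarian-cancer case-control design this package
#' targets: 414 cases vs 4225 controls, all female, with case shifts on
#' chromosomes 17 and 4 (the larger on 17).
#'
#' @param n_cases,n_controls Positive group sizes.
#' @param chromosomes Named vector of chromosome lengths in base pairs.
#' @param effect Named vector of case mean shifts in copy-number units
#'   (e.g. `c("17" = 0.06)` adds 0.06 copies to cases on chromosome 17);
#'   names must be a subset of `names(chromosomes)`.
#' @param between_subject_sd Between-subject SD of the latent copy number,
#'   copy-number units.
#' @param segment_noise_sd SD of per-segment measurement noise on the
#'   segment-mean (log2) scale.
#' @param segments_per_chromosome Integer range (length 1 or 2) for the
#'   number of segments per chromosome.
#' @param missing_prob Per-subject, per-chromosome dropout probability.
#' @param seed Integer seed; the generator is byte-stable given the seed.
#' @param case_label,control_label Diagnosis strings written to the clinical
#'   table.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 414, n_controls = 4225,
                             chromosomes = grch38_chromosome_lengths(),
                             effect = c(`17` = 0.06, `4` = 0.03),
                             between_subject_sd = 0.06,
                             segment_noise_sd = 0.01,
                             segments_per_chromosome = c(1, 4),
                             missing_prob = 0.01,
                             seed = 20210309,
                             case_label = "ovarian serous carcinoma",
                             control_label = "normal") {
  stopifnot(
    n_cases >= 1, n_controls >= 1,
    length(chromosomes) >= 1, all(chromosomes > 0), !is.null(names(chromosomes)),
    between_subject_sd >= 0, segment_noise_sd >= 0,
    missing_prob >= 0, missing_prob <= 1,
    length(segments_per_chromosome) %in% c(1, 2),
    all(segments_per_chromosome >= 1)
  )
  effect <- effect[!is.na(effect)]
  if (length(effect) > 0 && !all(names(effect) %in% names(chromosomes))) {
    stop("effect names must be a subset of chromosome names: ",
         paste(setdiff(names(effect), names(chromosomes)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    chromosomes = chromosomes, effect = effect,
    between_subject_sd = between_subject_sd,
    segment_noise_sd = segment_noise_sd,
    segments_per_chromosome = as.integer(rep(segments_per_chromosome, length.out = 2)),
    missing_prob = missing_prob, seed = as.integer(seed),
    case_label = case_label, control_label = control_label
  ), class = "synthetic_config")
}

#' Generate a synthetic case-control copy-number cohort
#'
#' Draws a cohort under the generative model described in
#' [synthetic_config()] and returns the same artefacts a real study would
#' provide: a segment table in the masked-SEG dialect, a clinical table, and
#' the latent truth (per-subject copy numbers) for validation. Sample
#' identifiers follow the TCGA barcode convention with sample-type code
#' `"10"` (blood-derived normal), so barcode-based germline selection works
#' on synthetic data too.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, `segments.seg` (gdc_masked
#'   dialect), `clinical.tsv` and `truth.tsv` are written there.
#' @return List with `segments` (segment data frame), `clinical` (clinical
#'   data frame in [read_clinical_table()] layout), `truth` (data frame:
#'   `sample_id`, `is_case`, latent `cn_chr*` columns), and `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_cases + config$n_controls
    is_case <- rep(c(TRUE, FALSE), c(config$n_cases, config$n_controls))
    sample_id <- sprintf("SYN-%02d-%04d-10A", seq_len(n) %% 97, seq_len(n))
    chroms <- names(config$chromosomes)

    # latent copy numbers, truncated below to stay biologically sensible
    eff <- stats::setNames(numeric(length(chroms)), chroms)
    if (length(config$effect) > 0) eff[names(config$effect)] <- config$effect
    cn <- matrix(
      2 + rep(is_case, times = length(chroms)) * rep(eff, each = n) +
        stats::rnorm(n * length(chroms), 0, config$between_subject_sd),
      nrow = n, dimnames = list(sample_id, chroms)
    )
    cn <- pmax(cn, 0.1)

    seg_list <- vector("list", length(chroms))
    kr <- config$segments_per_chromosome
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      L <- config$chromosomes[[ch]]
      present <- stats::runif(n) >= config$missing_prob
      idx <- which(present)
      if (length(idx) == 0) next
      k <- if (kr[1] == kr[2]) rep(kr[1], length(idx)) else
        sample(seq(kr[1], kr[2]), length(idx), replace = TRUE)
      # vectorized breakpoint draw: k-1 interior cuts per present subject
      ncuts <- k - 1L
      who <- rep(seq_along(idx), ncuts)
      cuts <- floor(stats::runif(sum(ncuts), 1, L))
      o <- order(who, cuts)
      who <- who[o]; cuts <- cuts[o]
      starts <- ends <- integer(0)
      sub <- integer(0)
      # boundaries per subject: [1, c1], [c1+1, c2], ..., [c_{k-1}+1, L]
      for (j in seq_along(idx)) {
        cj <- cuts[who == j]
        st <- c(1, cj + 1)
        en <- c(cj, L)
        ok <- st <= en  # duplicate cuts would create empty segments
        starts <- c(starts, st[ok]); ends <- c(ends, en[ok])
        sub <- c(sub, rep(idx[j], sum(ok)))
      }
      sm <- log2(cn[sub, ci] / 2) +
        stats::rnorm(length(sub), 0, config$segment_noise_sd)
      seg_list[[ci]] <- data.frame(
        sample_id = sample_id[sub], chromosome = ch,
        start = as.numeric(starts), end = as.numeric(ends),
        num_probes = pmax(1, round((ends - starts + 1) / 5000)),
        segment_mean = sm, stringsAsFactors = FALSE
      )
    }
    segments <- do.call(rbind, seg_list[!vapply(seg_list, is.null, logical(1))])
    segments <- segments[order(match(segments$sample_id, sample_id),
                               match(segments$chromosome, chroms),
                               segments$start), , drop = FALSE]
    rownames(segments) <- NULL

    clinical <- data.frame(
      sample_id = sample_id,
      patient_id = sub("-10A$", "", sample_id),
      sex = "female",
      diagnosis = ifelse(is_case, config$case_label, config$control_label),
      is_case = is_case,
      age_years = round(stats::rnorm(n, 59, 10), 1),
      race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                    prob = c(0.74, 0.11, 0.06, 0.09)),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(sample_id = sample_id, is_case = is_case, cn,
                        stringsAsFactors = FALSE, check.names = FALSE)
    names(truth) <- c("sample_id", "is_case", paste0("cn_chr", chroms))
    rownames(truth) <- NULL

    out <- list(segments = segments, clinical = clinical, truth = truth,
                config = config)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_segment_file(segments, file.path(dir, "segments.seg"), "gdc_masked")
      clin_out <- clinical
      clin_out$age_years <- format_full(clin_out$age_years)
      write_tsv_plain(clin_out, file.path(dir, "clinical.tsv"))
      truth_out <- truth
      num <- vapply(truth_out, is.numeric, logical(1))
      truth_out[num] <- lapply(truth_out[num], format_full)
      write_tsv_plain(truth_out, file.path(dir, "truth.tsv"))
    }
    out
  })
}

#' Analytic Bayes AUC for a single informative chromosome
#'
#' Under the generator's latent model with one informative chromosome, both
#' groups are Gaussian on the copy-number scale with common SD and mean
#' separation `effect`; the optimal classifier's AUC is then
#' `pnorm(|effect| / (sd * sqrt(2)))`. The log2 transform to the CSLV scale
#' is monotone, so the bound applies to pipeline scores computed from that
#' chromosome alone. Used as an independent oracle for pipeline accuracy.
#'
#' @param effect Case mean shift, copy-number units.
#' @param between_subject_sd Between-subject SD, copy-number units (> 0).
#' @return AUC in `[0.5, 1]`.
#' @export
analytic_auc <- function(effect, between_subject_sd) {
  stopifnot(is.numeric(effect), is.numeric(between_subject_sd))
  if (between_subject_sd <= 0) {
    stop("between_subject_sd must be positive", call. = FALSE)
  }
  stats::pnorm(abs(effect) / (between_subject_sd * sqrt(2)))
}
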