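#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Either `segments` + `clinical` paths (real data) or a `synthetic`
#' [synthetic_config()] must be given. All randomness downstream flows from
#' the named seeds here; no stage draws from global entropy.
#'
#' @param out_dir Output directory (created if absent).
#' @param segments,clinical Paths to a segment file and clinical table, or
#'   `NULL` when `synthetic` is given.
#' @param synthetic Optional [synthetic_config()] (or plain list of its
#'   arguments) used to generate the inputs.
#' @param dialect Segment-file dialect for reading.
#' @param case_label Diagnosis string identifying cases.
#' @param include_x Include chromosome X as a feature.
#' @param min_coverage Per-chromosome minimum coverage for a CSLV value.
#' @param learner A [learner_spec()] (or plain list of its arguments).
#' @param k Cross-validation folds.
#' @param n_bins Integer vector of stratification bin counts.
#' @param train_fraction Train fraction for the single-split final model.
#' @param seed Master integer seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, segments = NULL, clinical = NULL,
                       synthetic = NULL, dialect = "gdc_masked",
                       case_label = "ovarian serous carcinoma",
                       include_x = FALSE, min_coverage = 0,
                       learner = learner_spec(), k = 5, n_bins = c(5, 50),
                       train_fraction = 0.8, seed = 1) {
  if (is.null(synthetic) && (is.null(segments) || is.null(clinical))) {
    stop("config needs either segment+clinical paths or a synthetic config",
         call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  if (!inherits(learner, "learner_spec")) {
    learner <- do.call(learner_spec, learner)
  }
  if (is.null(synthetic)) {
    for (p in c(segments, clinical)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, segments = segments, clinical = clinical,
                 synthetic = synthetic, dialect = dialect,
                 case_label = case_label, include_x = include_x,
                 min_coverage = min_coverage, learner = learner,
                 k = as.integer(k), n_bins = as.integer(n_bins),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments
#'   (`synthetic` and `learner` as nested maps).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic) && !is.null(cfg$synthetic$effect)) {
    cfg$synthetic$effect <- unlist(cfg$synthetic$effect)
  }
  if (!is.null(cfg$synthetic) && !is.null(cfg$synthetic$chromosomes)) {
    cfg$synthetic$chromosomes <- unlist(cfg$synthetic$chromosomes)
  }
  do.call(run_config, cfg)
}

#' Run the full risk-score pipeline
#'
#' Wires every stage end to end: (optionally) simulate a cohort, read the
#' segment and clinical tables, extract CSLV profiles, assemble the labelled
#' cohort, compute out-of-fold risk scores, stratify into each requested
#' number of bins, compute the ROC/AUC with bootstrap CI, train the
#' single-split final model, and attribute its predictions to chromosomes.
#' Every intermediate lands in `out_dir` as a tab-separated file, plus a
#' `manifest.json` recording seeds, counts and settings; re-running with the
#' same config reproduces all outputs byte-identically.
#'
#' @param config A [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with all in-memory stage results (`profiles`,
#'   `cohort`, `scores`, `strata`, `roc`, `auc`, `auc_ci`, `final`,
#'   `attribution`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$synthetic)) {
    sim <- generate_cohort(config$synthetic, dir = config$out_dir)
    seg_path <- out("segments.seg")
    clin_path <- out("clinical.tsv")
    case_label <- config$synthetic$case_label
  } else {
    seg_path <- config$segments
    clin_path <- config$clinical
    case_label <- config$case_label
  }

  segments <- read_segment_file(seg_path, dialect = config$dialect)
  clinical <- read_clinical_table(clin_path, case_label = case_label)

  lengths <- if (!is.null(config$synthetic)) {
    config$synthetic$chromosomes
  } else {
    grch38_chromosome_lengths(include_x = config$include_x)
  }
  profiles <- build_profiles(segments, lengths = lengths,
                             min_coverage = config$min_coverage)
  write_profiles(profiles, out("profiles.tsv"))

  cohort <- assemble_cohort(profiles, clinical)
  write_cohort(cohort, out("cohort.tsv"))

  scores <- cross_validated_scores(cohort, config$learner, k = config$k,
                                   seed = config$seed)
  write_scores(scores, out("scores.tsv"))

  strata <- lapply(config$n_bins, function(b) {
    st <- stratify(scores, n_bins = b)
    write_strata(st, out(sprintf("strata_%d.tsv", b)))
    st
  })
  names(strata) <- paste0("bins_", config$n_bins)

  cv_auc <- auc(scores$score, scores$is_case)
  ci <- auc_ci(scores$score, scores$is_case, seed = config$seed + 1)
  roc <- roc_curve(scores$score, scores$is_case)
  roc_out <- roc
  roc_out[] <- lapply(roc_out, format_full)
  write_tsv_plain(roc_out, out("roc.tsv"))

  final <- train_final_model(cohort, config$learner,
                             train_fraction = config$train_fraction,
                             seed = config$seed + 2)
  attribution <- feature_attribution(final$model, cohort,
                                     seed = config$seed + 3)
  rank_out <- attribution$ranking
  rank_out$mean_abs_contribution <- format_full(rank_out$mean_abs_contribution)
  write_tsv_plain(rank_out, out("attribution.tsv"))

  manifest <- list(
    seed = config$seed,
    k = config$k,
    n_bins = config$n_bins,
    learner = unclass(config$learner),
    case_label = case_label,
    n_segments = nrow(segments),
    n_profiles = nrow(profiles),
    n_cohort = nrow(cohort),
    n_cases = sum(cohort$is_case),
    n_controls = sum(!cohort$is_case),
    exclusions = as.list(attr(cohort, "exclusions")),
    cv_auc = cv_auc,
    cv_auc_ci = unname(ci),
    holdout_auc = auc(final$holdout$score, final$holdout$is_case),
    top_chromosome = attribution$ranking$chromosome[1]
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profiles = profiles, cohort = cohort, scores = scores,
                 strata = strata, roc = roc, auc = cv_auc, auc_ci = ci,
                 final = final, attribution = attribution,
                 manifest = manifest))
}

#' A small one-command synthetic demonstration configuration
#'
#' A scaled-down synthetic cohort (200 cases / 200 controls, one strongly
#' informative chromosome) that exercises the whole pipeline in seconds.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return A `run_config`.
#' @export
demo_config <- function(out_dir = tempfile("cslv_demo_"), seed = 1) {
  run_config(
    out_dir = out_dir,
    synthetic = synthetic_config(
      n_cases = 200, n_controls = 200,
      effect = c(`17` = 0.12, `4` = 0.05),
      seed = seed + 1000
    ),
    seed = seed
  )
}
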