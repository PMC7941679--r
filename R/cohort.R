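#' Assemble a labelled case-control cohort table
#'
#' Joins chromosome profiles with clinical records into the feature table the
#' classifier consumes: one row per sample with a case/control label, the
#' per-chromosome CSLV features (missing values preserved), and demographics.
#' Only samples present in both inputs and passing the inclusion filter are
#' kept; every excluded sample is tallied under exactly one reason in the
#' `"exclusions"` attribute. Rows whose entire feature vector is missing are
#' excluded (they carry no information and break ranking).
#'
#' @param profiles Profile data frame from [build_profiles()].
#' @param clinical Clinical data frame from [read_clinical_table()].
#' @param inclusion_sex Keep only subjects of this sex (default `"female"`,
#'   the ovarian-cancer study design); `NULL` disables the filter.
#' @return A `data.frame` with columns `sample_id`, `is_case`, `age_years`,
#'   `race`, then the `chr*` feature columns. Attribute `"exclusions"` is a
#'   named integer vector (`no_clinical`, `no_profile`, `excluded_sex`,
#'   `all_features_missing`).
#' @export
assemble_cohort <- function(profiles, clinical, inclusion_sex = "female") {
  stopifnot("sample_id" %in% names(profiles), "sample_id" %in% names(clinical))
  feat_cols <- grep("^chr", names(profiles), value = TRUE)
  if (length(feat_cols) == 0) stop("profiles have no chr* feature columns", call. = FALSE)

  in_clin <- profiles$sample_id %in% clinical$sample_id
  excl <- c(no_clinical = sum(!in_clin),
            no_profile = sum(!clinical$sample_id %in% profiles$sample_id),
            excluded_sex = 0L, all_features_missing = 0L)

  merged <- merge(profiles[in_clin, , drop = FALSE],
                  clinical[, c("sample_id", "sex", "is_case", "age_years", "race")],
                  by = "sample_id", sort = FALSE)
  # merge() may reorder; restore profile order for determinism
  merged <- merged[order(match(merged$sample_id, profiles$sample_id)), , drop = FALSE]

  if (!is.null(inclusion_sex)) {
    drop_sex <- merged$sex != inclusion_sex
    excl["excluded_sex"] <- sum(drop_sex)
    merged <- merged[!drop_sex, , drop = FALSE]
  }

  all_na <- rowSums(!is.na(as.matrix(merged[, feat_cols, drop = FALSE]))) == 0
  excl["all_features_missing"] <- sum(all_na)
  merged <- merged[!all_na, , drop = FALSE]

  n_case <- sum(merged$is_case)
  n_ctrl <- sum(!merged$is_case)
  if (n_case == 0 || n_ctrl == 0) {
    stop("cohort is degenerate after filtering (", n_case, " cases, ",
         n_ctrl, " controls); downstream statistics are undefined",
         call. = FALSE)
  }
  message("cohort assembled: ", n_case, " cases, ", n_ctrl, " controls; ",
          sum(excl), " sample(s) excluded")

  out <- merged[, c("sample_id", "is_case", "age_years", "race", feat_cols)]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Summarize cohort demographics by group
#'
#' Per-group sample counts, mean age (ignoring missing ages) and race
#' percentages, in the layout of a case-control "Table 1".
#'
#' @param cohort Cohort data frame from [assemble_cohort()].
#' @return A list with `groups` (data frame: `group`, `n`, `mean_age`) and
#'   `race` (data frame: `group`, `race`, `count`, `percent`, integer
#'   percentages of the group size).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  grp <- ifelse(cohort$is_case, "case", "control")
  groups <- do.call(rbind, lapply(c("case", "control"), function(g) {
    sel <- grp == g
    ages <- cohort$age_years[sel]
    data.frame(group = g, n = sum(sel),
               mean_age = if (all(is.na(ages))) NA_real_ else mean(ages, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  race <- do.call(rbind, lapply(c("case", "control"), function(g) {
    sel <- grp == g
    r <- cohort$race[sel]
    r[is.na(r)] <- "unknown"
    tab <- table(r)
    data.frame(group = g, race = names(tab), count = as.integer(tab),
               percent = as.integer(round(100 * as.integer(tab) / sum(sel))),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- rownames(race) <- NULL
  list(groups = groups, race = race)
}

#' Read/write cohort tables
#'
#' Cohort tables travel as tab-separated files with a logical `is_case`
#' column and empty cells for missing values.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_full)
  out$is_case <- ifelse(cohort$is_case, "TRUE", "FALSE")
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("sample_id", "is_case")
  if (!all(req %in% names(df))) {
    stop("cohort table lacks required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$is_case <- as.logical(df$is_case)
  for (cn in grep("^chr|^age", names(df), value = TRUE)) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}
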