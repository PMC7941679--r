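#' Rank samples by score and partition into quantile bins
#'
#' Samples are ordered by ascending score (ties broken by `sample_id`, a
#' stable, documented policy) and cut into `n_bins` bins whose sizes differ
#' by at most one; when `n = q * B + r`, the first `r` (lowest-score) bins
#' receive `q + 1` samples. Bin 1 holds the lowest scores.
#'
#' @param scores Risk-score data frame (`sample_id`, `is_case`, `score`).
#' @param n_bins Number of bins `B >= 2`.
#' @return Integer vector of bin indices aligned with `scores` rows.
#' @export
rank_and_bin <- function(scores, n_bins) {
  stopifnot(n_bins >= 2, nrow(scores) >= n_bins)
  n <- nrow(scores)
  q <- n %/% n_bins
  r <- n %% n_bins
  sizes <- rep(q, n_bins) + rep(c(1L, 0L), c(r, n_bins - r))
  ord <- order(scores$score, scores$sample_id)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), sizes)
  bin
}

#' Odds ratio of a score bin relative to the entire cohort
#'
#' `(a / b) / (c / d)`: the odds of being a case inside the bin divided by
#' the odds in the full cohort (bin included). `a = 0` gives a valid OR of
#' 0; `b = 0` makes the OR undefined (`NA` with a warning).
#'
#' @param a,b Case and control counts inside the bin.
#' @param c,d Case and control counts in the entire cohort.
#' @return The odds ratio, or `NA` when undefined.
#' @export
odds_ratio_vs_cohort <- function(a, b, c, d) {
  stopifnot(c > 0, d > 0, a >= 0, b >= 0)
  if (b == 0) {
    warning("odds ratio undefined: no controls in bin", call. = FALSE)
    return(NA_real_)
  }
  (a / b) / (c / d)
}

#' Wald confidence interval for a log odds ratio
#'
#' Standard error `sqrt(1/a + 1/b + 1/c + 1/d)` on the log-OR scale; bounds
#' `exp(log(OR) +/- z * SE)` with the unrounded OR from
#' [odds_ratio_vs_cohort()] (rounding the OR first is available for
#' compatibility with displays that do so). Any zero cell makes the interval
#' undefined unless `continuity` adds 0.5 to every cell.
#'
#' @param a,b,c,d Bin case/control and cohort case/control counts.
#' @param alpha Two-sided miscoverage, default 0.05 for a 95% interval.
#' @param round_or Round the point OR to `round_or` decimals before taking
#'   logs (`NULL`, the default, uses the unrounded OR).
#' @param continuity Apply a 0.5 continuity correction to all cells.
#' @return Named numeric vector `c(ci_low, ci_high)`, `NA`s when undefined.
#' @export
wald_ci_log_or <- function(a, b, c, d, alpha = 0.05, round_or = NULL,
                           continuity = FALSE) {
  if (continuity) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (any(c(a, b, c, d) == 0)) {
    warning("confidence interval undefined: zero cell count", call. = FALSE)
    return(c(ci_low = NA_real_, ci_high = NA_real_))
  }
  or <- (a / b) / (c / d)
  if (!is.null(round_or)) or <- round(or, round_or)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  c(ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Stratify a scored cohort into risk quantiles
#'
#' Ranks the cohort by out-of-fold risk score, partitions it into `n_bins`
#' quantile bins, and summarizes each bin with case/control counts and its
#' odds ratio (with 95% Wald CI) relative to the entire cohort. `n_bins = 5`
#' gives the quintile table of a risk-stratification analysis; `n_bins = 50`
#' the fine-grained profile used for plotting.
#'
#' All stratum statistics depend on the scores only through their ranks, so
#' any strictly increasing transform of the scores leaves the result
#' unchanged.
#'
#' @param scores Risk-score data frame.
#' @param n_bins Number of quantile bins.
#' @param alpha CI miscoverage, default 0.05.
#' @return A `data.frame` with one row per bin: `bin`, `n_controls`,
#'   `n_cases`, `n_total`, `odds_ratio`, `ci_low`, `ci_high`. Cohort totals
#'   are attached as attributes `"total_cases"` and `"total_controls"`.
#' @export
stratify <- function(scores, n_bins = 5, alpha = 0.05) {
  bin <- rank_and_bin(scores, n_bins)
  cc <- sum(scores$is_case)
  dd <- sum(!scores$is_case)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(i) {
    a <- sum(scores$is_case[bin == i])
    b <- sum(!scores$is_case[bin == i])
    or <- suppressWarnings(odds_ratio_vs_cohort(a, b, cc, dd))
    ci <- suppressWarnings(wald_ci_log_or(a, b, cc, dd, alpha = alpha))
    data.frame(bin = i, n_controls = b, n_cases = a, n_total = a + b,
               odds_ratio = or, ci_low = unname(ci[1]),
               ci_high = unname(ci[2]))
  }))
  rownames(out) <- NULL
  attr(out, "total_cases") <- cc
  attr(out, "total_controls") <- dd
  out
}

#' Top-vs-bottom bin odds ratio
#'
#' Compares the highest-score bin directly against the lowest:
#' `(a_top / b_top) / (a_bottom / b_bottom)`, with a Wald CI on the log
#' scale using `sqrt(1/a_top + 1/b_top + 1/a_bottom + 1/b_bottom)`. This is
#' the "top 20% vs bottom 20%" contrast of risk-score reporting when
#' `stratify()` was run with 5 bins.
#'
#' @param strata Output of [stratify()].
#' @param alpha CI miscoverage.
#' @return Named vector `c(odds_ratio, ci_low, ci_high)` (`NA`s when a cell
#'   is zero).
#' @export
top_bottom_odds_ratio <- function(strata, alpha = 0.05) {
  top <- strata[which.max(strata$bin), ]
  bot <- strata[which.min(strata$bin), ]
  cells <- c(top$n_cases, top$n_controls, bot$n_cases, bot$n_controls)
  if (any(cells == 0)) {
    warning("top-vs-bottom odds ratio undefined: zero cell count",
            call. = FALSE)
    return(c(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  or <- (top$n_cases / top$n_controls) / (bot$n_cases / bot$n_controls)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  c(odds_ratio = or, ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se))
}

#' Write a stratum summary table
#'
#' @param strata Output of [stratify()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(strata, path) {
  out <- strata
  for (cn in c("odds_ratio", "ci_low", "ci_high")) {
    out[[cn]] <- format_full(out[[cn]])
  }
  write_tsv_plain(out, path)
  invisible(path)
}
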