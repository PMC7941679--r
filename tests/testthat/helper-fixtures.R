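# Shared fixtures and independent oracles, all built in code.

# Brute-force CSLV oracle: average the segment mean over every covered base
# pair of a toy chromosome. Only usable for chrom_length <= ~1e4.
per_base_cslv <- function(segments, chrom_length) {
  v <- rep(NA_real_, chrom_length)
  for (i in seq_len(nrow(segments))) {
    v[segments$start[i]:segments$end[i]] <- segments$segment_mean[i]
  }
  covered <- !is.na(v)
  list(value = if (any(covered)) mean(v[covered]) else NA_real_,
       coverage = sum(covered) / chrom_length)
}

# Pair-enumeration AUC oracle: fraction of (case, control) pairs won, ties
# counting one half.
pairwise_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  cs <- scores[labels]
  ct <- scores[!labels]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}

# Non-overlapping random segments on [1, chrom_length].
random_segments <- function(n_seg, chrom_length, sample_id = "S1",
                            chromosome = "1") {
  cuts <- sort(sample(seq_len(chrom_length - 1), 2 * n_seg))
  starts <- cuts[seq(1, 2 * n_seg, by = 2)]
  ends <- cuts[seq(2, 2 * n_seg, by = 2)]
  data.frame(sample_id = sample_id, chromosome = chromosome,
             start = starts, end = ends, num_probes = ends - starts + 1,
             segment_mean = round(stats::rnorm(n_seg, 0, 0.1), 4),
             stringsAsFactors = FALSE)
}

# Build a cohort table directly from a feature matrix, bypassing the
# segment/profile stages, for classifier-level tests.
make_cohort <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  colnames(features) <- paste0("chr", seq_len(ncol(features)))
  df <- data.frame(sample_id = sprintf("S%04d", seq_along(labels)),
                   is_case = as.logical(labels),
                   age_years = NA_real_, race = NA_character_,
                   features, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# A cleanly separable cohort: one feature equals the label plus small noise.
separable_cohort <- function(n_per_group, seed = 1, noise = 0.01) {
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s); expr
  }
  withr_seed(seed, {
    labels <- rep(c(TRUE, FALSE), each = n_per_group)
    x <- cbind(as.numeric(labels) + rnorm(2 * n_per_group, 0, noise),
               rnorm(2 * n_per_group))
    make_cohort(x, labels)
  })
}

# A pure-interaction cohort: the label depends only on the sign product of
# two features (XOR structure), invisible to a linear-logistic model.
interaction_cohort <- function(n_per_group, seed = 1, flip = 0.1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x1 <- rnorm(n, 0, 0.05)
  x2 <- rnorm(n, 0, 0.05)
  y <- xor(x1 * x2 > 0, runif(n) < flip)
  make_cohort(cbind(x1, x2), y)
}

write_lines_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
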