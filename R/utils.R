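`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Format doubles so that read-back reproduces them bit-for-bit.
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- NA_character_
  trimws(out)
}

# Header normalization used by all table readers: lower-case, drop
# punctuation, so "Segment_Mean", "seg.mean" and "Segment Mean" all compare
# equal to their canonical keys.
norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

match_column <- function(headers, synonyms, label, required = TRUE) {
  idx <- which(norm_header(headers) %in% synonyms)
  if (length(idx) == 0) {
    if (required) stop("missing required column '", label, "'", call. = FALSE)
    return(NA_integer_)
  }
  idx[1]
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("", "NA", "N/A"), check.names = FALSE)
}
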