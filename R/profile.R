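#' Build the per-position amino-acid frequency profile of an alignment
#'
#' The profile is the weighting object of every score in the predictor: a
#' 20 x L table giving, for each query position, the frequency of each
#' standard amino acid among the aligned homologs. Gap characters and
#' nonstandard residue codes are excluded from both numerator and
#' denominator, so frequencies are over observed standard residues and each
#' column with at least one observation sums to 1. Setting
#' `gaps_in_denominator = TRUE` keeps gaps in the denominator instead
#' (columns then sum to the fraction of non-gap rows). Columns with no
#' standard residue at all fall back to a one-hot column on the query
#' residue.
#'
#' Raw counts are used: no sequence weighting, no pseudocounts. The method
#' is untrained and the profile is meant to be exactly the observed
#' frequencies.
#'
#' @param msa A `ddg_msa` object from [read_msa()] or [msa()].
#' @param gaps_in_denominator Count gaps in the per-column denominator
#'   (default `FALSE`).
#' @return A `ddg_profile` object: list with `freqs` (20 x L matrix, rows in
#'   [AA_STANDARD] order), `depth` (per-column count of standard residues),
#'   `query` (query residue vector), `length`, and `one_hot` flag.
#' @examples
#' m <- msa(c("ACDEF", "ACDEF", "AC-EF"))
#' p <- build_profile(m)
#' p$freqs["C", 2]   # 1
#' p$depth[3]        # 2
#' @export
build_profile <- function(msa, gaps_in_denominator = FALSE) {
  stopifnot(inherits(msa, "ddg_msa"))
  rows <- strsplit(msa$sequences, "", fixed = TRUE)
  chars <- do.call(rbind, rows)                      # n_rows x L
  L <- ncol(chars)
  query <- chars[msa$query_index, ]
  counts <- apply(chars, 2L, function(col) {
    tabulate(factor(col, levels = AA_STANDARD), nbins = 20L)
  })
  counts <- matrix(counts, nrow = 20L, dimnames = list(AA_STANDARD, NULL))
  depth <- colSums(counts)
  denom <- if (gaps_in_denominator) rep(nrow(chars), L) else depth
  freqs <- sweep(counts, 2L, pmax(denom, 1L), "/")
  empty <- which(depth == 0L)
  for (j in empty) {                                  # one-hot fallback
    if (is_standard_aa(query[j])) freqs[query[j], j] <- 1
  }
  new_profile(freqs, depth = as.integer(depth), query = query,
              one_hot = FALSE)
}

#' One-hot profile from a bare sequence
#'
#' Lets the sequence mode run without an alignment: each column puts all its
#' weight on the query residue. The result is flagged `one_hot = TRUE` so
#' callers (e.g. the CLI) can warn that predictions carry no evolutionary
#' information and are degraded.
#'
#' @param sequence Residue string (standard amino acids only).
#' @return A `ddg_profile` with one-hot columns.
#' @export
single_sequence_profile <- function(sequence) {
  query <- split_residues(sequence)
  bad <- which(!is_standard_aa(query))
  if (length(bad)) {
    stop(sprintf("nonstandard residue '%s' at position %d; supply standard amino acids only",
                 query[bad[1]], bad[1]), call. = FALSE)
  }
  L <- length(query)
  freqs <- matrix(0, 20L, L, dimnames = list(AA_STANDARD, NULL))
  freqs[cbind(match(query, AA_STANDARD), seq_len(L))] <- 1
  new_profile(freqs, depth = rep(1L, L), query = query, one_hot = TRUE)
}

new_profile <- function(freqs, depth, query, one_hot) {
  structure(list(freqs = freqs, depth = depth, query = query,
                 length = ncol(freqs), one_hot = one_hot),
            class = "ddg_profile")
}

#' @export
print.ddg_profile <- function(x, ...) {
  cat(sprintf("Sequence profile: %d positions, median depth %s%s\n",
              x$length, stats::median(x$depth),
              if (x$one_hot) " (one-hot, no alignment information)" else ""))
  invisible(x)
}

#' Profile as a tibble
#'
#' One row per query position: `position`, `residue` (query), `depth`, then
#' one frequency column per standard amino acid. This is also the layout
#' written by [write_profile_tsv()].
#'
#' @param x A `ddg_profile`.
#' @param ... Unused.
#' @return A tibble with `2 + 1 + 20` columns and `length` rows.
#' @method as_tibble ddg_profile
#' @export
as_tibble.ddg_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(position = seq_len(x$length),
                   residue = x$query,
                   depth = x$depth),
    tibble::as_tibble(t(x$freqs))
  )
}

#' Write a profile to TSV for inspection
#'
#' @param profile A `ddg_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as_tibble.ddg_profile(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: frequency column at position j, with bounds check.
profile_column <- function(profile, j) {
  if (j < 1L || j > profile$length) {
    stop(sprintf("position %d outside profile of length %d", j, profile$length),
         call. = FALSE)
  }
  profile$freqs[, j]
}
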