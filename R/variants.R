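#' Parse one variant line
#'
#' A line holds one variant, possibly multi-site: single substitutions are
#' written `T7W` (wild-type residue, position, variant residue) and
#' simultaneous substitutions are comma-separated on the same line
#' (`"T7W, K6L"`). In structure mode positions are author residue numbers
#' and may carry a PDB insertion code, e.g. `T27AW` for number 27, insertion
#' code A. Input is uppercased before parsing; whitespace around commas is
#' tolerated.
#'
#' @param line Non-empty text for one (multi-)variant.
#' @param allow_identity Accept tokens whose wild-type and variant residue
#'   coincide (default `FALSE`; identity variants are only meaningful for
#'   consistency checks, where they must score 0).
#' @return A `ddg_multivariant`: a tibble with one row per substitution and
#'   columns `wt`, `pos` (integer position, `NA` until resolved for
#'   insertion-coded tokens), `resno` (author number), `ins` (insertion code
#'   or `""`), `mut`, `token`.
#' @examples
#' parse_variant_line("T7W")
#' parse_variant_line("T7W, K6L")
#' @export
parse_variant_line <- function(line, allow_identity = FALSE) {
  if (!is.character(line) || length(line) != 1L || !nzchar(trimws(line))) {
    stop("variant line must be one non-empty string", call. = FALSE)
  }
  tokens <- trimws(strsplit(toupper(line), ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("variant line '", line, "' has no tokens", call. = FALSE)
  parsed <- purrr::map_dfr(tokens, parse_variant_token,
                           allow_identity = allow_identity)
  key <- paste0(parsed$resno, parsed$ins)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated position in multi-variant line: token '",
         parsed$token[dup][1], "'", call. = FALSE)
  }
  structure(parsed, class = c("ddg_multivariant", class(parsed)))
}

parse_variant_token <- function(token, allow_identity = FALSE) {
  if (!grepl("^[A-Z][A-Z0-9]+[A-Z]$", token)) {
    stop("malformed variant token '", token,
         "' (expected e.g. T7W, or T27AW with a PDB insertion code)",
         call. = FALSE)
  }
  wt <- substr(token, 1L, 1L)
  mut <- substr(token, nchar(token), nchar(token))
  mid <- substr(token, 2L, nchar(token) - 1L)
  m <- regmatches(mid, regexec("^([0-9]+)([A-Z]?)$", mid))[[1]]
  if (length(m) == 0L) {
    stop("malformed position '", mid, "' in variant token '", token, "'",
         call. = FALSE)
  }
  check_standard_aa(c(wt, mut), "residue")
  if (wt == mut && !allow_identity) {
    stop("wild-type and variant residue are identical in token '", token, "'",
         call. = FALSE)
  }
  resno <- as.integer(m[2])
  ins <- m[3]
  tibble::tibble(wt = wt,
                 pos = if (ins == "") resno else NA_integer_,
                 resno = resno, ins = ins, mut = mut,
                 token = format_variant_token(wt, resno, ins, mut))
}

format_variant_token <- function(wt, resno, ins, mut) {
  paste0(wt, resno, ins, mut)
}

#' Format a multi-variant back to its line form
#'
#' Inverse of [parse_variant_line()]: `parse -> format -> parse` round-trips
#' exactly.
#'
#' @param mv A `ddg_multivariant`.
#' @return A single string, comma-separated for multi-site variants.
#' @export
format_variant <- function(mv) {
  stopifnot(inherits(mv, "ddg_multivariant"))
  paste(mv$token, collapse = ",")
}

#' Read a variants file
#'
#' Plain text, one (multi-)variant per line; blank lines and `#` comments
#' are skipped.
#'
#' @param path File path.
#' @return List of `ddg_multivariant` objects.
#' @export
read_variants_file <- function(path) {
  if (!file.exists(path)) stop("variants file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("variants file contains no variants: ", path, call. = FALSE)
  lapply(lines, parse_variant_line)
}

#' Validate a multi-variant against the query sequence
#'
#' Checks that each substitution's wild-type residue is the residue actually
#' present at its position in the query. Insertion-coded positions cannot be
#' resolved against a bare sequence and are rejected here; use
#' [resolve_positions()] with a structure first.
#'
#' @param mv A `ddg_multivariant`.
#' @param sequence Query residue string.
#' @param check_wt Require the wild-type residue to match the sequence
#'   (default `TRUE`). Disabling it still bounds-checks positions; it is
#'   meant for scoring a reverse substitution under the unchanged wild-type
#'   profile, where the token's "wild-type" is the mutant residue.
#' @return `mv`, with `pos` guaranteed set, invisibly unchanged otherwise.
#' @examples
#' mv <- parse_variant_line("C3A")
#' validate_against_sequence(mv, "AACDE")
#' @export
validate_against_sequence <- function(mv, sequence, check_wt = TRUE) {
  stopifnot(inherits(mv, "ddg_multivariant"))
  res <- split_residues(sequence)
  for (i in seq_len(nrow(mv))) {
    if (is.na(mv$pos[i])) {
      stop("variant '", mv$token[i],
           "' uses a PDB insertion code; it can only be resolved against a structure",
           call. = FALSE)
    }
    p <- mv$pos[i]
    if (p > length(res)) {
      stop(sprintf("variant '%s': position %d beyond sequence length %d",
                   mv$token[i], p, length(res)), call. = FALSE)
    }
    if (check_wt && res[p] != mv$wt[i]) {
      stop(sprintf("variant '%s': expected wild-type %s at position %d but sequence has %s",
                   mv$token[i], mv$wt[i], p, res[p]), call. = FALSE)
    }
  }
  mv
}

#' Resolve structure-mode positions to sequence positions
#'
#' Maps each substitution's author residue number + insertion code to the
#' 1-based position in the chain sequence of `model`, checks the wild-type
#' residue, and fills the `pos` column.
#'
#' @param mv A `ddg_multivariant`.
#' @param model A `ddg_structure` from [read_structure()].
#' @param check_wt Require the wild-type residue to match the chain
#'   (default `TRUE`); see [validate_against_sequence()].
#' @return `mv` with `pos` resolved to chain-sequence positions.
#' @export
resolve_positions <- function(mv, model, check_wt = TRUE) {
  stopifnot(inherits(mv, "ddg_multivariant"), inherits(model, "ddg_structure"))
  res <- model$residues
  for (i in seq_len(nrow(mv))) {
    hit <- which(res$resno == mv$resno[i] & res$ins == mv$ins[i])
    if (length(hit) != 1L) {
      stop(sprintf("variant '%s': residue %d%s not found in chain %s",
                   mv$token[i], mv$resno[i], mv$ins[i], model$chain_id),
           call. = FALSE)
    }
    if (check_wt && (is.na(res$aa[hit]) || res$aa[hit] != mv$wt[i])) {
      stop(sprintf("variant '%s': chain %s has %s at residue %d%s, not %s",
                   mv$token[i], model$chain_id,
                   ifelse(is.na(res$aa[hit]), res$resid[hit], res$aa[hit]),
                   mv$resno[i], mv$ins[i], mv$wt[i]), call. = FALSE)
    }
    mv$pos[i] <- res$seq_pos[hit]
  }
  mv
}
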