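#' Read a multiple sequence alignment
#'
#' Reads an alignment in aligned-FASTA or A3M dialect and normalizes it to
#' query coordinates. In A3M, insertions relative to the query are lowercase
#' (or `.`) and are removed row by row; in aligned FASTA, columns where the
#' query row carries a gap are dropped from every row. After normalization
#' all rows have the query's length and the query row is gap-free.
#'
#' The first record is taken as the query unless `query_index` says
#' otherwise. Sequences are uppercased after dialect normalization.
#'
#' @param path Path to the alignment file.
#' @param dialect `"auto"` (default; A3M is recognised by a `.a3m` extension
#'   or by lowercase insert states), `"a3m"`, or `"aligned_fasta"`.
#' @param query_index Row index of the query sequence (default 1).
#' @return A `ddg_msa` object: list with `sequences` (character vector in
#'   query coordinates), `names`, and `query_index`.
#' @seealso [build_profile()], [make_msa()]
#' @export
read_msa <- function(path, dialect = c("auto", "a3m", "aligned_fasta"),
                     query_index = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) == 0L) stop("alignment file is empty: ", path, call. = FALSE)
  seqs <- as.character(recs)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.a3m$", path, ignore.case = TRUE) ||
                   any(grepl("[a-z.]", seqs))) "a3m" else "aligned_fasta"
  }
  msa(seqs, query_index = query_index, dialect = dialect, source = path)
}

#' Construct an alignment object from in-memory sequences
#'
#' Same normalization as [read_msa()] but starting from a character vector;
#' used by the fixture generator and handy in tests.
#'
#' @param sequences Character vector of aligned rows.
#' @param query_index Row index of the query (default 1).
#' @param dialect `"aligned_fasta"` or `"a3m"`.
#' @param source Optional provenance label stored on the object.
#' @return A `ddg_msa` object.
#' @export
msa <- function(sequences, query_index = 1L,
                dialect = c("aligned_fasta", "a3m"), source = NULL) {
  dialect <- match.arg(dialect)
  if (length(sequences) == 0L) stop("alignment has no rows", call. = FALSE)
  if (query_index < 1L || query_index > length(sequences)) {
    stop("query_index ", query_index, " out of range for ",
         length(sequences), " rows", call. = FALSE)
  }
  if (dialect == "a3m") {
    # each row's own lowercase/'.' states are inserts relative to the query
    sequences <- gsub("[a-z.]", "", sequences)
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  qlen <- lens[query_index]
  if (any(lens != qlen)) {
    bad <- which(lens != qlen)[1]
    stop(sprintf("ragged alignment after normalization: row %d has length %d, query has %d",
                 bad, lens[bad], qlen), call. = FALSE)
  }
  rows <- strsplit(sequences, "", fixed = TRUE)
  qrow <- rows[[query_index]]
  keep <- qrow != "-"
  if (!all(keep)) {          # project every row onto query (non-gap) columns
    rows <- lapply(rows, function(r) r[keep])
    qrow <- qrow[keep]
  }
  if (length(qrow) == 0L) stop("query row is all gaps", call. = FALSE)
  structure(list(sequences = unname(vapply(rows, paste, "", collapse = "")),
                 names = names(sequences),
                 query_index = as.integer(query_index),
                 source = source),
            class = "ddg_msa")
}

#' @export
print.ddg_msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d rows x %d columns (query row %d)\n",
              length(x$sequences), nchar(x$sequences[x$query_index]),
              x$query_index))
  invisible(x)
}

#' Query sequence of an alignment
#'
#' @param msa A `ddg_msa` object.
#' @return The query row as a single string (no gaps).
#' @export
msa_query <- function(msa) {
  stopifnot(inherits(msa, "ddg_msa"))
  msa$sequences[msa$query_index]
}

#' Write an alignment as aligned FASTA
#'
#' @param msa A `ddg_msa` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "ddg_msa"))
  nm <- msa$names
  if (is.null(nm)) nm <- sprintf("seq%d", seq_along(msa$sequences))
  writeLines(rbind(paste0(">", nm), msa$sequences), path)
  invisible(path)
}
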