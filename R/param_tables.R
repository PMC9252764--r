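#' Load a bundled scoring table
#'
#' The predictor is untrained: every parameter it uses lives in one of four
#' fixed tables shipped with the package as plain text under
#' `inst/extdata/matrices/`:
#'
#' * `"blosum62"` — the BLOSUM62 substitution matrix (20x20, symmetric,
#'   half-bit scores).
#' * `"skolnick"` — a symmetric 20x20 pairwise contact potential used for
#'   sequence-window interactions. The bundled file is a deterministic
#'   synthetic surrogate (see its header for the construction recipe); all
#'   score-level properties (symmetry of the table, anti-symmetry of the
#'   derived variant scores) are independent of the entries.
#' * `"bastolla_vendruscolo"` — a symmetric 20x20 pairwise contact potential
#'   used for spatial (structural) contacts; likewise a labelled synthetic
#'   surrogate.
#' * `"kyte_doolittle"` — the Kyte-Doolittle hydropathy scale (per-residue
#'   scalar).
#'
#' Matrices are returned as numeric 20x20 matrices with row and column names
#' in [AA_STANDARD] order; the hydropathy scale as a named numeric vector.
#' Repeated calls return identical values (tables are read once per session
#' and cached).
#'
#' @param name One of `"blosum62"`, `"skolnick"`, `"kyte_doolittle"`,
#'   `"bastolla_vendruscolo"`.
#' @return A named 20x20 numeric matrix, or for `"kyte_doolittle"` a named
#'   numeric vector of length 20.
#' @examples
#' B <- load_table("blosum62")
#' B["A", "A"]                      # 4
#' K <- load_table("kyte_doolittle")
#' K[["I"]]                         # 4.5
#' @export
load_table <- function(name) {
  files <- c(blosum62              = "blosum62.mat",
             skolnick              = "skolnick_synthetic.mat",
             bastolla_vendruscolo  = "bastolla_vendruscolo_synthetic.mat",
             kyte_doolittle        = "kyte_doolittle.tsv")
  if (!is.character(name) || length(name) != 1L || !name %in% names(files)) {
    stop(sprintf("unknown table '%s'; available: %s",
                 paste(name, collapse = ","), paste(names(files), collapse = ", ")),
         call. = FALSE)
  }
  cached <- .table_cache[[name]]
  if (!is.null(cached)) return(cached)

  path <- system.file("extdata", "matrices", files[[name]],
                      package = "ddgpred", mustWork = TRUE)
  tab <- if (name == "kyte_doolittle") read_aa_scale(path) else read_aa_matrix(path)
  .table_cache[[name]] <- tab
  tab
}

.table_cache <- new.env(parent = emptyenv())

# BLAST-style square matrix dialect: '#' comments, header row of one-letter
# codes, then one labelled row per residue.
read_aa_matrix <- function(path) {
  df <- utils::read.table(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(sort(rownames(m)), sort(AA_STANDARD)) ||
      !identical(sort(colnames(m)), sort(AA_STANDARD))) {
    stop("matrix file ", path, " does not cover exactly the 20 standard amino acids",
         call. = FALSE)
  }
  m <- m[AA_STANDARD, AA_STANDARD]
  storage.mode(m) <- "double"
  if (!isSymmetric(unname(m))) {
    stop("matrix file ", path, " is not symmetric", call. = FALSE)
  }
  m
}

read_aa_scale <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  if (!identical(sort(names(v)), sort(AA_STANDARD))) {
    stop("scale file ", path, " does not cover exactly the 20 standard amino acids",
         call. = FALSE)
  }
  v[AA_STANDARD]
}

#' Look up a pair score in a bundled matrix
#'
#' Thin checked accessor: errors loudly on nonstandard codes instead of
#' returning `NA`, so scoring code never propagates silent missing values.
#'
#' @param table A matrix returned by [load_table()].
#' @param a,b One-letter residue codes.
#' @return The scalar score `table[a, b]`.
#' @export
lookup_pair <- function(table, a, b) {
  check_standard_aa(c(a, b), "residue")
  table[a, b]
}
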