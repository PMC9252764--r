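#' The twenty standard amino acids
#'
#' One-letter codes in the conventional BLAST matrix order. Every bundled
#' parameter table, every profile row and every score is defined over
#' exactly this alphabet; nonstandard codes (B, J, O, U, X, Z) are rejected
#' or skipped at well-defined points rather than silently mapped.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Test for standard amino-acid codes
#'
#' @param x Character vector of one-letter residue codes.
#' @return Logical vector, `TRUE` where the code is one of the 20 standard
#'   amino acids (uppercase).
#' @export
is_standard_aa <- function(x) x %in% AA_STANDARD

# Internal: stop unless every element of `x` is a standard one-letter code.
# `what` names the offending argument in the error message.
check_standard_aa <- function(x, what = "residue") {
  bad <- which(!is_standard_aa(x))
  if (length(bad)) {
    stop(sprintf("nonstandard %s code '%s' (position %d); only the 20 standard amino acids are allowed",
                 what, x[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(x)
}

# Internal: split a residue string into single characters, uppercased.
split_residues <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# Three-letter -> one-letter conversion for PDB residue names, standard
# amino acids only; anything else maps to NA.
aa3_to_aa1 <- function(aa3) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  unname(map[toupper(aa3)])
}

aa1_to_aa3 <- function(aa1) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  unname(map[toupper(aa1)])
}
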