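# Synthetic inputs with controlled properties: toy alignments with tunable
# per-position conservation, and toy PDB chains with engineered contact
# distances, burial, and insertion-coded numbering. Everything is
# deterministic in the spec's seed and round-trips through the package's
# own readers.

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; the same spec always yields the same fixture.
#' @param n_sequences Alignment rows including the query.
#' @param length Query length (alignment columns).
#' @param conservation Dirichlet concentration placed on the query residue
#'   per column: large values give near one-hot columns, values near 0 give
#'   near-uniform columns.
#' @param gap_rate Per-cell probability of a gap in homolog rows.
#' @param geometry Toy-structure layout: `"isolated"` (single residue),
#'   `"pair"` (two residues at a controlled minimum heavy-atom distance),
#'   `"buried"` (a central residue enclosed by a shell), or
#'   `"insertion_coded"` (three residues numbered 27, 27A, 28).
#' @param distance Target minimum heavy-atom distance in Å for `"pair"`.
#' @param n_shell Number of shell residues for `"buried"`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_sequences = 20L, length = 30L,
                         conservation = 5, gap_rate = 0,
                         geometry = c("isolated", "pair", "buried",
                                      "insertion_coded"),
                         distance = 4.0, n_shell = 26L) {
  geometry <- match.arg(geometry)
  stopifnot(n_sequences >= 1L, length >= 1L, conservation >= 0,
            gap_rate >= 0, gap_rate < 1, distance > 0, n_shell >= 1L)
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 length = as.integer(length), conservation = conservation,
                 gap_rate = gap_rate, geometry = geometry,
                 distance = distance, n_shell = as.integer(n_shell)),
            class = "fixture_spec")
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multiple sequence alignment
#'
#' The query is sampled uniformly over the standard amino acids. For each
#' column a residue distribution is drawn from a Dirichlet prior
#' concentrated on the query residue (`conservation` pseudo-counts on the
#' query residue, 0.5 on each other residue), and homolog rows are sampled
#' i.i.d. from it, with optional gaps. In the large-`conservation` limit
#' all rows equal the query and the profile is one-hot.
#'
#' @param spec A [fixture_spec()].
#' @return A `ddg_msa`.
#' @export
make_msa <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    L <- spec$length
    query <- sample(AA_STANDARD, L, replace = TRUE)
    rows <- matrix("", nrow = spec$n_sequences, ncol = L)
    rows[1L, ] <- query
    if (spec$n_sequences > 1L) {
      for (j in seq_len(L)) {
        alpha <- rep(0.5, 20)
        alpha[match(query[j], AA_STANDARD)] <- alpha[match(query[j], AA_STANDARD)] +
          spec$conservation
        g <- stats::rgamma(20, shape = alpha)
        p <- g / sum(g)
        col <- sample(AA_STANDARD, spec$n_sequences - 1L, replace = TRUE, prob = p)
        if (spec$gap_rate > 0) {
          col[stats::runif(length(col)) < spec$gap_rate] <- "-"
        }
        rows[-1L, j] <- col
      }
    }
    seqs <- apply(rows, 1L, paste, collapse = "")
    names(seqs) <- c("query", sprintf("hom%03d", seq_len(spec$n_sequences - 1L) + 1L))[
      seq_len(spec$n_sequences)]
    msa(seqs, query_index = 1L, dialect = "aligned_fasta",
        source = sprintf("synthetic msa seed %d", spec$seed))
  })
}

# idealized residue template: heavy atoms in a local frame (A)
residue_template <- function(type = c("ALA", "GLY")) {
  type <- match.arg(type)
  atoms <- rbind(N  = c(-1.458, 0.000, 0.000),
                 CA = c(0.000, 0.000, 0.000),
                 C  = c(1.525, 0.000, 0.000),
                 O  = c(2.153, 1.062, 0.000))
  if (type == "ALA") atoms <- rbind(atoms, CB = c(-0.530, -0.770, -1.200))
  atoms
}

pdb_atom_line <- function(serial, name, resn, chain, resno, icode, xyz) {
  elem <- substr(name, 1L, 1L)
  sprintf("ATOM  %5d  %-3s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resno,
          if (nzchar(icode)) icode else " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
}

# minimum heavy-atom distance between two coordinate matrices
min_cross_dist <- function(a, b) min(cross_dist(a, b))

#' Generate a synthetic PDB chain
#'
#' Emits syntactically valid PDB text for the layout named in the spec:
#'
#' * `"isolated"`: one alanine, fully solvent-exposed.
#' * `"pair"`: two alanines whose minimum heavy-atom distance equals
#'   `spec$distance` to within 0.01 Å (solved by bisection on a rigid
#'   translation), for exercising the contact radius.
#' * `"buried"`: a central alanine enclosed by a quasi-uniform spherical
#'   shell of `n_shell` glycines, forcing low solvent accessibility of the
#'   centre.
#' * `"insertion_coded"`: three alanines with author numbers 27, 27A, 28.
#'
#' Toy geometry uses idealized residue templates; only distances and
#' exposure are controlled, not stereochemistry.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional output file; when given the text is written there
#'   and the path returned invisibly.
#' @param chain Chain identifier (default `"A"`).
#' @param serial_start First atom serial number (useful when concatenating
#'   chains into one file).
#' @return Character vector of PDB lines (or `path` invisibly).
#' @export
make_structure <- function(spec, path = NULL, chain = "A", serial_start = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  tmpl <- residue_template("ALA")
  place <- function(shift) sweep(tmpl, 2L, shift, "+")
  residues <- switch(spec$geometry,
    isolated = list(list(resn = "ALA", resno = 1L, icode = "", xyz = place(c(0, 0, 0)))),
    pair = {
      a <- place(c(0, 0, 0))
      gap_for <- function(delta) min_cross_dist(a, sweep(a, 2L, c(delta, 0, 0), "+"))
      # gap_for is monotone increasing for delta beyond the template extent
      lo <- 3.0; hi <- spec$distance + 10
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (gap_for(mid) < spec$distance) lo <- mid else hi <- mid
      }
      list(list(resn = "ALA", resno = 1L, icode = "", xyz = a),
           list(resn = "ALA", resno = 2L, icode = "",
                xyz = sweep(a, 2L, c((lo + hi) / 2, 0, 0), "+")))
    },
    buried = {
      shell_dirs <- fibonacci_sphere(spec$n_shell)
      gly <- residue_template("GLY")
      c(list(list(resn = "ALA", resno = 1L, icode = "", xyz = place(c(0, 0, 0)))),
        lapply(seq_len(spec$n_shell), function(i) {
          list(resn = "GLY", resno = i + 1L, icode = "",
               xyz = sweep(gly, 2L, shell_dirs[i, ] * 4.6, "+"))
        }))
    },
    insertion_coded = list(
      list(resn = "ALA", resno = 27L, icode = "", xyz = place(c(0, 0, 0))),
      list(resn = "ALA", resno = 27L, icode = "A", xyz = place(c(3.8, 0, 0))),
      list(resn = "ALA", resno = 28L, icode = "", xyz = place(c(7.6, 0, 0)))))
  lines <- character(0)
  serial <- serial_start - 1L
  for (r in residues) {
    for (an in rownames(r$xyz)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, an, r$resn, chain, r$resno,
                                      r$icode, r$xyz[an, ]))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  lines
}
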