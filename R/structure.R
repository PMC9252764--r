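#' Read one chain of a PDB file
#'
#' Extracts a single chain from a PDB file, keeping the author residue
#' numbering including insertion codes. Only `ATOM` records are used
#' (waters and other HETATM groups are ignored for scoring), hydrogens are
#' dropped, the first model is used when several are present, and alternate
#' locations are resolved per atom to the highest occupancy (ties to
#' altloc `A`). Residues of nonstandard type are retained for geometry but
#' carry `aa = NA` and are never scored.
#'
#' By default residues are numbered 1..n along the chain's resolved
#' sequence (`seq_pos`); use [map_structure()] to re-map onto an external
#' query sequence.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single character).
#' @return A `ddg_structure`: list with `chain_id`, `residues` (tibble:
#'   `resno`, `ins`, `resid`, `aa`, `seq_pos`, `key`), `atoms` (tibble:
#'   `key`, `elety`, `elesy`, `x`, `y`, `z`), and `sequence` (one-letter
#'   string over the standard residues).
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- tibble::as_tibble(pdb$atom)
  if (!chain %in% at$chain) {
    stop("chain '", chain, "' not found in ", path,
         " (chains present: ", paste(sort(unique(at$chain)), collapse = ", "), ")",
         call. = FALSE)
  }
  at <- dplyr::filter(at, .data$type == "ATOM", .data$chain == !!chain)
  # drop hydrogens/deuteriums and waters
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 substr(gsub("^[0-9]+", "", at$elety), 1L, 1L), at$elesy)
  at$elesy <- toupper(elem)
  at <- dplyr::filter(at, !.data$elesy %in% c("H", "D"),
                      !.data$resid %in% c("HOH", "WAT", "DOD"))
  if (nrow(at) == 0L) stop("chain '", chain, "' has no heavy atoms", call. = FALSE)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)

  # altloc: highest occupancy per (residue, atom name), ties -> 'A'/blank first
  at <- at |>
    dplyr::group_by(.data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  key <- paste0(at$resno, at$insert, "|", at$resid)
  ord <- order(match(key, unique(key)), method = "radix")
  at <- at[ord, ]
  key <- key[ord]

  res <- at |>
    dplyr::mutate(key = key) |>
    dplyr::distinct(.data$key, .data$resno, .data$insert, .data$resid) |>
    dplyr::rename(ins = "insert") |>
    dplyr::mutate(aa = aa3_to_aa1(.data$resid),
                  seq_pos = ifelse(is.na(.data$aa), NA_integer_,
                                   cumsum(!is.na(.data$aa))))
  if (all(is.na(res$aa))) {
    stop("chain '", chain, "' contains no standard amino-acid residues", call. = FALSE)
  }
  atoms <- tibble::tibble(key = key, elety = at$elety, elesy = at$elesy,
                          x = at$x, y = at$y, z = at$z)
  structure(list(chain_id = chain,
                 residues = res,
                 atoms = atoms,
                 sequence = paste(res$aa[!is.na(res$aa)], collapse = ""),
                 source = path),
            class = "ddg_structure")
}

#' @export
print.ddg_structure <- function(x, ...) {
  cat(sprintf("Structure chain %s: %d residues (%d standard), %d heavy atoms\n",
              x$chain_id, nrow(x$residues), sum(!is.na(x$residues$aa)),
              nrow(x$atoms)))
  invisible(x)
}

#' Chain sequence of a structure
#'
#' @param model A `ddg_structure`.
#' @return One-letter sequence over the chain's standard residues.
#' @export
structure_sequence <- function(model) {
  stopifnot(inherits(model, "ddg_structure"))
  model$sequence
}

#' Map a structure chain onto a query sequence
#'
#' Aligns the chain's resolved sequence to `sequence` by exact contiguous
#' match (the shorter must occur exactly once in the longer; leading and
#' trailing overhang is allowed) and rewrites each residue's `seq_pos` to
#' query coordinates. Structure residues falling outside the query get
#' `seq_pos = NA` and are skipped (with a warning) by the spatial score.
#'
#' @param model A `ddg_structure`.
#' @param sequence Query residue string (e.g. the profile's query).
#' @return `model` with remapped `seq_pos`.
#' @export
map_structure <- function(model, sequence) {
  stopifnot(inherits(model, "ddg_structure"))
  chain_seq <- model$sequence
  query <- toupper(sequence)
  if (nchar(chain_seq) <= nchar(query)) {
    hits <- gregexpr(chain_seq, query, fixed = TRUE)[[1]]
    if (identical(as.integer(hits), -1L) || length(hits) != 1L) {
      stop("chain sequence does not match the query sequence at exactly one offset; ",
           "check that structure and alignment describe the same protein",
           call. = FALSE)
    }
    offset <- as.integer(hits) - 1L            # chain pos i -> query pos i + offset
  } else {
    hits <- gregexpr(query, chain_seq, fixed = TRUE)[[1]]
    if (identical(as.integer(hits), -1L) || length(hits) != 1L) {
      stop("query sequence does not match the chain sequence at exactly one offset",
           call. = FALSE)
    }
    offset <- -(as.integer(hits) - 1L)
  }
  new_pos <- model$residues$seq_pos + offset
  new_pos[new_pos < 1L | new_pos > nchar(query)] <- NA_integer_
  model$residues$seq_pos <- new_pos
  model
}

#' Locate a residue in a structure
#'
#' @param model A `ddg_structure`.
#' @param seq_pos Sequence position (in the model's current `seq_pos`
#'   coordinates), or
#' @param resno,ins author residue number and insertion code.
#' @return A one-row tibble from `model$residues` (class
#'   `ddg_structure_site`).
#' @export
structure_site <- function(model, seq_pos = NULL, resno = NULL, ins = "") {
  stopifnot(inherits(model, "ddg_structure"))
  res <- model$residues
  hit <- if (!is.null(seq_pos)) {
    which(!is.na(res$seq_pos) & res$seq_pos == seq_pos)
  } else {
    which(res$resno == resno & res$ins == ins)
  }
  if (length(hit) != 1L) {
    stop("residue not found (or ambiguous) in chain ", model$chain_id, call. = FALSE)
  }
  site <- res[hit, ]
  class(site) <- c("ddg_structure_site", class(site))
  site
}

residue_coords <- function(model, key) {
  a <- model$atoms[model$atoms$key == key, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Structural environment of a variant site
#'
#' The environment is the set of residues with any heavy atom within
#' `radius` of any heavy atom of the site (minimum heavy-atom distance
#' rule), computed on the wild-type structure only; the site itself is
#' never its own neighbour. The default 5 Å radius defines the contact
#' sphere used by the spatial score.
#'
#' @param model A `ddg_structure`.
#' @param site A `ddg_structure_site` from [structure_site()].
#' @param radius Contact radius in Å (default 5.0).
#' @return A `ddg_environment`: list with `center` (the site row),
#'   `neighbors` (tibble of neighbouring residue rows plus their minimum
#'   distance `dist`), and `radius`.
#' @export
find_environment <- function(model, site, radius = 5.0) {
  stopifnot(inherits(model, "ddg_structure"), inherits(site, "ddg_structure_site"))
  xyz_site <- residue_coords(model, site$key)
  if (nrow(xyz_site) == 0L) stop("site residue has no coordinates", call. = FALSE)
  others <- model$residues[model$residues$key != site$key, , drop = FALSE]
  if (nrow(others) == 0L) {
    return(structure(list(center = site, neighbors = others, radius = radius),
                     class = "ddg_environment"))
  }
  mind <- vapply(others$key, function(k) {
    min(cross_dist(xyz_site, residue_coords(model, k)))
  }, 0, USE.NAMES = FALSE)
  nb <- others[mind <= radius, , drop = FALSE]
  nb$dist <- mind[mind <= radius]
  structure(list(center = site, neighbors = nb, radius = radius),
            class = "ddg_environment")
}

# all pairwise Euclidean distances between two coordinate matrices
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Spatial-contact score for one substitution
#'
#' Profile-weighted difference in contact energy between the variant and
#' wild-type residue with the residues of the structural environment:
#' \deqn{s_{BV} = \sum_{r \in env} \sum_a f_{pos(r)}(a)\,[P(a,m) - P(a,w)]}
#' where \eqn{P} is the spatial-contact pair potential and
#' \eqn{f_{pos(r)}} the profile column of neighbour \eqn{r}. Neighbours of
#' nonstandard type or without a mapping into the profile are skipped with
#' a warning. An empty environment scores 0. Anti-symmetric under
#' wild-type/variant exchange, like the sequence scores.
#'
#' @param profile A `ddg_profile`.
#' @param env A `ddg_environment` from [find_environment()].
#' @param v A single substitution (string or one-row `ddg_multivariant`).
#' @return Scalar score (dimensionless).
#' @export
score_bastolla <- function(profile, env, v) {
  v <- as_single_variant(v)
  stopifnot(inherits(env, "ddg_environment"))
  nb <- env$neighbors
  if (nrow(nb) == 0L) return(0)
  usable <- !is.na(nb$aa) & !is.na(nb$seq_pos) & nb$seq_pos <= profile$length
  if (any(!usable)) {
    warning(sum(!usable), " environment residue(s) not mapped to the profile; skipped",
            call. = FALSE)
  }
  if (!any(usable)) return(0)
  delta <- pair_delta(load_table("bastolla_vendruscolo"), v$wt, v$mut)
  sum(vapply(nb$seq_pos[usable],
             function(j) sum(profile_column(profile, j) * delta), 0))
}
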