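#' @name evo_scores
#' @title Profile-weighted sequence scores for one substitution
#'
#' @description
#' The three sequence-based scores underlying the predictor. Each is a
#' profile-weighted difference "variant minus wild-type", so each is exactly
#' anti-symmetric: scoring the reverse substitution under the same profile
#' flips the sign, and an identity substitution scores 0.
#'
#' * `score_blosum()` — conservation term. With the profile column
#'   \eqn{f_j} at the variant position \eqn{j},
#'   \deqn{s_{Bl} = \sum_a f_j(a)\,[B(a, m) - B(a, w)]}
#'   where \eqn{B} is BLOSUM62, \eqn{w} the wild-type and \eqn{m} the
#'   variant residue. Under a one-hot profile this reduces to the plain
#'   matrix difference \eqn{B(w,m) - B(w,w)}.
#' * `score_skolnick()` — sequence-neighbour interaction term. Over
#'   positions \eqn{k} within `window` of \eqn{j} (both sides, excluding
#'   \eqn{j}, clipped to the sequence),
#'   \deqn{s_{Sk} = \sum_{k} \sum_a f_k(a)\,[P(a, m) - P(a, w)]}
#'   with \eqn{P} the sequence-contact pair potential; each neighbour is
#'   weighted by its own profile column.
#' * `score_hydrophobicity()` — hydropathy term,
#'   \deqn{s_{Hp} = f_j(m)\,K(m) - f_j(w)\,K(w)}
#'   with \eqn{K} the Kyte-Doolittle scale.
#'
#' @param profile A `ddg_profile`.
#' @param v A single substitution: either a one-row `ddg_multivariant` with
#'   `pos` resolved, or a string like `"A5R"`.
#' @param window Sequence half-window for `score_skolnick()` (positions
#'   within `window` of the site on either side; default 2).
#' @return A scalar score (dimensionless).
#' @examples
#' p <- single_sequence_profile("AAAAA")
#' score_blosum(p, "A3R")          # B(A,R) - B(A,A) = -5
#' score_hydrophobicity(p, "A3R")  # -K(A) = -1.8
NULL

# Internal: coerce `v` to a validated single substitution list(wt, pos, mut).
as_single_variant <- function(v) {
  if (is.character(v)) v <- parse_variant_line(v)
  stopifnot(inherits(v, "ddg_multivariant"))
  if (nrow(v) != 1L) {
    stop("expected a single substitution, got a multi-variant of size ", nrow(v),
         call. = FALSE)
  }
  if (is.na(v$pos[1])) {
    stop("variant '", v$token[1], "' has an unresolved (insertion-coded) position",
         call. = FALSE)
  }
  list(wt = v$wt[1], pos = v$pos[1], mut = v$mut[1])
}

pair_delta <- function(table, wt, mut) table[, mut] - table[, wt]

#' @rdname evo_scores
#' @export
score_blosum <- function(profile, v) {
  v <- as_single_variant(v)
  f <- profile_column(profile, v$pos)
  sum(f * pair_delta(load_table("blosum62"), v$wt, v$mut))
}

#' @rdname evo_scores
#' @export
score_skolnick <- function(profile, v, window = 2L) {
  v <- as_single_variant(v)
  stopifnot(window >= 1L)
  ks <- setdiff(seq(v$pos - window, v$pos + window), v$pos)
  ks <- ks[ks >= 1L & ks <= profile$length]
  if (length(ks) == 0L) return(0)
  delta <- pair_delta(load_table("skolnick"), v$wt, v$mut)
  sum(vapply(ks, function(k) sum(profile_column(profile, k) * delta), 0))
}

#' @rdname evo_scores
#' @export
score_hydrophobicity <- function(profile, v) {
  v <- as_single_variant(v)
  f <- profile_column(profile, v$pos)
  K <- load_table("kyte_doolittle")
  f[[v$mut]] * K[[v$mut]] - f[[v$wt]] * K[[v$wt]]
}

#' All scores for one substitution
#'
#' Convenience wrapper producing the full per-substitution breakdown used
#' by [predict_ddg()]: the three sequence scores and, when a structure is
#' supplied, the spatial-contact score and relative solvent accessibility.
#'
#' @inheritParams evo_scores
#' @param model Optional `ddg_structure`; when present `s_bv` and `rel_acc`
#'   are computed over its 5 Å environment (see [find_environment()]).
#' @param radius Contact radius in Å for the structural environment.
#' @param sasa_n Quadrature points per atom for the accessibility routine.
#' @return One-row tibble: `s_bl`, `s_sk`, `s_hp`, `s_bv`, `rel_acc` (the
#'   last two `NA` without a structure).
#' @export
score_breakdown <- function(profile, v, model = NULL, window = 2L,
                            radius = 5, sasa_n = 256L) {
  sv <- as_single_variant(v)
  out <- tibble::tibble(
    s_bl = score_blosum(profile, v),
    s_sk = score_skolnick(profile, v, window = window),
    s_hp = score_hydrophobicity(profile, v),
    s_bv = NA_real_, rel_acc = NA_real_)
  if (!is.null(model)) {
    site <- structure_site(model, seq_pos = sv$pos)
    env <- find_environment(model, site, radius = radius)
    out$s_bv <- score_bastolla(profile, env, v)
    out$rel_acc <- relative_accessibility(model, site, n_points = sasa_n)
  }
  out
}
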