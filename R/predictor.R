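#' Fixed combination weights
#'
#' The untrained linear-combination weights over the individual scores,
#' chosen a priori (proportional to typical stability changes and
#' normalized to sum to 1), never fitted: sequence mode uses
#' 0.30/0.43/0.27 over (`s_bl`, `s_sk`, `s_hp`); structure mode uses
#' 0.20/0.29/0.18/0.33 over (`s_bl`, `s_sk`, `s_hp`, `s_bv`).
#'
#' @format Named numeric vectors.
#' @export
DDG_WEIGHTS_SEQ <- c(s_bl = 0.30, s_sk = 0.43, s_hp = 0.27)

#' @rdname DDG_WEIGHTS_SEQ
#' @export
DDG_WEIGHTS_3D <- c(s_bl = 0.20, s_sk = 0.29, s_hp = 0.18, s_bv = 0.33)

#' Combine scores into a sequence-mode stability change
#'
#' \deqn{\Delta\Delta G_{seq} = 0.30\,s_{Bl} + 0.43\,s_{Sk} + 0.27\,s_{Hp}}
#' interpreted directly as kcal/mol; no calibration constant is applied.
#'
#' @param b A score breakdown: one-row data frame or named list with
#'   `s_bl`, `s_sk`, `s_hp` (and for [combine_3d()] also `s_bv`,
#'   `rel_acc`). Vectorized over data-frame rows.
#' @return Predicted stability change(s) in kcal/mol.
#' @examples
#' combine_seq(list(s_bl = 1, s_sk = 1, s_hp = 1))   # 1: weights sum to 1
#' @export
combine_seq <- function(b) {
  need <- c("s_bl", "s_sk", "s_hp")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("breakdown lacks ", paste(miss, collapse = ", "), call. = FALSE)
  DDG_WEIGHTS_SEQ[["s_bl"]] * b[["s_bl"]] +
    DDG_WEIGHTS_SEQ[["s_sk"]] * b[["s_sk"]] +
    DDG_WEIGHTS_SEQ[["s_hp"]] * b[["s_hp"]]
}

#' Combine scores into a structure-mode stability change
#'
#' \deqn{\Delta\Delta G_{3D} = (1.1 - ac)\,(0.20\,s_{Bl} + 0.29\,s_{Sk} +
#'   0.18\,s_{Hp} + 0.33\,s_{BV})}
#' where `ac` is the wild-type residue's relative solvent accessibility.
#' The `(1.1 - ac)` factor damps predictions at exposed sites (factor
#' exactly 1 at `ac = 0.1`, down to 0.1 at `ac = 1`) and leaves buried
#' sites near full strength. Because `ac` comes from the wild-type
#' structure only, this factor is the one place where exact anti-symmetry
#' can be lost.
#'
#' @inheritParams combine_seq
#' @return Predicted stability change(s) in kcal/mol.
#' @export
combine_3d <- function(b) {
  need <- c("s_bl", "s_sk", "s_hp", "s_bv", "rel_acc")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("breakdown lacks ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(b[["s_bv"]]) || anyNA(b[["rel_acc"]])) {
    stop("structure-mode combination requires s_bv and rel_acc; ",
         "was a structure supplied?", call. = FALSE)
  }
  (1.1 - b[["rel_acc"]]) *
    (DDG_WEIGHTS_3D[["s_bl"]] * b[["s_bl"]] +
       DDG_WEIGHTS_3D[["s_sk"]] * b[["s_sk"]] +
       DDG_WEIGHTS_3D[["s_hp"]] * b[["s_hp"]] +
       DDG_WEIGHTS_3D[["s_bv"]] * b[["s_bv"]])
}

#' Combine per-substitution predictions for a multi-site variant
#'
#' \deqn{s_{mult} = \max(s) + \min(s) - \mathrm{mean}(s)}
#' over the single-substitution predictions: the extremes are assumed to
#' dominate the joint effect and their sum is centred on the mean. For one
#' component this is the identity; for two it equals their mean.
#'
#' @param components Numeric vector of per-substitution predictions
#'   (kcal/mol), length >= 1, all finite.
#' @return Combined prediction (kcal/mol).
#' @examples
#' combine_multi(c(-1, 0, 4))   # 4 + (-1) - 1 = 2
#' @export
combine_multi <- function(components) {
  if (length(components) == 0L) stop("no components to combine", call. = FALSE)
  if (any(!is.finite(components))) stop("non-finite component prediction", call. = FALSE)
  max(components) + min(components) - mean(components)
}

#' Classify a predicted stability change
#'
#' The prediction is rounded for display (default 1 decimal); exactly 0.0
#' after rounding is a neutral effect, positive is a stability increase,
#' negative a decrease. The sign convention is
#' \eqn{\Delta\Delta G = \Delta G_{variant} - \Delta G_{wild-type}}, so
#' negative values are destabilizing.
#'
#' @param ddg Predicted stability change(s), kcal/mol.
#' @param decimals Decimals used for the displayed value (default 1).
#' @return Character vector in `{"increase", "decrease", "neutral"}`.
#' @export
classify_effect <- function(ddg, decimals = 1L) {
  r <- round(ddg, decimals)
  dplyr::case_when(r > 0 ~ "increase", r < 0 ~ "decrease", TRUE ~ "neutral")
}

#' Arrow/ASCII symbol for an effect class
#'
#' @param effect Character vector from [classify_effect()].
#' @param ascii Use `+`/`-`/`=` instead of arrows.
#' @return Character vector of symbols.
#' @export
effect_symbol <- function(effect, ascii = FALSE) {
  up <- if (ascii) "+" else "↑"
  down <- if (ascii) "-" else "↓"
  dplyr::case_when(effect == "increase" ~ up,
                   effect == "decrease" ~ down,
                   TRUE ~ "=")
}

#' Predict stability changes for a set of variants
#'
#' The main entry point. For every input (multi-)variant it computes the
#' per-substitution score breakdown, combines it into a sequence-based
#' and/or structure-based stability change, combines multi-site components
#' with the max + min - mean rule, and classifies the effect.
#'
#' Position conventions: without a structure, variant positions are
#' 1-based positions in the profile's query sequence. With a structure,
#' positions are the author residue numbers of the PDB chain (insertion
#' codes allowed, e.g. `T27AW`); the chain is aligned to the profile query
#' automatically (exact contiguous match, overhang allowed).
#'
#' @param variants Variants as a character vector of lines (multi-site
#'   variants comma-separated within a line), a data frame with a
#'   `variant` column, or a list of parsed `ddg_multivariant` objects.
#' @param profile A `ddg_profile` ([build_profile()] or
#'   [single_sequence_profile()]).
#' @param model Optional `ddg_structure`; required for modes `"3d"` and
#'   `"both"`.
#' @param mode `"seq"`, `"3d"`, or `"both"`.
#' @param window Sequence half-window for the neighbour score (default 2).
#' @param radius Contact radius in Å for the structural environment
#'   (default 5).
#' @param decimals Display rounding used for classification (default 1).
#' @param sasa_n Quadrature points per atom for accessibility (default 256).
#' @param check_wt Require each token's wild-type residue to match the
#'   query/chain (default `TRUE`). Set `FALSE` to score reverse
#'   substitutions under the unchanged wild-type profile, as in
#'   anti-symmetry checks.
#' @return A tibble (class `ddg_prediction`) with one row per input
#'   (multi-)variant: `variant`, `n_sites`, the score columns `s_bl`,
#'   `s_sk`, `s_hp` (plus `s_bv`, `rel_acc` in structure modes; `NA` for
#'   multi-site rows, see `components`), `ddg_seq`/`ddg_3d` (kcal/mol,
#'   full precision), matching `effect_*` classes, and a `components`
#'   list-column holding the per-substitution breakdown tibble.
#' @examples
#' p <- build_profile(make_msa(fixture_spec(seed = 7)))
#' predict_ddg(c("A3R", "A3R,A5W"), p)
#' @export
predict_ddg <- function(variants, profile, model = NULL,
                        mode = c("seq", "3d", "both"),
                        window = 2L, radius = 5, decimals = 1L,
                        sasa_n = 256L, check_wt = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "ddg_profile"))
  with_structure <- mode %in% c("3d", "both")
  if (with_structure && is.null(model)) {
    stop("mode '", mode, "' requires a structure model", call. = FALSE)
  }
  mvs <- normalize_variants(variants)
  query <- paste(profile$query, collapse = "")
  if (!is.null(model)) model <- map_structure(model, query)

  rows <- purrr::map(mvs, function(mv) {
    mv <- if (is.null(model)) validate_against_sequence(mv, query, check_wt = check_wt)
          else resolve_positions(mv, model, check_wt = check_wt)
    comp <- purrr::map_dfr(seq_len(nrow(mv)), function(i) {
      b <- score_breakdown(profile, mv[i, ],
                           model = if (with_structure) model else NULL,
                           window = window, radius = radius, sasa_n = sasa_n)
      dplyr::bind_cols(tibble::tibble(token = mv$token[i]), b)
    })
    comp$ddg_seq <- combine_seq(comp)
    if (with_structure) comp$ddg_3d <- combine_3d(comp)
    single <- nrow(comp) == 1L
    out <- tibble::tibble(
      variant = format_variant(mv),
      n_sites = nrow(comp),
      s_bl = if (single) comp$s_bl else NA_real_,
      s_sk = if (single) comp$s_sk else NA_real_,
      s_hp = if (single) comp$s_hp else NA_real_)
    if (with_structure) {
      out$s_bv <- if (single) comp$s_bv else NA_real_
      out$rel_acc <- if (single) comp$rel_acc else NA_real_
    }
    if (mode %in% c("seq", "both")) {
      out$ddg_seq <- combine_multi(comp$ddg_seq)
      out$effect_seq <- classify_effect(out$ddg_seq, decimals)
    }
    if (with_structure) {
      out$ddg_3d <- combine_multi(comp$ddg_3d)
      out$effect_3d <- classify_effect(out$ddg_3d, decimals)
    }
    out$components <- list(comp)
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "decimals") <- decimals
  class(out) <- c("ddg_prediction", class(out))
  out
}

normalize_variants <- function(variants) {
  if (inherits(variants, "ddg_multivariant")) return(list(variants))
  if (is.data.frame(variants)) {
    if (!"variant" %in% names(variants)) {
      stop("variant data frame needs a 'variant' column", call. = FALSE)
    }
    variants <- variants$variant
  }
  if (is.character(variants)) return(lapply(variants, parse_variant_line))
  if (is.list(variants) && all(vapply(variants, inherits, TRUE, "ddg_multivariant"))) {
    return(variants)
  }
  stop("cannot interpret 'variants'; supply strings, a data frame, or parsed variants",
       call. = FALSE)
}
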