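# Dual-perturbation dysregulation scoring.
#
# A protein's condition response (log2 fold change) is measured once under
# a reference perturbation state (vehicle, or knockout depending on the
# contrast) and once under an alternative state (inhibitor, or wild type).
# The dysregulation effect is the difference of the two log2 responses;
# its antilog (2^effect) is the linear ratio the flagging thresholds are
# applied to. Proteins affected similarly by two independent inhibitors of
# the same pathway are selected by the ratio of their effects
# (concordance) and the selection is confirmed by Pearson correlation.

#' Dysregulation effect of a perturbation on a condition response
#'
#' @param response_ref log2 condition response in the reference state
#'   (vehicle, or knockout for the genotype contrast).
#' @param response_alt log2 condition response in the alternative state
#'   (inhibitor, or wild type).
#' @param protein_id optional ids (recycled names for vector input).
#' @return data.frame (`DysregulationRecord`, unflagged): `protein_id`,
#'   `response_ref`, `response_alt`, `effect` (ref - alt), `linear_ratio`
#'   (2^effect).
#' @examples
#' inhibitor_effect(2.0, 0.0)  # effect 2, linear ratio 4
#' @export
inhibitor_effect <- function(response_ref, response_alt, protein_id = NULL) {
  if (any(!is.finite(response_ref)) || any(!is.finite(response_alt)))
    stop("responses must be finite")
  if (length(response_ref) != length(response_alt))
    stop("responses must have equal length")
  effect <- response_ref - response_alt
  data.frame(
    protein_id = if (is.null(protein_id))
      sprintf("p%d", seq_along(effect)) else as.character(protein_id),
    response_ref = response_ref,
    response_alt = response_alt,
    effect = effect,
    linear_ratio = 2^effect,
    stringsAsFactors = FALSE
  )
}

#' Flag dysregulated proteins
#'
#' Two flagging rules are in use for different experiments: the linear
#' `"ratio"` rule marks a protein dysregulated when `2^effect > 3` or
#' `< 0.33` (the printed bounds are used verbatim; 0.33 is not treated as
#' exactly 1/3), and the `"log2_threshold"` rule marks `|effect| >=
#' threshold` (boundary inclusive, default 0.25).
#'
#' @param records [inhibitor_effect()] output.
#' @param mode `"ratio"` or `"log2_threshold"`.
#' @param threshold log2 threshold for `"log2_threshold"` mode.
#' @return records with a logical `dysregulated` column and a `mode`
#'   column.
#' @export
flag_dysregulated <- function(records, mode = c("ratio", "log2_threshold"),
                              threshold = 0.25) {
  mode <- match.arg(mode)
  records$dysregulated <- switch(mode,
    ratio = records$linear_ratio > 3 | records$linear_ratio < 0.33,
    log2_threshold = abs(records$effect) >= threshold
  )
  records$mode <- mode
  records
}

#' Concordance of two inhibitors' effects
#'
#' Per-protein ratio of inhibitor A's dysregulation effect to inhibitor
#' B's; proteins with a ratio between `bounds[1]` and `bounds[2]`
#' (inclusive; default 0.3 and 3) are concordant, i.e. affected to a
#' similar degree by both perturbations. Proteins whose denominator effect
#' is within `epsilon` of zero have an unstable ratio and are excluded.
#'
#' @param effects_a,effects_b named numeric vectors of log2 effects
#'   (names = protein ids; the intersection is scored).
#' @param epsilon exclusion band for near-zero denominators (log2 units,
#'   default 0.05).
#' @param bounds concordance interval (default `c(0.3, 3)`).
#' @return data.frame (`ConcordanceRecord`): `protein_id`, `effect_a`,
#'   `effect_b`, `ratio`, `concordant`. Attribute `n_excluded` counts the
#'   near-zero-denominator exclusions.
#' @export
concordance <- function(effects_a, effects_b, epsilon = 0.05,
                        bounds = c(0.3, 3)) {
  stopifnot(epsilon > 0, length(bounds) == 2L, bounds[1] < bounds[2])
  shared <- intersect(names(effects_a), names(effects_b))
  if (!length(shared)) stop("no shared protein ids between effect sets")
  a <- effects_a[shared]; b <- effects_b[shared]
  keep <- abs(b) >= epsilon
  ratio <- a[keep] / b[keep]
  out <- data.frame(protein_id = shared[keep],
                    effect_a = unname(a[keep]),
                    effect_b = unname(b[keep]),
                    ratio = unname(ratio),
                    concordant = unname(ratio >= bounds[1] & ratio <= bounds[2]),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Pearson correlation of paired inhibitor effects
#'
#' @param records data.frame with `effect_a` and `effect_b` columns
#'   ([concordance()] output, typically restricted to concordant proteins).
#' @param r_gate correlation considered "highly correlated" when `r >
#'   r_gate` (default 0.7).
#' @return list: `pearson_r`, `highly_correlated`, `n`.
#' @export
correlate_effects <- function(records, r_gate = 0.7) {
  if (nrow(records) < 3L) stop("need >= 3 records to correlate")
  if (stats::var(records$effect_a) == 0 || stats::var(records$effect_b) == 0)
    stop("undefined correlation: zero variance on one axis")
  r <- stats::cor(records$effect_a, records$effect_b)
  list(pearson_r = r, highly_correlated = r > r_gate, n = nrow(records))
}

#' Genotype differential (knockout vs wild type)
#'
#' The genotype analogue of [inhibitor_effect()] + [flag_dysregulated()]:
#' the learning-induced change in knockouts minus the change in wild-type
#' controls, flagged with the linear ratio rule (> 3 or < 0.33).
#'
#' @param responses_ko,responses_wt named log2 responses per protein.
#' @return flagged `DysregulationRecord` data.frame with (ref, alt) =
#'   (KO, WT).
#' @export
genotype_differential <- function(responses_ko, responses_wt) {
  shared <- intersect(names(responses_ko), names(responses_wt))
  if (!length(shared)) stop("no shared protein ids between genotypes")
  rec <- inhibitor_effect(unname(responses_ko[shared]),
                          unname(responses_wt[shared]),
                          protein_id = shared)
  flag_dysregulated(rec, mode = "ratio")
}
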