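# Internal-standard quantification of targeted lipids from MRM peak areas.
#
# Acyl-CoAs are quantified against a fixed spike of pentadecanoyl (C15:0)
# CoA added to every sample before extraction; derivatized free fatty
# acids are quantified against an isotopologue-tagged internal-standard
# channel of known concentration. Single-point internal standardization:
# amount = (analyte area / IS area) x IS amount x response factor.

#' Internal-standard quantification of MRM peak areas
#'
#' @param peaks data.frame of one sample's MRM peaks with `analyte` and
#'   `area` columns (areas >= 0).
#' @param is_name analyte name of the internal standard (must be present
#'   with area > 0).
#' @param is_amount amount of internal standard spiked per sample (default
#'   20, in ng as added; any unit propagates).
#' @param response_factors named numeric vector of per-analyte response
#'   factors relative to the IS (default 1 for every analyte).
#' @param molar convert amounts to pmol using monoisotopic masses from the
#'   mass engine; requires `chain_lengths` naming each analyte's acyl
#'   carbon count.
#' @param chain_lengths named integer vector (analyte -> acyl carbons),
#'   used only when `molar = TRUE` (the IS amount is converted via its own
#'   chain length, which must be included).
#' @return data.frame (`AnalyteQuant`): `analyte`, `area`, `amount` (IS
#'   units, or pmol when `molar`).
#' @examples
#' pk <- data.frame(analyte = c("C14:0 CoA", "C15:0 CoA"), area = c(50, 100))
#' is_quantify(pk, "C15:0 CoA", is_amount = 20)  # 10 ng of C14:0 CoA
#' @export
is_quantify <- function(peaks, is_name, is_amount = 20,
                        response_factors = NULL, molar = FALSE,
                        chain_lengths = NULL) {
  stopifnot(all(c("analyte", "area") %in% names(peaks)))
  if (any(peaks$area < 0)) stop("areas must be >= 0")
  is_row <- peaks$analyte == is_name
  if (!any(is_row)) stop("internal standard '", is_name, "' missing")
  is_area <- sum(peaks$area[is_row])
  if (is_area <= 0) stop("internal standard area must be > 0")
  analytes <- peaks[!is_row, , drop = FALSE]
  rf <- rep(1, nrow(analytes))
  if (!is.null(response_factors)) {
    hit <- analytes$analyte %in% names(response_factors)
    rf[hit] <- response_factors[analytes$analyte[hit]]
  }
  amount <- (analytes$area / is_area) * is_amount * rf
  if (molar) {
    if (is.null(chain_lengths))
      stop("molar conversion requires chain_lengths for each analyte")
    needed <- c(analytes$analyte, is_name)
    missing_cl <- setdiff(needed, names(chain_lengths))
    if (length(missing_cl))
      stop("no chain length for: ", paste(missing_cl, collapse = ", "))
    mass_of <- function(a)
      monoisotopic_mass(acyl_coa_formula(chain_lengths[[a]]))
    # ng -> pmol: pmol = ng / (g/mol) * 1000; IS amount is in ng
    is_pmol <- is_amount / mass_of(is_name) * 1000
    amount <- (analytes$area / is_area) * is_pmol * rf
  }
  data.frame(analyte = analytes$analyte, area = analytes$area,
             amount = amount, stringsAsFactors = FALSE)
}

#' Quantify FFAST-derivatized free fatty acids
#'
#' Multiplexed quantification against the heavy-tag internal-standard
#' channel: the IS solution of known molar concentration contributes
#' `is_conc * volume_ul` pmol per sample, and each light-channel FFA is
#' quantified by its channel ratio, normalized per mg of tissue. The two
#' sample channels of a multiplexed pair are quantified independently by
#' calling this once per channel.
#'
#' @param areas_light named numeric vector: sample-channel peak area per
#'   FFA.
#' @param areas_is named numeric vector: internal-standard-channel area
#'   per FFA (all > 0; names must cover `areas_light`).
#' @param is_conc IS concentration in uM (default 2.5).
#' @param volume_ul reconstitution volume in uL (default 200).
#' @param tissue_mg tissue mass (or protein-equivalent denominator) in mg
#'   (> 0).
#' @return data.frame: `analyte`, `pmol_per_mg`.
#' @examples
#' ffast_quantify(c(myristic = 50), c(myristic = 50), tissue_mg = 1)
#' # unity ratio, 2.5 uM x 200 uL -> 500 pmol/mg
#' @export
ffast_quantify <- function(areas_light, areas_is, is_conc = 2.5,
                           volume_ul = 200, tissue_mg) {
  if (missing(tissue_mg) || tissue_mg <= 0) stop("tissue_mg must be > 0")
  missing_is <- setdiff(names(areas_light), names(areas_is))
  if (length(missing_is))
    stop("no IS-channel area for: ", paste(missing_is, collapse = ", "))
  is_a <- areas_is[names(areas_light)]
  if (any(is_a <= 0)) stop("IS-channel areas must be > 0")
  if (any(areas_light < 0)) stop("areas must be >= 0")
  # uM = pmol/uL, so IS pmol in the vial = is_conc * volume_ul
  pmol <- (areas_light / is_a) * is_conc * volume_ul
  data.frame(analyte = names(areas_light),
             pmol_per_mg = unname(pmol / tissue_mg),
             stringsAsFactors = FALSE)
}

#' Molar composition of an analyte panel
#'
#' Percent of each analyte in the summed molar amount of the panel --
#' typically the myristoyl/palmitoyl/stearoyl CoA trio whose resting and
#' stimulated proportions characterize acyl-CoA substrate flux.
#'
#' @param amounts named non-negative molar amounts, sum > 0.
#' @return data.frame: `analyte`, `percent` (sums to 100).
#' @examples
#' composition_percent(c(myr = 0.003, palm = 0.522, stear = 0.475))
#' @export
composition_percent <- function(amounts) {
  if (any(amounts < 0)) stop("amounts must be >= 0")
  total <- sum(amounts)
  if (total <= 0) stop("undefined composition: zero total amount")
  data.frame(analyte = names(amounts),
             percent = unname(100 * amounts / total),
             stringsAsFactors = FALSE)
}

#' Relative change of analyte amounts between conditions
#'
#' log2 of the condition mean over the control mean, per analyte (and per
#' timepoint when a `timepoint` column is present). Zero control means are
#' flagged `undefined` rather than dropped.
#'
#' @param quants_condition,quants_control data.frames with `analyte`,
#'   `amount` and optionally `timepoint` columns, replicate rows.
#' @return data.frame: `analyte` (, `timepoint`), `log2_change`, `status`.
#' @export
relative_change <- function(quants_condition, quants_control) {
  by_cols <- intersect(c("analyte", "timepoint"), names(quants_condition))
  agg <- function(df) stats::aggregate(df["amount"], df[by_cols], mean)
  mc <- agg(quants_condition); m0 <- agg(quants_control)
  merged <- merge(mc, m0, by = by_cols, suffixes = c("_cond", "_ctrl"))
  undefined <- merged$amount_ctrl <= 0
  merged$log2_change <- ifelse(undefined, NA,
                               log2(merged$amount_cond / merged$amount_ctrl))
  merged$status <- ifelse(undefined, "undefined_zero_control", "ok")
  merged[order(merged[[by_cols[1]]]), c(by_cols, "log2_change", "status")]
}
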