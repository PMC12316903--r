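# Physical constants used by the mass engine.
#
# Monoisotopic atomic masses (u) for the most abundant isotope of each
# element, CODATA/AME2020 values truncated well below the 1e-3 Da accuracy
# contract of monoisotopic_mass(). Hard-coded in this one file so that every
# printed m/z in the package is reproducible without external dependencies.

.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268,
  F  = 18.99840316,
  Br = 78.91833760,
  I  = 126.90447300,
  Se = 79.91652180,
  Fe = 55.93493633,
  Si = 27.97692653
)

# Mass of the proton: the charge carrier for all [M+H]+ species here.
# Deliberately not the hydrogen-atom mass (which includes the electron);
# the printed one-decimal MRM values are reproduced with the proton.
.PROTON_MASS <- 1.00727646688

# Amino-acid residue compositions (peptide-bond residues, i.e. the monomer
# minus water). Residue masses are always derived from these via the atomic
# table above so the whole package uses a single mass scale.
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

# Coenzyme A (free acid) and the neutral loss that dominates positive-mode
# acyl-CoA fragmentation (3'-phospho-ADP), giving the characteristic
# precursor - 507.0 product ions monitored on triple quadrupoles.
.COA_FORMULA <- "C21H36N7O16P3S"
.PHOSPHO_ADP_LOSS_FORMULA <- "C10H16N5O13P3"

#' Round half-up at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; instrument software and printed
#' transition tables round half away from zero. All reported m/z values in
#' this package use half-up rounding at the printed precision.
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
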