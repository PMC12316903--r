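# Elemental-formula mass engine: formula arithmetic, monoisotopic masses,
# theoretical acyl-CoA MRM transitions and N-acyl b1 marker ions.

#' Create an elemental formula
#'
#' An elemental formula is a named integer vector of element counts
#' (class `"elemental_formula"`). It can be built from a Hill-style string
#' such as `"C21H36N7O16P3S"` or from a named vector of counts. Formulas
#' support `+` and `-`; subtraction that would drive any element negative is
#' an error, since a molecular composition cannot contain negative atoms.
#'
#' @param x a formula string (e.g. `"H2O"`), a named numeric vector of
#'   counts, or an existing `elemental_formula`.
#' @return an `elemental_formula` object.
#' @examples
#' elemental_formula("H2O")
#' elemental_formula(c(C = 2, H = 2, O = 1))
#' @export
elemental_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    counts <- .parse_formula_string(x)
  } else if (is.numeric(x)) {
    if (length(x) > 0L && is.null(names(x)))
      stop("numeric formula input must be named by element symbol")
    counts <- x
  } else {
    stop("cannot interpret input as an elemental formula")
  }
  .validate_counts(counts)
}

.parse_formula_string <- function(s) {
  if (s == "") return(stats::setNames(numeric(0), character(0)))
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(matches))[[1]]
  if (sum(nchar(parts)) != nchar(s))
    stop("malformed formula string: ", s)
  elems <- sub("[0-9]*$", "", parts)
  n <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  tapply(n, elems, sum)[unique(elems)]
}

.validate_counts <- function(counts) {
  counts <- counts[counts != 0]
  bad <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0))
    stop("element counts must be non-negative")
  if (any(counts != floor(counts)))
    stop("element counts must be integers")
  structure(counts[order(names(counts))], class = "elemental_formula")
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  a <- unclass(elemental_formula(e1)); b <- unclass(elemental_formula(e2))
  elems <- union(names(a), names(b))
  out <- stats::setNames(rep(0, length(elems)), elems)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  .validate_counts(out)
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  a <- unclass(elemental_formula(e1)); b <- unclass(elemental_formula(e2))
  elems <- union(names(a), names(b))
  out <- stats::setNames(rep(0, length(elems)), elems)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0))
    stop("formula subtraction would yield negative element counts")
  .validate_counts(out)
}

#' @export
format.elemental_formula <- function(x, ...) {
  counts <- unclass(x)
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  paste0(hill, ifelse(counts[hill] > 1, counts[hill], ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of count-weighted monoisotopic atomic masses. Deterministic; accurate
#' to well under 1e-3 Da for formulas of the size handled here.
#'
#' @param formula an [elemental_formula()] or formula string.
#' @return mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("H2O")              # 18.0106
#' monoisotopic_mass("C21H36N7O16P3S")   # coenzyme A, 767.1152
#' @export
monoisotopic_mass <- function(formula) {
  f <- elemental_formula(formula)
  counts <- unclass(f)
  if (length(counts) == 0L) return(0)
  sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Molecular formula of an acyl-CoA thioester
#'
#' Coenzyme A condensed with a fatty acid of the given chain length and
#' number of double bonds (loss of one water in the thioester linkage).
#'
#' @param chain_length number of acyl carbons (2--30).
#' @param n_double_bonds number of C=C double bonds (each removes H2).
#' @return an `elemental_formula`.
#' @export
acyl_coa_formula <- function(chain_length, n_double_bonds = 0) {
  .check_chain(chain_length, n_double_bonds)
  fatty_acid <- elemental_formula(c(C = chain_length,
                                    H = 2 * chain_length - 2 * n_double_bonds,
                                    O = 2))
  elemental_formula(.COA_FORMULA) + fatty_acid - elemental_formula("H2O")
}

.check_chain <- function(chain_length, n_double_bonds) {
  if (length(chain_length) != 1L || chain_length < 2 || chain_length > 30 ||
      chain_length != floor(chain_length))
    stop("chain_length must be a single integer in [2, 30]")
  if (length(n_double_bonds) != 1L || n_double_bonds < 0 ||
      n_double_bonds >= chain_length / 2 ||
      n_double_bonds != floor(n_double_bonds))
    stop("n_double_bonds must be a single integer in [0, chain_length/2)")
  invisible(TRUE)
}

#' Theoretical MRM transition for an acyl-CoA species
#'
#' Positive-mode acyl-CoAs fragment by neutral loss of 3'-phospho-ADP
#' (C10H16N5O13P3, 506.996 Da), so the quantifier product ion sits at a
#' fixed offset below every [M+H]+ precursor. Both values are reported
#' rounded half-up to one decimal, the precision used on triple-quadrupole
#' instruments; the unrounded masses are carried alongside.
#'
#' @param chain_length number of acyl carbons.
#' @param n_double_bonds number of C=C double bonds (default 0, saturated).
#' @return a one-row data.frame (a `TransitionSpec`): `analyte`,
#'   `precursor_mz`, `product_mz` at printed precision, plus
#'   `precursor_mz_exact` and `product_mz_exact`.
#' @examples
#' acyl_coa_transition(14)  # myristoyl-CoA: 978.3 -> 471.3
#' acyl_coa_transition(16)  # palmitoyl-CoA: 1006.4 -> 499.4
#' @export
acyl_coa_transition <- function(chain_length, n_double_bonds = 0) {
  f <- acyl_coa_formula(chain_length, n_double_bonds)
  precursor <- monoisotopic_mass(f) + .PROTON_MASS
  product <- precursor - monoisotopic_mass(.PHOSPHO_ADP_LOSS_FORMULA)
  data.frame(
    analyte = sprintf("C%d:%d CoA", chain_length, n_double_bonds),
    precursor_mz = round_half_up(precursor, 1),
    product_mz = round_half_up(product, 1),
    precursor_mz_exact = precursor,
    product_mz_exact = product,
    stringsAsFactors = FALSE
  )
}

#' Transition table for a set of acyl chain lengths
#'
#' @param chain_lengths integer vector of acyl carbon counts.
#' @param n_double_bonds recycled against `chain_lengths`.
#' @return data.frame of transitions, one row per chain.
#' @export
acyl_coa_transition_table <- function(chain_lengths, n_double_bonds = 0) {
  n_double_bonds <- rep_len(n_double_bonds, length(chain_lengths))
  do.call(rbind, Map(acyl_coa_transition, chain_lengths, n_double_bonds))
}

#' b1 marker-ion m/z of an N-acylated residue
#'
#' The b1 acylium ion of an N-terminally acylated peptide retains the first
#' residue plus the acyl group; for myristoylated glycine it is the
#' diagnostic 268.23 m/z fragment that flags a myristoylated peptide
#' independent of sequence identification. The acyl formula is the *net*
#' mass addition of the modification (RCO- replacing one amide hydrogen),
#' e.g. `"C14H26O"` for myristoyl, `"C2H2O"` for acetyl; `NULL` gives the
#' unmodified b1 ion.
#'
#' @param acyl_formula net acyl composition (formula or string), or `NULL`.
#' @param residue one-letter code of a standard amino acid.
#' @return m/z rounded half-up to two decimals.
#' @examples
#' acyl_b1_mz("C14H26O", "G")  # 268.23, myristoyl-glycine marker
#' acyl_b1_mz(NULL, "G")       # 58.03
#' @export
acyl_b1_mz <- function(acyl_formula, residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% names(.RESIDUE_FORMULA))
    stop("residue must be one of the 20 standard one-letter codes")
  res_mass <- monoisotopic_mass(.RESIDUE_FORMULA[[residue]])
  acyl_mass <- if (is.null(acyl_formula)) 0 else monoisotopic_mass(acyl_formula)
  round_half_up(res_mass + acyl_mass + .PROTON_MASS, 2)
}

#' Monoisotopic mass of a proton
#'
#' @return the proton mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS

#' Net acyl-group formula of common N-acyl modifications
#'
#' @param name one of `"myristoyl"`, `"palmitoyl"`, `"stearoyl"`,
#'   `"acetyl"`.
#' @return an `elemental_formula` for the net mass addition.
#' @export
acyl_group_formula <- function(name = c("myristoyl", "palmitoyl",
                                        "stearoyl", "acetyl")) {
  name <- match.arg(name)
  elemental_formula(switch(name,
    myristoyl = "C14H26O",
    palmitoyl = "C16H30O",
    stearoyl  = "C18H34O",
    acetyl    = "C2H2O"
  ))
}
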