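---
title: "Methods: marker-ion myristoylome profiling, spike-in-calibrated differential proteomics and targeted acyl-CoA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-ion myristoylome profiling, spike-in-calibrated differential proteomics and targeted acyl-CoA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myrms)
```

## Scientific setting

During synaptic plasticity, the phospholipase A1 isoform DDHD2 releases
saturated free fatty acids — most notably myristic acid (C14:0) — from
membrane phospholipids. Myristic acid is activated as myristoyl-CoA, the
substrate N-myristoyl transferases (NMT1/2) use to myristoylate synaptic
proteins. Probing this pathway by mass spectrometry requires four kinds of
analysis that this package implements as one toolbox:

1. **Targeted lipid quantification.** Acyl-CoA species are measured by
   multiple reaction monitoring (MRM) on a triple quadrupole against a
   pentadecanoyl (C15:0) CoA internal standard; derivatized free fatty
   acids are measured against an isotopologue-tagged internal-standard
   channel. The theoretical transitions come from an elemental-formula
   mass engine.
2. **Spike-in-calibrated differential proteomics.** Protein-level DIA
   intensity matrices are tested for condition effects per protein, with
   the fold-change significance threshold derived from an exogenous
   chicken-lysozyme process control spiked equally into every sample.
3. **Database-independent myristoylome profiling.** MS/MS spectra are
   scanned for the diagnostic b1 fragment of N-myristoylated glycine at
   268.23 m/z; precursor features of hit spectra are binned, aligned
   across samples, and profiled by PCA — no sequence database needed.
4. **Dual-perturbation dysregulation scoring.** The degree to which an
   inhibitor (or a genotype) disrupts a condition-induced protein response
   is scored per protein, and two independent inhibitors of the same
   pathway are compared by concordance and correlation.

## The mass engine

Monoisotopic masses are summed from a single hard-coded table of atomic
masses (`R/masses.R`); everything printed by the package derives from that
one scale. Three conventions matter and are deliberate:

- **Charge carrier is a proton** (1.00728 Da), not a hydrogen atom. The
  electron mass (0.00055 Da) is below the one-decimal precision of the MRM
  tables but using the H-atom mass is conceptually wrong for [M+H]+.
- **Rounding is half-up at the printed precision** (one decimal for MRM
  transitions, two for the marker ion). Base R's `round()` rounds half to
  even, which instrument software does not; `round_half_up()` makes every
  reported value deterministic and table-faithful.
- **Acyl-CoA composition is assembled, not looked up**: CoA
  (C~21~H~36~N~7~O~16~P~3~S) plus the fatty acid C~n~H~2n−2d~O~2~ minus
  one water. The quantifier product ion is the neutral loss of
  3′-phospho-ADP (C~10~H~16~N~5~O~13~P~3~, 506.996 Da), so precursor −
  product is constant across all saturated species — a structural
  invariant the tests exploit.

```{r}
acyl_coa_transition_table(c(14, 15, 16, 18))[, 1:3]
acyl_b1_mz(acyl_group_formula("myristoyl"), "G")
```

Unsaturated chains subtract two hydrogens per double bond; the saturated
C15:0 internal standard is used throughout (its printed precursor matches
the saturated formula, not the C15:1 one, which settles an ambiguity in
how the standard is sometimes named).

## Marker-ion profiling

`scan_spectrum()` reports a hit when a fragment peak lies within ±`tol` of
268.23 m/z with intensity strictly above 20 counts. Both values are
parameters:

- `min_intensity = 20` counts is read literally as an absolute gate with
  strict inequality.
- `tol = 0.02` Da (~75 ppm at 268 m/z) is a deliberately generous default
  for QTOF-class accuracy; the target is only printed to two decimals, so
  a ppm-exact tolerance would be false precision.

`bin_precursors()` then sums precursor intensities of hit spectra within
1 m/z, absorbing repeated MS/MS sampling of isotope satellites into one
feature. The clustering is **seed-anchored**: walking hits in ascending
precursor m/z, a hit joins the open bin iff its m/z minus the bin's first
member is < 1. This is deterministic, order-free (the sort fixes the
order), and matches the purpose of the rule — satellites sit *above* the
monoisotopic seed. The bin m/z and RT centroid are intensity-weighted
means. Summed intensity is conserved exactly (tested against a
brute-force clustering oracle).

Cross-sample alignment (`build_profile_matrix()`) is not described by the
upstream procedure at all, but a profile matrix cannot exist without it;
we merge bins across samples at `align_tol = 0.5` m/z (half the bin
width) and `rt_tol = 1` min, and impute absent features as 0 — absence of
marker evidence is informative, and PCA needs complete data. PCA runs on
mean-centered, unit-variance-scaled features (comparability across
intensity scales; whether the original analysis scaled or
log-transformed is unknown, so both knobs are exposed), retaining
components by the Kaiser rule (eigenvalue > 1) with the top two as the
plotted dimensions. Whether repeated sampling of one precursor across RT
should be deduplicated before summing is likewise unstated; the default
keeps all scans.

## Spike-in calibration and differential testing

Equal spike-in amounts mean the spread of the measured spike intensity is
pure measurement variability. `calibrate_spikein()` normalizes the spike
values to mean 1 and maps mean ± 2 SD into a log2 fold-change cut-off:

\[ c = \log_2(1 + 2\,\mathrm{SD}) \]

The rule is stated verbally upstream ("mean ± 2 standard deviations");
this mapping is the one that reproduces the quoted ±0.3 cut-off from the
quoted 13% spike SD (log2(1.26) = 0.333, reported rounded to 0.3). An
alternative mode applies 2 SD in log2 space. The "mean ±" part cannot
re-center anything — the normalized mean is 1 by construction.

`diff_expression()` computes per-protein log2 fold changes of group means
and two-sided pooled-variance Student's t-tests (as named in the source
legends; Welch is available in `log2_response()`). Conventions for
degenerate inputs: zero intensities are missing values (tested on the
remaining replicates when ≥ 2 remain, otherwise flagged, never silently
dropped); zero pooled variance with equal means is p = 1; nonpositive
group means make the fold change undefined and the record is flagged.
Volcano significance (`classify_volcano()`) requires both |log2FC| ≥
cut-off and raw p < 0.05 — multiple-testing correction is applied only
where the original analyses applied it (the lipid panels, via
`holm_sidak()`), and both behaviours are exposed. Different experiments
use different fold-change thresholds (the spike-derived 0.3 for
whole-proteome panels, 0.25 for membrane-fraction panels); the threshold
is always a parameter with per-arm defaults.

`holm_sidak()` is the step-down procedure: sort ascending, adjust the
k-th of m p values to 1 − (1−p)^(m−k+1), enforce monotonicity, cap at 1.

## Dysregulation and concordance

For each protein the condition response (log2[stimulated/control]) is
measured under a reference state and under a perturbation;
`inhibitor_effect()` scores the perturbation as the difference of the two
responses, and `2^effect` is the linear ratio. Two flagging rules exist
because the source experiments used two:

- **ratio rule**: dysregulated iff 2^effect > 3 or < 0.33. The printed
  0.33 is used verbatim, *not* as exactly 1/3 — a protein at ratio
  0.3333 is not flagged. The upper bound corresponds to |Δlog2| > 1.585.
- **log2-threshold rule**: dysregulated iff |effect| ≥ 0.25 (inclusive).

`concordance()` divides one inhibitor's effect by the other's and selects
ratios within [0.3, 3] (inclusive). Effects within `epsilon = 0.05` log2
units of zero in the denominator are excluded — the ratio of two
near-zero noise values is meaningless; the bound is our choice, exposed
as a parameter. `correlate_effects()` confirms a concordant set with
Pearson correlation, "highly correlated" meaning r > 0.7. The genotype
contrast (`genotype_differential()`) is the same arithmetic with
(reference, alternative) = (knockout, wild type).

## Lipid quantification

Single-point internal standardization throughout:
amount = (area / IS area) × IS amount × response factor. Response factors
default to 1 (no calibration curves are described upstream); a response
factor table is accepted. The FFAST free-fatty-acid variant uses the
internal-standard channel concentration (2.5 µM) and reconstitution
volume: a µM is a pmol/µL, so the IS contributes `is_conc × volume_ul`
pmol, scaled by the channel ratio and normalized per mg tissue. This
formula is reconstructed from the stated IS concentration and the
tissue normalization; for cultured-neuron samples any per-sample
denominator (e.g. protein content) can stand in for tissue mass.
ng↔pmol conversion uses monoisotopic masses from the mass engine
(difference from average masses < 0.1%). `composition_percent()` closes a
panel to 100% exactly and is scale-invariant.

## The synthetic-data generators

The generators define the conditions every quantitative test runs under;
they are first-class, tested code.

**`gen_msms()`** plants marker scans on a jittered grid of precursor
features (spacing ≫ bin width so features are well-separated), marker
peaks at 268.23 + N(0, 0.005) Da with intensity drawn above the gate
(50–500 counts), decoy peaks kept ≥ 0.1 Da from the target, and one
isotope satellite scan per marker scan with probability 0.6 at
+1.0034/z with intensity decay 0.6. At charge 2 one satellite stays
strictly inside the 1-m/z summing window; the second isotope would sit on
its boundary, which is why the generator plants at most one. Group
structure for PCA is a log2 intensity shift on half the features in half
the samples.

**`gen_quant()`** draws log-normal protein intensities (multiplicative
noise of CV `noise_cv`), plants a signed effect of magnitude
`effect_log2` on a fraction of proteins in the stimulated condition —
random up/down, matching the roughly balanced up/down counts real
experiments show, and necessary for a meaningful between-protein
correlation in the concordance analysis — attenuated per treatment by
`inhibitor_attenuation`. The spike-in row has its sample CV controlled
*exactly* at `spike_cv` (deviations standardized and rescaled), so the
calibration cut-off is determined by the parameter rather than by the
sampling noise of an SD at small n: at the default 13% the derived
cut-off is 0.3 in every run.

**`gen_mrm()`** converts planted amounts to areas through a shared
instrument response factor and two noise components: a per-sample run
factor of CV `noise_cv` common to every peak in the sample (injection,
extraction, ionisation drift — exactly what an internal standard is for)
and an independent per-peak factor of CV `noise_cv`/2. After IS
normalization the run factor cancels and the residual relative error
comes from the independent component only; with fully independent
analyte and IS noise the IS division would *add* √2× the noise, which
contradicts both the physics and the observable precision of
internal-standard assays. The default planted time-course follows the
published composition regime: the myristoyl species at a trace share of
the trio at rest (0.3%) surging about ten-fold on stimulation (3.2%) and
re-equilibrating by 120 min.

What the generators do **not** emulate: chromatogram-level peak shapes,
real peptide sequences, identification FDR, batch structure, or
missingness mechanisms beyond zeros-as-missing. Passing tests therefore
demonstrate correctness of the computational procedures under their
stated statistical assumptions, not robustness to every artefact of real
instrument data.

## Problem sizes and simulation scale

The test suite runs the volcano-recovery study at 1000 proteins × 3
replicates per group × 100 seeds, the concordance study at 400 proteins
over the full 2 × 3 design × 100 seeds, and the lipid round-trip at 100
seeds, completing in well under a minute; these sizes give binomial
standard errors small enough that the 95%-accuracy checks are stable
across seeds. The exact-recovery checks for the ratio rule plant effects
of 2 log2 units: the rule flags |Δlog2| > 1.585, so an effect of 1 —
appropriate for volcano-scale recovery — cannot trip it by construction,
and 2 is the smallest round magnitude the rule's own definition can
recover.

## Known limitations

- MGF is the supported spectra format. The reader contract
  (`msms_spectrum`) is adapter-ready, but no mzML adapter ships: the
  pipeline's own interchange needs are text-based, and shipped test data
  must be plain text.
- Peptide identification, site localization (lysine vs N-terminal
  myristoylation), spectral search, and enrichment/network analyses are
  out of scope; protein-level matrices are consumed as produced by DIA
  search engines.
- The concordance epsilon, cross-sample alignment tolerances, and the
  PCA scaling choice are package decisions where the upstream procedure
  is silent; all are exposed as configuration.
- Dataset-scale published counts (numbers of regulated proteins in
  specific experiments) depend on the deposited raw data and are not
  reproduced by the synthetic studies here.
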