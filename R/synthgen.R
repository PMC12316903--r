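# Seeded synthetic-data generators.
#
# Each generator emulates the statistical structure one pipeline stage
# assumes -- marker-ion MS/MS spectra, DIA-style protein quantification
# matrices with a spike-in control, and MRM peak-area tables -- and returns
# machine-readable ground truth alongside the data, so every downstream
# operation is testable at a known answer without instrument data. Noise is
# multiplicative (log-normal) throughout, the standard model for MS
# intensity data, which makes planted log2 effects additive.

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate marker-ion MS/MS datasets
#'
#' Simulates per-sample MGF-style MS/MS runs in which a set fraction of
#' scans carries the diagnostic marker ion. Marker scans are drawn from a
#' shared grid of precursor features (m/z, RT, base intensity); the marker
#' peak sits at `target_mz` plus Gaussian mass error, with intensity above
#' the detection gate. Isotope satellites add extra scans at
#' +1.0034/charge with geometric intensity decay 0.6, exercising the
#' 1-m/z precursor binning rule. Decoy fragment peaks are kept at least
#' 0.1 Da from the target so false positives cannot arise at sane match
#' tolerances. Samples in the second half of the run are "group B": their
#' marker precursor intensities are scaled by `2^group_shift` on half of
#' the features, giving PCA a planted group structure.
#'
#' @param n_scans scans per sample (marker + decoy-only).
#' @param frac_marker fraction of scans carrying the marker (in `[0, 1]`).
#' @param marker_intensity_range uniform range for marker peak intensity;
#'   keep the lower bound above the scan gate (default `c(50, 500)`).
#' @param mass_error_sd SD of the marker mass error in Da (default 0.005).
#' @param isotope_satellites add satellite scans per marker scan.
#' @param n_samples number of samples (>= 2; split into two groups).
#' @param group_shift log2 intensity shift applied to shifted features in
#'   group-B samples (default 0 = no group structure).
#' @param n_features size of the shared precursor feature grid.
#' @param target_mz marker ion m/z (default 268.23).
#' @param seed RNG seed; the dataset is fully determined by the arguments
#'   plus the seed.
#' @return list: `spectra` (named list sample -> list of
#'   [msms_spectrum()]), `truth` (list with `scans`, `features`, `samples`
#'   data.frames), `params`.
#' @export
gen_msms <- function(n_scans = 200, frac_marker = 0.2,
                     marker_intensity_range = c(50, 500),
                     mass_error_sd = 0.005, isotope_satellites = TRUE,
                     n_samples = 6, group_shift = 0, n_features = 20,
                     target_mz = 268.23, seed = 1) {
  if (frac_marker < 0 || frac_marker > 1)
    stop("frac_marker must be within [0, 1]")
  if (n_samples < 1) stop("need at least one sample")
  set.seed(seed)
  features <- data.frame(
    feature_id = sprintf("MF%02d", seq_len(n_features)),
    # jittered grid with spacing >> bin width, so features never collide
    mz = seq(430, 1170, length.out = n_features) +
      stats::runif(n_features, -0.3, 0.3),
    rt = stats::runif(n_features, 8, 55),
    base_intensity = stats::rlnorm(n_features, log(1e5), 0.5),
    shifted = seq_len(n_features) <= n_features / 2
  )
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    group = ifelse(seq_len(n_samples) <= ceiling(n_samples / 2), "A", "B"),
    stringsAsFactors = FALSE
  )
  n_marker <- round(frac_marker * n_scans)
  charge <- 2L
  spectra <- list()
  truth_scans <- list()
  for (s in seq_len(n_samples)) {
    sid <- samples$sample_id[s]
    scans <- list()
    rows <- list()
    if (n_marker > 0) {
      feat_idx <- rep_len(seq_len(n_features), n_marker)
      for (j in seq_len(n_marker)) {
        fi <- feat_idx[j]
        shift <- if (samples$group[s] == "B" && features$shifted[fi])
          2^group_shift else 1
        base_int <- features$base_intensity[fi] * shift * .lognoise(1, 0.2)
        rt <- features$rt[fi] + stats::rnorm(1, 0, 0.2)
        # one satellite at +1.0034/z keeps the envelope inside the 1-m/z
        # summing window at charge 2 (the second isotope would fall on its
        # boundary)
        n_sat <- if (isotope_satellites) stats::rbinom(1, 1, 0.6) else 0L
        for (k in 0:n_sat) {
          scan_id <- sprintf("%s_scan%04d%s", sid, j,
                             if (k > 0) sprintf("_iso%d", k) else "")
          prec_mz <- features$mz[fi] + k * 1.0034 / charge
          prec_int <- base_int * 0.6^k
          marker_peak <- c(target_mz + stats::rnorm(1, 0, mass_error_sd),
                           stats::runif(1, marker_intensity_range[1],
                                        marker_intensity_range[2]))
          decoys <- .decoy_peaks(5, target_mz)
          scans[[length(scans) + 1L]] <- msms_spectrum(
            scan_id, prec_mz, prec_int, rt,
            peaks = rbind(marker_peak, decoys), charge = charge)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, scan_id = scan_id,
            feature_id = features$feature_id[fi],
            precursor_mz = prec_mz, precursor_intensity = prec_int,
            is_marker = TRUE, satellite = k > 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (j in seq_len(n_scans - n_marker)) {
      scan_id <- sprintf("%s_bg%04d", sid, j)
      prec_mz <- stats::runif(1, 400, 1200)
      scans[[length(scans) + 1L]] <- msms_spectrum(
        scan_id, prec_mz, stats::rlnorm(1, log(5e4), 0.6),
        stats::runif(1, 5, 58), peaks = .decoy_peaks(8, target_mz),
        charge = charge)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, scan_id = scan_id, feature_id = NA_character_,
        precursor_mz = prec_mz, precursor_intensity = NA_real_,
        is_marker = FALSE, satellite = FALSE, stringsAsFactors = FALSE)
    }
    spectra[[sid]] <- scans
    truth_scans[[sid]] <- do.call(rbind, rows)
  }
  list(spectra = spectra,
       truth = list(scans = do.call(rbind, truth_scans),
                    features = features, samples = samples),
       params = list(n_scans = n_scans, frac_marker = frac_marker,
                     marker_intensity_range = marker_intensity_range,
                     mass_error_sd = mass_error_sd,
                     isotope_satellites = isotope_satellites,
                     n_samples = n_samples, group_shift = group_shift,
                     n_features = n_features, target_mz = target_mz,
                     seed = seed))
}

# decoy fragment peaks kept >= 0.1 Da away from the marker target
.decoy_peaks <- function(n, target_mz) {
  mz <- stats::runif(n, 100, 1300)
  near <- abs(mz - target_mz) < 0.1
  while (any(near)) {
    mz[near] <- stats::runif(sum(near), 100, 1300)
    near <- abs(mz - target_mz) < 0.1
  }
  cbind(mz, stats::runif(n, 25, 2000))
}

#' Build a condition x treatment sample design
#'
#' @param treatments treatment (or genotype) arms.
#' @param conditions the stimulated condition and its matched control, in
#'   that order.
#' @param n_rep biological replicates per cell (>= 2 for statistics).
#' @return data.frame (`SampleDesign`): `sample_id`, `condition`,
#'   `treatment`, `replicate`.
#' @export
make_quant_design <- function(treatments = c("vehicle", "KLH-45", "IMP-1088"),
                              conditions = c("cLTP", "APV"), n_rep = 3) {
  grid <- expand.grid(replicate = seq_len(n_rep), condition = conditions,
                      treatment = treatments, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d", grid$treatment, grid$condition,
                            grid$replicate)
  grid[, c("sample_id", "condition", "treatment", "replicate")]
}

#' Generate a spike-in quantification matrix with planted effects
#'
#' Log-normal protein intensity matrix over a condition x treatment design.
#' A fraction of proteins is responsive: in the stimulated condition their
#' intensity shifts by a signed log2 effect (random up/down at magnitude
#' `effect_log2`, emulating balanced up- and down-regulation), attenuated
#' per treatment by `inhibitor_attenuation` (0 = full response under
#' vehicle/reference; 1 = response abolished). The spike-in row has its
#' across-sample coefficient of variation controlled exactly at
#' `spike_cv`, so the calibration cut-off derived from it is determined by
#' the parameter and not by sampling noise.
#'
#' @param n_proteins number of (non-spike) proteins.
#' @param design a [make_quant_design()] data.frame.
#' @param frac_responsive fraction of proteins with a planted effect.
#' @param effect_log2 magnitude of the planted log2 effect.
#' @param inhibitor_attenuation named vector (treatment -> attenuation in
#'   `[0, 1]`), or a single value applied to every non-reference
#'   treatment; the first treatment in the design is the reference with
#'   attenuation 0 unless named explicitly.
#' @param spike_cv exact coefficient of variation of the spike-in row.
#' @param noise_cv multiplicative measurement noise CV for protein rows.
#' @param spikein_id rowname of the spike-in row.
#' @param seed RNG seed.
#' @return list: `matrix` (proteins+spike x samples), `design`, `truth`
#'   (list: `proteins` with responsive flags/signs, `effects` with the true
#'   per-treatment log2 effect of each responsive protein), `params`.
#' @export
gen_quant <- function(n_proteins = 1000, design = make_quant_design(),
                      frac_responsive = 0.1, effect_log2 = 1,
                      inhibitor_attenuation = 0.5, spike_cv = 0.13,
                      noise_cv = 0.05, spikein_id = "LYSC_CHICK", seed = 1) {
  treatments <- unique(design$treatment)
  conditions <- unique(design$condition)
  if (length(conditions) != 2L)
    stop("design must have exactly 2 conditions (stimulated, control)")
  if (any(table(design$treatment, design$condition) < 2))
    stop("degenerate design: every condition x treatment cell needs >= 2 replicates")
  atten <- if (is.null(names(inhibitor_attenuation))) {
    stats::setNames(c(0, rep(inhibitor_attenuation, length(treatments) - 1)),
                    treatments)
  } else {
    a <- stats::setNames(rep(0, length(treatments)), treatments)
    a[names(inhibitor_attenuation)] <- inhibitor_attenuation
    a
  }
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  base <- stats::rlnorm(n_proteins, log(1e6), 1)
  n_resp <- round(frac_responsive * n_proteins)
  responsive <- seq_len(n_proteins) %in% sample.int(n_proteins, n_resp)
  sign_eff <- ifelse(stats::runif(n_proteins) < 0.5, -1, 1)
  sign_eff[!responsive] <- 0
  stim <- conditions[1]
  mat <- matrix(0, n_proteins, nrow(design),
                dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    eff <- if (design$condition[j] == stim)
      sign_eff * effect_log2 * (1 - atten[[design$treatment[j]]]) else 0
    mat[, j] <- base * 2^eff * .lognoise(n_proteins, noise_cv)
  }
  # spike-in row: exact sample CV = spike_cv (standardized deviations)
  raw <- .lognoise(nrow(design), max(spike_cv, 1e-6))
  rel <- if (spike_cv > 0 && stats::sd(raw) > 0)
    pmax(1 + (raw - mean(raw)) / stats::sd(raw) * spike_cv, 1e-6)
  else rep(1, nrow(design))
  spike <- matrix(1e7 * rel, nrow = 1,
                  dimnames = list(spikein_id, design$sample_id))
  effects <- expand.grid(protein_id = ids[responsive],
                         treatment = treatments, stringsAsFactors = FALSE)
  effects$true_effect_log2 <- sign_eff[match(effects$protein_id, ids)] *
    effect_log2 * (1 - atten[effects$treatment])
  list(matrix = rbind(mat, spike),
       design = design,
       truth = list(proteins = data.frame(protein_id = ids,
                                          responsive = responsive,
                                          sign = sign_eff,
                                          base_intensity = base,
                                          stringsAsFactors = FALSE),
                    effects = effects),
       params = list(n_proteins = n_proteins,
                     frac_responsive = frac_responsive,
                     effect_log2 = effect_log2,
                     inhibitor_attenuation = atten, spike_cv = spike_cv,
                     noise_cv = noise_cv, spikein_id = spikein_id,
                     seed = seed))
}

#' Default planted acyl-CoA time-course scenario
#'
#' A stimulated/control time-course over the acyl-CoA trio in which the
#' myristoyl species surges at the first timepoint and re-equilibrates
#' toward its resting share by the last; the resting and peak molar
#' proportions follow the composition regime the quantification stage is
#' designed around (a trace myristoyl share at rest, a ten-fold relative
#' surge on stimulation).
#'
#' @param total_ng total trio amount per sample in IS units (default 10).
#' @return data.frame: `analyte`, `condition`, `timepoint`, `amount`.
#' @export
default_mrm_truth <- function(total_ng = 10) {
  apv <- c("C14:0 CoA" = 0.3, "C16:0 CoA" = 52.2, "C18:0 CoA" = 47.5)
  cltp10 <- c("C14:0 CoA" = 3.2, "C16:0 CoA" = 40.1, "C18:0 CoA" = 56.7)
  cltp30 <- (cltp10 + apv) / 2
  rows <- rbind(
    data.frame(analyte = names(apv), condition = "APV", timepoint = 10,
               amount = total_ng * apv / 100),
    data.frame(analyte = names(apv), condition = "APV", timepoint = 30,
               amount = total_ng * apv / 100),
    data.frame(analyte = names(apv), condition = "APV", timepoint = 120,
               amount = total_ng * apv / 100),
    data.frame(analyte = names(cltp10), condition = "cLTP", timepoint = 10,
               amount = total_ng * cltp10 / 100),
    data.frame(analyte = names(cltp30), condition = "cLTP", timepoint = 30,
               amount = total_ng * cltp30 / 100),
    data.frame(analyte = names(apv), condition = "cLTP", timepoint = 120,
               amount = total_ng * apv / 100)
  )
  rownames(rows) <- NULL
  rows
}

#' Generate MRM peak areas from planted concentrations
#'
#' Areas are concentration times a shared instrument response factor times
#' log-normal noise; the internal-standard area is generated the same way
#' from its known spiked amount. The noise has two components: a shared
#' per-sample run factor with CV `noise_cv` (injection volume, extraction
#' recovery, ionisation drift -- exactly the variation an internal
#' standard exists to cancel) and an independent per-peak factor with CV
#' `noise_cv / 2`. At zero noise the internal-standard quantification is
#' the exact inverse of this generator; at nonzero noise the residual
#' error after IS normalization comes from the independent component only.
#'
#' @param truth data.frame of planted amounts ([default_mrm_truth()]
#'   format: `analyte`, `condition`, `timepoint`, `amount`).
#' @param is_name internal-standard analyte name.
#' @param is_amount spiked IS amount per sample (same unit as `amount`).
#' @param noise_cv multiplicative area noise CV.
#' @param n_rep replicates per condition x timepoint.
#' @param instrument_factor area counts per unit amount.
#' @param seed RNG seed.
#' @return list: `peaks` (sample_id, analyte, area), `samples` (sample_id,
#'   condition, timepoint, replicate), `truth`, `params`.
#' @export
gen_mrm <- function(truth = default_mrm_truth(), is_name = "C15:0 CoA",
                    is_amount = 20, noise_cv = 0.1, n_rep = 3,
                    instrument_factor = 1e5, seed = 1) {
  if (any(truth$amount < 0)) stop("planted amounts must be >= 0")
  set.seed(seed)
  cells <- unique(truth[, c("condition", "timepoint")])
  peaks <- list(); samples <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- truth[truth$condition == cells$condition[i] &
                  truth$timepoint == cells$timepoint[i], ]
    for (r in seq_len(n_rep)) {
      sid <- sprintf("%s_t%d_r%d", cells$condition[i], cells$timepoint[i], r)
      samples[[sid]] <- data.frame(sample_id = sid,
                                   condition = cells$condition[i],
                                   timepoint = cells$timepoint[i],
                                   replicate = r, stringsAsFactors = FALSE)
      run_factor <- .lognoise(1, noise_cv)
      area <- cell$amount * instrument_factor * run_factor *
        .lognoise(nrow(cell), noise_cv / 2)
      is_area <- is_amount * instrument_factor * run_factor *
        .lognoise(1, noise_cv / 2)
      peaks[[sid]] <- data.frame(
        sample_id = sid,
        analyte = c(cell$analyte, is_name),
        area = c(area, is_area),
        stringsAsFactors = FALSE)
    }
  }
  list(peaks = do.call(rbind, c(peaks, make.row.names = FALSE)),
       samples = do.call(rbind, c(samples, make.row.names = FALSE)),
       truth = truth,
       params = list(is_name = is_name, is_amount = is_amount,
                     noise_cv = noise_cv, n_rep = n_rep,
                     instrument_factor = instrument_factor, seed = seed))
}
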