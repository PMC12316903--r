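# Orchestration: wire the stages into the four analysis arms (lipid
# time-course; differential proteome + dysregulation; myristoylome
# profiling; membrane-fraction enrichment), with a config object whose
# defaults are the values documented on each stage, a run manifest, and a
# command-line dispatcher.

.default_config <- function() {
  list(
    out_dir = "msmyr_out",
    seed = 1,
    inputs = list(quant_tsv = NULL, design_csv = NULL, mgf_dir = NULL,
                  peaks_csv = NULL, samples_csv = NULL),
    markerion = list(target_mz = 268.23, tol = 0.02, min_intensity = 20,
                     bin_width = 1.0, align_tol = 0.5, rt_tol = 1.0),
    quantcal = list(alpha = 0.05, cutoff = NULL, spikein_id = "LYSC_CHICK",
                    adjust = "none", calibration_mode = "linear"),
    dysreg = list(mode = "ratio", threshold = 0.25, epsilon = 0.05,
                  concordance_bounds = c(0.3, 3), r_gate = 0.7),
    lipids = list(is_name = "C15:0 CoA", is_amount = 20),
    simulate = list(n_proteins = 500, n_scans = 200, frac_marker = 0.2,
                    frac_responsive = 0.1, effect_log2 = 1,
                    inhibitor_attenuation = 0.5, spike_cv = 0.13,
                    noise_cv = 0.05, group_shift = 1, n_samples = 6,
                    mrm_noise_cv = 0.1)
  )
}

#' Build a run configuration
#'
#' Defaults for every stage parameter equal the values documented on the
#' stage functions; overrides are merged recursively and unknown keys are
#' rejected by name, so a typo cannot silently fall back to a default.
#'
#' @param overrides named list (possibly nested) of parameter overrides,
#'   or a path to a YAML file of the same shape.
#' @return the merged configuration list.
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  .merge_config(.default_config(), overrides, path = "")
}

.merge_config <- function(base, over, path) {
  if (is.null(over)) return(base)
  if (!is.list(over) || is.null(names(over)))
    stop("config overrides must be a named list at ", path)
  for (k in names(over)) {
    full <- paste0(path, k)
    if (!k %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], over[[k]], paste0(full, "$"))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

.write_manifest <- function(config, arm, out_dir, input_files = character(0)) {
  checksums <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  manifest <- list(
    tool = "myrms",
    version = as.character(utils::packageVersion("myrms")),
    arm = arm,
    seed = config$seed,
    config = config,
    input_checksums = checksums
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

#' Run one analysis arm
#'
#' Executes an arm's full stage sequence on the configured inputs (or, when
#' no inputs are configured, on a synthetic dataset generated under the
#' configured seed), writing result tables, a run manifest echoing every
#' effective parameter, and a summary. Arms: `"lipids"` (internal-standard
#' quantification, time-course relative change, composition), `"diffexp"`
#' (spike-in calibration, volcano classification per treatment,
#' dysregulation + concordance), `"myristoylome"` (marker-ion scan, bin,
#' align, PCA), `"membrane"` (ANOVA selection, log2-threshold
#' dysregulation, concordance, correlation gate).
#'
#' @param arm one of `"lipids"`, `"diffexp"`, `"myristoylome"`,
#'   `"membrane"`.
#' @param config a [run_config()] list (or overrides passed to it).
#' @return the arm's summary list, invisibly; tables are written under
#'   `config$out_dir`.
#' @export
run_arm <- function(arm = c("lipids", "diffexp", "myristoylome", "membrane"),
                    config = run_config()) {
  arm <- match.arg(arm)
  if (!is.list(config) || is.null(config$out_dir)) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- switch(arm,
    lipids = .arm_lipids(config),
    diffexp = .arm_diffexp(config),
    myristoylome = .arm_myristoylome(config),
    membrane = .arm_membrane(config)
  )
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))
  invisible(summary)
}

.arm_inputs_quant <- function(config, design = make_quant_design()) {
  inp <- config$inputs
  if (!is.null(inp$quant_tsv)) {
    list(matrix = read_quant_tsv(inp$quant_tsv),
         design = read_design_csv(inp$design_csv),
         files = c(inp$quant_tsv, inp$design_csv))
  } else {
    sim <- config$simulate
    g <- gen_quant(n_proteins = sim$n_proteins, design = design,
                   frac_responsive = sim$frac_responsive,
                   effect_log2 = sim$effect_log2,
                   inhibitor_attenuation = sim$inhibitor_attenuation,
                   spike_cv = sim$spike_cv, noise_cv = sim$noise_cv,
                   spikein_id = config$quantcal$spikein_id,
                   seed = config$seed)
    list(matrix = g$matrix, design = g$design, files = character(0))
  }
}

.treatment_responses <- function(mat, design, qc) {
  conditions <- unique(design$condition)
  stim <- conditions[1]; ctrl <- conditions[2]
  out <- list()
  for (tr in unique(design$treatment)) {
    cond_s <- design$sample_id[design$treatment == tr &
                               design$condition == stim]
    ctrl_s <- design$sample_id[design$treatment == tr &
                               design$condition == ctrl]
    fc <- suppressWarnings(diff_expression(mat, cond_s, ctrl_s))
    fc <- fc[fc$protein_id != qc$spikein_id, ]
    fc$treatment <- tr
    out[[tr]] <- fc
  }
  out
}

.arm_diffexp <- function(config) {
  io <- .arm_inputs_quant(config)
  qc <- config$quantcal
  cal <- calibrate_spikein(io$matrix, qc$spikein_id,
                           mode = qc$calibration_mode)
  cutoff <- if (is.null(qc$cutoff)) cal$log2_cutoff else qc$cutoff
  responses <- .treatment_responses(io$matrix, io$design, qc)
  volcano <- lapply(responses, function(fc) {
    if (qc$adjust == "holm-sidak") {
      ok <- !is.na(fc$p_value)
      fc$p_adjusted <- NA_real_
      fc$p_adjusted[ok] <- holm_sidak(fc$p_value[ok])
    }
    classify_volcano(fc, cutoff, alpha = qc$alpha,
                     use_adjusted = qc$adjust == "holm-sidak")
  })
  all_fc <- do.call(rbind, c(volcano, make.row.names = FALSE))
  write_result_tsv(all_fc, file.path(config$out_dir, "fold_changes.tsv"))
  treatments <- names(responses)
  ref <- treatments[1]
  effects <- lapply(responses, function(fc)
    stats::setNames(fc$log2fc, fc$protein_id))
  dys_tables <- list()
  for (tr in setdiff(treatments, ref)) {
    shared <- intersect(names(effects[[ref]]), names(effects[[tr]]))
    ok <- shared[is.finite(effects[[ref]][shared]) &
                 is.finite(effects[[tr]][shared])]
    rec <- inhibitor_effect(unname(effects[[ref]][ok]),
                            unname(effects[[tr]][ok]), protein_id = ok)
    rec <- flag_dysregulated(rec, mode = config$dysreg$mode,
                             threshold = config$dysreg$threshold)
    rec$treatment <- tr
    dys_tables[[tr]] <- rec
  }
  dys <- do.call(rbind, c(dys_tables, make.row.names = FALSE))
  write_result_tsv(dys, file.path(config$out_dir, "dysregulation.tsv"))
  conc_summary <- list()
  if (length(dys_tables) >= 2L) {
    eff <- lapply(dys_tables, function(d)
      stats::setNames(d$effect, d$protein_id))
    inhibitors <- names(dys_tables)
    conc <- concordance(eff[[inhibitors[2]]], eff[[inhibitors[1]]],
                        epsilon = config$dysreg$epsilon,
                        bounds = config$dysreg$concordance_bounds)
    write_result_tsv(conc, file.path(config$out_dir, "concordance.tsv"))
    cc <- conc[conc$concordant, ]
    corr <- if (nrow(cc) >= 3L)
      correlate_effects(cc, r_gate = config$dysreg$r_gate)
    else list(pearson_r = NA_real_, highly_correlated = NA, n = nrow(cc))
    conc_summary <- list(n_concordant = sum(conc$concordant),
                         pearson_r = corr$pearson_r,
                         highly_correlated = corr$highly_correlated)
  }
  .write_manifest(config, "diffexp", config$out_dir, io$files)
  counts <- lapply(volcano, function(v) as.list(attr(v, "counts")))
  c(list(arm = "diffexp", log2_cutoff = cutoff,
         spike_sd = cal$spike_sd, volcano_counts = counts,
         n_dysregulated = if (!is.null(dys)) sum(dys$dysregulated) else 0L),
    conc_summary)
}

.arm_membrane <- function(config) {
  design <- make_quant_design()
  io <- .arm_inputs_quant(config, design = design)
  qc <- config$quantcal
  mat <- io$matrix[rownames(io$matrix) != qc$spikein_id, , drop = FALSE]
  d <- io$design[match(colnames(mat), io$design$sample_id), ]
  sel <- suppressWarnings(
    anova_select(mat, interaction(d$condition, d$treatment, drop = TRUE),
                 alpha = qc$alpha))
  write_result_tsv(sel$table, file.path(config$out_dir, "anova.tsv"))
  responses <- .treatment_responses(io$matrix, io$design, qc)
  treatments <- names(responses)
  ref <- treatments[1]
  effects <- lapply(responses, function(fc)
    stats::setNames(fc$log2fc, fc$protein_id))
  dys_tables <- list()
  for (tr in setdiff(treatments, ref)) {
    keep <- intersect(sel$selected,
                      names(effects[[ref]])[is.finite(effects[[ref]])])
    keep <- intersect(keep,
                      names(effects[[tr]])[is.finite(effects[[tr]])])
    rec <- inhibitor_effect(unname(effects[[ref]][keep]),
                            unname(effects[[tr]][keep]), protein_id = keep)
    rec <- flag_dysregulated(rec, mode = "log2_threshold",
                             threshold = config$dysreg$threshold)
    rec$treatment <- tr
    dys_tables[[tr]] <- rec
  }
  dys <- do.call(rbind, c(dys_tables, make.row.names = FALSE))
  write_result_tsv(dys, file.path(config$out_dir, "dysregulation.tsv"))
  conc_summary <- list()
  if (length(dys_tables) >= 2L) {
    eff <- lapply(dys_tables, function(d)
      stats::setNames(d$effect, d$protein_id))
    inhibitors <- names(dys_tables)
    conc <- concordance(eff[[inhibitors[2]]], eff[[inhibitors[1]]],
                        epsilon = config$dysreg$epsilon,
                        bounds = config$dysreg$concordance_bounds)
    write_result_tsv(conc, file.path(config$out_dir, "concordance.tsv"))
    cc <- conc[conc$concordant, ]
    corr <- if (nrow(cc) >= 3L)
      correlate_effects(cc, r_gate = config$dysreg$r_gate)
    else list(pearson_r = NA_real_, highly_correlated = NA, n = nrow(cc))
    conc_summary <- list(n_concordant = sum(conc$concordant),
                         pearson_r = corr$pearson_r,
                         highly_correlated = corr$highly_correlated)
  }
  .write_manifest(config, "membrane", config$out_dir, io$files)
  c(list(arm = "membrane", n_anova_selected = length(sel$selected),
         n_dysregulated = if (!is.null(dys)) sum(dys$dysregulated) else 0L),
    conc_summary)
}

.arm_myristoylome <- function(config) {
  mi <- config$markerion
  inp <- config$inputs
  files <- character(0)
  if (!is.null(inp$mgf_dir)) {
    files <- sort(list.files(inp$mgf_dir, pattern = "\\.mgf$",
                             full.names = TRUE))
    if (!length(files)) stop("no .mgf files under ", inp$mgf_dir)
    spectra <- lapply(files, read_mgf)
    names(spectra) <- sub("\\.mgf$", "", basename(files))
  } else {
    sim <- config$simulate
    g <- gen_msms(n_scans = sim$n_scans, frac_marker = sim$frac_marker,
                  n_samples = sim$n_samples, group_shift = sim$group_shift,
                  target_mz = mi$target_mz, seed = config$seed)
    spectra <- g$spectra
  }
  hits <- lapply(spectra, scan_spectra, target_mz = mi$target_mz,
                 tol = mi$tol, min_intensity = mi$min_intensity)
  hit_tab <- do.call(rbind, c(Map(function(h, s)
    if (nrow(h)) cbind(sample_id = s, h) else NULL,
    hits, names(hits)), make.row.names = FALSE))
  if (!is.null(hit_tab))
    write_result_tsv(hit_tab, file.path(config$out_dir, "marker_hits.tsv"))
  profiles <- lapply(hits, bin_precursors, width = mi$bin_width)
  prof_tab <- do.call(rbind, c(Map(function(p, s)
    if (nrow(p)) cbind(sample_id = s, p) else NULL,
    profiles, names(profiles)), make.row.names = FALSE))
  if (!is.null(prof_tab))
    write_result_tsv(prof_tab, file.path(config$out_dir, "profiles.tsv"))
  aligned <- build_profile_matrix(profiles, align_tol = mi$align_tol,
                                  rt_tol = mi$rt_tol)
  pca <- pca_profiles(aligned$matrix)
  scores <- data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, seq_len(min(2, ncol(pca$scores))),
                                  drop = FALSE],
                       stringsAsFactors = FALSE)
  write_result_tsv(scores, file.path(config$out_dir, "pca_scores.tsv"))
  .write_manifest(config, "myristoylome", config$out_dir, files)
  list(arm = "myristoylome",
       hits_per_sample = lapply(hits, nrow),
       n_features = nrow(aligned$features),
       components_retained = pca$components_retained,
       top_eigenvalues = as.list(round(utils::head(pca$eigenvalues, 2), 4)))
}

.arm_lipids <- function(config) {
  lp <- config$lipids
  inp <- config$inputs
  files <- character(0)
  if (!is.null(inp$peaks_csv)) {
    peaks <- utils::read.csv(inp$peaks_csv, stringsAsFactors = FALSE)
    samples <- utils::read.csv(inp$samples_csv, stringsAsFactors = FALSE)
    files <- c(inp$peaks_csv, inp$samples_csv)
  } else {
    g <- gen_mrm(noise_cv = config$simulate$mrm_noise_cv,
                 is_name = lp$is_name, is_amount = lp$is_amount,
                 seed = config$seed)
    peaks <- g$peaks; samples <- g$samples
  }
  quants <- do.call(rbind, c(lapply(split(peaks, peaks$sample_id),
    function(pk) cbind(sample_id = pk$sample_id[1],
                       is_quantify(pk, lp$is_name, lp$is_amount))),
    make.row.names = FALSE))
  quants <- merge(quants, samples, by = "sample_id")
  write_result_tsv(quants[order(quants$sample_id, quants$analyte), ],
                   file.path(config$out_dir, "analyte_quants.tsv"))
  stim <- unique(samples$condition)[unique(samples$condition) != "APV"][1]
  rc <- relative_change(quants[quants$condition == stim, ],
                        quants[quants$condition == "APV", ])
  write_result_tsv(rc, file.path(config$out_dir, "relative_change.tsv"))
  comp <- do.call(rbind, c(lapply(
    split(quants, list(quants$condition, quants$timepoint), drop = TRUE),
    function(q) {
      means <- tapply(q$amount, q$analyte, mean)
      cbind(condition = q$condition[1], timepoint = q$timepoint[1],
            composition_percent(stats::setNames(as.numeric(means),
                                                names(means))))
    }), make.row.names = FALSE))
  write_result_tsv(comp, file.path(config$out_dir, "composition.tsv"))
  .write_manifest(config, "lipids", config$out_dir, files)
  list(arm = "lipids",
       n_samples = length(unique(quants$sample_id)),
       analytes = sort(unique(quants$analyte)),
       composition_total_check = as.numeric(tapply(comp$percent,
         paste(comp$condition, comp$timepoint), sum))[1])
}

#' Write a synthetic scenario to disk
#'
#' Generates the three synthetic datasets (marker-ion MGFs, a spike-in
#' quantification matrix + design, MRM peak areas) under one seed and
#' writes them, with their ground-truth tables, under `out_dir`.
#'
#' @param config a [run_config()] list; `config$simulate` holds the
#'   generator parameters and `config$seed` the seed.
#' @return list of written paths, invisibly.
#' @export
simulate_scenario <- function(config = run_config()) {
  dir.create(file.path(config$out_dir, "mgf"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- config$simulate
  g1 <- gen_msms(n_scans = sim$n_scans, frac_marker = sim$frac_marker,
                 n_samples = sim$n_samples, group_shift = sim$group_shift,
                 seed = config$seed)
  paths <- character(0)
  for (sid in names(g1$spectra)) {
    p <- file.path(config$out_dir, "mgf", paste0(sid, ".mgf"))
    write_mgf(g1$spectra[[sid]], p)
    paths <- c(paths, p)
  }
  write_result_tsv(g1$truth$scans,
                   file.path(config$out_dir, "truth_msms_scans.tsv"))
  g2 <- gen_quant(n_proteins = sim$n_proteins,
                  frac_responsive = sim$frac_responsive,
                  effect_log2 = sim$effect_log2,
                  inhibitor_attenuation = sim$inhibitor_attenuation,
                  spike_cv = sim$spike_cv, noise_cv = sim$noise_cv,
                  spikein_id = config$quantcal$spikein_id,
                  seed = config$seed)
  write_quant_tsv(g2$matrix, file.path(config$out_dir, "quant_matrix.tsv"))
  utils::write.csv(g2$design, file.path(config$out_dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  write_result_tsv(g2$truth$proteins,
                   file.path(config$out_dir, "truth_proteins.tsv"))
  write_result_tsv(g2$truth$effects,
                   file.path(config$out_dir, "truth_effects.tsv"))
  g3 <- gen_mrm(noise_cv = sim$mrm_noise_cv, seed = config$seed)
  utils::write.csv(g3$peaks, file.path(config$out_dir, "mrm_peaks.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(g3$samples, file.path(config$out_dir, "mrm_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  write_result_tsv(g3$truth, file.path(config$out_dir, "truth_mrm.tsv"))
  .write_manifest(config, "simulate", config$out_dir)
  invisible(c(paths, file.path(config$out_dir,
    c("quant_matrix.tsv", "design.csv", "mrm_peaks.csv",
      "mrm_samples.csv"))))
}

#' Command-line dispatcher
#'
#' Thin argument parser behind the installed `msmyr` script. Subcommands:
#' `transitions` (emit acyl-CoA transition CSV), `markerscan`, `calibrate`,
#' `diffexp`, `dysreg` via `run-arm`, `lipids`, `simulate`. Flags are
#' `--key value` pairs mapping onto [run_config()] keys, plus `--config
#' FILE` for a YAML config.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
msmyr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: msmyr <transitions|simulate|run-arm|markerscan> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  status <- 0L
  tryCatch({
    flags <- .parse_flags(args[-1])
    if (cmd == "transitions") {
      chains <- if (!is.null(flags$chains))
        as.integer(strsplit(flags$chains, ",")[[1]]) else c(14L, 15L, 16L, 18L)
      tab <- acyl_coa_transition_table(chains)
      out <- if (!is.null(flags$out)) flags$out else stdout()
      utils::write.csv(tab[, c("analyte", "precursor_mz", "product_mz")],
                       out, row.names = FALSE, quote = FALSE)
    } else if (cmd == "simulate") {
      config <- .flags_to_config(flags)
      simulate_scenario(config)
    } else if (cmd == "run-arm") {
      arm <- flags$arm
      if (is.null(arm)) stop("run-arm requires --arm")
      flags$arm <- NULL
      config <- .flags_to_config(flags)
      run_arm(arm, config)
    } else if (cmd == "markerscan") {
      config <- .flags_to_config(flags)
      run_arm("myristoylome", config)
    } else {
      stop("unknown subcommand: ", cmd)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --flag, got: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value")
    flags[[key]] <- args[i + 1]
    i <- i + 2L
  }
  flags
}

.flags_to_config <- function(flags) {
  overrides <- if (!is.null(flags$config)) yaml::read_yaml(flags$config)
               else list()
  if (!is.null(flags$out)) overrides$out_dir <- flags$out
  if (!is.null(flags$seed)) overrides$seed <- as.integer(flags$seed)
  map <- c("quant-tsv" = "quant_tsv", "design-csv" = "design_csv",
           "mgf-dir" = "mgf_dir", "peaks-csv" = "peaks_csv",
           "samples-csv" = "samples_csv")
  for (fl in names(map)) {
    if (!is.null(flags[[fl]])) {
      if (is.null(overrides$inputs)) overrides$inputs <- list()
      overrides$inputs[[map[[fl]]]] <- flags[[fl]]
    }
  }
  run_config(overrides)
}
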