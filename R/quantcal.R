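# Spike-in-calibrated differential protein expression.
#
# An exogenous protein (chicken lysozyme) is spiked in equal amount into
# every sample before processing, so the spread of its measured intensity
# across samples estimates the workflow's measurement uncertainty. The
# fold-change acceptance cut-off is set at the mean +/- 2 SD of the
# normalized spike values: under normality, changes beyond the cut-off have
# ~95% confidence of being biological rather than technical.

#' Calibrate the fold-change cut-off from the spike-in control
#'
#' Spike intensities are normalized to their across-sample mean (giving a
#' per-sample value relative to one); the cut-off is the log2 fold change
#' corresponding to the mean + 2 SD of those values, i.e.
#' `log2(1 + 2 * sd)`. The reported value is rounded half-up to one decimal
#' (as thresholds are quoted); the unrounded value is returned alongside.
#' With the alternative `mode = "log2"`, 2 SD is taken in log2 space:
#' `2 * sd(log2(normalized))`.
#'
#' @param mat proteins x samples intensity matrix with protein ids as
#'   rownames.
#' @param spikein_id rowname of the spike-in protein.
#' @param mode `"linear"` (default; 2 SD of the normalized linear values)
#'   or `"log2"`.
#' @return list of class `spike_calibration`: `normalized_spike` (mean 1),
#'   `spike_sd`, `log2_cutoff` (rounded), `log2_cutoff_exact`, `mode`.
#' @examples
#' m <- rbind(LYSC = c(100, 110, 90), P1 = c(5, 6, 7))
#' calibrate_spikein(m, "LYSC")$spike_sd  # 0.1
#' @export
calibrate_spikein <- function(mat, spikein_id, mode = c("linear", "log2")) {
  mode <- match.arg(mode)
  if (!spikein_id %in% rownames(mat))
    stop("spike-in row '", spikein_id, "' not found in matrix")
  spike <- as.numeric(mat[spikein_id, ])
  if (any(!is.finite(spike)) || any(spike <= 0))
    stop("spike-in intensities must all be finite and > 0")
  normalized <- spike / mean(spike)
  spike_sd <- stats::sd(normalized)
  cutoff_exact <- switch(mode,
    linear = log2(1 + 2 * spike_sd),
    log2 = 2 * stats::sd(log2(normalized))
  )
  structure(list(normalized_spike = stats::setNames(normalized, colnames(mat)),
                 spike_sd = spike_sd,
                 log2_cutoff = round_half_up(cutoff_exact, 1),
                 log2_cutoff_exact = cutoff_exact,
                 mode = mode),
            class = "spike_calibration")
}

#' @export
print.spike_calibration <- function(x, ...) {
  cat(sprintf("<spike_calibration> spike SD %.3f -> log2 cut-off %.1f (exact %.4f, mode %s)\n",
              x$spike_sd, x$log2_cutoff, x$log2_cutoff_exact, x$mode))
  invisible(x)
}

#' Per-protein log2 response with a two-sample t-test
#'
#' `log2fc = log2(mean(condition) / mean(control))`; the p value is from a
#' two-sided unpaired Student's t-test (pooled variance) on the
#' per-replicate intensities, or Welch's variant when `var_equal = FALSE`.
#' Zero-variance groups with equal means are p = 1 by convention (no
#' evidence of change); unequal means at zero pooled variance give p = 0.
#'
#' @param x_cond,x_ctrl numeric replicate intensities (>= 2 finite values
#'   each).
#' @param var_equal pooled-variance Student's test (default) or Welch.
#' @return one-row data.frame: `log2fc`, `t`, `df`, `p_value`.
#' @export
log2_response <- function(x_cond, x_ctrl, var_equal = TRUE) {
  x_cond <- x_cond[is.finite(x_cond)]
  x_ctrl <- x_ctrl[is.finite(x_ctrl)]
  if (length(x_cond) < 2L || length(x_ctrl) < 2L)
    stop("need >= 2 finite replicates per group")
  m1 <- mean(x_cond); m2 <- mean(x_ctrl)
  if (m1 <= 0 || m2 <= 0)
    stop("undefined fold change: nonpositive group mean")
  if (stats::var(x_cond) == 0 && stats::var(x_ctrl) == 0) {
    eq <- isTRUE(all.equal(m1, m2))
    return(data.frame(log2fc = log2(m1 / m2), t = if (eq) 0 else Inf,
                      df = length(x_cond) + length(x_ctrl) - 2,
                      p_value = if (eq) 1 else 0))
  }
  tt <- stats::t.test(x_cond, x_ctrl, var.equal = var_equal)
  data.frame(log2fc = log2(m1 / m2), t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value)
}

#' Differential expression across a whole quantification matrix
#'
#' Vectorized per-protein log2 fold changes and Student's (pooled-variance)
#' t-tests between two sample groups. Zero intensities are treated as
#' missing; a protein is tested on the remaining replicates when each group
#' keeps at least 2, and is otherwise returned flagged (`status`) with NA
#' statistics rather than silently dropped. Proteins with a nonpositive
#' group mean are likewise flagged.
#'
#' @param mat proteins x samples intensity matrix (rownames = protein ids).
#' @param cond_samples,ctrl_samples column names (or indices) of the two
#'   groups.
#' @param zero_as_missing treat 0 cells as missing (default TRUE).
#' @return data.frame: `protein_id`, `log2fc`, `t`, `df`, `p_value`,
#'   `status` (`"ok"`, `"insufficient_replicates"`, `"nonpositive_mean"`).
#' @export
diff_expression <- function(mat, cond_samples, ctrl_samples,
                            zero_as_missing = TRUE) {
  a <- mat[, cond_samples, drop = FALSE]
  b <- mat[, ctrl_samples, drop = FALSE]
  if (zero_as_missing) {
    a[a == 0] <- NA
    b[b == 0] <- NA
  }
  n1 <- rowSums(is.finite(a)); n2 <- rowSums(is.finite(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- .row_var(a, m1, n1); v2 <- .row_var(b, m2, n2)
  df <- n1 + n2 - 2
  sp2 <- ifelse(df > 0, ((n1 - 1) * v1 + (n2 - 1) * v2) / df, NA)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero pooled variance: equal means carry no evidence (p = 1)
  zero_var <- is.finite(sp2) & sp2 == 0
  tstat[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 0, Inf)
  p[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 1, 0)
  status <- rep("ok", nrow(mat))
  status[n1 < 2 | n2 < 2] <- "insufficient_replicates"
  bad_mean <- status == "ok" & (!is.finite(m1) | !is.finite(m2) |
                                m1 <= 0 | m2 <= 0)
  status[bad_mean] <- "nonpositive_mean"
  log2fc <- ifelse(status == "ok", log2(m1 / m2), NA)
  out <- data.frame(protein_id = rownames(mat),
                    log2fc = log2fc,
                    t = ifelse(status == "ok", tstat, NA),
                    df = ifelse(status == "ok", df, NA),
                    p_value = ifelse(status == "ok", p, NA),
                    status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(status != "ok"))
    warning(sum(status != "ok"), " protein(s) not testable (",
            paste(unique(status[status != "ok"]), collapse = ", "), ")")
  out
}

.row_var <- function(x, m, n) {
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  ifelse(n > 1, ss / (n - 1), NA)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' P values are sorted ascending; the k-th smallest is adjusted to
#' `1 - (1 - p_(k))^(m - k + 1)`, adjusted values are made monotone
#' non-decreasing, capped at 1, and returned in the input order.
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must be finite and within [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  ord <- order(p_values)
  expo <- m - seq_len(m) + 1
  adj <- 1 - (1 - p_values[ord])^expo
  adj[expo == 1] <- p_values[ord][expo == 1]  # exact at a single test
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Classify volcano-plot significance
#'
#' A protein is significant iff `|log2fc| >= log2_cutoff` and its (raw or
#' adjusted, per `use_adjusted`) p value is below `alpha`. Untestable
#' records (NA statistics) are never significant.
#'
#' @param records data.frame with `log2fc` and `p_value` columns
#'   ([diff_expression()] output); optionally `p_adjusted`.
#' @param log2_cutoff non-negative fold-change threshold, typically the
#'   spike-derived value from [calibrate_spikein()].
#' @param alpha significance level (default 0.05, strict `<`).
#' @param use_adjusted test `p_adjusted` instead of `p_value`.
#' @return the records with added `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"ns"`) columns, plus attribute `counts`
#'   (named vector: up, down, significant, tested).
#' @export
classify_volcano <- function(records, log2_cutoff, alpha = 0.05,
                             use_adjusted = FALSE) {
  stopifnot(log2_cutoff >= 0)
  p <- if (use_adjusted) records$p_adjusted else records$p_value
  sig <- !is.na(records$log2fc) & !is.na(p) &
    abs(records$log2fc) >= log2_cutoff & p < alpha
  records$significant <- sig
  records$direction <- ifelse(!sig, "ns",
                              ifelse(records$log2fc > 0, "up", "down"))
  attr(records, "counts") <- c(up = sum(sig & records$log2fc > 0),
                               down = sum(sig & records$log2fc < 0),
                               significant = sum(sig),
                               tested = sum(!is.na(p)))
  records
}

#' One-way ANOVA protein selection
#'
#' Per-protein one-way fixed-effects ANOVA of intensity across group
#' labels; proteins with `p <= alpha` are retained. Proteins constant
#' across all samples have an undefined F statistic and are excluded with a
#' warning.
#'
#' @param mat proteins x samples intensity matrix.
#' @param groups group label per column of `mat` (>= 2 groups, each with
#'   >= 2 replicates).
#' @param alpha retention threshold (default 0.05, inclusive `<=`).
#' @return list: `selected` (protein ids), `table` (protein_id, f, p_value).
#' @export
anova_select <- function(mat, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (length(groups) != ncol(mat))
    stop("groups must label every column of the matrix")
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 replicates each")
  res <- lapply(seq_len(nrow(mat)), function(i) {
    y <- as.numeric(mat[i, ])
    fit <- tryCatch(
      stats::oneway.test(y ~ groups, var.equal = TRUE),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$p.value))
      return(data.frame(f = NA_real_, p_value = NA_real_))
    data.frame(f = unname(fit$statistic), p_value = fit$p.value)
  })
  tab <- cbind(data.frame(protein_id = rownames(mat),
                          stringsAsFactors = FALSE),
               do.call(rbind, res))
  rownames(tab) <- NULL
  n_bad <- sum(is.na(tab$p_value))
  if (n_bad > 0)
    warning(n_bad, " protein(s) excluded from ANOVA (constant or untestable)")
  list(selected = tab$protein_id[!is.na(tab$p_value) & tab$p_value <= alpha],
       table = tab)
}
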