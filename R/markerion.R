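# Database-independent myristoylome profiling: scan MS/MS spectra for the
# diagnostic 268.23 m/z myristoyl-glycine b1 ion, cluster precursors of hit
# spectra into 1-m/z bins (absorbing isotope satellites), align bins across
# samples into a feature matrix, and profile samples by PCA.

#' Scan one spectrum for the diagnostic marker ion
#'
#' Reports a hit if at least one fragment peak lies within `tol` of
#' `target_mz` with intensity strictly above `min_intensity` (the workflow's
#' noise gate). When several peaks qualify the most intense one is recorded.
#'
#' @param spectrum an [msms_spectrum()].
#' @param target_mz diagnostic ion m/z (default 268.23, myristoyl-glycine b1).
#' @param tol absolute match tolerance in Da (default 0.02, ~75 ppm at
#'   268 m/z).
#' @param min_intensity intensity gate in counts; peaks must exceed it
#'   strictly (default 20).
#' @return a one-row data.frame (`MarkerHit`: scan_id, precursor_mz,
#'   precursor_intensity, rt, marker_intensity, marker_mz_observed), or
#'   `NULL` when no peak qualifies.
#' @export
scan_spectrum <- function(spectrum, target_mz = 268.23, tol = 0.02,
                          min_intensity = 20) {
  stopifnot(inherits(spectrum, "msms_spectrum"), tol > 0)
  pk <- spectrum$peaks
  ok <- abs(pk[, "mz"] - target_mz) <= tol & pk[, "intensity"] > min_intensity
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(pk[ok, "intensity"])]
  data.frame(scan_id = spectrum$scan_id,
             precursor_mz = spectrum$precursor_mz,
             precursor_intensity = spectrum$precursor_intensity,
             rt = spectrum$rt,
             marker_intensity = pk[best, "intensity"],
             marker_mz_observed = pk[best, "mz"],
             stringsAsFactors = FALSE)
}

#' Scan a list of spectra for marker-ion hits
#'
#' @param spectra list of [msms_spectrum()] objects (one sample).
#' @inheritParams scan_spectrum
#' @return data.frame of marker hits (possibly zero rows).
#' @export
scan_spectra <- function(spectra, target_mz = 268.23, tol = 0.02,
                         min_intensity = 20) {
  hits <- lapply(spectra, scan_spectrum, target_mz = target_mz, tol = tol,
                 min_intensity = min_intensity)
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(.empty_hits())
  do.call(rbind, hits)
}

.empty_hits <- function() {
  data.frame(scan_id = character(0), precursor_mz = numeric(0),
              precursor_intensity = numeric(0), rt = numeric(0),
              marker_intensity = numeric(0), marker_mz_observed = numeric(0),
              stringsAsFactors = FALSE)
}

#' Cluster marker-hit precursors into m/z bins
#'
#' Precursor intensities of spectra within 1 m/z are summed so that
#' repeated MS/MS sampling of the isotope satellites of one precursor is
#' counted once. Clustering is seed-anchored: hits are walked in ascending
#' precursor m/z, and a hit joins the current bin iff its m/z minus the
#' bin's first member (the seed, normally the monoisotopic precursor) is
#' strictly less than `width`; otherwise it seeds a new bin. This is
#' deterministic and matches the purpose of absorbing isotope satellites
#' sitting above the monoisotopic peak.
#'
#' @param hits data.frame of marker hits ([scan_spectra()]), one sample.
#' @param width bin width in Da (default 1.0).
#' @return a `marker_profile` data.frame: `bin_mz` (intensity-weighted mean
#'   member m/z), `summed_intensity`, `rt_centroid` (intensity-weighted
#'   mean RT) and `n_scans`, sorted by `bin_mz`.
#' @export
bin_precursors <- function(hits, width = 1.0) {
  stopifnot(width > 0)
  if (nrow(hits) == 0L)
    return(data.frame(bin_mz = numeric(0), summed_intensity = numeric(0),
                      rt_centroid = numeric(0), n_scans = integer(0)))
  hits <- hits[order(hits$precursor_mz), , drop = FALSE]
  seed <- hits$precursor_mz[1]
  cluster <- integer(nrow(hits))
  cluster[1] <- 1L
  k <- 1L
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$precursor_mz[i] - seed < width) {
      cluster[i] <- k
    } else {
      k <- k + 1L
      cluster[i] <- k
      seed <- hits$precursor_mz[i]
    }
  }
  out <- do.call(rbind, lapply(split(hits, cluster), function(m) {
    w <- m$precursor_intensity
    data.frame(bin_mz = sum(m$precursor_mz * w) / sum(w),
               summed_intensity = sum(w),
               rt_centroid = sum(m$rt * w) / sum(w),
               n_scans = nrow(m))
  }))
  rownames(out) <- NULL
  out[order(out$bin_mz), , drop = FALSE]
}

#' Align per-sample marker profiles into a feature matrix
#'
#' Bins from different samples are merged into one feature when their bin
#' m/z values agree within `align_tol` and their RT centroids within
#' `rt_tol` (both judged against the feature's first member). Cells with no
#' marker evidence are 0, not NA: absence of the diagnostic ion is itself
#' informative, and downstream PCA needs complete data.
#'
#' @param profiles named list of [bin_precursors()] outputs; names are
#'   sample ids and must be unique.
#' @param align_tol cross-sample m/z tolerance in Da (default 0.5, half the
#'   1-m/z bin width).
#' @param rt_tol cross-sample RT tolerance in minutes (default 1.0).
#' @return list with `matrix` (features x samples, summed intensities) and
#'   `features` (data.frame of feature bin_mz / rt_centroid references).
#' @export
build_profile_matrix <- function(profiles, align_tol = 0.5, rt_tol = 1.0) {
  if (length(profiles) < 2L) stop("need profiles from at least 2 samples")
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("profiles must be uniquely named by sample_id")
  all_bins <- do.call(rbind, lapply(ids, function(s) {
    p <- profiles[[s]]
    if (nrow(p) == 0L) return(NULL)
    cbind(p, sample_id = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all_bins)) stop("all profiles are empty; nothing to align")
  all_bins <- all_bins[order(all_bins$bin_mz, all_bins$rt_centroid), ,
                       drop = FALSE]
  feat <- integer(nrow(all_bins))
  ref_mz <- numeric(0); ref_rt <- numeric(0)
  for (i in seq_len(nrow(all_bins))) {
    match_i <- which(abs(ref_mz - all_bins$bin_mz[i]) <= align_tol &
                     abs(ref_rt - all_bins$rt_centroid[i]) <= rt_tol)
    if (length(match_i)) {
      feat[i] <- match_i[1]
    } else {
      ref_mz <- c(ref_mz, all_bins$bin_mz[i])
      ref_rt <- c(ref_rt, all_bins$rt_centroid[i])
      feat[i] <- length(ref_mz)
    }
  }
  mat <- matrix(0, nrow = length(ref_mz), ncol = length(ids),
                dimnames = list(sprintf("F%03d", seq_along(ref_mz)), ids))
  for (i in seq_len(nrow(all_bins)))
    mat[feat[i], all_bins$sample_id[i]] <-
      mat[feat[i], all_bins$sample_id[i]] + all_bins$summed_intensity[i]
  list(matrix = mat,
       features = data.frame(feature_id = rownames(mat),
                             bin_mz = ref_mz, rt_centroid = ref_rt,
                             stringsAsFactors = FALSE))
}

#' PCA of marker-profile samples
#'
#' Features are mean-centered and scaled to unit variance before the
#' decomposition, so components reflect profile shape rather than total
#' signal. Retention follows the Kaiser rule (eigenvalues of the
#' correlation matrix > 1); the top two retained components are the plotted
#' dimensions.
#'
#' @param mat features x samples matrix ([build_profile_matrix()]`$matrix`)
#'   or any numeric matrix with samples in columns.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `eigenvalues` (non-increasing), `components_retained` (count of
#'   eigenvalues > 1), `n_features_used`.
#' @export
pca_profiles <- function(mat) {
  if (ncol(mat) < 3L) stop("PCA needs at least 3 samples")
  v <- apply(mat, 1, stats::var)
  keep <- is.finite(v) & v > 0
  if (sum(keep) < 2L)
    stop("degenerate input: fewer than 2 features with nonzero variance")
  x <- t(mat[keep, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  structure(list(scores = pc$x,
                 eigenvalues = eig,
                 components_retained = sum(eig > 1),
                 n_features_used = sum(keep)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d features, %d component(s) with eigenvalue > 1\n",
              nrow(x$scores), x$n_features_used, x$components_retained))
  cat("top eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n")
  invisible(x)
}
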