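# Independent oracles and fixture builders shared across test files.

# Brute-force seed-rule clustering: peel off, from the sorted values, the
# maximal prefix lying strictly within `width` of its smallest member, then
# recurse on the rest. Formulated differently from the production
# single-pass walk on purpose.
oracle_seed_clusters <- function(mz, width) {
  ord <- order(mz)
  remaining <- ord
  clusters <- list()
  while (length(remaining)) {
    seed <- mz[remaining[1]]
    members <- remaining[mz[remaining] - seed < width]
    clusters[[length(clusters) + 1L]] <- members
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# a random marker-hit table
random_hits <- function(n, mz_range = c(400, 1200)) {
  data.frame(scan_id = sprintf("s%d", seq_len(n)),
             precursor_mz = runif(n, mz_range[1], mz_range[2]),
             precursor_intensity = runif(n, 10, 1e5),
             rt = runif(n, 1, 60),
             marker_intensity = runif(n, 21, 500),
             marker_mz_observed = 268.23,
             stringsAsFactors = FALSE)
}

# a spectrum with given fragment peaks
spectrum_with_peaks <- function(peaks, precursor_mz = 650.30,
                                precursor_intensity = 1e5, rt = 12.1) {
  msms_spectrum("scan_1", precursor_mz, precursor_intensity, rt,
                peaks = peaks)
}

# random elemental formula over CHNOPS
random_formula <- function() {
  elems <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:5, 1)
  pick <- sample(elems, n)
  elemental_formula(setNames(sample(1:40, n, replace = TRUE), pick))
}
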