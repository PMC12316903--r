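# Marker-ion scanning, precursor binning, cross-sample alignment, PCA.

test_that("scan_spectrum finds the marker within tolerance above the gate", {
  sp <- spectrum_with_peaks(rbind(c(268.229, 150), c(400.1, 999)))
  hit <- scan_spectrum(sp)
  expect_identical(hit$marker_intensity, 150)
  expect_identical(hit$precursor_mz, 650.30)
  expect_identical(hit$precursor_intensity, 1e5)
  expect_identical(hit$rt, 12.1)
})

test_that("the intensity gate is strict and the tolerance absolute", {
  expect_null(scan_spectrum(spectrum_with_peaks(rbind(c(268.23, 10)))))
  expect_null(scan_spectrum(spectrum_with_peaks(rbind(c(268.23, 20)))))
  expect_null(scan_spectrum(spectrum_with_peaks(rbind(c(270.10, 500))),
                            tol = 0.02))
  # several qualifying peaks: the most intense wins
  sp <- spectrum_with_peaks(rbind(c(268.225, 40), c(268.235, 90)))
  expect_identical(scan_spectrum(sp)$marker_intensity, 90)
})

test_that("raising the gate never adds hits (monotonicity)", {
  set.seed(21)
  for (i in 1:20) {
    peaks <- cbind(runif(30, 100, 1300), runif(30, 1, 200))
    peaks[sample(30, 3), 1] <- 268.23 + rnorm(3, 0, 0.01)
    sp <- spectrum_with_peaks(peaks)
    gates <- c(5, 20, 50, 100, 150)
    hits <- lapply(gates, function(g)
      scan_spectrum(sp, min_intensity = g))
    found <- !vapply(hits, is.null, logical(1))
    # once absent at a low gate, absent at every higher gate
    expect_true(all(diff(found) <= 0))
    ints <- vapply(hits[found], `[[`, numeric(1), "marker_intensity")
    expect_true(all(diff(ints) >= 0))
  }
})

test_that("bin_precursors reproduces worked clustering examples", {
  hits <- random_hits(3)
  hits$precursor_mz <- c(650.30, 650.80, 652.00)
  hits$precursor_intensity <- c(100, 50, 30)
  prof <- bin_precursors(hits, width = 1.0)
  expect_identical(prof$n_scans, c(2L, 1L))
  expect_equal(prof$bin_mz[1], (650.30 * 100 + 650.80 * 50) / 150,
               tolerance = 1e-12)
  expect_identical(prof$summed_intensity, c(150, 30))

  hits$precursor_mz <- c(650.30, 651.20, 651.90)
  hits$precursor_intensity <- c(100, 40, 10)
  prof <- bin_precursors(hits, width = 1.0)
  # 651.20 - 650.30 = 0.90 < 1 joins the seed; 651.90 - 650.30 = 1.60 seeds anew
  expect_identical(prof$summed_intensity, c(140, 10))
  expect_identical(prof$n_scans, c(2L, 1L))
})

test_that("a single hit bins to itself and empty input to an empty profile", {
  h <- random_hits(1)
  prof <- bin_precursors(h)
  expect_identical(prof$bin_mz, h$precursor_mz)
  expect_identical(prof$summed_intensity, h$precursor_intensity)
  expect_identical(nrow(bin_precursors(h[0, ])), 0L)
})

test_that("binning equals the brute-force seed-rule oracle on random hits", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(1:200, 1)
    hits <- random_hits(n, mz_range = c(400, 420))  # force dense clusters
    prof <- bin_precursors(hits, width = 1.0)
    clusters <- oracle_seed_clusters(hits$precursor_mz, width = 1.0)
    expect_identical(nrow(prof), length(clusters))
    oracle_sums <- sort(vapply(clusters, function(idx)
      sum(hits$precursor_intensity[idx]), numeric(1)))
    expect_equal(sort(prof$summed_intensity), oracle_sums, tolerance = 1e-9)
    # conservation of summed intensity
    expect_equal(sum(prof$summed_intensity), sum(hits$precursor_intensity),
                 tolerance = 1e-9)
  }
})

test_that("profile alignment merges matching bins and zero-fills gaps", {
  h <- random_hits(4)
  h$precursor_mz <- c(500.1, 600.2, 700.3, 800.4)
  p <- bin_precursors(h)
  aligned <- build_profile_matrix(list(a = p, b = p))
  expect_identical(aligned$matrix[, "a"], aligned$matrix[, "b"])
  expect_identical(nrow(aligned$matrix), 4L)

  h2 <- h; h2$precursor_mz <- h$precursor_mz + 100 + 0.9  # disjoint
  p2 <- bin_precursors(h2)
  aligned2 <- build_profile_matrix(list(a = p, b = p2))
  expect_identical(nrow(aligned2$matrix), 8L)
  expect_true(all(aligned2$matrix[aligned2$matrix[, "a"] > 0, "b"] == 0))
})

test_that("alignment rejects unnamed or duplicate sample ids", {
  p <- bin_precursors(random_hits(2))
  expect_error(build_profile_matrix(list(p, p)), "named")
  expect_error(build_profile_matrix(stats::setNames(list(p, p), c("a", "a"))),
               "named")
  expect_error(build_profile_matrix(list(a = p)), "2 samples")
})

test_that("PCA separates planted groups and respects sample permutation", {
  g <- gen_msms(n_scans = 120, frac_marker = 0.3, n_samples = 6,
                group_shift = 3, seed = 42)
  profiles <- lapply(g$spectra, function(s) bin_precursors(scan_spectra(s)))
  aligned <- build_profile_matrix(profiles)
  pca <- pca_profiles(log2(aligned$matrix + 1))
  grp <- g$truth$samples$group[match(rownames(pca$scores),
                                     g$truth$samples$sample_id)]
  pc1 <- pca$scores[, 1]
  # mean silhouette of PC1 scores against the two planted groups
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[setdiff(which(grp == grp[i]), i)]))
    other <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
    (other - own) / max(own, other)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_identical(pca$components_retained,
                   sum(pca$eigenvalues > 1))

  perm <- c(3, 1, 2, 6, 5, 4)
  pca_perm <- pca_profiles(log2(aligned$matrix + 1)[, perm])
  expect_equal(abs(pca_perm$scores[order(rownames(pca_perm$scores)), 1]),
               abs(pca$scores[order(rownames(pca$scores)), 1]),
               tolerance = 1e-8)
})

test_that("degenerate profile matrices are rejected", {
  flat <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  expect_error(pca_profiles(flat), "degenerate")
  expect_error(pca_profiles(flat[, 1:2]), "3 samples")
})

test_that("MGF round-trips through write and read", {
  sp <- list(
    msms_spectrum("a", 650.30125, 12345.67, 12.5,
                  peaks = rbind(c(268.23, 150), c(300.12, 40)), charge = 2L),
    msms_spectrum("b", 900.5, 2.25, 40.1, peaks = rbind(c(120.08, 99)))
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_identical(length(back), 2L)
  expect_identical(back[[1]]$scan_id, "a")
  expect_equal(back[[1]]$precursor_mz, 650.30125, tolerance = 1e-5)
  expect_equal(back[[1]]$rt, 12.5, tolerance = 1e-4)
  expect_identical(back[[1]]$charge, 2L)
  expect_equal(back[[1]]$peaks, sp[[1]]$peaks, tolerance = 1e-5,
               ignore_attr = TRUE)
})
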