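# Spike-in calibration, differential expression, multiple testing, ANOVA.

test_that("spike-in calibration reproduces worked values", {
  m <- rbind(LYSC = c(100, 110, 90), P1 = c(5, 6, 7))
  cal <- calibrate_spikein(m, "LYSC")
  expect_equal(unname(cal$normalized_spike), c(1.0, 1.1, 0.9),
               tolerance = 1e-12)
  expect_equal(cal$spike_sd, 0.1, tolerance = 1e-12)
  expect_equal(mean(cal$normalized_spike), 1, tolerance = 1e-9)

  # 13% spike SD gives the 0.3 cut-off (exact value log2(1.26) = 0.333)
  m13 <- rbind(LYSC = c(0.87, 1, 1.13) * 1e7, P1 = c(5, 6, 7))
  cal13 <- calibrate_spikein(m13, "LYSC")
  expect_equal(cal13$spike_sd, 0.13, tolerance = 1e-9)
  expect_equal(cal13$log2_cutoff_exact, log2(1.26), tolerance = 1e-9)
  expect_identical(cal13$log2_cutoff, 0.3)

  flat <- rbind(LYSC = c(7, 7, 7), P1 = c(5, 6, 7))
  expect_identical(calibrate_spikein(flat, "LYSC")$log2_cutoff, 0)
})

test_that("spike calibration is scale-invariant in the right ways", {
  set.seed(5)
  m <- matrix(rlnorm(40, 10, 1), 5, 8,
              dimnames = list(c("LYSC", paste0("P", 1:4)), paste0("s", 1:8)))
  cal <- calibrate_spikein(m, "LYSC")
  # global rescale changes nothing
  cal_g <- calibrate_spikein(m * 7, "LYSC")
  expect_equal(cal_g$spike_sd, cal$spike_sd, tolerance = 1e-12)
  # rescaling one sample moves only that sample's normalized value
  m2 <- m; m2[, 3] <- m2[, 3] * 2
  cal_1 <- calibrate_spikein(m2, "LYSC")
  ratio <- cal_1$normalized_spike / cal$normalized_spike
  expect_equal(unname(ratio[3] / ratio[1]), 2, tolerance = 1e-9)
})

test_that("spike calibration rejects bad inputs", {
  m <- rbind(LYSC = c(1, 0, 2), P1 = c(5, 6, 7))
  expect_error(calibrate_spikein(m, "LYSC"), "> 0")
  expect_error(calibrate_spikein(m, "nope"), "not found")
})

test_that("log2_response matches worked t-test values", {
  r <- log2_response(c(2, 2, 2), c(1, 1, 1))
  expect_identical(r$log2fc, 1)
  expect_identical(log2_response(c(3, 3, 3), c(3, 3, 3))$p_value, 1)
  r2 <- log2_response(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$log2fc, log2(2 / 3), tolerance = 1e-9)
  expect_equal(r2$t, -1.224745, tolerance = 1e-5)
  expect_identical(r2$df, 4)
  expect_equal(r2$p_value, 0.2878641, tolerance = 1e-6)
  expect_error(log2_response(c(1, 2), c(-1, -2)), "nonpositive")
  expect_error(log2_response(1, c(1, 2)), "replicates")
})

test_that("log2_response is antisymmetric under group swap", {
  set.seed(6)
  for (i in 1:10) {
    a <- rlnorm(3, 2, 0.3); b <- rlnorm(3, 2, 0.3)
    expect_equal(log2_response(a, b)$log2fc, -log2_response(b, a)$log2fc,
                 tolerance = 1e-12)
    expect_equal(log2_response(a, b)$p_value, log2_response(b, a)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("vectorized diff_expression agrees with per-protein t.test", {
  set.seed(7)
  m <- matrix(rlnorm(60, 10, 0.3), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
  de <- diff_expression(m, paste0("s", 1:3), paste0("s", 4:6))
  for (i in 1:10) {
    ref <- log2_response(m[i, 1:3], m[i, 4:6])
    expect_equal(de$log2fc[i], ref$log2fc, tolerance = 1e-10)
    expect_equal(de$p_value[i], ref$p_value, tolerance = 1e-10)
  }
})

test_that("zeros are treated as missing and thin groups are flagged", {
  m <- matrix(rlnorm(18, 10, 0.2), 3, 6,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:6)))
  m[1, 1] <- 0          # one missing replicate: still testable on 2
  m[2, 1:2] <- 0        # one replicate left: flagged
  de <- suppressWarnings(diff_expression(m, paste0("s", 1:3), paste0("s", 4:6)))
  expect_identical(de$status, c("ok", "insufficient_replicates", "ok"))
  expect_true(is.na(de$p_value[2]))
  ref <- log2_response(m[1, 2:3], m[1, 4:6])
  expect_equal(de$log2fc[1], ref$log2fc, tolerance = 1e-10)
})

test_that("holm_sidak reproduces worked values and its properties", {
  expect_identical(holm_sidak(0.05), 0.05)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  expect_identical(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("volcano classification applies both gates", {
  rec <- data.frame(protein_id = c("a", "b", "c", "d"),
                    log2fc = c(0.5, 0.5, -0.4, 0.1),
                    p_value = c(0.01, 0.2, 0.03, 0.001))
  out <- classify_volcano(rec, log2_cutoff = 0.3)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$direction, c("up", "ns", "down", "ns"))
  counts <- attr(out, "counts")
  expect_identical(unname(counts[c("up", "down")]), c(1L, 1L))
})

test_that("ANOVA selection holds its null rate and finds real shifts", {
  set.seed(9)
  # null: 3 groups of 3, no true differences; 10 seeds x 200 proteins
  rates <- vapply(1:10, function(s) {
    m <- matrix(rlnorm(200 * 9, 10, 0.2), 200, 9,
                dimnames = list(sprintf("P%03d", 1:200), paste0("s", 1:9)))
    sel <- anova_select(m, rep(c("a", "b", "c"), each = 3))
    length(sel$selected) / 200
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (10 * 200))
  expect_lt(abs(mean(rates) - 0.05), 3 * se)

  # one group shifted by ~10 SD is always retained
  m <- matrix(rlnorm(9, 10, 0.05), 1, 9,
              dimnames = list("P1", paste0("s", 1:9)))
  m[1, 7:9] <- m[1, 7:9] * 2
  expect_identical(anova_select(m, rep(c("a", "b", "c"), each = 3))$selected,
                   "P1")

  # constant protein is excluded with a warning
  flat <- matrix(5, 1, 9, dimnames = list("P1", paste0("s", 1:9)))
  expect_warning(sel <- anova_select(flat, rep(c("a", "b", "c"), each = 3)),
                 "excluded")
  expect_identical(length(sel$selected), 0L)
  expect_error(anova_select(m, rep(c("a", "b", "c"), 3)[1:8]), "label")
})
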