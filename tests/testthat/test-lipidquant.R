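# Internal-standard quantification, composition and relative change.

test_that("internal-standard quantification follows the area ratio", {
  pk <- data.frame(analyte = c("A", "B", "IS"), area = c(100, 0, 100))
  q <- is_quantify(pk, "IS", is_amount = 20)
  expect_identical(q$amount[q$analyte == "A"], 20)   # unity ratio
  expect_identical(q$amount[q$analyte == "B"], 0)
  pk2 <- data.frame(analyte = c("A", "IS"), area = c(35, 100))
  q2 <- is_quantify(pk2, "IS", is_amount = 20, response_factors = c(A = 1.2))
  expect_equal(q2$amount, 8.4, tolerance = 1e-12)    # 0.35 * 20 * 1.2
  expect_error(is_quantify(data.frame(analyte = "A", area = 5), "IS"),
               "missing")
  expect_error(is_quantify(data.frame(analyte = c("A", "IS"),
                                      area = c(5, 0)), "IS"), "> 0")
})

test_that("quantification is linear and scale-invariant in shared area scale", {
  pk <- data.frame(analyte = c("A", "IS"), area = c(37.5, 80))
  base <- is_quantify(pk, "IS")$amount
  pk2 <- pk; pk2$area <- pk$area * 13
  expect_equal(is_quantify(pk2, "IS")$amount, base, tolerance = 1e-12)
  pk3 <- pk; pk3$area[1] <- pk$area[1] * 3
  expect_equal(is_quantify(pk3, "IS")$amount, base * 3, tolerance = 1e-12)
})

test_that("molar conversion uses acyl-CoA monoisotopic masses", {
  pk <- data.frame(analyte = c("C14:0 CoA", "C15:0 CoA"), area = c(100, 100))
  q <- is_quantify(pk, "C15:0 CoA", is_amount = 20, molar = TRUE,
                   chain_lengths = c("C14:0 CoA" = 14, "C15:0 CoA" = 15))
  # 20 ng of C15:0 CoA (991.33 g/mol) = 20.17 pmol; unity area ratio
  expect_equal(q$amount, 20 / 991.3292 * 1000, tolerance = 1e-3)
})

test_that("FFAST quantification converts channel ratios to pmol per mg", {
  q <- ffast_quantify(c(myristic = 50), c(myristic = 50), is_conc = 2.5,
                      volume_ul = 200, tissue_mg = 1)
  expect_identical(q$pmol_per_mg, 500)   # 2.5 pmol/uL x 200 uL over 1 mg
  q0 <- ffast_quantify(c(myristic = 0), c(myristic = 50), tissue_mg = 2)
  expect_identical(q0$pmol_per_mg, 0)
  expect_error(ffast_quantify(c(a = 1), c(a = 1)), "tissue_mg")
  expect_error(ffast_quantify(c(a = 1), c(b = 1), tissue_mg = 1), "IS-channel")
})

test_that("composition percentages reproduce the printed trio shares", {
  comp <- composition_percent(c("C14:0 CoA" = 0.003, "C16:0 CoA" = 0.522,
                                "C18:0 CoA" = 0.475))
  expect_equal(comp$percent, c(0.3, 52.2, 47.5), tolerance = 1e-9)
  comp2 <- composition_percent(c(a = 0.032, b = 0.401, c = 0.567))
  expect_equal(comp2$percent, c(3.2, 40.1, 56.7), tolerance = 1e-9)
  expect_equal(sum(composition_percent(c(a = 1, b = 1, c = 1))$percent), 100,
               tolerance = 1e-12)
  # scale invariance and exact closure
  set.seed(16)
  x <- stats::setNames(runif(3, 0.1, 5), c("a", "b", "c"))
  expect_equal(composition_percent(x)$percent,
               composition_percent(x * 1e4)$percent, tolerance = 1e-12)
  expect_equal(sum(composition_percent(x)$percent), 100, tolerance = 1e-9)
  expect_error(composition_percent(c(a = 0, b = 0)), "zero total")
})

test_that("relative change is zero at equality and log2 of the mean ratio", {
  qc <- data.frame(analyte = "A", amount = c(4, 4, 4))
  expect_identical(relative_change(qc, qc)$log2_change, 0)
  q4 <- data.frame(analyte = "A", amount = c(8, 8))
  q1 <- data.frame(analyte = "A", amount = c(2, 2))
  expect_identical(relative_change(q4, q1)$log2_change, 2)
  qz <- data.frame(analyte = "A", amount = c(0, 0))
  out <- relative_change(q4, qz)
  expect_identical(out$status, "undefined_zero_control")
  expect_true(is.na(out$log2_change))
})

test_that("noiseless MRM generation round-trips exactly", {
  g <- gen_mrm(noise_cv = 0, seed = 17)
  quants <- do.call(rbind, lapply(split(g$peaks, g$peaks$sample_id),
    function(pk) cbind(sample_id = pk$sample_id[1],
                       is_quantify(pk, "C15:0 CoA", 20))))
  merged <- merge(quants, g$samples, by = "sample_id")
  truth <- merge(merged, g$truth,
                 by = c("analyte", "condition", "timepoint"))
  expect_equal(truth$amount.x, truth$amount.y, tolerance = 1e-9)
  # composition of the recovered amounts reproduces the planted proportions
  rest <- truth[truth$condition == "APV" & truth$timepoint == 10 &
                truth$replicate == 1, ]
  comp <- composition_percent(stats::setNames(rest$amount.x, rest$analyte))
  expect_equal(sort(comp$percent), c(0.3, 47.5, 52.2), tolerance = 1e-9)
})

test_that("planted time-course decays monotonically after the peak", {
  g <- gen_mrm(noise_cv = 0.02, seed = 18)
  quants <- do.call(rbind, lapply(split(g$peaks, g$peaks$sample_id),
    function(pk) cbind(sample_id = pk$sample_id[1],
                       is_quantify(pk, "C15:0 CoA", 20))))
  merged <- merge(quants, g$samples, by = "sample_id")
  rc <- relative_change(merged[merged$condition == "cLTP", ],
                        merged[merged$condition == "APV", ])
  myr <- rc[rc$analyte == "C14:0 CoA", ]
  myr <- myr[order(myr$timepoint), ]
  expect_true(all(diff(myr$log2_change) < 0))
  expect_equal(myr$log2_change[1], log2(3.2 / 0.3), tolerance = 0.2)
  expect_equal(myr$log2_change[3], 0, tolerance = 0.15)
})
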