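CU <- standard_curve(slope = SLOPE100, intercept = 30, cq_loq = 35)

test_that("individual-sample slope matches the two-dilution formula", {
  expect_equal(sample_slope(c(24.0, 27.3219), c(1, 0.1)), -3.3219,
               tolerance = 1e-9)
  expect_equal(sample_slope(c(25, 25), c(1, 0.1)), 0)
  # inhibited sample: the more diluted reaction comes up EARLIER
  expect_gt(sample_slope(c(28, 27.2), c(1, 0.1)), 0)
  expect_true(is.na(sample_slope(c(24, NA), c(1, 0.1))))
})

test_that("extraction verdict fails only when every reference gene fails", {
  qc <- qc_settings()
  ev <- evaluate_extraction(c(R1 = 21, R2 = 22), qc)
  expect_true(all(ev$per_gene)); expect_equal(ev$verdict, "PASS")

  ev <- evaluate_extraction(c(R1 = 35.1, R2 = 36.0), qc)
  expect_false(any(ev$per_gene)); expect_equal(ev$verdict, "FAIL")

  ev <- evaluate_extraction(c(R1 = 35.1, R2 = 22), qc)
  expect_equal(unname(ev$per_gene), c(FALSE, TRUE))
  expect_equal(ev$verdict, "PASS")

  ev <- evaluate_extraction(c(R1 = NA, R2 = NA), qc)  # nothing amplified
  expect_equal(ev$verdict, "FAIL")
})

test_that("LOQ and LOD imputation follow the curve and the reference average", {
  # Cq(LOQ) five cycles past the intercept of a doubling assay: 2^-5 copies
  expect_equal(impute_loq(CU, 35, 1), 0.03125, tolerance = 1e-9)
  expect_equal(impute_loq(CU, 35, 0.5), 0.0625, tolerance = 1e-9)
  expect_equal(impute_loq(CU, 35, 0.03125), 1.0, tolerance = 1e-9)

  qc <- qc_settings()  # lod_divisor 5
  expect_equal(impute_lod(CU, 35, 1, qc), 0.00625, tolerance = 1e-9)
  set.seed(2)
  for (k in 1:20) {
    ra <- 10^runif(1, -2, 2)
    loq <- runif(1, 31, 39)
    lo <- impute_lod(CU, loq, ra, qc); hi <- impute_loq(CU, loq, ra)
    expect_gt(lo, 0)
    expect_lt(lo, hi)
  }
})

test_that("the decision tree resolves each textbook situation", {
  qc <- qc_settings()
  ref <- c(`1` = 50, `2` = 50)

  # happy path: both dilutions quantifiable, slope on the curve
  tgt <- rbind(dil_row(1, 24.0, 100), dil_row(2, 24.0 - SLOPE100, 100))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "OK")
  expect_equal(d$value, 2.0, tolerance = 1e-12)
  expect_length(d$warnings, 0)

  # nothing amplified at either dilution: imputed below the LOD
  tgt <- rbind(dil_row(1, NA, NA, cv = NA, n_detected = 0L),
               dil_row(2, NA, NA, cv = NA, n_detected = 0L))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "IMPUTED_LOD")
  expect_equal(d$value, impute_lod(CU, 35, 50, qc), tolerance = 1e-12)
  expect_gt(length(d$warnings), 0)

  # replicate scatter beyond the CV ceiling reads as sub-LOQ
  tgt <- rbind(dil_row(1, 29, 60, cv = 47.14),
               dil_row(2, 29 - SLOPE100, 60))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "IMPUTED_LOQ")
  expect_equal(d$value, impute_loq(CU, 35, 50), tolerance = 1e-12)

  # inhibition signature: sample slope -1.2 with range [-4.5, -2.5]
  tgt <- rbind(dil_row(1, 24.0, 100), dil_row(2, 25.2, 100))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "NO_RESULT_EFFICIENCY")
  expect_true(is.na(d$value))
  expect_match(d$warnings[1], "SLOPE_OUT_OF_RANGE")

  # slope inside the range but too far from the curve's
  tgt <- rbind(dil_row(1, 24.0, 100), dil_row(2, 28.4, 100))  # slope -4.4
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "NO_RESULT_EFFICIENCY")
  expect_match(d$warnings[1], "SLOPE_DIFF")

  # only the more diluted reactions under the LOQ: dilution 1 carries it
  tgt <- rbind(dil_row(1, 33, 0.5), dil_row(2, 36.4, 0.5))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "OK_DIL1_ONLY")
  expect_equal(d$value, 0.5 / 50, tolerance = 1e-12)

  # partial replicate dropout at dilution 1 is a sub-LOQ trigger
  tgt <- rbind(dil_row(1, 34.0, 0.3, n_detected = 1L),
               dil_row(2, NA, NA, cv = NA, n_detected = 0L))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "IMPUTED_LOQ")
})

test_that("the hierarchy masks downstream stages", {
  qc <- qc_settings()
  ref <- c(`1` = 50, `2` = 50)
  undetected <- rbind(dil_row(1, NA, NA, cv = NA, n_detected = 0L),
                      dil_row(2, NA, NA, cv = NA, n_detected = 0L))

  # extraction failure beats even a sub-LOD target
  d <- decide_final("S", "G", undetected, ref, CU, qc,
                    ref_state = list(extraction_verdict = "FAIL",
                                     efficiency_all_failed = FALSE))
  expect_equal(d$status, "NO_RESULT_EXTRACTION")
  expect_true(is.na(d$value))

  # all reference genes discarded by the efficiency control
  d <- decide_final("S", "G", undetected, ref, CU, qc,
                    ref_state = list(extraction_verdict = "PASS",
                                     efficiency_all_failed = TRUE))
  expect_equal(d$status, "NO_RESULT_EFFICIENCY")

  # dilution-1-only path skips the efficiency control entirely:
  # the implied slope here is absurd, yet the result is still given
  tgt <- rbind(dil_row(1, 24, 100), dil_row(2, 36.5, 0.01))
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "OK_DIL1_ONLY")
  expect_false(is.na(d$value))
})

test_that("simple mode never consults dilution 2 or the efficiency control", {
  qc <- qc_settings(mode = "simple")
  ref <- c(`1` = 50)
  tgt <- dil_row(1, 24.0, 100)
  d <- decide_final("S", "G", tgt, ref, CU, qc)
  expect_equal(d$status, "OK")
  expect_equal(d$value, 2.0)

  d <- decide_final("S", "G", dil_row(1, 36.2, 0.02), ref, CU, qc)
  expect_equal(d$status, "IMPUTED_LOQ")

  d <- decide_final("S", "G", dil_row(1, NA, NA, cv = NA, n_detected = 0L),
                    ref, CU, qc)
  expect_equal(d$status, "IMPUTED_LOD")
})

test_that("tightening QC never upgrades a cell to OK", {
  loose <- qc_settings()
  tight <- qc_settings(cv_max_percent = 10, slope_min = -3.7,
                       slope_max = -3.0, slope_diff_max = 0.3)
  for (seed in 1:6) {
    cfg <- sim_mixed_config(15, cq_noise_sd = 0.15, seed = seed)
    sim <- simulate_experiment(cfg)
    a <- quantify_experiment(sim$experiment, sim$standards, loose)$decisions
    b <- quantify_experiment(sim$experiment, sim$standards, tight)$decisions
    upgraded <- b$status == "OK" & a$status != "OK"
    expect_false(any(upgraded),
                 label = paste("seed", seed, "tightened QC upgraded",
                               sum(upgraded), "cell(s)"))
  }
})
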