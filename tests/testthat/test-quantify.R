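test_that("copy numbers invert the standard-curve line", {
  cu <- standard_curve(slope = SLOPE100, intercept = 30, cq_loq = 35)
  expect_equal(copy_number_from_cq(30, cu), 1.0, tolerance = 1e-12)
  expect_equal(copy_number_from_cq(30 + SLOPE100 * 1, cu), 10,
               tolerance = 1e-9)
  # printed-precision variant of the same inversion
  cu4 <- standard_curve(slope = -3.3219, intercept = 30, cq_loq = 35)
  expect_equal(copy_number_from_cq(26.6781, cu4), 10, tolerance = 1e-3)
  expect_true(is.na(copy_number_from_cq(NA_real_, cu)))
  # strictly decreasing in Cq for a negative slope
  cqs <- seq(15, 40, by = 0.5)
  expect_true(all(diff(copy_number_from_cq(cqs, cu)) < 0))
})

test_that("replicate summaries use the n-1 CV on copy numbers", {
  s <- summarize_replicates(c(100, 100, 100))
  expect_equal(s$mean, 100); expect_equal(s$cv_percent, 0)
  expect_equal(s$n_detected, 3L)

  s <- summarize_replicates(c(90, 110))
  expect_equal(s$mean, 100)
  expect_equal(s$cv_percent, sd(c(90, 110)) / 100 * 100, tolerance = 1e-12)
  expect_equal(s$cv_percent, 14.14, tolerance = 1e-2)

  s <- summarize_replicates(c(40, 80))  # beyond the default CV ceiling
  expect_equal(s$mean, 60)
  expect_equal(s$cv_percent, 47.14, tolerance = 1e-2)
  expect_gt(s$cv_percent, 30)

  s <- summarize_replicates(c(NA, 120, NA))
  expect_equal(s$n_detected, 1L)
  expect_true(is.na(s$cv_percent))

  s <- summarize_replicates(c(NA_real_, NA_real_))
  expect_equal(s$n_detected, 0L)
  expect_true(is.na(s$mean))
})

test_that("reference genes scale to the first-imported one before averaging", {
  dq <- function(vals, dil = 1) {
    data.frame(sample = names(vals), dilution = dil, rel_quantity = 1,
               mean_cq = 25, replicate_copies = "", mean_copy_number = vals,
               cv_percent = 1, n_detected = 2L, n_total = 2L,
               dilution_corrected = unname(vals), stringsAsFactors = FALSE)
  }
  # single reference: self-scaling, average = input
  one <- scale_and_average_references(list(R1 = dq(c(A = 100, B = 200))))
  expect_equal(one$averages$ref_average, c(100, 200))

  # second gene ten-fold lower: factor 10, equal weight after scaling
  two <- scale_and_average_references(list(R1 = dq(c(A = 100, B = 200)),
                                           R2 = dq(c(A = 10, B = 20))))
  expect_equal(two$factors$factor[two$factors$gene == "R2"], 10)
  expect_equal(two$averages$ref_average, c(100, 200))

  # global rescaling of one reference gene is absorbed by its factor
  for (const in c(0.05, 3, 40)) {
    alt <- scale_and_average_references(
      list(R1 = dq(c(A = 100, B = 200)),
           R2 = dq(c(A = 10, B = 20) * const)))
    expect_equal(alt$averages$ref_average, two$averages$ref_average,
                 tolerance = 1e-12)
  }

  # QC-dropped gene leaves the sample's average, not the factors
  drop <- scale_and_average_references(
    list(R1 = dq(c(A = 100, B = 200)), R2 = dq(c(A = 10, B = 20))),
    use = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("A", "B"), c("R1", "R2"))))
  expect_equal(drop$averages$ref_average[drop$averages$sample == "A"], 100)
  expect_equal(drop$averages$genes_used[drop$averages$sample == "A"], "R1")
  expect_equal(drop$factors$factor[drop$factors$gene == "R2"], 10)
})

test_that("normalization divides by the reference average and averages dilutions", {
  nc <- normalize_and_combine(c(`1` = 200), c(`1` = 100))
  expect_equal(nc$value, 2)
  nc <- normalize_and_combine(c(`1` = 200, `2` = 220),
                              c(`1` = 100, `2` = 100))
  expect_equal(unname(nc$per_dilution), c(2.0, 2.2))
  expect_equal(nc$value, 2.1)
  expect_true(is.na(normalize_and_combine(c(`1` = 2),
                                          c(`1` = NA_real_))$value))
})

test_that("delta-delta-Cq comparator reproduces textbook ratios", {
  t_cq <- c(S1 = 26, S2 = 24, S3 = 27)
  r_cq <- c(S1 = 20, S2 = 20, S3 = 21)
  ratios <- ddcq_quantify(t_cq, r_cq, "S1")
  expect_equal(unname(ratios["S1"]), 1.0)
  expect_equal(unname(ratios["S2"]), 4.0)     # 2 cycles earlier, ref equal
  expect_equal(unname(ratios["S3"]), 1.0)     # both shifted by one cycle
  expect_true(is.na(ddcq_quantify(c(S1 = 26, S2 = NA), r_cq[1:2],
                                  "S1")["S2"]))
})

test_that("reference import order only rescales; between-sample ratios are invariant", {
  cfg <- ideal_sim(8, n_refs = 2, seed = 21)
  sim <- simulate_experiment(cfg)
  res_a <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)

  swapped <- sim$experiment
  swapped$assays$R1$import_order <- 2L
  swapped$assays$R2$import_order <- 1L
  res_b <- quantify_experiment(swapped, sim$standards, cfg$qc)

  va <- res_a$decisions$value
  vb <- res_b$decisions$value
  expect_equal(va / va[1], vb / vb[1], tolerance = 1e-9)
  ratio <- vb / va
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
})

test_that("noise-free dilution-corrected values agree across dilutions", {
  sim <- simulate_experiment(ideal_sim(6, seed = 9))
  res <- quantify_experiment(sim$experiment, sim$standards, qc_settings())
  for (g in names(res$details)) {
    d <- res$details[[g]]
    d1 <- d$dilution_corrected[d$dilution == 1]
    d2 <- d$dilution_corrected[d$dilution == 2]
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("at exactly 100% efficiency the standard-curve and ddCq routes coincide", {
  cfg <- ideal_sim(10, seed = 13)
  sim <- simulate_experiment(cfg)
  res <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)
  d <- res$decisions
  expect_true(all(d$status == "OK"))

  mean_cq1 <- function(g) {
    r <- sim$experiment$assays[[g]]$reactions
    r <- r[r$dilution == 1, ]
    tapply(r$cq, r$sample, mean)[sim$experiment$sample_ids]
  }
  dd <- ddcq_quantify(mean_cq1("T1"), mean_cq1("R1"), "S01")
  sc <- d$value / d$value[d$sample == "S01"]
  expect_equal(unname(sc), unname(dd[d$sample]), tolerance = 1e-9)
})
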