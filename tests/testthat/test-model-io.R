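test_that("gene tables parse row-for-row with undetected-Cq normalization", {
  txt <- paste(
    "sample\tdilution\treplicate\tcq\trel_quantity",
    "S1\t1\t1\t24.1\t1",
    "S1\t1\t2\t24.3\t1",
    "S1\t2\t1\t27.5\t0.1",
    "S1\t2\t2\t27.4\t0.1",
    "S2\t1\t1\t25.0\t1",
    "S2\t1\t2\t25.2\t1",
    "S2\t2\t1\t28.6\t0.1",
    "S2\t2\t2\t28.4\t0.1",
    sep = "\n")
  a <- parse_gene_table(txt, "G1", "target")
  expect_s3_class(a, "gene_assay")
  expect_equal(nrow(a$reactions), 8L)
  expect_equal(a$n_dilutions, 2L)
  expect_equal(unique(a$reactions$sample), c("S1", "S2"))

  # every instrument convention for "no signal" maps to the same sentinel
  for (token in c("", "NA", "Undetermined", "999")) {
    t2 <- paste("sample\tdilution\treplicate\tcq\trel_quantity",
                paste("S1\t1\t1", token, "1", sep = "\t"), sep = "\n")
    expect_true(is.na(parse_gene_table(t2, "G", "target")$reactions$cq))
  }
})

test_that("value invariants are enforced at parse time with line numbers", {
  bad_q <- paste("sample\tdilution\treplicate\tcq\trel_quantity",
                 "S1\t1\t1\t24.0\t0", sep = "\n")
  expect_error(parse_gene_table(bad_q, "G", "target"), "BAD_VALUE")

  bad_cq <- paste("sample\tdilution\treplicate\tcq\trel_quantity",
                  "S1\t1\t1\t61.2\t1", sep = "\n")
  expect_error(parse_gene_table(bad_cq, "G", "target"), "outside \\(0, 50\\]")

  short <- paste("sample\tdilution\treplicate\tcq\trel_quantity",
                 "S1\t1\t1\t24.0\t1", "S1\t1\t24.0\t1", sep = "\n")
  expect_error(parse_gene_table(short, "G", "target"), "line 3")
})

test_that("standard tables keep replicate points and refuse flat series", {
  ten <- paste(c("quantity\tcq",
                 vapply(0:4, function(k)
                   paste0(10^-k, "\t", 20 + 3.32 * k, "\n",
                          10^-k, "\t", 20.1 + 3.32 * k),
                   character(1))), collapse = "\n")
  std <- parse_standard_table(ten)
  expect_equal(nrow(std), 10L)
  expect_equal(length(unique(std$quantity)), 5L)

  flat <- paste("quantity\tcq", "1\t20", "1\t20.2", sep = "\n")
  expect_error(parse_standard_table(flat), "distinct quantities")

  two <- paste("quantity\tcq", "1\t20", "0.1\t23.3219", sep = "\n")
  expect_equal(nrow(parse_standard_table(two)), 2L)
})

test_that("serialize -> parse round-trips an assay bit-exactly", {
  cfg <- sim_mixed_config(10, cq_noise_sd = 0.2, seed = 42)
  sim <- simulate_experiment(cfg)
  for (g in names(sim$experiment$assays)) {
    a <- sim$experiment$assays[[g]]
    b <- parse_gene_table(serialize_gene_table(a), a$gene_id, a$role,
                          a$import_order)
    expect_identical(b$reactions, a$reactions)
    std <- parse_standard_table(serialize_standard_table(sim$standards[[g]]))
    expect_identical(std$quantity, sim$standards[[g]]$quantity)
    expect_identical(std$cq, sim$standards[[g]]$cq)
  }
})

test_that("consistent experiments yield an empty report", {
  sim <- simulate_experiment(ideal_sim(6, n_refs = 2))
  expect_equal(nrow(check_consistency(sim$experiment)), 0L)
})

test_that("every single structural mutation is detected and attributed", {
  base <- simulate_experiment(ideal_sim(6, n_refs = 2))$experiment
  mutate <- list(
    drop_sample = function(e) {  # a sample vanishes from the target gene
      r <- e$assays$T1$reactions
      e$assays$T1$reactions <- r[r$sample != "S03", ]
      list(e = e, code = "MISSING_SAMPLE", gene = "T1", sample = "S03")
    },
    extra_sample = function(e) {  # a stray sample pasted into a reference
      r <- e$assays$R1$reactions
      extra <- r[r$sample == "S01", ]
      extra$sample <- "S99"
      e$assays$R1$reactions <- rbind(r, extra)
      list(e = e, code = "EXTRA_SAMPLE", gene = "R1", sample = "S99")
    },
    drop_replicate = function(e) {  # one well lost in one gene
      r <- e$assays$R2$reactions
      i <- which(r$sample == "S02" & r$dilution == 1 & r$replicate == 2)
      e$assays$R2$reactions <- r[-i, ]
      list(e = e, code = "REPLICATE_MISMATCH", gene = "R2", sample = "S02")
    },
    drop_dilution = function(e) {  # a whole dilution missing from a gene
      r <- e$assays$R2$reactions
      e$assays$R2$reactions <- r[r$dilution != 2, ]
      list(e = e, code = "DILUTION_MISMATCH", gene = "R2", sample = NA)
    },
    bad_rel_quantity = function(e) {  # dilution 2 claims more template
      r <- e$assays$T1$reactions
      r$rel_quantity[r$sample == "S04" & r$dilution == 2] <- 2
      e$assays$T1$reactions <- r
      list(e = e, code = "BAD_VALUE", gene = "T1", sample = "S04")
    })
  for (nm in names(mutate)) {
    m <- mutate[[nm]](base)
    rep <- check_consistency(m$e)
    expect_gt(nrow(rep), 0L, label = nm)
    hit <- rep[rep$code == m$code & rep$gene_id == m$gene, , drop = FALSE]
    expect_gt(nrow(hit), 0L, label = paste(nm, "code+gene attributed"))
    if (!is.na(m$sample))
      expect_true(m$sample %in% hit$sample_id, label = paste(nm, "sample"))
  }
})

test_that("value and warnings matrices share shape; imputed and refused cells are marked", {
  cfg <- sim_mixed_config(12, cq_noise_sd = 0, seed = 7)
  sim <- simulate_experiment(cfg)
  res <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)
  m <- export_matrix(res, warnings_on = TRUE)
  expect_identical(dim(m$values), dim(m$warnings))
  expect_identical(names(m$values), names(m$warnings))
  expect_identical(m$values$sample, res$sample_ids)

  d <- res$decisions
  lod <- d$sample[d$status == "IMPUTED_LOD"][1]
  expect_false(is.na(m$values$T[m$values$sample == lod]))
  expect_match(m$warnings$T[m$warnings$sample == lod], "IMPUTED_LOD")
  eff <- d$sample[d$status == "NO_RESULT_EFFICIENCY"][1]
  expect_true(is.na(m$values$T[m$values$sample == eff]))
  expect_match(m$warnings$T[m$warnings$sample == eff],
               "NO_RESULT_EFFICIENCY")
  ok <- d$sample[d$status == "OK"][1]
  expect_match(m$warnings$T[m$warnings$sample == ok], "^OK$")
})

test_that("a written simulation reloads through the config path and reproduces the run", {
  cfg <- sim_mixed_config(8, cq_noise_sd = 0.1, seed = 3)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  run <- load_run(file.path(dir, "run.cfg"))
  expect_equal(nrow(check_consistency(run$experiment)), 0L)
  direct <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)
  redone <- quantify_experiment(run$experiment, run$standards, cfg$qc)
  expect_equal(redone$decisions$value, direct$decisions$value,
               tolerance = 1e-12)
  expect_identical(redone$decisions$status, direct$decisions$status)
})

test_that("QC thresholds and per-gene LOQ overrides read back from config text", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "qc.cfg")
  writeLines(c("mode = simple", "cq_extc = 30", "cv_max_percent = 20",
               "cq_loq.T = 32.5  # tighter for the target",
               "slope_min = -4.0", "slope_max = -2.8"), p)
  cfg <- read_run_config(p)
  expect_s3_class(cfg$qc, "qc_settings")
  expect_equal(cfg$qc$mode, "simple")
  expect_equal(cfg$qc$cq_extc, 30)
  expect_equal(cfg$qc$cq_loq[["T"]], 32.5)
  expect_equal(cfg$qc$slope_min, -4.0)
  expect_error(read_run_config({
    writeLines("no_such_key = 1", p); p
  }), "unknown config key")
})
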