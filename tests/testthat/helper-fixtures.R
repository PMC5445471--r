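# Shared fixtures and independent oracles, built in code.

SLOPE100 <- -1 / log10(2)  # slope of a 100%-efficient (doubling) assay

# closed-form normal-equations solution for y ~ a + b*x, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  a <- sy / n - b * sx / n
  fitted <- a + b * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - sy / n)^2)
  list(intercept = a, slope = b, r_squared = 1 - sse / sst)
}

# compact builder: one gene assay from per-(sample, dilution) Cq vectors.
# cqs: named list "sample.dilution" -> numeric vector of replicate Cqs
# (NA = undetected); rel_q: named numeric "dilution" -> rel_quantity.
make_assay <- function(gene_id, role, cqs, rel_q = c(`1` = 1, `2` = 0.1),
                       import_order = NA_integer_) {
  rows <- list()
  for (key in names(cqs)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    s <- parts[1]; d <- as.integer(parts[2])
    v <- cqs[[key]]
    rows[[length(rows) + 1]] <- data.frame(
      sample = s, dilution = d, replicate = seq_along(v), cq = v,
      rel_quantity = unname(rel_q[[as.character(d)]]),
      stringsAsFactors = FALSE)
  }
  gene_assay(gene_id, role, do.call(rbind, rows), import_order)
}

# a dilution_quants-style one-row summary, for driving decide_final directly
dil_row <- function(dilution, mean_cq, dc, cv = 5, n_detected = 2L,
                    n_total = 2L, rel_q = 10^-(dilution - 1)) {
  data.frame(sample = "S", dilution = dilution, rel_quantity = rel_q,
             mean_cq = mean_cq, replicate_copies = "",
             mean_copy_number = dc * rel_q, cv_percent = cv,
             n_detected = n_detected, n_total = n_total,
             dilution_corrected = dc, stringsAsFactors = FALSE)
}

# ideal-conditions simulation: all genes 100% efficient, no noise, no
# perturbations; quantities within the quantifiable range
ideal_sim <- function(n_samples = 10, n_targets = 1, n_refs = 1, seed = 1) {
  genes <- data.frame(
    gene_id = c(paste0("T", seq_len(n_targets)),
                paste0("R", seq_len(n_refs))),
    role = rep(c("target", "reference"), c(n_targets, n_refs)),
    true_slope = SLOPE100,
    true_intercept = 20 + seq_len(n_targets + n_refs) / 2,
    stringsAsFactors = FALSE)
  set.seed(seed)
  q <- matrix(10^runif(n_samples * nrow(genes), -2, 0),
              nrow = n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              genes$gene_id))
  sim_config(genes, q, cq_noise_sd = 0, seed = seed)
}

# hand-transcribed decision-tree truth table (the expected status for a
# combination of the tree's decision axes)
expected_branch_status <- function(ext, det, l1, l2, eff,
                                   mode = "two_dilution") {
  if (ext == "all_fail") return("NO_RESULT_EXTRACTION")
  if (det == "none") return("IMPUTED_LOD")
  if (mode == "simple") {
    if (l1 == "under") return("IMPUTED_LOQ")
    return("OK")
  }
  if (det == "partial") {
    # dilution 2 fully undetected is itself a sub-LOQ signal
    return(if (l1 == "under") "IMPUTED_LOQ" else "OK_DIL1_ONLY")
  }
  if (l1 == "under") return("IMPUTED_LOQ")
  if (l2 == "under") return("OK_DIL1_ONLY")
  if (eff != "pass") return("NO_RESULT_EFFICIENCY")
  "OK"
}

# run one branch fixture end to end and return the target-cell status
branch_status <- function(...) {
  cfg <- sim_branch_config(...)
  sim <- simulate_experiment(cfg)
  res <- quantify_experiment(sim$experiment, sim$standards, cfg$qc)
  res$decisions$status[res$decisions$gene == "T"]
}
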