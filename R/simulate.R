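# Seedable synthetic-experiment generator with ground truth: known true
# per-sample template quantities and curve parameters, plus the decision
# status each injected perturbation should provoke.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of a synthetic qPCR experiment
#'
#' @param genes Data frame with columns \code{gene_id}, \code{role}
#'   (\code{target}/\code{reference}), \code{true_slope},
#'   \code{true_intercept} — the true amplification line of each assay.
#' @param true_quantity Numeric matrix of true relative template
#'   quantities, rows = samples (rownames required), columns = genes
#'   (colnames matching \code{genes$gene_id}).
#' @param n_replicates Technical replicates per (sample, dilution).
#' @param dilution_factor Fold-dilution between dilution 1 and 2.
#' @param n_dilutions 1 or 2.
#' @param cq_noise_sd Gaussian noise on the Cq scale, in cycles
#'   (log-normal on copies). Standard wells stay noise-free so curve error
#'   never confounds decision-tree tests.
#' @param lod_cq_cutoff Wells whose expected (noise-free) Cq exceeds this
#'   go undetected, emulating the assay's limit of detection.
#' @param inhibition PCR inhibition, modeled as an extra Cq offset applied
#'   to dilution-1 wells only (reproducing the reversed-dilution signature
#'   of inhibited samples). Either a named numeric vector
#'   (sample -> offset, applied to every gene of the sample) or a data
#'   frame \code{gene_id}, \code{sample_id}, \code{offset} for
#'   gene-specific inhibition.
#' @param seed RNG seed; a fixed seed reproduces the experiment exactly.
#' @param qc \code{\link{qc_settings}} used to derive each sample's
#'   intended decision status.
#' @param n_standard_levels,standard_replicates Ten-fold standard dilution
#'   series (from quantity 1 downwards), generated noise-free from the
#'   gene's true line.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(genes, true_quantity, n_replicates = 2L,
                       dilution_factor = 10, n_dilutions = 2L,
                       cq_noise_sd = 0, lod_cq_cutoff = 38,
                       inhibition = NULL, seed = 1L,
                       qc = qc_settings(), n_standard_levels = 5L,
                       standard_replicates = 2L) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "role", "true_slope", "true_intercept")
                %in% names(genes)),
            is.matrix(true_quantity),
            !is.null(rownames(true_quantity)),
            identical(sort(colnames(true_quantity)), sort(genes$gene_id)),
            dilution_factor > 1, cq_noise_sd >= 0,
            n_dilutions %in% c(1L, 2L))
  structure(list(genes = genes, true_quantity = true_quantity,
                 n_replicates = as.integer(n_replicates),
                 dilution_factor = dilution_factor,
                 n_dilutions = as.integer(n_dilutions),
                 cq_noise_sd = cq_noise_sd,
                 lod_cq_cutoff = lod_cq_cutoff,
                 inhibition = inhibition, seed = as.integer(seed),
                 qc = qc,
                 n_standard_levels = as.integer(n_standard_levels),
                 standard_replicates = as.integer(standard_replicates)),
            class = "sim_config")
}

# inhibition offset for (gene, sample); 0 when none configured
.inhib_offset <- function(cfg, gene_id, sample_id) {
  inh <- cfg$inhibition
  if (is.null(inh)) return(0)
  if (is.data.frame(inh)) {
    i <- which(inh$gene_id == gene_id & inh$sample_id == sample_id)
    if (length(i)) sum(inh$offset[i]) else 0
  } else {
    if (sample_id %in% names(inh)) unname(inh[[sample_id]]) else 0
  }
}

# expected (noise-free) Cq of one well, inhibition included
.expected_cq <- function(cfg, gene_id, sample_id, dilution) {
  g <- cfg$genes[cfg$genes$gene_id == gene_id, ]
  rel_q <- cfg$dilution_factor^(-(dilution - 1L))
  q <- cfg$true_quantity[sample_id, gene_id]
  cq <- g$true_intercept + g$true_slope * log10(q * rel_q)
  if (dilution == 1L) cq <- cq + .inhib_offset(cfg, gene_id, sample_id)
  cq
}

# Cq(LOQ) the pipeline will estimate for this gene (most-diluted standard
# level on the true line), unless the config's QC overrides it
.sim_cq_loq <- function(cfg, gene_id) {
  g <- cfg$genes[cfg$genes$gene_id == gene_id, ]
  est <- g$true_intercept +
    g$true_slope * log10(10^(-(cfg$n_standard_levels - 1L)))
  v <- cfg$qc$cq_loq
  if (is.null(v)) return(est)
  if (!is.null(names(v)))
    return(if (gene_id %in% names(v)) unname(v[[gene_id]]) else est)
  as.numeric(v)
}

# the decision status the injected perturbations should provoke for one
# sample x target cell, derived analytically from expected Cq values
.intended_status <- function(cfg, target_id, sample_id) {
  qc <- cfg$qc
  two_dil <- qc$mode == "two_dilution" && cfg$n_dilutions == 2L
  refs <- cfg$genes$gene_id[cfg$genes$role == "reference"]
  lf <- log10(cfg$dilution_factor)

  ext_pass <- eff_ok <- logical(length(refs))
  for (i in seq_along(refs)) {
    g <- refs[i]
    e1 <- .expected_cq(cfg, g, sample_id, 1L)
    ext_pass[i] <- e1 <= cfg$lod_cq_cutoff && e1 <= qc$cq_extc
    eff_ok[i] <- TRUE
    if (two_dil) {
      e2 <- .expected_cq(cfg, g, sample_id, 2L)
      if (e1 <= cfg$lod_cq_cutoff && e2 <= cfg$lod_cq_cutoff) {
        sl <- cfg$genes$true_slope[cfg$genes$gene_id == g] +
          .inhib_offset(cfg, g, sample_id) / lf
        eff_ok[i] <- sl >= qc$slope_min && sl <= qc$slope_max &&
          abs(sl - cfg$genes$true_slope[cfg$genes$gene_id == g]) <=
            qc$slope_diff_max
      }
    }
  }
  if (!any(ext_pass)) return("NO_RESULT_EXTRACTION")
  if (!any(ext_pass & eff_ok)) return("NO_RESULT_EFFICIENCY")

  cq_loq <- .sim_cq_loq(cfg, target_id)
  e1 <- .expected_cq(cfg, target_id, sample_id, 1L)
  det1 <- e1 <= cfg$lod_cq_cutoff
  if (!two_dil) {
    if (!det1) return("IMPUTED_LOD")
    if (e1 > cq_loq) return("IMPUTED_LOQ")
    return("OK")
  }
  e2 <- .expected_cq(cfg, target_id, sample_id, 2L)
  det2 <- e2 <= cfg$lod_cq_cutoff
  if (!det1 && !det2) return("IMPUTED_LOD")
  if (!det1 || e1 > cq_loq) return("IMPUTED_LOQ")
  if (!det2 || e2 > cq_loq) return("OK_DIL1_ONLY")
  sl <- cfg$genes$true_slope[cfg$genes$gene_id == target_id] +
    .inhib_offset(cfg, target_id, sample_id) / lf
  if (sl < qc$slope_min || sl > qc$slope_max ||
      abs(sl - cfg$genes$true_slope[cfg$genes$gene_id == target_id]) >
        qc$slope_diff_max)
    return("NO_RESULT_EFFICIENCY")
  "OK"
}

#' Simulate a qPCR experiment with known ground truth
#'
#' Standard tables are generated noise-free from each gene's true line
#' over ten-fold dilution levels. Each sample well's Cq is the true line
#' evaluated at (true quantity x dilution rel_quantity), plus Gaussian
#' Cq noise and any configured inhibition offset; wells whose expected
#' (noise-free) Cq exceeds \code{lod_cq_cutoff} go undetected. The same
#' seed reproduces the experiment exactly.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{experiment} (a \code{qpcr_experiment}),
#'   \code{standards} (named list of standard tables), \code{truth} (data
#'   frame \code{sample}, \code{gene}, \code{true_ratio},
#'   \code{intended_status} for every sample x target cell) and the
#'   \code{config}.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- cfg$genes
  samples <- rownames(cfg$true_quantity)

  standards <- lapply(stats::setNames(genes$gene_id, genes$gene_id),
                      function(g) {
    gi <- genes[genes$gene_id == g, ]
    q <- rep(10^(0:-(cfg$n_standard_levels - 1L)),
             each = cfg$standard_replicates)
    data.frame(quantity = q,
               cq = gi$true_intercept + gi$true_slope * log10(q),
               included = TRUE)
  })

  assays <- .with_seed(cfg$seed, {
    out <- list()
    ref_order <- 0L
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene_id[i]
      rows <- list()
      for (s in samples) for (d in seq_len(cfg$n_dilutions)) {
        ecq <- .expected_cq(cfg, g, s, d)
        rel_q <- cfg$dilution_factor^(-(d - 1L))
        for (r in seq_len(cfg$n_replicates)) {
          cq <- if (ecq > cfg$lod_cq_cutoff) NA_real_
                else ecq + stats::rnorm(1L, 0, cfg$cq_noise_sd)
          rows[[length(rows) + 1L]] <-
            data.frame(sample = s, dilution = d, replicate = r, cq = cq,
                       rel_quantity = rel_q, stringsAsFactors = FALSE)
        }
      }
      io <- NA_integer_
      if (genes$role[i] == "reference") {
        ref_order <- ref_order + 1L
        io <- ref_order
      }
      out[[g]] <- gene_assay(g, genes$role[i], do.call(rbind, rows),
                             import_order = io)
    }
    out
  })

  refs <- genes$gene_id[genes$role == "reference"]
  targets <- genes$gene_id[genes$role == "target"]
  # true normalized ratio: reference genes scaled to the first one by the
  # ratio of across-sample means, then averaged, exactly as the pipeline
  # does on noise-free data with all reference genes admitted
  q1 <- cfg$true_quantity[, refs[1L], drop = TRUE]
  scaled_refs <- matrix(NA_real_, nrow = length(samples),
                        ncol = length(refs))
  for (j in seq_along(refs)) {
    v <- cfg$true_quantity[, refs[j]]
    scaled_refs[, j] <- v * (mean(q1) / mean(v))
  }
  ravg <- rowMeans(scaled_refs)

  truth <- do.call(rbind, lapply(targets, function(tg) {
    data.frame(sample = samples, gene = tg,
               true_ratio = cfg$true_quantity[, tg] / ravg,
               intended_status = vapply(samples, function(s)
                 .intended_status(cfg, tg, s), character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  list(experiment = experiment(assays, name = "simulated"),
       standards = standards, truth = truth, config = cfg)
}

#' Compare pipeline decisions against the simulation's ground truth
#'
#' @param truth The \code{truth} data frame from
#'   \code{\link{simulate_experiment}}.
#' @param decisions The \code{decisions} data frame of a
#'   \code{quant_result} computed on the same experiment.
#' @return List with \code{table} (per-cell comparison incl.
#'   \code{status_match} and, for cells correctly quantified as
#'   \code{OK}/\code{OK_DIL1_ONLY}, the relative error of the value
#'   against the true ratio), \code{status_agreement_percent},
#'   \code{median_rel_error_percent} and \code{n_quantified}.
#' @export
truth_table <- function(truth, decisions) {
  m <- merge(truth, decisions, by = c("sample", "gene"), sort = FALSE)
  m$status_match <- m$intended_status == m$status
  quant_ok <- m$status_match & m$status %in% c("OK", "OK_DIL1_ONLY")
  m$rel_error <- ifelse(quant_ok,
                        abs(m$value - m$true_ratio) / m$true_ratio,
                        NA_real_)
  list(table = m,
       status_agreement_percent = 100 * mean(m$status_match),
       median_rel_error_percent =
         100 * stats::median(m$rel_error, na.rm = TRUE),
       n_quantified = sum(quant_ok))
}

#' A mixed-regime validation scenario
#'
#' One target and two reference genes over \code{n_samples} samples
#' covering the regimes the decision tree must separate: well-quantifiable
#' samples spanning 2.5 orders of magnitude, sub-LOD and sub-LOQ samples,
#' a PCR-inhibited sample (target inhibited, +2 cycles on dilution 1), and
#' a failed-extraction sample (both reference genes above the extraction
#' ceiling). Quantities are placed with wide margins to every QC
#' threshold so the intended statuses are unambiguous at low Cq noise.
#'
#' @param n_samples Total number of samples (>= 8).
#' @param cq_noise_sd Cq noise in cycles.
#' @param seed RNG seed.
#' @return A \code{\link{sim_config}}.
#' @export
sim_mixed_config <- function(n_samples = 20L, cq_noise_sd = 0, seed = 1L) {
  stopifnot(n_samples >= 8L)
  genes <- data.frame(
    gene_id = c("R1", "R2", "T"),
    role = c("reference", "reference", "target"),
    true_slope = c(-1 / log10(2), -3.45, -1 / log10(2)),
    true_intercept = c(20, 21, 20),
    stringsAsFactors = FALSE)

  n_lod <- max(1L, round(0.10 * n_samples))
  n_loq <- max(1L, round(0.10 * n_samples))
  n_inh <- max(1L, round(0.05 * n_samples))
  n_ext <- max(1L, round(0.05 * n_samples))
  n_ok <- n_samples - n_lod - n_loq - n_inh - n_ext
  ids <- sprintf("S%02d", seq_len(n_samples))

  tq <- c(10^seq(0, -2.5, length.out = n_ok),   # quantifiable range
          rep(1e-6, n_lod),                     # below detection
          rep(10^-4.6, n_loq),                  # below quantification
          rep(10^-1, n_inh),                    # inhibited (target only)
          rep(10^-1, n_ext))                    # failed extraction
  rq <- rep(1, n_samples)
  ext_idx <- seq.int(n_samples - n_ext + 1L, n_samples)
  rq[ext_idx] <- 10^-4.6                        # reference genes collapse
  inh_idx <- seq.int(n_samples - n_ext - n_inh + 1L, n_samples - n_ext)

  true_quantity <- cbind(R1 = rq, R2 = rq, T = tq)
  rownames(true_quantity) <- ids

  inhibition <- data.frame(gene_id = "T", sample_id = ids[inh_idx],
                           offset = 2.0, stringsAsFactors = FALSE)

  sim_config(genes, true_quantity, n_replicates = 2L,
             dilution_factor = 10, n_dilutions = 2L,
             cq_noise_sd = cq_noise_sd, lod_cq_cutoff = 38,
             inhibition = inhibition, seed = seed)
}

#' Fixture for one branch of the decision tree
#'
#' Builds a single-sample experiment that realizes a requested combination
#' of the decision tree's axes: extraction verdict, target detection,
#' per-dilution LOQ state, and the efficiency verdict. Axes that the tree
#' never consults on the requested path (e.g. the efficiency axis when
#' dilution 1 is under the LOQ) are ignored by the construction.
#'
#' @param extraction \code{"none_fail"}, \code{"some_fail"} (one of two
#'   reference genes over the ceiling) or \code{"all_fail"}.
#' @param detection Target wells: \code{"full"}, \code{"partial"}
#'   (dilution 2 undetected) or \code{"none"}.
#' @param loq1,loq2 \code{"over"} (quantifiable) or \code{"under"} for
#'   dilutions 1 and 2.
#' @param efficiency \code{"pass"}, \code{"fail_range"} (sample slope
#'   outside the allowed range) or \code{"fail_diff"} (slope inside the
#'   range but too far from the curve's).
#' @param mode \code{"two_dilution"} or \code{"simple"}.
#' @return A \code{\link{sim_config}} realizing the branch.
#' @export
sim_branch_config <- function(extraction = "none_fail",
                              detection = "full",
                              loq1 = "over", loq2 = "over",
                              efficiency = "pass",
                              mode = "two_dilution") {
  m <- -1 / log10(2)  # slope: 100% efficiency
  b <- 20
  # standards span quantities 1..1e-4, so Cq(LOQ) = b + 4*|m| ~ 33.29;
  # detection cutoff 38; extraction ceiling 34 (defaults)
  q_ref_fail <- 10^-4.4   # dil-1 Cq 34.6: fails extraction, still detected

  r1 <- if (extraction %in% c("some_fail", "all_fail")) q_ref_fail else 1
  r2 <- if (extraction == "all_fail") q_ref_fail else 1

  dilution_factor <- 10
  off <- 0
  if (detection == "none") {
    tq <- 1e-6                       # both dilutions beyond the cutoff
  } else if (detection == "partial") {
    if (loq1 == "under") {
      tq <- 10^-4.8                  # dil1 Cq 35.9 (> LOQ), dil2 undetected
    } else {
      dilution_factor <- 100         # dil1 Cq 32.6 (quantifiable),
      tq <- 10^-3.8                  # dil2 Cq 39.3 (undetected)
    }
  } else {                           # full detection
    if (loq1 == "under") {
      tq <- 10^-4.1                  # Cqs 33.6 / 36.9: dil1 over the LOQ Cq
    } else if (loq2 == "under") {
      tq <- 10^-3.9                  # Cqs 33.0 / 36.3: only dil2 under
    } else {
      tq <- 1                        # Cqs 20 / 23.3: fully quantifiable
      if (efficiency == "fail_range") off <- 2.0    # slope -1.32
      if (efficiency == "fail_diff") off <- -1.08   # slope -4.40, diff 1.08
    }
  }

  genes <- data.frame(gene_id = c("R1", "R2", "T"),
                      role = c("reference", "reference", "target"),
                      true_slope = m, true_intercept = b,
                      stringsAsFactors = FALSE)
  true_quantity <- cbind(R1 = r1, R2 = r2, T = tq)
  rownames(true_quantity) <- "S1"
  inhibition <- if (off != 0)
    data.frame(gene_id = "T", sample_id = "S1", offset = off,
               stringsAsFactors = FALSE) else NULL

  sim_config(genes, true_quantity, n_replicates = 2L,
             dilution_factor = dilution_factor,
             n_dilutions = if (mode == "simple") 1L else 2L,
             cq_noise_sd = 0, lod_cq_cutoff = 38,
             inhibition = inhibition, seed = 1L,
             qc = qc_settings(mode = mode))
}

#' Write a simulated experiment to disk in the import dialects
#'
#' Emits, for every gene, \code{gene_<id>.tsv} and
#' \code{standard_<id>.tsv}, plus \code{truth.tsv} and a ready-to-run
#' \code{run.cfg}.
#'
#' @param sim Result of \code{\link{simulate_experiment}}.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  cfg_lines <- c(paste0("mode = ", sim$config$qc$mode))
  for (g in names(sim$experiment$assays)) {
    a <- sim$experiment$assays[[g]]
    p <- file.path(dir, paste0("gene_", g, ".tsv"))
    writeLines(serialize_gene_table(a), p); files <- c(files, p)
    ps <- file.path(dir, paste0("standard_", g, ".tsv"))
    writeLines(serialize_standard_table(sim$standards[[g]]), ps)
    files <- c(files, ps)
    cfg_lines <- c(cfg_lines,
                   paste0("gene.", g, ".role = ", a$role),
                   paste0("gene.", g, ".file = ", basename(p)),
                   paste0("gene.", g, ".standard = ", basename(ps)))
  }
  pt <- file.path(dir, "truth.tsv"); .write_tsv(sim$truth, pt)
  pc <- file.path(dir, "run.cfg"); writeLines(cfg_lines, pc)
  invisible(c(files, pt, pc))
}

#' Synthetic two-target gene-expression study
#'
#' Emulates a typical plant gene-expression qPCR design: two target genes
#' with near- (but not exactly) 100\% amplification efficiencies, two
#' stable reference genes, and a shared per-sample extraction/RT yield, so
#' that the standard-curve route and the classic delta-delta-Cq route can
#' be compared on the same synthetic data. All quantities lie inside the
#' quantifiable range. This is a synthetic emulation of such a study, not
#' measured data.
#'
#' @param n_samples Number of samples.
#' @param cq_noise_sd Cq noise in cycles.
#' @param seed RNG seed.
#' @return A \code{\link{sim_config}}.
#' @export
sim_expression_study <- function(n_samples = 24L, cq_noise_sd = 0.15,
                                 seed = 1L) {
  genes <- data.frame(
    gene_id = c("T1", "T2", "R1", "R2"),
    role = c("target", "target", "reference", "reference"),
    true_slope = c(-3.45, -3.25, -1 / log10(2), -3.40),
    true_intercept = c(22, 23, 20, 21),
    stringsAsFactors = FALSE)
  q <- .with_seed(seed, {
    yield <- 10^stats::rnorm(n_samples, 0, 0.2)   # extraction/RT yield
    t1 <- 10^stats::runif(n_samples, -2, 0)       # induced over 2 logs
    t2 <- 10^stats::runif(n_samples, -1.5, 0)
    r1 <- 10^stats::rnorm(n_samples, 0, 0.05)     # stable reference genes
    r2 <- 10^stats::rnorm(n_samples, 0, 0.05)
    cbind(T1 = yield * t1, T2 = yield * t2,
          R1 = yield * r1, R2 = yield * r2)
  })
  rownames(q) <- sprintf("S%02d", seq_len(n_samples))
  sim_config(genes, q, cq_noise_sd = cq_noise_sd, seed = seed + 1L)
}

#' Synthetic GMO quantification with strong PCR inhibition
#'
#' Emulates a GMO-diagnostics scenario: the transgene content of one
#' sample, measured as the ratio of transgene to taxon reference-gene
#' (lectin) copy numbers in percent, with two independent DNA isolations
#' both strongly inhibited. Inhibition delays the less-diluted reactions
#' so much that they come up LATER than the more diluted ones (reversed
#' dilution signature), and hits the reference assay harder than the
#' transgene assay, so the uncontrolled per-dilution \%GMO estimates
#' scatter over more than an order of magnitude around the true 33\%.
#' This is a synthetic emulation of such a scenario, not measured data.
#'
#' @param true_gmo_percent True transgene/reference copy ratio in percent.
#' @param seed RNG seed.
#' @return A \code{\link{sim_config}}; samples \code{iso1}, \code{iso2}
#'   are the two inhibited DNA isolations.
#' @export
sim_gmo_inhibition <- function(true_gmo_percent = 33, seed = 1L) {
  genes <- data.frame(
    gene_id = c("lectin", "rrs"),
    role = c("reference", "target"),
    true_slope = c(-1 / log10(2), -3.35),
    true_intercept = c(19, 22),
    stringsAsFactors = FALSE)
  q <- cbind(lectin = c(1, 1),
             rrs = rep(true_gmo_percent / 100, 2))
  rownames(q) <- c("iso1", "iso2")
  inhibition <- data.frame(
    gene_id = c("lectin", "rrs", "lectin", "rrs"),
    sample_id = c("iso1", "iso1", "iso2", "iso2"),
    offset = c(4.0, 1.5, 5.0, 0.5),
    stringsAsFactors = FALSE)
  sim_config(genes, q, cq_noise_sd = 0.1, inhibition = inhibition,
             seed = seed)
}

#' Uncontrolled per-dilution \%GMO estimates
#'
#' The "no quality control" route: for every sample and dilution, the
#' transgene dilution-corrected copy number divided by the reference-gene
#' one, in percent, with no decision-support filtering at all.
#'
#' @param sim Result of \code{\link{simulate_experiment}} on a
#'   \code{\link{sim_gmo_inhibition}} configuration.
#' @return Data frame \code{sample}, \code{dilution}, \code{gmo_percent}.
#' @export
gmo_noqc_percent <- function(sim) {
  curves <- lapply(sim$standards, fit_standard_curve)
  ref <- dilution_quants(sim$experiment$assays$lectin, curves$lectin)
  tgt <- dilution_quants(sim$experiment$assays$rrs, curves$rrs)
  m <- merge(tgt, ref, by = c("sample", "dilution"),
             suffixes = c("_t", "_r"))
  data.frame(sample = m$sample, dilution = m$dilution,
             gmo_percent = 100 * m$dilution_corrected_t /
               m$dilution_corrected_r,
             stringsAsFactors = FALSE)
}
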