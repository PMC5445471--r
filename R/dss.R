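# Hierarchical quality-control decision support: extraction control,
# LOD/LOQ imputation, and per-sample amplification-efficiency control.

QC_STATUSES <- c("OK", "OK_DIL1_ONLY", "IMPUTED_LOQ", "IMPUTED_LOD",
                 "NO_RESULT_EXTRACTION", "NO_RESULT_EFFICIENCY")

#' Quality-control settings of the decision support system
#'
#' All thresholds of the decision tree, user-tunable per experiment.
#' Defaults are deliberately loose, aimed at reliable detection of two-fold
#' copy-number differences; tighten them when the application demands
#' smaller measurement uncertainty.
#'
#' @param cq_extc Extraction-control Cq ceiling on reference genes
#'   (default 34 cycles): a reference gene whose dilution-1 mean Cq exceeds
#'   it indicates a failed nucleic-acid extraction for that sample.
#' @param cq_loq Cq at the limit of quantification. Either a single value,
#'   a named vector (per gene), or \code{NULL} to estimate each gene's
#'   Cq(LOQ) from its standard curve (most-diluted level mean).
#' @param cv_max_percent Maximum acceptable replicate CV of copy numbers
#'   (default 30\%); higher variability is read as sub-LOQ stochasticity.
#' @param slope_min,slope_max Acceptable range for the individual-sample
#'   slope in two-dilution mode (defaults -4.5 and -2.5, roughly 67--150\%
#'   amplification efficiency).
#' @param slope_diff_max Maximum absolute difference between the sample
#'   slope and the standard-curve slope (default 1.0 cycles/log10).
#' @param lod_divisor The LOD-imputed value is the LOQ-imputed value
#'   divided by this (> 1, default 5), keeping it strictly positive and
#'   strictly below the LOQ imputation.
#' @param std_replicate_dev_max Max Cq deviation of a standard replicate
#'   from its level partners before a pipetting flag (default 0.5 cycles).
#' @param mode \code{"two_dilution"} (default; full decision tree including
#'   the efficiency control) or \code{"simple"} (one dilution; no
#'   per-sample efficiency control).
#' @return An object of class \code{qc_settings}.
#' @export
qc_settings <- function(cq_extc = 34, cq_loq = NULL, cv_max_percent = 30,
                        slope_min = -4.5, slope_max = -2.5,
                        slope_diff_max = 1.0, lod_divisor = 5,
                        std_replicate_dev_max = 0.5,
                        mode = c("two_dilution", "simple")) {
  mode <- match.arg(mode)
  stopifnot(slope_min < slope_max, slope_max < 0, lod_divisor > 1,
            cv_max_percent > 0, std_replicate_dev_max > 0, cq_extc > 0)
  structure(list(cq_extc = cq_extc, cq_loq = cq_loq,
                 cv_max_percent = cv_max_percent,
                 slope_min = slope_min, slope_max = slope_max,
                 slope_diff_max = slope_diff_max,
                 lod_divisor = lod_divisor,
                 std_replicate_dev_max = std_replicate_dev_max,
                 mode = mode),
            class = "qc_settings")
}

.cq_loq_for <- function(qc, gene_id, curve) {
  v <- qc$cq_loq
  if (is.null(v)) return(curve$cq_loq)
  if (!is.null(names(v))) {
    if (gene_id %in% names(v)) return(unname(v[[gene_id]]))
    return(curve$cq_loq)
  }
  as.numeric(v)
}

#' Individual-sample slope from two dilutions
#'
#' The slope implied by one sample's own dilution pair:
#' \code{(Cq2 - Cq1) / (log10(q2) - log10(q1))}, comparable to the standard
#' curve's slope. Deviations signal PCR inhibition (shallower or even
#' positive slope when the less-diluted reaction is disproportionately
#' delayed) or over-amplification.
#'
#' @param mean_cq Numeric length-2: mean Cq at dilution 1 and dilution 2.
#' @param rel_quantity Numeric length-2: relative template quantities of
#'   the two dilutions (q1 > q2).
#' @return The sample slope, or \code{NA} if either Cq is missing.
#' @examples
#' sample_slope(c(24, 27.3219), c(1, 0.1))  # about -3.32: efficiency ok
#' @export
sample_slope <- function(mean_cq, rel_quantity) {
  stopifnot(length(mean_cq) == 2L, length(rel_quantity) == 2L,
            all(rel_quantity > 0))
  if (anyNA(mean_cq)) return(NA_real_)
  (mean_cq[2L] - mean_cq[1L]) /
    (log10(rel_quantity[2L]) - log10(rel_quantity[1L]))
}

#' Extraction control over the reference genes of one sample
#'
#' A reference gene passes when its dilution-1 mean Cq is detected and does
#' not exceed \code{qc$cq_extc}; a failing gene is dropped from the
#' sample's reference averaging. The global verdict is \code{"FAIL"} only
#' when every reference gene fails, in which case no target result is
#' calculated for the sample.
#'
#' @param ref_dil1_cq Named numeric vector: dilution-1 mean Cq per
#'   reference gene (\code{NA} = all wells undetected).
#' @param qc \code{\link{qc_settings}}.
#' @return List with \code{per_gene} (named logical, TRUE = pass) and
#'   \code{verdict} (\code{"PASS"}/\code{"FAIL"}).
#' @export
evaluate_extraction <- function(ref_dil1_cq, qc = qc_settings()) {
  pass <- !is.na(ref_dil1_cq) & ref_dil1_cq <= qc$cq_extc
  list(per_gene = pass,
       verdict = if (any(pass)) "PASS" else "FAIL")
}

#' Impute a below-LOQ result
#'
#' A sample whose target reactions fall below the limit of quantification
#' gets the value the pipeline would produce for a target sitting exactly
#' at the LOQ: the copy number at \code{cq_loq} on the standard curve,
#' normalized by the sample's own reference average. Comparable to, and by
#' construction not smaller than nothing below, the directly quantified
#' values of near-LOQ samples.
#'
#' @param curve The target gene's \code{standard_curve}.
#' @param cq_loq Cq at the LOQ.
#' @param ref_average The sample's reference average (> 0).
#' @return The imputed normalized value.
#' @export
impute_loq <- function(curve, cq_loq, ref_average) {
  stopifnot(!is.na(ref_average), ref_average > 0)
  copy_number_from_cq(cq_loq, curve) / ref_average
}

#' Impute a below-LOD result
#'
#' When every target reaction of a sample is undetected, the target is
#' below the limit of detection; the result is imputed as the LOQ
#' imputation divided by \code{qc$lod_divisor} — a very small number,
#' strictly positive and strictly below any LOQ-imputed value, so
#' downstream analyses need no extra missing-data handling.
#'
#' @inheritParams impute_loq
#' @param qc \code{\link{qc_settings}} (uses \code{lod_divisor}).
#' @return The imputed normalized value.
#' @export
impute_lod <- function(curve, cq_loq, ref_average, qc = qc_settings()) {
  impute_loq(curve, cq_loq, ref_average) / qc$lod_divisor
}

# A per-dilution summary row is "under LOQ" when its mean Cq exceeds
# cq_loq, its replicate CV exceeds the ceiling, or any replicate dropped
# out (partial dropout is read as sub-LOQ stochasticity).
.under_loq <- function(row, cq_loq, qc) {
  if (row$n_detected == 0L) return(TRUE)
  if (row$n_detected < row$n_total) return(TRUE)
  if (!is.na(row$mean_cq) && row$mean_cq > cq_loq) return(TRUE)
  if (!is.na(row$cv_percent) && row$cv_percent > qc$cv_max_percent)
    return(TRUE)
  FALSE
}

#' Decide the final result for one sample x target-gene cell
#'
#' Applies the QC decision tree hierarchically:
#' \enumerate{
#'   \item \emph{Extraction control}: if every reference gene failed, no
#'     result (\code{NO_RESULT_EXTRACTION}); if all surviving reference
#'     genes were discarded by the efficiency control,
#'     \code{NO_RESULT_EFFICIENCY}.
#'   \item \emph{LOD}: all target wells undetected at every dilution ->
#'     \code{IMPUTED_LOD}.
#'   \item \emph{LOQ}: dilution 1 under the LOQ (high mean Cq, replicate
#'     CV over the ceiling, or replicate dropout) -> \code{IMPUTED_LOQ};
#'     only dilution 2 under the LOQ -> dilution 1 alone is used
#'     (\code{OK_DIL1_ONLY}) and the efficiency control is skipped.
#'   \item \emph{Efficiency} (two-dilution mode): sample slope outside
#'     \code{[slope_min, slope_max]} or further than \code{slope_diff_max}
#'     from the standard-curve slope -> \code{NO_RESULT_EFFICIENCY}.
#' }
#' Otherwise the value is the mean of the per-dilution normalized values
#' (\code{OK}).
#'
#' @param sample_id,gene_id Cell identifiers (bookkeeping only).
#' @param target Data frame from \code{\link{dilution_quants}} restricted
#'   to this sample (one row per dilution).
#' @param ref_average Named numeric vector: the sample's reference average
#'   per dilution (names = dilution indices; NA when unavailable).
#' @param curve The target gene's \code{standard_curve}.
#' @param qc \code{\link{qc_settings}}.
#' @param ref_state List describing the reference-gene QC for this sample:
#'   \code{extraction_verdict} (\code{"PASS"}/\code{"FAIL"}) and
#'   \code{efficiency_all_failed} (logical). Defaults assume healthy
#'   references.
#' @return A list of class \code{quant_decision}: \code{sample_id},
#'   \code{gene_id}, \code{value} (NA when refused), \code{status}, and an
#'   ordered character vector of \code{warnings}.
#' @export
decide_final <- function(sample_id, gene_id, target, ref_average, curve,
                         qc = qc_settings(),
                         ref_state = list(extraction_verdict = "PASS",
                                          efficiency_all_failed = FALSE)) {
  warn <- character()
  decision <- function(value, status) {
    structure(list(sample_id = sample_id, gene_id = gene_id,
                   value = value, status = status, warnings = warn),
              class = "quant_decision")
  }

  # 1) extraction control (on the reference genes)
  if (identical(ref_state$extraction_verdict, "FAIL")) {
    warn <- c(warn, "EXTRACTION_FAIL_ALL_REFERENCES")
    return(decision(NA_real_, "NO_RESULT_EXTRACTION"))
  }
  if (isTRUE(ref_state$efficiency_all_failed)) {
    warn <- c(warn, "EFFICIENCY_FAIL_ALL_REFERENCES")
    return(decision(NA_real_, "NO_RESULT_EFFICIENCY"))
  }

  target <- target[order(target$dilution), , drop = FALSE]
  d1 <- target[target$dilution == 1L, , drop = FALSE]
  if (nrow(d1) != 1L) stop("decide_final: dilution 1 summary missing")
  two_dil <- qc$mode == "two_dilution" && nrow(target) >= 2L
  d2 <- if (two_dil) target[target$dilution == 2L, , drop = FALSE] else NULL

  cq_loq <- .cq_loq_for(qc, gene_id, curve)
  ravg1 <- if ("1" %in% names(ref_average)) unname(ref_average[["1"]])
           else NA_real_
  impute_ref <- if (!is.na(ravg1)) ravg1 else {
    other <- ref_average[!is.na(ref_average)]
    if (length(other)) unname(other[[1L]]) else NA_real_
  }

  # 2) limit of detection: every well of every dilution undetected
  if (sum(target$n_detected) == 0L) {
    if (is.na(impute_ref)) {
      warn <- c(warn, "NO_REFERENCE_DATA")
      return(decision(NA_real_, "NO_RESULT_EXTRACTION"))
    }
    warn <- c(warn, "ALL_REPLICATES_UNDETECTED_IMPUTED_LOD")
    return(decision(impute_lod(curve, cq_loq, impute_ref, qc),
                    "IMPUTED_LOD"))
  }

  # 3) limit of quantification
  loq_reason <- function(row) {
    r <- character()
    if (row$n_detected > 0L && row$n_detected < row$n_total)
      r <- c(r, "REPLICATE_DROPOUT")
    if (row$n_detected == 0L) r <- c(r, "UNDETECTED")
    if (!is.na(row$mean_cq) && row$mean_cq > cq_loq) r <- c(r, "CQ_OVER_LOQ")
    if (!is.na(row$cv_percent) && row$cv_percent > qc$cv_max_percent)
      r <- c(r, "CV_OVER_MAX")
    r
  }
  if (.under_loq(d1, cq_loq, qc)) {
    if (is.na(impute_ref)) {
      warn <- c(warn, "NO_REFERENCE_DATA")
      return(decision(NA_real_, "NO_RESULT_EXTRACTION"))
    }
    warn <- c(warn, paste0("DIL1_UNDER_LOQ_", loq_reason(d1)))
    return(decision(impute_loq(curve, cq_loq, impute_ref), "IMPUTED_LOQ"))
  }
  if (two_dil && .under_loq(d2, cq_loq, qc)) {
    if (is.na(ravg1)) {
      warn <- c(warn, "NO_REFERENCE_DATA")
      return(decision(NA_real_, "NO_RESULT_EXTRACTION"))
    }
    warn <- c(warn, paste0("DIL2_UNDER_LOQ_", loq_reason(d2)))
    return(decision(d1$dilution_corrected / ravg1, "OK_DIL1_ONLY"))
  }

  # 4) individual-sample amplification-efficiency control
  if (two_dil) {
    sl <- sample_slope(c(d1$mean_cq, d2$mean_cq),
                       c(d1$rel_quantity, d2$rel_quantity))
    if (is.na(sl) || sl < qc$slope_min || sl > qc$slope_max) {
      warn <- c(warn, sprintf("SAMPLE_SLOPE_OUT_OF_RANGE(%.3f)", sl))
      return(decision(NA_real_, "NO_RESULT_EFFICIENCY"))
    }
    if (abs(sl - curve$slope) > qc$slope_diff_max) {
      warn <- c(warn, sprintf("SAMPLE_SLOPE_DIFF_TOO_LARGE(%.3f)",
                              sl - curve$slope))
      return(decision(NA_real_, "NO_RESULT_EFFICIENCY"))
    }
  }

  tgt <- stats::setNames(target$dilution_corrected,
                         as.character(target$dilution))
  if (!two_dil) tgt <- tgt["1"]
  nc <- normalize_and_combine(tgt, ref_average)
  if (is.na(nc$value)) {
    warn <- c(warn, "NO_REFERENCE_DATA")
    return(decision(NA_real_, "NO_RESULT_EXTRACTION"))
  }
  decision(nc$value, "OK")
}

#' @export
print.quant_decision <- function(x, ...) {
  cat(sprintf("%s / %s: %s [%s]%s\n", x$sample_id, x$gene_id,
              ifelse(is.na(x$value), "-", formatC(x$value, digits = 5,
                                                  format = "g")),
              x$status,
              if (length(x$warnings))
                paste0(" ", paste(x$warnings, collapse = "; ")) else ""))
  invisible(x)
}

#' Run the full quantification pipeline on an experiment
#'
#' Fits (or accepts) one standard curve per gene, back-calculates and
#' summarizes copy numbers, applies the reference-gene QC (extraction and,
#' in two-dilution mode, per-sample efficiency), scales and averages the
#' reference genes, and walks every sample x target-gene cell through the
#' decision tree.
#'
#' @param exp A consistent \code{qpcr_experiment} (see
#'   \code{\link{check_consistency}}).
#' @param standards Named list, gene id -> standard table (data frame) or
#'   prefitted \code{standard_curve}.
#' @param qc \code{\link{qc_settings}}.
#' @return An object of class \code{quant_result}: \code{decisions} (data
#'   frame \code{sample}, \code{gene}, \code{value}, \code{status},
#'   \code{warnings}), per-gene \code{details} data frames with all
#'   intermediate values, fitted \code{curves}, the reference-averaging
#'   \code{ref} block, \code{sample_ids}, \code{target_genes} and the
#'   settings used.
#' @export
quantify_experiment <- function(exp, standards, qc = qc_settings()) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  rep_check <- check_consistency(exp)
  if (nrow(rep_check) > 0L)
    stop("experiment is not consistent (", nrow(rep_check),
         " issue(s)); run check_consistency() for details")
  genes <- names(exp$assays)
  missing_std <- setdiff(genes, names(standards))
  if (length(missing_std))
    stop("no standard table/curve for gene(s): ",
         paste(missing_std, collapse = ", "))

  curves <- lapply(stats::setNames(genes, genes), function(g) {
    s <- standards[[g]]
    cu <- if (inherits(s, "standard_curve")) s else fit_standard_curve(s)
    cu$cq_loq <- .cq_loq_for(qc, g, cu)
    cu
  })
  quants <- lapply(stats::setNames(genes, genes), function(g)
    dilution_quants(exp$assays[[g]], curves[[g]]))

  roles <- vapply(exp$assays, `[[`, character(1), "role")
  refs <- genes[roles == "reference"]
  refs <- refs[order(vapply(exp$assays[refs], `[[`, integer(1),
                            "import_order"))]
  targets <- genes[roles == "target"]
  if (length(refs) == 0L) stop("experiment has no reference gene")
  samples <- exp$sample_ids
  two_dil <- qc$mode == "two_dilution" && exp$n_dilutions >= 2L

  # reference-gene QC per sample: extraction (dilution-1 Cq ceiling) and,
  # in two-dilution mode, the per-sample efficiency control
  ext_pass <- eff_pass <- matrix(TRUE, length(samples), length(refs),
                                 dimnames = list(samples, refs))
  for (g in refs) {
    q <- quants[[g]]
    for (s in samples) {
      r1 <- q[q$sample == s & q$dilution == 1L, , drop = FALSE]
      cq1 <- if (nrow(r1) && r1$n_detected > 0L) r1$mean_cq else NA_real_
      ext_pass[s, g] <- !is.na(cq1) && cq1 <= qc$cq_extc
      if (two_dil) {
        r2 <- q[q$sample == s & q$dilution == 2L, , drop = FALSE]
        if (nrow(r2) == 1L && nrow(r1) == 1L &&
            r1$n_detected > 0L && r2$n_detected > 0L) {
          sl <- sample_slope(c(r1$mean_cq, r2$mean_cq),
                             c(r1$rel_quantity, r2$rel_quantity))
          eff_pass[s, g] <- sl >= qc$slope_min & sl <= qc$slope_max &
            abs(sl - curves[[g]]$slope) <= qc$slope_diff_max
        }
      }
    }
  }
  use <- ext_pass & eff_pass

  ref_block <- scale_and_average_references(quants[refs], use = use)
  avg <- ref_block$averages

  ref_avg_for <- function(s) {
    rows <- avg[avg$sample == s, , drop = FALSE]
    stats::setNames(rows$ref_average, as.character(rows$dilution))
  }

  decisions <- list()
  for (g in targets) {
    q <- quants[[g]]
    for (s in samples) {
      tgt <- q[q$sample == s, , drop = FALSE]
      ref_state <- list(
        extraction_verdict = if (any(ext_pass[s, ])) "PASS" else "FAIL",
        efficiency_all_failed = any(ext_pass[s, ]) && !any(use[s, ]))
      dec <- decide_final(s, g, tgt, ref_avg_for(s), curves[[g]], qc,
                          ref_state = ref_state)
      # surface dropped (but not all-failing) reference genes in the audit
      # trail of the cell
      dropped <- refs[ext_pass[s, ] & !eff_pass[s, ]]
      if (length(dropped) && !startsWith(dec$status, "NO_RESULT"))
        dec$warnings <- c(paste0("REFERENCE_DROPPED_EFFICIENCY:", dropped),
                          dec$warnings)
      decisions[[length(decisions) + 1L]] <-
        data.frame(sample = s, gene = g, value = dec$value,
                   status = dec$status,
                   warnings = paste(dec$warnings, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  decisions <- do.call(rbind, decisions)

  details <- lapply(stats::setNames(genes, genes), function(g) {
    q <- quants[[g]]
    m <- merge(q, avg, by = c("sample", "dilution"), all.x = TRUE,
               sort = FALSE)
    if (roles[[g]] == "reference") {
      sc <- ref_block$scaled[ref_block$scaled$gene == g,
                             c("sample", "dilution", "scaled_value")]
      m <- merge(m, sc, by = c("sample", "dilution"), all.x = TRUE,
                 sort = FALSE)
    } else {
      m$normalized_value <- m$dilution_corrected / m$ref_average
    }
    m[order(match(m$sample, samples), m$dilution), , drop = FALSE]
  })

  structure(list(decisions = decisions, details = details, curves = curves,
                 ref = c(ref_block, list(extraction_pass = ext_pass,
                                         efficiency_pass = eff_pass,
                                         used = use)),
                 qc = qc, name = exp$name, sample_ids = samples,
                 target_genes = targets, reference_genes = refs),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Quantification result '", x$name, "': ",
      length(x$sample_ids), " samples x ", length(x$target_genes),
      " target gene(s), mode ", x$qc$mode, "\n", sep = "")
  print(table(x$decisions$status))
  invisible(x)
}
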