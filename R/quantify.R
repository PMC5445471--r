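# Copy-number back-calculation, replicate summaries, dilution correction,
# reference-gene scaling/averaging, normalization, and the classic
# delta-delta-Cq comparator.

#' Back-calculate a copy number from a Cq value
#'
#' Inverts the standard-curve line: \code{10^((cq - intercept) / slope)}.
#' Undetected wells (\code{NA}) pass through as \code{NA}.
#'
#' @param cq Numeric vector of Cq values (NA = undetected).
#' @param curve A fitted \code{standard_curve} with negative slope.
#' @return Copy numbers on the scale of the standard quantities.
#' @examples
#' cu <- standard_curve(slope = -1 / log10(2), intercept = 30, cq_loq = 35)
#' copy_number_from_cq(c(30, 26.6781, NA), cu)
#' @export
copy_number_from_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Summarize technical-replicate copy numbers
#'
#' Mean and coefficient of variation over the detected replicates of one
#' sample-dilution. The CV uses the n-1 (sample) standard deviation in
#' percent of the mean, computed on copy numbers, not on Cq. Undetected
#' replicates are excluded; \code{n_detected} reports how many remained.
#'
#' @param copy_numbers Numeric vector of replicate copy numbers
#'   (NA = undetected).
#' @return List with \code{mean}, \code{cv_percent} (NA when fewer than two
#'   detected replicates) and \code{n_detected}.
#' @examples
#' summarize_replicates(c(90, 110))   # mean 100, CV 14.1%
#' @export
summarize_replicates <- function(copy_numbers) {
  v <- copy_numbers[!is.na(copy_numbers)]
  n <- length(v)
  if (n == 0L) return(list(mean = NA_real_, cv_percent = NA_real_,
                           n_detected = 0L))
  m <- mean(v)
  cv <- if (n >= 2L) stats::sd(v) / m * 100 else NA_real_
  list(mean = m, cv_percent = cv, n_detected = n)
}

#' Per-dilution quantification of one gene assay
#'
#' For every (sample, dilution) of the assay: back-calculates replicate
#' copy numbers from the standard curve, averages the detected replicates,
#' computes the replicate CV, and corrects for the sample dilution
#' (\code{mean / rel_quantity}), putting all dilutions of a sample on a
#' common scale.
#'
#' @param assay A \code{gene_assay}.
#' @param curve The gene's fitted \code{standard_curve}.
#' @return Data frame with one row per (sample, dilution): \code{sample},
#'   \code{dilution}, \code{rel_quantity}, \code{mean_cq} (over detected
#'   wells), \code{replicate_copies} (semicolon-joined),
#'   \code{mean_copy_number}, \code{cv_percent}, \code{n_detected},
#'   \code{n_total}, \code{dilution_corrected}.
#' @export
dilution_quants <- function(assay, curve) {
  stopifnot(inherits(assay, "gene_assay"), inherits(curve, "standard_curve"))
  r <- assay$reactions
  key <- unique(r[, c("sample", "dilution")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    rows <- r[r$sample == key$sample[i] & r$dilution == key$dilution[i], ,
              drop = FALSE]
    rq <- unique(rows$rel_quantity)
    if (length(rq) != 1L)
      stop("inconsistent rel_quantity within sample '", key$sample[i],
           "' dilution ", key$dilution[i], " of gene '", assay$gene_id, "'")
    copies <- copy_number_from_cq(rows$cq, curve)
    s <- summarize_replicates(copies)
    data.frame(sample = key$sample[i], dilution = key$dilution[i],
               rel_quantity = rq,
               mean_cq = if (s$n_detected > 0L)
                 mean(rows$cq, na.rm = TRUE) else NA_real_,
               replicate_copies = paste(
                 ifelse(is.na(copies), "", formatC(copies, digits = 6,
                                                   format = "g")),
                 collapse = ";"),
               mean_copy_number = s$mean,
               cv_percent = s$cv_percent,
               n_detected = s$n_detected,
               n_total = nrow(rows),
               dilution_corrected = s$mean / rq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scale reference genes to the first-imported one and average them
#'
#' To give each reference gene equal weight and to keep normalization
#' possible when one reference gene is dropped by QC for a sample, every
#' reference gene is rescaled to the level of the first-imported reference
#' gene before averaging. The scale factor of gene k is the ratio of the
#' across-sample means (first gene / gene k), computed for each dilution
#' separately over the samples where both genes have a value. A sample's
#' reference average is then the arithmetic mean of its available scaled
#' values over the genes admitted for that sample.
#'
#' @param ref_quants Named list (gene id -> \code{\link{dilution_quants}}
#'   data frame), ordered by reference import order (first element is the
#'   scaling anchor).
#' @param use Optional logical matrix \code{[sample x gene]} (dimnames
#'   required) saying which reference genes are admitted for which sample
#'   after QC; defaults to all TRUE. Excluded genes still contribute to the
#'   scale factors (their values exist; they are only dropped from this
#'   sample's average).
#' @return List with \code{averages} (data frame \code{sample},
#'   \code{dilution}, \code{ref_average}, \code{n_genes},
#'   \code{genes_used}), \code{scaled} (long data frame of per-gene scaled
#'   values) and \code{factors} (per gene x dilution).
#' @export
scale_and_average_references <- function(ref_quants, use = NULL) {
  stopifnot(is.list(ref_quants), length(ref_quants) >= 1L,
            !is.null(names(ref_quants)))
  genes <- names(ref_quants)
  first <- ref_quants[[1L]]
  dils <- sort(unique(first$dilution))

  get_val <- function(df, s, d) {
    i <- which(df$sample == s & df$dilution == d)
    if (length(i) == 0L) NA_real_ else df$dilution_corrected[i]
  }
  samples <- unique(first$sample)

  factors <- expand.grid(gene = genes, dilution = dils,
                         stringsAsFactors = FALSE)
  factors$factor <- NA_real_
  scaled <- list()
  for (d in dils) {
    v1 <- vapply(samples, get_val, numeric(1), df = first, d = d)
    for (g in genes) {
      vg <- vapply(samples, get_val, numeric(1), df = ref_quants[[g]], d = d)
      both <- !is.na(v1) & !is.na(vg)
      f <- if (g == genes[1L]) 1
           else if (!any(both)) NA_real_
           else mean(v1[both]) / mean(vg[both])
      factors$factor[factors$gene == g & factors$dilution == d] <- f
      scaled[[length(scaled) + 1L]] <-
        data.frame(gene = g, sample = samples, dilution = d,
                   value = vg, scaled_value = vg * f,
                   stringsAsFactors = FALSE)
    }
  }
  scaled <- do.call(rbind, scaled)

  if (is.null(use)) {
    use <- matrix(TRUE, nrow = length(samples), ncol = length(genes),
                  dimnames = list(samples, genes))
  }
  averages <- list()
  for (s in samples) for (d in dils) {
    rows <- scaled[scaled$sample == s & scaled$dilution == d, , drop = FALSE]
    ok <- !is.na(rows$scaled_value) & use[s, rows$gene]
    averages[[length(averages) + 1L]] <-
      data.frame(sample = s, dilution = d,
                 ref_average = if (any(ok)) mean(rows$scaled_value[ok])
                               else NA_real_,
                 n_genes = sum(ok),
                 genes_used = paste(rows$gene[ok], collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  list(averages = do.call(rbind, averages), scaled = scaled,
       factors = factors)
}

#' Normalize a target to the reference average and combine dilutions
#'
#' Per-dilution normalized value = target dilution-corrected copy number
#' divided by the sample's reference average for that dilution; the final
#' value is the unweighted mean over the supplied dilutions (a single value
#' in one-dilution mode, or when only dilution 1 survived QC).
#'
#' @param target Named numeric vector of the target's dilution-corrected
#'   copy numbers, names = dilution indices.
#' @param ref_average Named numeric vector of reference averages for the
#'   same dilutions.
#' @return List with \code{per_dilution} (named numeric) and \code{value}
#'   (their mean), or value \code{NA} if no dilution is usable.
#' @export
normalize_and_combine <- function(target, ref_average) {
  dils <- intersect(names(target), names(ref_average))
  per <- target[dils] / ref_average[dils]
  per <- per[!is.na(per)]
  list(per_dilution = per,
       value = if (length(per)) mean(per) else NA_real_)
}

#' Classic delta-delta-Cq quantification
#'
#' The comparative-threshold-cycle comparator, assuming equal 100\%
#' amplification efficiencies for target and reference:
#' \code{ratio = 2^-((CqT_s - CqR_s) - (CqT_cal - CqR_cal))}. Used here to
#' compare standard-curve results with the common one-dilution approach.
#'
#' @param target_cqs Named numeric vector: mean target Cq per sample.
#' @param ref_cqs Named numeric vector: mean reference Cq per sample
#'   (same names).
#' @param calibrator_sample Name of the calibrator sample (ratio 1).
#' @return Named numeric vector of per-sample ratios; \code{NA} where a
#'   Cq is missing.
#' @export
ddcq_quantify <- function(target_cqs, ref_cqs, calibrator_sample) {
  target_cqs <- c(target_cqs)  # drop any array dims (e.g. from tapply)
  ref_cqs <- c(ref_cqs)
  stopifnot(calibrator_sample %in% names(target_cqs),
            calibrator_sample %in% names(ref_cqs))
  samples <- names(target_cqs)
  dcq <- target_cqs - ref_cqs[samples]
  ddcq <- dcq - (target_cqs[[calibrator_sample]] -
                   ref_cqs[[calibrator_sample]])
  out <- 2^(-ddcq)
  names(out) <- samples
  out
}
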