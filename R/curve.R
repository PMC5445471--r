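# Standard-curve regression, amplification efficiency, quantification range.

#' Fit a standard curve by ordinary least squares
#'
#' Regresses Cq on log10(quantity) over the included standard points.
#' Replicate standard wells enter as individual points, so replicate
#' scatter is reflected in the R-squared. The slope of a usable assay is
#' negative; 100\% amplification efficiency (template doubling each cycle)
#' corresponds to a slope of -1/log10(2), about -3.32 cycles per ten-fold
#' dilution.
#'
#' @param points Data frame with columns \code{quantity} (> 0), \code{cq},
#'   and optionally \code{included} (logical; defaults to all TRUE).
#' @param cq_loq_override User-supplied Cq at the limit of quantification;
#'   when \code{NULL} it is estimated from the most-diluted included
#'   standard level (see \code{\link{estimate_cq_loq}}).
#' @return An object of class \code{standard_curve}: \code{slope},
#'   \code{intercept} (Cq at quantity 1), \code{r_squared},
#'   \code{efficiency_percent}, \code{n_points_used}, \code{cq_loq}, and
#'   the \code{points} used.
#' @examples
#' std <- data.frame(quantity = 10^(0:-3), cq = c(20, 23.3219, 26.6439, 29.9658))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(points, cq_loq_override = NULL) {
  stopifnot(is.data.frame(points),
            all(c("quantity", "cq") %in% names(points)))
  if (is.null(points$included)) points$included <- TRUE
  use <- points$included & !is.na(points$cq) & points$quantity > 0
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) < 2L || length(unique(pts$quantity)) < 2L)
    stop("standard curve unfittable: need >= 2 included points with >= 2 distinct quantities")
  fit <- stats::lm(cq ~ I(log10(quantity)), data = pts)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # noise-free standards give a numerically perfect fit; the summary.lm
  # warning about it is expected and uninformative here
  r2 <- if (length(unique(pts$cq)) == 1L) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope,
                 intercept = intercept,
                 r_squared = r2,
                 efficiency_percent = efficiency_from_slope(slope),
                 n_points_used = nrow(pts),
                 cq_loq = estimate_cq_loq(points, override = cq_loq_override),
                 points = points),
            class = "standard_curve")
}

#' Construct a standard curve from known parameters
#'
#' Useful when curve parameters come from a previous in-house validation
#' rather than from points in the current experiment.
#'
#' @param slope Cycles per log10(quantity) (negative for a valid assay).
#' @param intercept Cq at quantity 1.
#' @param cq_loq Cq at the limit of quantification.
#' @param r_squared,n_points_used Optional bookkeeping fields.
#' @return A \code{standard_curve} object.
#' @export
standard_curve <- function(slope, intercept, cq_loq,
                           r_squared = NA_real_, n_points_used = NA_integer_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency_percent = efficiency_from_slope(slope),
                 n_points_used = n_points_used,
                 cq_loq = cq_loq, points = NULL),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Cq = %.4f %+.4f * log10(quantity)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.1f%%, R^2 %s, %s point(s), Cq(LOQ) %.4g\n",
              x$efficiency_percent,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              ifelse(is.na(x$n_points_used), "?", x$n_points_used),
              x$cq_loq))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' Efficiency is the fraction of template molecules copied per PCR cycle,
#' in percent: \code{(10^(-1/slope) - 1) * 100}. A slope of -1/log10(2)
#' gives exactly 100\% (doubling per cycle).
#'
#' @param slope Standard-curve slope (cycles per log10 quantity), non-zero.
#' @return Efficiency in percent. A non-negative slope describes a
#'   non-amplifying curve; the formula is still evaluated but a warning is
#'   raised.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) stop("efficiency undefined for slope 0")
  if (any(slope > 0))
    warning("non-negative slope: amplification efficiency undefined ",
            "for a non-amplifying curve")
  (10^(-1 / slope) - 1) * 100
}

#' Standard-curve slope implied by an amplification efficiency
#'
#' Inverse of \code{\link{efficiency_from_slope}}:
#' \code{slope = -1/log10(1 + E/100)}.
#'
#' @param efficiency_percent Efficiency in percent (> 0).
#' @return The slope in cycles per log10(quantity).
#' @export
slope_from_efficiency <- function(efficiency_percent) {
  stopifnot(all(efficiency_percent > 0))
  -1 / log10(1 + efficiency_percent / 100)
}

#' Estimate the Cq at the limit of quantification
#'
#' Default estimate from the experiment's standard curve: the mean Cq of
#' the most-diluted included standard level (beyond it, quantification is
#' unverified by the standards). A user override always takes precedence.
#'
#' @param points Standard points data frame (\code{quantity}, \code{cq},
#'   optional \code{included}).
#' @param override Optional user-supplied Cq(LOQ).
#' @return Cq at the LOQ, in cycles.
#' @export
estimate_cq_loq <- function(points, override = NULL) {
  if (!is.null(override) && !is.na(override)) return(as.numeric(override))
  if (is.null(points$included)) points$included <- TRUE
  use <- points$included & !is.na(points$cq)
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no included standard points to estimate Cq(LOQ)")
  qmin <- min(pts$quantity)
  mean(pts$cq[pts$quantity == qmin])
}

#' Flag suspect standard-curve reactions
#'
#' Highlights, without removing, standard wells the user should review:
#' \code{PIPETTING} when a replicate's Cq deviates from the mean of the
#' other replicates at its dilution level by more than
#' \code{qc$std_replicate_dev_max}, and
#' \code{OUT_OF_RANGE} when a level's mean Cq lies beyond the Cq(LOQ)
#' (outside the quantification range). Exclusion of flagged points is a
#' user decision, applied by setting \code{included = FALSE} and refitting.
#'
#' @param points Standard points data frame.
#' @param curve The fitted \code{standard_curve}.
#' @param qc \code{\link{qc_settings}} (uses \code{std_replicate_dev_max}).
#' @return Character vector, one element per row of \code{points}:
#'   semicolon-joined flags, or \code{""} when the point is unremarkable.
#' @export
flag_standard_outliers <- function(points, curve, qc = qc_settings()) {
  stopifnot(inherits(curve, "standard_curve"))
  n <- nrow(points)
  flags <- character(n)
  level_mean <- tapply(points$cq, points$quantity, mean, na.rm = TRUE)
  for (i in seq_len(n)) {
    f <- character()
    key <- as.character(points$quantity[i])
    lm_i <- level_mean[[key]]
    peers <- points$cq[setdiff(which(points$quantity == points$quantity[i]), i)]
    if (!is.na(points$cq[i]) && length(peers) > 0L &&
        abs(points$cq[i] - mean(peers, na.rm = TRUE)) >
          qc$std_replicate_dev_max)
      f <- c(f, "PIPETTING")
    if (!is.na(lm_i) && lm_i > curve$cq_loq)
      f <- c(f, "OUT_OF_RANGE")
    flags[i] <- paste(f, collapse = ";")
  }
  flags
}
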