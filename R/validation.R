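#' Fit a calibration line by least squares
#'
#' Ordinary (optionally 1/x or 1/x^2 weighted) least-squares regression of
#' detector signal (peak area) on standard concentration. The residual
#' standard deviation of the low-concentration calibration line is the
#' usual sigma for LOD/LOQ estimation.
#'
#' @param conc standard concentrations (ug/mL), >= 3 distinct levels
#'   (2 points fit an exact interpolating line).
#' @param signal measured responses (peak area, arbitrary units).
#' @param weighting \code{"none"} (default), \code{"1/x"} or \code{"1/x2"}.
#' @return an object of class \code{calibration_fit}: \code{slope},
#'   \code{intercept}, \code{r.squared}, \code{sigma} (residual SD),
#'   \code{response_factors} (signal/concentration per point) and the data.
#' @examples
#' cal <- fit_calibration(c(0.1, 0.4, 0.8, 1.6, 2), c(0.52, 2.1, 4.0, 8.1, 9.9))
#' coef(cal)
#' @export
fit_calibration <- function(conc, signal, weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(conc), is.numeric(signal),
            length(conc) == length(signal))
  if (length(unique(conc)) < 2L)
    stop("all concentrations identical: calibration design is degenerate",
         call. = FALSE)
  w <- switch(weighting, none = NULL, `1/x` = 1 / conc, `1/x2` = 1 / conc^2)
  fit <- stats::lm(signal ~ conc, weights = w)
  res <- stats::residuals(fit)
  dfr <- stats::df.residual(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r.squared = suppressWarnings(summary(fit)$r.squared),
    sigma = if (dfr > 0) sqrt(sum(res^2) / dfr) else 0,
    response_factors = signal / conc,
    conc = conc, signal = signal, weighting = weighting, lm = fit),
    class = "calibration_fit")
}

#' @export
coef.calibration_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$conc else as.numeric(newdata)
  object$intercept + object$slope * conc
}

#' Back-calculate concentration from signal
#'
#' @param object a \code{calibration_fit}.
#' @param signal measured responses.
#' @return estimated concentrations (ug/mL).
#' @export
invert_calibration <- function(object, signal) {
  stopifnot(inherits(object, "calibration_fit"))
  (as.numeric(signal) - object$intercept) / object$slope
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration (%d points, weighting %s): signal = %.6g + %.6g * conc\n",
    length(x$conc), x$weighting, x$intercept, x$slope))
  cat(sprintf("R-squared %.6f, residual SD %.4g\n", x$r.squared, x$sigma))
  invisible(x)
}

#' @export
residuals.calibration_fit <- function(object, ...)
  object$signal - predict(object)

#' @export
plot.calibration_fit <- function(x, ...) {
  graphics::plot(x$conc, x$signal, xlab = "Concentration (ug/mL)",
                 ylab = "Signal (area)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Limits of detection and quantitation
#'
#' LOD = 3.3 sigma / S and LOQ = 10 sigma / S, where sigma is a standard
#' deviation of the response (by default the residual SD of a
#' low-concentration calibration line) and S the calibration slope. Their
#' ratio is always 10/3.3.
#'
#' @param sigma response-unit standard deviation (>= 0), or a
#'   \code{calibration_fit} whose residual SD and slope are used.
#' @param slope calibration slope S in response units per ug/mL (> 0);
#'   ignored when \code{sigma} is a fit.
#' @return named vector \code{c(lod, loq)} in ug/mL.
#' @export
lod_loq <- function(sigma, slope = NULL) {
  if (inherits(sigma, "calibration_fit")) {
    slope <- sigma$slope
    sigma <- sigma$sigma
  }
  stopifnot(is.numeric(sigma), is.numeric(slope))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  c(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Relative standard deviation of replicate measurements
#'
#' %RSD = 100 * SD / mean, with the sample (n - 1) standard deviation.
#'
#' @param x >= 2 replicate observations with positive mean.
#' @return the percent relative standard deviation.
#' @export
precision_rsd <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(x)
  if (m <= 0) stop("mean must be positive for %RSD", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Percent accuracy of an observed concentration
#'
#' % accuracy = 100 * observed / nominal.
#'
#' @param observed observed (mean) concentration, ug/mL.
#' @param nominal nominal spiked concentration, ug/mL (> 0).
#' @return percent accuracy (100 = perfect recovery).
#' @export
accuracy_pct <- function(observed, nominal) {
  stopifnot(is.numeric(observed), is.numeric(nominal))
  if (any(nominal <= 0)) stop("nominal concentration must be positive",
                              call. = FALSE)
  100 * observed / nominal
}

#' Stability accuracy of a stored QC sample
#'
#' Same ratio as [accuracy_pct()], applied to a measured stability sample
#' against its spiked concentration.
#'
#' @param measured measured concentration after storage (ug/mL).
#' @param spiked spiked nominal concentration (ug/mL).
#' @return percent accuracy.
#' @export
stability_accuracy <- function(measured, spiked) accuracy_pct(measured, spiked)

#' Precision/accuracy acceptance check for a QC level
#'
#' Bioanalytical acceptance: %RSD and absolute accuracy bias may not
#' exceed 15%, relaxed to 20% at the lower limit of quantitation.
#'
#' @param replicates observed concentrations at one nominal level.
#' @param nominal nominal concentration (ug/mL).
#' @param is_lloq is this the LLOQ level?
#' @return list with \code{pass}, \code{rsd}, \code{accuracy},
#'   \code{threshold} and \code{reasons} (character, empty on pass).
#' @export
acceptance_check <- function(replicates, nominal, is_lloq = FALSE) {
  thr <- if (is_lloq) 20 else 15
  rsd <- precision_rsd(replicates)
  acc <- accuracy_pct(mean(replicates), nominal)
  reasons <- character()
  if (rsd > thr)
    reasons <- c(reasons, sprintf("%%RSD %.2f exceeds %d%%", rsd, thr))
  if (abs(100 - acc) > thr)
    reasons <- c(reasons, sprintf("accuracy bias %.2f%% exceeds %d%%",
                                  abs(100 - acc), thr))
  list(pass = !length(reasons), rsd = rsd, accuracy = acc,
       threshold = thr, reasons = reasons)
}

#' Chromatographic system-suitability metrics
#'
#' From peak descriptors computes the capacity factor
#' k' = (tR - t0)/t0, theoretical plate number by the base-width formula
#' N = 16 (tR/w)^2 and the half-height formula N = 5.54 (tR/w50)^2, the
#' USP tailing factor T = w05 / (2 f) (widths at 5% height), and, when a
#' second peak is supplied, the resolution
#' Rs = 2 (tR2 - tR1) / (w1 + w2) from base widths.
#'
#' @param peak named list or one-row data.frame with fields \code{tr}
#'   (retention time, min), \code{w_base}, \code{w_half}, \code{w_05}
#'   (widths at base, half height and 5% height, min), \code{f_05}
#'   (leading half-width at 5% height, min) and \code{t0} (void time,
#'   min). Fields irrelevant to a metric may be NA; that metric is
#'   returned as NA.
#' @param reference optional second peak (same fields) for resolution;
#'   omitted, Rs is not reported.
#' @return named list: \code{k_prime}, \code{n_base}, \code{n_half},
#'   \code{tailing}, and \code{rs} when a reference peak is given.
#' @export
system_suitability <- function(peak, reference = NULL) {
  peak <- as.list(peak)
  num <- function(nm) if (is.null(peak[[nm]])) NA_real_ else as.numeric(peak[[nm]])
  tr <- num("tr"); t0 <- num("t0")
  w <- num("w_base"); wh <- num("w_half"); w5 <- num("w_05"); f <- num("f_05")
  if (!is.na(tr) && tr <= 0) stop("retention time must be positive", call. = FALSE)
  if (!is.na(t0) && t0 <= 0) stop("void time t0 must be positive", call. = FALSE)
  if (!is.na(f) && !is.na(w5) && f > w5 + 1e-12)
    stop("leading half-width cannot exceed the full 5%-height width",
         call. = FALSE)
  out <- list(
    k_prime = if (!is.na(t0)) (tr - t0) / t0 else NA_real_,
    n_base = if (!is.na(w)) 16 * (tr / w)^2 else NA_real_,
    n_half = if (!is.na(wh)) 5.54 * (tr / wh)^2 else NA_real_,
    tailing = if (!is.na(w5) && !is.na(f)) w5 / (2 * f) else NA_real_)
  if (!is.null(reference)) {
    ref <- as.list(reference)
    out$rs <- 2 * abs(as.numeric(ref$tr) - tr) /
      (w + as.numeric(ref$w_base))
  }
  out
}

#' Assemble an analytical-method validation report
#'
#' Bundles calibration linearity, LOD/LOQ and per-level QC precision /
#' accuracy with pass flags into one printable object.
#'
#' @param calibration a [fit_calibration()] result for the working range.
#' @param lod_calibration optional low-concentration calibration fit used
#'   for sigma and slope in LOD/LOQ (defaults to \code{calibration}).
#' @param qc named list: each element a list with \code{nominal} and
#'   \code{replicates}; the element named by \code{lloq_level} (matched on
#'   nominal) uses the 20% threshold.
#' @param lloq_level nominal concentration treated as LLOQ (optional).
#' @return object of class \code{validation_report}.
#' @export
validation_report <- function(calibration, qc = list(),
                              lod_calibration = NULL, lloq_level = NA) {
  stopifnot(inherits(calibration, "calibration_fit"))
  lims <- lod_loq(lod_calibration %||% calibration)
  rows <- lapply(qc, function(q) {
    is_lloq <- !is.na(lloq_level) && isTRUE(all.equal(q$nominal, lloq_level))
    chk <- acceptance_check(q$replicates, q$nominal, is_lloq)
    data.frame(nominal = q$nominal, n = length(q$replicates),
               mean = mean(q$replicates), sd = stats::sd(q$replicates),
               rsd_pct = chk$rsd, accuracy_pct = chk$accuracy,
               lloq = is_lloq, pass = chk$pass)
  })
  structure(list(calibration = calibration, lod = unname(lims["lod"]),
                 loq = unname(lims["loq"]),
                 qc = if (length(rows)) do.call(rbind, rows) else NULL),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Analytical method validation report\n")
  cat(sprintf("Calibration: slope %.6g, intercept %.6g, R2 %.6f\n",
              x$calibration$slope, x$calibration$intercept,
              x$calibration$r.squared))
  cat(sprintf("LOD %.4g ug/mL, LOQ %.4g ug/mL (3.3 / 10 sigma/S)\n",
              x$lod, x$loq))
  if (!is.null(x$qc)) {
    cat("QC levels:\n")
    print(format(x$qc, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.list.validation_report <- function(x, ...) {
  list(calibration = list(slope = x$calibration$slope,
                          intercept = x$calibration$intercept,
                          r_squared = x$calibration$r.squared,
                          sigma = x$calibration$sigma),
       lod = x$lod, loq = x$loq,
       qc = if (!is.null(x$qc)) as.list(x$qc))
}
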