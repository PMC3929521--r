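#' Encapsulation efficiency of a nanoparticle batch
#'
#' EE% = 100 * (drug added - free drug in supernatant) / drug added. The
#' loaded amount is inferred by difference: whatever is not recovered free
#' in the supernatant is taken as encapsulated.
#'
#' @param added drug added during nanoparticle preparation (mg, > 0).
#' @param free free drug measured in the supernatant (mg, >= 0).
#' @return percent encapsulation efficiency in [0, 100].
#' @examples
#' encapsulation_efficiency(100, 25.66)  # 74.34
#' @export
encapsulation_efficiency <- function(added, free) {
  stopifnot(is.numeric(added), is.numeric(free))
  if (any(added <= 0)) stop("drug added must be positive", call. = FALSE)
  if (any(free < 0)) stop("free drug cannot be negative", call. = FALSE)
  if (any(free > added))
    stop("free drug exceeds drug added: mass balance violated", call. = FALSE)
  100 * (added - free) / added
}

#' Drug loading of recovered nanoparticles
#'
#' DL% = 100 * drug weight in nanoparticles / nanoparticle weight recovered.
#'
#' @param drug_in_np drug weight in the recovered nanoparticles (mg, >= 0).
#' @param np_weight nanoparticle weight recovered (mg, > 0).
#' @return percent drug loading.
#' @export
drug_loading <- function(drug_in_np, np_weight) {
  stopifnot(is.numeric(drug_in_np), is.numeric(np_weight))
  if (any(np_weight <= 0)) stop("nanoparticle weight must be positive",
                                call. = FALSE)
  if (any(drug_in_np < 0)) stop("drug weight cannot be negative", call. = FALSE)
  100 * drug_in_np / np_weight
}

#' Construct a dissolution release profile
#'
#' Stores sampled aliquot concentrations together with the sampling
#' protocol (medium volume, aliquot volume replaced with fresh buffer,
#' dose in the device) needed for the mass-balance correction.
#'
#' @param time sample times, strictly increasing, first >= 0.
#' @param conc aliquot concentrations at each time (ug/mL), or
#'   already-cumulative percent released when \code{percent = TRUE}.
#' @param medium_volume dissolution medium volume (mL).
#' @param aliquot_volume volume withdrawn and replaced per sample (mL);
#'   0 means non-destructive sampling.
#' @param dose drug dose in the device (mg).
#' @param time_unit "days" or "hours" (carried, never converted silently).
#' @param percent is \code{conc} already cumulative percent released?
#' @return object of class \code{release_profile}.
#' @export
release_profile <- function(time, conc, medium_volume, aliquot_volume = 0,
                            dose, time_unit = c("days", "hours"),
                            percent = FALSE) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(time), is.numeric(conc), length(time) == length(conc))
  if (any(diff(time) <= 0) || time[1] < 0)
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  if (medium_volume <= 0 || aliquot_volume < 0)
    stop("volumes must be positive (aliquot >= 0)", call. = FALSE)
  if (aliquot_volume >= medium_volume)
    stop("aliquot volume must be smaller than the medium volume", call. = FALSE)
  if (!percent && dose <= 0) stop("dose must be positive", call. = FALSE)
  structure(list(time = time, conc = conc, medium_volume = medium_volume,
                 aliquot_volume = aliquot_volume, dose = dose,
                 time_unit = time_unit, percent = percent),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf(
    "Release profile: %d samples over %g %s; medium %g mL, aliquot %g mL\n",
    length(x$time), max(x$time), x$time_unit, x$medium_volume,
    x$aliquot_volume))
  invisible(x)
}

#' Sampling-corrected cumulative release
#'
#' When each sample withdraws an aliquot that is replaced with fresh
#' buffer, the measured concentration at time n understates the cumulative
#' amount released. The standard additive correction
#' \deqn{C_n^{corr} = C_n + \frac{V_a}{V_m} \sum_{i<n} C_i}
#' restores the mass removed in earlier aliquots before conversion of mass
#' to percent of dose. With aliquot volume 0 this reduces to naive
#' scaling. Profiles already expressed in percent are returned unchanged.
#'
#' @param profile a [release_profile()].
#' @param tolerance percent overshoot above 100 tolerated before a
#'   mass-balance warning is raised.
#' @return data.frame with \code{time}, \code{conc}, \code{conc_corrected}
#'   and cumulative \code{release_pct}; attribute \code{mass_balance_warning}
#'   flags release above 100% + tolerance.
#' @export
cumulative_release <- function(profile, tolerance = 2) {
  stopifnot(inherits(profile, "release_profile"))
  if (profile$percent) {
    out <- data.frame(time = profile$time, conc = NA_real_,
                      conc_corrected = NA_real_, release_pct = profile$conc)
    attr(out, "mass_balance_warning") <- any(profile$conc > 100 + tolerance)
    return(out)
  }
  cn <- profile$conc
  prior <- c(0, cumsum(cn)[-length(cn)])
  corr <- cn + (profile$aliquot_volume / profile$medium_volume) * prior
  # ug/mL * mL = ug; dose in mg
  pct <- 100 * corr * profile$medium_volume / (profile$dose * 1000)
  warn <- any(pct > 100 + tolerance)
  if (warn) warning("corrected cumulative release exceeds 100%: check mass balance")
  out <- data.frame(time = profile$time, conc = cn, conc_corrected = corr,
                    release_pct = pct)
  attr(out, "mass_balance_warning") <- warn
  out
}

#' Fit a drug-release kinetics model
#'
#' Fits one of the classical linearized release models by least squares:
#' zero order (Q = Q0 + k0 t), first order (ln(100 - Q) linear in t, rate
#' k1) or Higuchi (Q linear in sqrt(t), rate kH). The zero-order fit keeps
#' a free intercept by default so an initial burst appears as Q0 > 0; it
#' can be forced through the origin.
#'
#' @param time sample times (>= 3 points).
#' @param release cumulative percent released at each time.
#' @param model \code{"zero"}, \code{"first"} or \code{"higuchi"}.
#' @param intercept keep a free intercept (burst term)? Zero-order only.
#' @return object of class \code{release_fit}: \code{model}, \code{k}
#'   (rate constant in %/time, 1/time or %/sqrt(time)), \code{intercept},
#'   \code{r.squared} (of the linearizing regression), and the data used.
#'   Points with a non-finite transform (Q >= 100 under first order) are
#'   dropped with a warning.
#' @examples
#' t <- 0:10
#' fit_release(t, 5 * t, "zero")     # k0 = 5, R2 = 1
#' @export
fit_release <- function(time, release, model = c("zero", "first", "higuchi"),
                        intercept = TRUE) {
  model <- match.arg(model)
  stopifnot(is.numeric(time), is.numeric(release),
            length(time) == length(release))
  tx <- switch(model, zero = time, first = time, higuchi = sqrt(time))
  ty <- switch(model, zero = release, higuchi = release,
               first = suppressWarnings(log(100 - release)))
  ok <- is.finite(tx) & is.finite(ty)
  if (any(!ok)) {
    warning(sprintf("%d point(s) excluded: non-finite under the %s transform",
                    sum(!ok), model))
    tx <- tx[ok]; ty <- ty[ok]
  }
  if (length(tx) < 3L) stop("need at least 3 usable points", call. = FALSE)
  fit <- if (intercept || model != "zero") stats::lm(ty ~ tx)
  else stats::lm(ty ~ tx - 1)
  cf <- stats::coef(fit)
  slope <- unname(cf[length(cf)])
  icpt <- if (length(cf) == 2L) unname(cf[1]) else 0
  k <- switch(model, zero = slope, higuchi = slope, first = -slope)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(model = model, k = k, intercept = icpt, r.squared = r2,
                 time = time[ok], release = release[ok], lm = fit),
            class = "release_fit")
}

#' @export
coef.release_fit <- function(object, ...)
  c(intercept = object$intercept, k = object$k)

#' @export
print.release_fit <- function(x, ...) {
  unit <- switch(x$model, zero = "%/time", first = "1/time",
                 higuchi = "%/sqrt(time)")
  cat(sprintf("%s-order release fit: k = %.4g %s, intercept %.4g, R2 = %.4f\n",
              switch(x$model, zero = "Zero", first = "First",
                     higuchi = "Higuchi"),
              x$k, unit, x$intercept, x$r.squared))
  invisible(x)
}

#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else as.numeric(newdata)
  switch(object$model,
         zero = object$intercept + object$k * t,
         higuchi = object$intercept + object$k * sqrt(t),
         first = 100 - exp(object$intercept - object$k * t))
}

#' @export
residuals.release_fit <- function(object, ...)
  object$release - predict(object)

#' @export
plot.release_fit <- function(x, ...) {
  graphics::plot(x$time, x$release, xlab = "Time", ylab = "Cumulative release (%)",
                 ...)
  tt <- seq(min(x$time), max(x$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}
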