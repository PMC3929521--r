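#' Simulate responses from a known quadratic surface
#'
#' Evaluates the full second-order polynomial with the supplied
#' coefficients at the coded design points and adds i.i.d. Gaussian noise.
#' With \code{noise_sd = 0} the surface is returned exactly, so refitting
#' recovers the coefficients to floating tolerance.
#'
#' @param coefs coefficient vector in model-matrix order (b0, linear,
#'   interactions i<j, quadratics); length must be 1 + 2k + k(k-1)/2.
#' @param design a \code{design_table} or matrix of coded points.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed optional seed (applied locally, global RNG untouched).
#' @return numeric response vector with attribute \code{truth} carrying
#'   the generating coefficients and noise level.
#' @export
simulate_rsm_response <- function(coefs, design, noise_sd = 0, seed = NULL) {
  x <- design_matrix(design)
  X <- rsm_model_matrix(x)
  if (length(coefs) != ncol(X))
    stop(sprintf("coefficient vector has length %d; design with %d factors needs %d",
                 length(coefs), ncol(x), ncol(X)), call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  mu <- drop(X %*% coefs)
  y <- if (noise_sd == 0) mu else {
    gen <- function() mu + stats::rnorm(length(mu), 0, noise_sd)
    if (is.null(seed)) gen() else withr_seed(seed, gen())
  }
  names(coefs) <- colnames(X)
  attr(y, "truth") <- list(coefficients = coefs, noise_sd = noise_sd)
  y
}

#' Simulate one-compartment oral-absorption plasma profiles
#'
#' Bateman model,
#' \deqn{C(t) = \frac{D k_a}{(V/F)(k_a - k_e)}(e^{-k_e t} - e^{-k_a t})}
#' sampled at the supplied times, with multiplicative log-normal noise
#' (so simulated concentrations stay non-negative) of the requested
#' coefficient of variation.
#'
#' @param ka absorption rate constant (1/h), > 0, != ke.
#' @param ke elimination rate constant (1/h), > 0.
#' @param v_over_f apparent volume of distribution V/F (L).
#' @param dose administered dose (mg; concentrations come out in mg/L =
#'   ug/mL).
#' @param times sampling times (h).
#' @param cv noise coefficient of variation (0 = noise-free).
#' @param n_subjects number of subjects.
#' @param seed optional seed (applied locally).
#' @return data.frame with columns \code{subject}, \code{time},
#'   \code{conc}; attribute \code{truth} holds the parameters and the
#'   analytic tmax, Cmax and AUC0-inf.
#' @export
simulate_oral_pk <- function(ka, ke, v_over_f, dose, times,
                             cv = 0, n_subjects = 1L, seed = NULL) {
  stopifnot(ka > 0, ke > 0, v_over_f > 0, dose > 0, cv >= 0)
  if (abs(ka - ke) < 1e-12)
    stop("ka = ke is the degenerate flip-flop case; perturb one rate",
         call. = FALSE)
  mu <- dose * ka / (v_over_f * (ka - ke)) * (exp(-ke * times) - exp(-ka * times))
  mu <- pmax(mu, 0)
  gen <- function() {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      conc <- if (cv == 0) mu else {
        sdlog <- sqrt(log(1 + cv^2))
        mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      }
      data.frame(subject = s, time = times, conc = conc)
    }))
  }
  out <- if (is.null(seed)) gen() else withr_seed(seed, gen())
  tmax <- log(ka / ke) / (ka - ke)
  attr(out, "truth") <- list(
    ka = ka, ke = ke, v_over_f = v_over_f, dose = dose, cv = cv,
    tmax = tmax,
    cmax = dose * ka / (v_over_f * (ka - ke)) *
      (exp(-ke * tmax) - exp(-ka * tmax)),
    auc_inf = dose / (v_over_f * ke))
  out
}

#' Simulate a burst plus zero-order release profile
#'
#' Cumulative release
#' \deqn{Q(t) = B (1 - e^{-r t}) + k_0 t}
#' capped at 100%, with additive Gaussian noise. The defaults reproduce a
#' sustained-release nanoparticle study: a 15% burst essentially complete
#' within the first day (burst rate 5/day) followed by a constant phase
#' reaching about 80% cumulative release at day 15.
#'
#' @param burst burst magnitude (% of dose).
#' @param k0 zero-order rate (%/day); default (80 - 15)/15 so that
#'   Q(15) is about 80%.
#' @param burst_rate first-order burst rate (1/day).
#' @param times sampling days.
#' @param noise_sd additive Gaussian noise SD (percentage points).
#' @param seed optional seed (applied locally).
#' @return a [release_profile()] (percent units) with attribute
#'   \code{truth} carrying the generating parameters.
#' @export
simulate_release <- function(burst = 15, k0 = (80 - 15) / 15, burst_rate = 5,
                             times = 0:15, noise_sd = 0, seed = NULL) {
  stopifnot(burst >= 0, k0 >= 0, burst_rate > 0, noise_sd >= 0)
  if (burst + k0 * max(times) > 100)
    stop("parameters imply release above 100%", call. = FALSE)
  q <- burst * (1 - exp(-burst_rate * times)) + k0 * times
  if (noise_sd > 0) {
    gen <- function() q + stats::rnorm(length(q), 0, noise_sd)
    q <- if (is.null(seed)) gen() else withr_seed(seed, gen())
  }
  q <- pmin(pmax(q, 0), 100)
  prof <- release_profile(time = times, conc = q,
                          medium_volume = 200, aliquot_volume = 0,
                          dose = 200, time_unit = "days", percent = TRUE)
  attr(prof, "truth") <- list(burst = burst, k0 = k0,
                              burst_rate = burst_rate, noise_sd = noise_sd)
  prof
}

emg_height <- function(t, tr, sigma, tau) {
  if (tau <= 0) return(exp(-(t - tr)^2 / (2 * sigma^2)))
  z <- (sigma / tau - (t - tr) / sigma) / sqrt(2)
  # scaled so the tau -> 0 limit has unit height
  (sigma / tau) * sqrt(pi / 2) *
    exp(0.5 * (sigma / tau)^2 - (t - tr) / tau) * pracma::erfc(z)
}

peak_descriptors <- function(tr, sigma, tau, t0) {
  if (tau <= 0) {
    # exact Gaussian widths
    w_half <- 2 * sigma * sqrt(2 * log(2))
    w_05 <- 2 * sigma * sqrt(2 * log(20))
    return(list(tr = tr, w_base = 4 * sigma, w_half = w_half,
                w_05 = w_05, f_05 = w_05 / 2, t0 = t0))
  }
  lo <- tr - 8 * sigma
  hi <- tr + 8 * sigma + 12 * tau
  opt <- stats::optimize(function(t) emg_height(t, tr, sigma, tau),
                         c(lo, hi), maximum = TRUE)
  apex <- opt$maximum; hmax <- opt$objective
  cross <- function(frac) {
    f <- function(t) emg_height(t, tr, sigma, tau) - frac * hmax
    left <- stats::uniroot(f, c(lo, apex), tol = 1e-10)$root
    right <- stats::uniroot(f, c(apex, hi + 40 * tau), tol = 1e-10)$root
    c(left, right)
  }
  h50 <- cross(0.5); h05 <- cross(0.05); hb <- cross(exp(-2))
  list(tr = apex, w_base = diff(hb) * 2, w_half = diff(h50),
       w_05 = diff(h05), f_05 = apex - h05[1], t0 = t0)
}

#' Simulate a chromatogram of exponentially modified Gaussian peaks
#'
#' Each peak is an exponentially modified Gaussian (EMG) with retention
#' time \code{tr}, Gaussian width \code{sigma} and exponential tailing
#' constant \code{tau}; \code{tau = 0} gives a symmetric Gaussian whose
#' tailing factor is exactly 1. Peak descriptors (apex time, widths at
#' half and 5% height, leading half-width, base width) are derived from
#' the analytic peak shape by root finding, not from the sampled trace,
#' so they feed [system_suitability()] without integration error.
#'
#' @param peaks data.frame (or list of lists) with columns \code{tr}
#'   (min), \code{height}, \code{sigma} (min) and \code{tau} (min, >= 0).
#' @param t0 void time (min) stamped onto each peak record.
#' @param baseline_sd additive baseline noise SD on the trace.
#' @param dt trace sampling interval (min).
#' @param seed optional seed for the baseline noise (applied locally).
#' @return list with \code{trace} (data.frame time, signal) and
#'   \code{peaks} (list of descriptor lists consumable by
#'   [system_suitability()]).
#' @export
simulate_chromatogram <- function(peaks, t0 = 0.9, baseline_sd = 0,
                                  dt = 0.005, seed = NULL) {
  if (is.data.frame(peaks)) peaks <- split(peaks, seq_len(nrow(peaks)))
  peaks <- lapply(peaks, as.list)
  for (p in peaks)
    if (p$tr <= 0 || p$sigma <= 0 || p$height <= 0 || p$tau < 0)
      stop("peak parameters must be positive (tau >= 0)", call. = FALSE)
  tmax <- max(vapply(peaks, function(p) p$tr + 8 * p$sigma + 12 * p$tau,
                     numeric(1)))
  tt <- seq(0, tmax, by = dt)
  sig <- Reduce(`+`, lapply(peaks, function(p)
    p$height * emg_height(tt, p$tr, p$sigma, p$tau)))
  if (baseline_sd > 0) {
    gen <- function() sig + stats::rnorm(length(sig), 0, baseline_sd)
    sig <- if (is.null(seed)) gen() else withr_seed(seed, gen())
  }
  desc <- lapply(peaks, function(p)
    peak_descriptors(p$tr, p$sigma, p$tau, t0))
  list(trace = data.frame(time = tt, signal = sig), peaks = desc)
}

#' Simulate calibration-curve data
#'
#' Linear detector response signal = slope * conc + intercept + Gaussian
#' noise, sampled at the standard working-range schedule (eight levels,
#' 0.040-2.0 ug/mL) by default.
#'
#' @param slope true slope (area per ug/mL).
#' @param intercept true intercept.
#' @param levels standard concentrations (ug/mL), positive and distinct.
#' @param noise_sd additive Gaussian noise SD (area units).
#' @param seed optional seed (applied locally).
#' @return data.frame \code{conc}, \code{signal} with attribute
#'   \code{truth}.
#' @export
simulate_calibration <- function(slope, intercept = 0,
                                 levels = c(0.040, 0.1, 0.2, 0.4, 0.8, 1.2,
                                            1.6, 2.0),
                                 noise_sd = 0, seed = NULL) {
  stopifnot(all(levels > 0), !anyDuplicated(levels), noise_sd >= 0)
  mu <- slope * levels + intercept
  sig <- if (noise_sd == 0) mu else {
    gen <- function() mu + stats::rnorm(length(mu), 0, noise_sd)
    if (is.null(seed)) gen() else withr_seed(seed, gen())
  }
  out <- data.frame(conc = levels, signal = sig)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}
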