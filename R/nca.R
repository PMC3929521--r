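trapz_auc <- function(t, c) sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2)

#' Non-compartmental analysis of a concentration-time profile
#'
#' Standard NCA: Cmax and tmax by direct maximum (earliest time on ties);
#' the terminal rate constant lambda-z by least-squares regression of
#' log concentration on time over a terminal window; AUC and AUMC by the
#' linear trapezoidal rule with the usual tail extrapolation
#' \deqn{AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z}
#' \deqn{AUMC_{0-\infty} = AUMC_{0-t} + C_{last} t_{last}/\lambda_z +
#'       C_{last}/\lambda_z^2}
#' plus t1/2 = ln 2 / lambda-z and MRT = AUMC(0-inf) / AUC(0-inf).
#'
#' The default terminal window examines every suffix of at least three
#' positive-concentration points strictly after tmax and keeps the one
#' with maximal adjusted R-squared; an explicit window overrides this.
#'
#' @param time sampling times (h), strictly increasing, first >= 0.
#' @param conc concentrations (ug/mL), >= 0; values below \code{loq}
#'   after the first post-dose sample are treated as missing.
#' @param terminal \code{"best-fit"} or a numeric \code{c(from, to)} time
#'   window for the lambda-z regression.
#' @param loq optional lower limit of quantitation (ug/mL).
#' @return object of class \code{nca_result} with \code{cmax}, \code{tmax},
#'   \code{lambda_z}, \code{t_half}, \code{auc_last}, \code{auc_inf},
#'   \code{aumc_last}, \code{aumc_inf}, \code{mrt} and \code{diagnostics}
#'   (terminal points used, adjusted R2, extrapolated AUC fraction).
#' @examples
#' t <- c(0, 1, 2, 4, 6, 8, 12, 24, 48)
#' cc <- 10 * exp(-0.1 * t)
#' nca(t, cc)
#' @export
nca <- function(time, conc, terminal = "best-fit", loq = NA) {
  stopifnot(is.numeric(time), is.numeric(conc), length(time) == length(conc))
  if (any(diff(time) <= 0) || time[1] < 0)
    stop("times must be strictly increasing, starting at >= 0", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0",
                                        call. = FALSE)
  if (!is.na(loq)) {
    below <- conc < loq & seq_along(conc) > 1L
    conc[below] <- NA_real_
  }
  keep <- !is.na(conc)
  time <- time[keep]; conc <- conc[keep]
  if (sum(conc > 0) < 3L)
    stop("need at least 3 positive concentrations", call. = FALSE)

  imax <- which.max(conc)          # which.max returns the earliest tie
  cmax <- conc[imax]; tmax <- time[imax]

  cand <- which(time > tmax & conc > 0)
  fit_window <- function(idx) {
    f <- stats::lm(log(conc[idx]) ~ time[idx])
    list(idx = idx, slope = unname(stats::coef(f)[2]),
         adj_r2 = suppressWarnings(summary(f)$adj.r.squared))
  }
  if (is.numeric(terminal) && length(terminal) == 2L) {
    idx <- which(time >= terminal[1] & time <= terminal[2] & conc > 0)
    if (length(idx) < 3L)
      stop("terminal window contains fewer than 3 positive points",
           call. = FALSE)
    best <- fit_window(idx)
  } else {
    if (length(cand) < 3L)
      stop("fewer than 3 positive points after tmax: cannot estimate lambda-z",
           call. = FALSE)
    fits <- lapply(seq_len(length(cand) - 2L),
                   function(s) fit_window(cand[s:length(cand)]))
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "adj_r2"))]]
  }
  if (best$slope >= 0)
    stop("terminal slope is non-negative: lambda-z undefined", call. = FALSE)
  lz <- -best$slope

  auc_last <- trapz_auc(time, conc)
  aumc_last <- trapz_auc(time, time * conc)
  clast <- conc[length(conc)]; tlast <- time[length(time)]
  auc_inf <- auc_last + clast / lz
  aumc_inf <- aumc_last + clast * tlast / lz + clast / lz^2
  structure(list(
    cmax = cmax, tmax = tmax, lambda_z = lz, t_half = t_half(lz),
    auc_last = auc_last, auc_inf = auc_inf,
    aumc_last = aumc_last, aumc_inf = aumc_inf,
    mrt = aumc_inf / auc_inf,
    diagnostics = list(n_terminal = length(best$idx),
                       terminal_times = range(time[best$idx]),
                       adj_r2 = best$adj_r2,
                       extrap_fraction = (auc_inf - auc_last) / auc_inf),
    time = time, conc = conc),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, digits = 4, ...) {
  cat("Non-compartmental analysis\n")
  v <- c(`Cmax (ug/mL)` = x$cmax, `tmax (h)` = x$tmax,
         `lambda-z (1/h)` = x$lambda_z, `t1/2 (h)` = x$t_half,
         `AUC0-t (ug/mL*h)` = x$auc_last, `AUC0-inf (ug/mL*h)` = x$auc_inf,
         `AUMC0-inf (ug/mL*h^2)` = x$aumc_inf, `MRT (h)` = x$mrt)
  print(round(v, digits))
  cat(sprintf("Terminal fit: %d points, adj R2 %.4f, %.1f%% AUC extrapolated\n",
              x$diagnostics$n_terminal, x$diagnostics$adj_r2,
              100 * x$diagnostics$extrap_fraction))
  invisible(x)
}

#' @export
plot.nca_result <- function(x, log = "y", ...) {
  pos <- x$conc > 0
  graphics::plot(x$time[pos], x$conc[pos], log = log, xlab = "Time (h)",
                 ylab = "Concentration (ug/mL)", ...)
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(cmax = x$cmax, tmax = x$tmax, lambda_z = x$lambda_z,
             t_half = x$t_half, auc_last = x$auc_last, auc_inf = x$auc_inf,
             aumc_inf = x$aumc_inf, mrt = x$mrt)
}

#' Elimination half-life from a first-order rate constant
#'
#' @param ke elimination rate constant (1/h), > 0.
#' @return t1/2 = ln(2)/ke, in hours.
#' @export
t_half <- function(ke) {
  if (any(ke <= 0)) stop("rate constant must be positive", call. = FALSE)
  log(2) / ke
}

#' Welch's unpaired two-sample comparison
#'
#' Two-tailed unequal-variance t test: t = (ma - mb) / sqrt(sa^2/na +
#' sb^2/nb) with the Welch-Satterthwaite degrees of freedom. When both
#' groups have zero variance and equal means, p = 1 by convention.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param parameter optional label for the compared quantity.
#' @return object of class \code{group_comparison}: group means and SDs,
#'   \code{t}, \code{df}, two-tailed \code{p}.
#' @export
welch_t_test <- function(a, b, parameter = "") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(t = if (equal) 0 else Inf,
                df = length(a) + length(b) - 2, p = if (equal) 1 else 0)
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(list(parameter = parameter,
                 mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 t = res$t, df = res$df, p = res$p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (nzchar(x$parameter)) cat("Parameter:", x$parameter, "\n")
  cat(sprintf("Group A: %.4g +/- %.4g (n = %d)\n", x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("Group B: %.4g +/- %.4g (n = %d)\n", x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("Welch t = %.4g, df = %.3f, two-tailed p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Per-parameter mean and SD over a cohort of NCA results
#'
#' @param results list of \code{nca_result} objects (>= 2 subjects).
#' @return data.frame with one row per PK parameter: mean, sd, n.
#' @export
summarize_group <- function(results) {
  if (length(results) < 2L) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "nca_result")))
  tab <- do.call(rbind, lapply(results, as.data.frame))
  data.frame(parameter = names(tab),
             mean = vapply(tab, mean, numeric(1)),
             sd = vapply(tab, stats::sd, numeric(1)),
             n = nrow(tab), row.names = NULL)
}
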