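#' Second-order response-surface model matrix
#'
#' Expands a matrix of coded factor settings into the full quadratic model:
#' intercept, linear terms, all pairwise interactions and pure quadratic
#' terms, in that order. For k factors the matrix has
#' 1 + 2k + k(k-1)/2 columns. Column names follow the b0/b1/b12/b11
#' convention used when reporting fitted polynomials.
#'
#' @param x numeric matrix (runs x factors) of coded levels.
#' @return the model matrix with named columns.
#' @keywords internal
rsm_model_matrix <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  cols <- list(b0 = rep(1, nrow(x)))
  for (i in seq_len(k)) cols[[paste0("b", i)]] <- x[, i]
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      cols[[paste0("b", i, j)]] <- x[, i] * x[, j]
  for (i in seq_len(k)) cols[[paste0("b", i, i)]] <- x[, i]^2
  do.call(cbind, cols)
}

#' Fit a second-order polynomial response-surface model
#'
#' Fits, by ordinary least squares on the coded factor scale, the full
#' quadratic model
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j +
#'       \sum_i b_{ii} x_i^2}
#' to one measured response over a designed experiment. On an orthogonal
#' design such as the face-centred CCD, the linear coefficients reduce to
#' \eqn{\sum x_i y / \sum x_i^2} and are unaffected by the presence of the
#' quadratic terms. The fit is always performed in coded units; actual-unit
#' settings are recovered through the attached factor definitions.
#'
#' @param design a \code{design_table} (see [fccd_design()]) or a
#'   data.frame/matrix of coded factor columns.
#' @param response numeric vector of responses in run order of the design
#'   rows (i.e. by \code{exp_no}), or a data.frame of responses from which
#'   \code{response_name} selects a column.
#' @param response_name label for the response (used in printing; required
#'   when \code{response} is a data.frame with several columns).
#' @return an object of class \code{rsm_fit} with components
#'   \code{coefficients} (named b0, b1, ..., b12, ..., b11, ...),
#'   \code{se} (coefficient standard errors), \code{sigma} (residual SD),
#'   \code{r.squared}, \code{fitted.values}, \code{residuals},
#'   \code{design}, \code{y} and \code{k}.
#' @examples
#' ccd <- read_design_table(fbd_fixture("table2_ccd.csv"))
#' fit <- fit_rsm(ccd, ccd$Y1, "retention time")
#' coef(fit)
#' @export
fit_rsm <- function(design, response, response_name = NULL) {
  x <- design_matrix(design)
  if (is.data.frame(response)) {
    if (is.null(response_name) && ncol(response) == 1L)
      response_name <- names(response)
    if (is.null(response_name) || !response_name %in% names(response))
      stop("response_name must name a column of the response table",
           call. = FALSE)
    response <- response[[response_name]]
  }
  y <- as.numeric(response)
  if (length(y) != nrow(x))
    stop("response length must equal the number of design runs",
         call. = FALSE)
  X <- rsm_model_matrix(x)
  p <- ncol(X)
  if (nrow(X) < p)
    stop(sprintf("need at least %d runs to fit %d coefficients", p, p),
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop("singular model matrix; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  dfr <- nrow(X) - p
  sigma <- if (dfr > 0) sqrt(sum(res^2) / dfr) else NA_real_
  xtxi <- chol2inv(qr.R(qx))
  se <- if (dfr > 0) sigma * sqrt(diag(xtxi)) else rep(NA_real_, p)
  names(se) <- colnames(X)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(coefficients = beta, se = se, sigma = sigma,
                 r.squared = r2, fitted.values = fitted, residuals = res,
                 design = design, x = x, y = y, k = ncol(x),
                 response_name = response_name %||% "y",
                 df.residual = dfr),
            class = "rsm_fit")
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted.values

#' @export
print.rsm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Second-order response-surface fit: %s (%d runs, %d factors)\n",
              x$response_name, length(x$y), x$k))
  print(round(x$coefficients, digits))
  cat(sprintf("Residual SD %.4g on %d df, R-squared %.4f\n",
              x$sigma, x$df.residual, x$r.squared))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  tval <- object$coefficients / object$se
  pval <- 2 * stats::pt(abs(tval), object$df.residual, lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, sigma = object$sigma,
              r.squared = object$r.squared, df.residual = object$df.residual,
              response_name = object$response_name)
  class(out) <- "summary.rsm_fit"
  out
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  cat(sprintf("Response: %s\n", x$response_name))
  stats::printCoefmat(x$coefficients, ...)
  cat(sprintf("Residual SD %.4g on %d df, R-squared %.4f\n",
              x$sigma, x$df.residual, x$r.squared))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' Evaluates the fitted polynomial at new coded points. Points outside the
#' coded cube [-1, +1]^k are extrapolations; they are evaluated but
#' flagged with a warning.
#'
#' @param object an \code{rsm_fit}.
#' @param newdata matrix/data.frame of coded points (columns in the order
#'   of the design factors), or a numeric vector for a single point.
#'   Defaults to the design points.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop(sprintf("newdata has %d columns; model has %d factors",
                 ncol(newdata), object$k), call. = FALSE)
  if (any(abs(newdata) > 1 + 1e-9))
    warning("some points lie outside the coded region [-1, 1]^k (extrapolation)")
  drop(rsm_model_matrix(newdata) %*% object$coefficients)
}

#' Simulate responses from a fitted surface
#'
#' Draws new response vectors at the design points using the fitted
#' surface plus Gaussian noise at the residual SD.
#'
#' @param object an \code{rsm_fit}.
#' @param nsim number of response vectors.
#' @param seed optional seed, applied locally.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns.
#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  gen <- function() {
    out <- as.data.frame(replicate(
      nsim, object$fitted.values + stats::rnorm(length(object$y), 0, object$sigma)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# pure-error decomposition: group rows by identical coded settings
pure_error_ss <- function(x, y) {
  key <- apply(round(x, 9), 1L, paste, collapse = ",")
  ss <- 0; df <- 0L
  for (g in split(seq_along(y), key)) {
    if (length(g) > 1L) {
      ss <- ss + sum((y[g] - mean(y[g]))^2)
      df <- df + length(g) - 1L
    }
  }
  list(ss = ss, df = df)
}

#' ANOVA with lack-of-fit test for a response-surface model
#'
#' Partitions the total sum of squares into model and residual, and splits
#' the residual into lack of fit and pure error using replicated design
#' points (the centre replicates on a CCD). The lack-of-fit F statistic is
#' MS(lack of fit) / MS(pure error); a large value indicates that the
#' quadratic model is inadequate relative to replicate noise. With no
#' replicated rows the lack-of-fit split is omitted and only the
#' model/residual table is returned.
#'
#' @param object an \code{rsm_fit}.
#' @param ... unused.
#' @return a data.frame of class \code{anova} with SS, df, MS, F and p
#'   rows for Model, Residual, Lack of fit, Pure error and Total.
#' @export
anova.rsm_fit <- function(object, ...) {
  y <- object$y
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(object$residuals^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- length(object$coefficients) - 1L
  df_res <- object$df.residual
  pe <- pure_error_ss(object$x, y)
  rows <- list(
    Model = c(ss_mod, df_mod),
    Residual = c(ss_res, df_res))
  if (pe$df > 0L) {
    ss_lof <- ss_res - pe$ss
    df_lof <- df_res - pe$df
    rows$`Lack of fit` <- c(ss_lof, df_lof)
    rows$`Pure error` <- c(pe$ss, pe$df)
  }
  rows$Total <- c(ss_tot, length(y) - 1L)
  tab <- do.call(rbind, rows)
  ms <- ifelse(tab[, 2] > 0, tab[, 1] / tab[, 2], NA_real_)
  Fv <- rep(NA_real_, nrow(tab)); pv <- rep(NA_real_, nrow(tab))
  ms_res <- ss_res / df_res
  if (df_res > 0 && ms_res > 0) {
    Fv[1] <- ms[1] / ms_res
    pv[1] <- stats::pf(Fv[1], df_mod, df_res, lower.tail = FALSE)
  }
  if (pe$df > 0L) {
    i <- which(rownames(tab) == "Lack of fit")
    ms_pe <- pe$ss / pe$df
    if (ms_pe > 0) {
      Fv[i] <- ms[i] / ms_pe
      pv[i] <- stats::pf(Fv[i], tab[i, 2], pe$df, lower.tail = FALSE)
    }
  }
  out <- data.frame(`Sum Sq` = tab[, 1], Df = tab[, 2], `Mean Sq` = ms,
                    `F value` = Fv, `Pr(>F)` = pv, check.names = FALSE,
                    row.names = rownames(tab))
  structure(out, heading = sprintf("ANOVA, response %s", object$response_name),
            class = c("anova", "data.frame"))
}

#' Grid of surface predictions for plotting or export
#'
#' @param object an \code{rsm_fit}.
#' @param lower,upper coded bounds per factor (recycled).
#' @param resolution points per axis (>= 2).
#' @return long-format data.frame: one coded column per factor plus
#'   \code{pred}; predictions equal [predict.rsm_fit()] pointwise.
#' @export
surface_grid <- function(object, lower = -1, upper = 1, resolution = 21L) {
  stopifnot(inherits(object, "rsm_fit"), resolution >= 2L)
  lower <- rep_len(lower, object$k); upper <- rep_len(upper, object$k)
  axes <- lapply(seq_len(object$k), function(i)
    seq(lower[i], upper[i], length.out = resolution))
  names(axes) <- colnames(object$x)
  g <- do.call(expand.grid, axes)
  g$pred <- predict(object, as.matrix(g))
  g
}

#' Perspective / contour display of a two-factor response surface
#'
#' @param x an \code{rsm_fit} with exactly two factors.
#' @param type \code{"persp"} or \code{"contour"}.
#' @param resolution grid points per axis.
#' @param ... passed on to [graphics::persp()] or [graphics::contour()].
#' @return invisibly, the prediction grid.
#' @export
plot.rsm_fit <- function(x, type = c("persp", "contour"), resolution = 41L, ...) {
  type <- match.arg(type)
  if (x$k != 2L)
    stop("surface plotting is implemented for two-factor models", call. = FALSE)
  s <- seq(-1, 1, length.out = resolution)
  z <- outer(s, s, function(a, b) predict(x, cbind(a, b)))
  labs <- colnames(x$x)
  if (type == "persp")
    graphics::persp(s, s, z, xlab = labs[1], ylab = labs[2],
                    zlab = x$response_name, ticktype = "detailed", ...)
  else {
    graphics::contour(s, s, z, xlab = labs[1], ylab = labs[2], ...)
    graphics::title(main = x$response_name)
  }
  invisible(data.frame(expand.grid(s, s), pred = as.vector(z)))
}
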