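#' Define a desirability goal for one response
#'
#' Derringer-Suich desirability maps each predicted response onto a score
#' d in [0, 1] by a linear ramp: for \code{"maximize"} d rises from 0 at
#' \code{low} to 1 at \code{high}; for \code{"minimize"} it falls from 1
#' at \code{low} to 0 at \code{high}; for \code{"target"} it ramps up to 1
#' at \code{target} and back down to 0 at \code{high}. The weight
#' enters the overall desirability as the response's exponent in the
#' weighted geometric mean, so scaling every weight by the same constant
#' leaves the combined score unchanged while raising one weight
#' emphasises that response.
#'
#' @param response name of the fitted response the goal applies to.
#' @param direction one of \code{"minimize"}, \code{"maximize"},
#'   \code{"target"}.
#' @param low,high acceptable bounds (low < high).
#' @param target target value (required when direction is "target").
#' @param weight positive weight exponent.
#' @return an object of class \code{desirability_goal}.
#' @export
desirability_goal <- function(response,
                              direction = c("minimize", "maximize", "target"),
                              low, high, target = NULL, weight = 1) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(low), is.numeric(high), weight > 0)
  if (!(low < high)) stop("need low < high", call. = FALSE)
  if (direction == "target") {
    if (is.null(target)) stop("direction 'target' requires a target value",
                              call. = FALSE)
    if (!(low <= target && target <= high))
      stop("target must lie within [low, high]", call. = FALSE)
  }
  structure(list(response = response, direction = direction, low = low,
                 high = high, target = target, weight = weight),
            class = "desirability_goal")
}

#' Individual desirability of predicted response values
#'
#' @param y numeric vector of (predicted) response values.
#' @param goal a [desirability_goal()].
#' @return desirabilities in [0, 1].
#' @export
desirability <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  ramp <- function(z) pmin(pmax(z, 0), 1)
  switch(goal$direction,
    maximize = ramp((y - goal$low) / (goal$high - goal$low)),
    minimize = ramp((goal$high - y) / (goal$high - goal$low)),
    target = {
      up <- ramp((y - goal$low) / (goal$target - goal$low))
      dn <- ramp((goal$high - y) / (goal$high - goal$target))
      ifelse(y <= goal$target, up, dn)
    })
}

#' Multi-response optimization by overall desirability
#'
#' Evaluates every fitted response surface on a dense grid over the coded
#' square/cube, converts predictions to individual desirabilities under
#' the stated goals, combines them into the overall desirability
#' \deqn{D = \left(\prod_i d_i^{w_i}\right)^{1/\sum_i w_i}}
#' (the weighted geometric mean, so D = 0 wherever any single goal is
#' fully unmet) and returns the grid point with maximal D. The exhaustive
#' grid keeps the search auditable: the optimum is reproducible by brute
#' force over the same grid.
#'
#' @param fits named list of \code{rsm_fit} objects sharing the same
#'   factors; names must cover every goal's \code{response}.
#' @param goals list of [desirability_goal()] objects (at least one).
#' @param resolution grid points per axis (default 201).
#' @return an object of class \code{desirability_opt}: coded optimum,
#'   actual-unit optimum when factor definitions are attached to the
#'   design, overall D, per-response predictions and desirabilities at
#'   the optimum, and the searched grid summary.
#' @examples
#' ccd <- read_design_table(fbd_fixture("table2_ccd.csv"))
#' fits <- list(Y1 = fit_rsm(ccd, ccd$Y1, "Y1"), Y2 = fit_rsm(ccd, ccd$Y2, "Y2"))
#' goals <- list(desirability_goal("Y1", "minimize", 4, 13),
#'               desirability_goal("Y2", "maximize", 2, 9))
#' optimize_desirability(fits, goals, resolution = 101)
#' @export
optimize_desirability <- function(fits, goals, resolution = 201L) {
  if (!length(goals)) stop("at least one goal is required", call. = FALSE)
  if (!all(vapply(goals, inherits, logical(1), "desirability_goal")))
    stop("'goals' must be desirability_goal objects", call. = FALSE)
  resp <- vapply(goals, `[[`, character(1), "response")
  missing <- setdiff(resp, names(fits))
  if (length(missing))
    stop("no fitted model for goal response(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  k <- fits[[resp[1]]]$k
  axes <- rep(list(seq(-1, 1, length.out = resolution)), k)
  grid <- as.matrix(do.call(expand.grid, axes))
  colnames(grid) <- colnames(fits[[resp[1]]]$x)

  w <- vapply(goals, `[[`, numeric(1), "weight")
  logD <- matrix(0, nrow(grid), length(goals))
  pred <- matrix(NA_real_, nrow(grid), length(goals),
                 dimnames = list(NULL, resp))
  for (i in seq_along(goals)) {
    p <- predict(fits[[resp[i]]], grid)
    pred[, i] <- p
    logD[, i] <- w[i] * log(desirability(p, goals[[i]]))
  }
  D <- exp(rowSums(logD) / sum(w))  # 0 whenever any d is 0 (log -> -Inf)
  D[!is.finite(D)] <- 0
  best <- which.max(D)
  coded <- grid[best, , drop = TRUE]

  factors <- attr(fits[[resp[1]]]$design, "factors")
  actual <- if (!is.null(factors))
    stats::setNames(mapply(coded_to_actual, factors, coded),
                    vapply(factors, `[[`, character(1), "symbol"))
  d_best <- vapply(seq_along(goals), function(i)
    desirability(pred[best, i], goals[[i]]), numeric(1))
  structure(list(coded = coded, actual = actual, D = D[best],
                 predictions = pred[best, ], desirability = d_best,
                 goals = goals, resolution = resolution,
                 all_zero = all(D == 0)),
            class = "desirability_opt")
}

#' @export
print.desirability_opt <- function(x, digits = 4, ...) {
  cat("Desirability optimization (grid ", x$resolution, " per axis)\n", sep = "")
  if (x$all_zero)
    cat("Overall desirability is zero everywhere on the grid;",
        "reporting an arbitrary grid point.\n")
  cat("Optimum (coded): ",
      paste(sprintf("%s = %.3f", names(x$coded), x$coded), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$actual))
    cat("Optimum (actual units): ",
        paste(sprintf("%s = %.3f", names(x$actual), x$actual), collapse = ", "),
        "\n", sep = "")
  cat(sprintf("Overall desirability D = %.*f\n", digits, x$D))
  for (i in seq_along(x$goals))
    cat(sprintf("  %s: predicted %.4g (d = %.3f, %s)\n",
                x$goals[[i]]$response, x$predictions[i], x$desirability[i],
                x$goals[[i]]$direction))
  invisible(x)
}
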