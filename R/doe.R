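#' Define an experimental factor
#'
#' A factor is described by its name, a single-letter symbol used as the
#' column label in design tables, and three actual levels bound to the coded
#' levels -1, 0, +1. The three levels need not be equidistant (e.g. a pH
#' factor studied at 2.5 / 3.5 / 4.0): the coded scale is treated as a pair
#' of linear segments, one from low to centre and one from centre to high.
#'
#' @param name factor name, e.g. "Methanol concentration".
#' @param symbol single-letter label used as the design column name.
#' @param low,centre,high actual levels mapped to coded -1, 0, +1;
#'   must be strictly increasing.
#' @param units unit string for reporting (e.g. "% v/v", "pH").
#' @return an object of class \code{doe_factor}.
#' @examples
#' methanol <- doe_factor("Methanol concentration", "A", 10, 20, 30, "% v/v")
#' coded_to_actual(methanol, c(-1, 0, 1))
#' @export
doe_factor <- function(name, symbol, low, centre, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(symbol), nchar(symbol) >= 1L,
            is.numeric(low), is.numeric(centre), is.numeric(high))
  if (!(low < centre && centre < high))
    stop("factor levels must satisfy low < centre < high", call. = FALSE)
  structure(list(name = name, symbol = symbol,
                 low = low, centre = centre, high = high, units = units),
            class = "doe_factor")
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("Factor %s (%s): %g / %g / %g %s  [coded -1 / 0 / +1]\n",
              x$symbol, x$name, x$low, x$centre, x$high, x$units))
  invisible(x)
}

#' Convert coded factor levels to actual units
#'
#' Piecewise-linear mapping: coded values in [-1, 0] interpolate between the
#' low and centre levels, values in [0, +1] between centre and high. When the
#' centre level is the midpoint of low and high this reduces to the usual
#' single linear map.
#'
#' @param factor a \code{\link{doe_factor}}.
#' @param coded numeric vector of coded levels, each in [-1, +1].
#' @return actual levels in factor units.
#' @seealso [actual_to_coded()] for the inverse.
#' @export
coded_to_actual <- function(factor, coded) {
  stopifnot(inherits(factor, "doe_factor"), is.numeric(coded))
  if (any(coded < -1 - 1e-12 | coded > 1 + 1e-12))
    stop("coded levels must lie in [-1, +1]", call. = FALSE)
  coded <- pmin(pmax(coded, -1), 1)
  ifelse(coded <= 0,
         factor$centre + coded * (factor$centre - factor$low),
         factor$centre + coded * (factor$high - factor$centre))
}

#' Convert actual factor levels to the coded scale
#'
#' Inverse of [coded_to_actual()]; piecewise-linear on the same two segments.
#'
#' @inheritParams coded_to_actual
#' @param actual numeric vector of actual levels in [low, high].
#' @return coded levels in [-1, +1].
#' @export
actual_to_coded <- function(factor, actual) {
  stopifnot(inherits(factor, "doe_factor"), is.numeric(actual))
  if (any(actual < factor$low - 1e-9 | actual > factor$high + 1e-9))
    stop("actual levels must lie within [low, high]", call. = FALSE)
  ifelse(actual <= factor$centre,
         (actual - factor$centre) / (factor$centre - factor$low),
         (actual - factor$centre) / (factor$high - factor$centre))
}

new_design_table <- function(df, factors = NULL, type = "fccd") {
  structure(df, factors = factors, design_type = type,
            class = c("design_table", "data.frame"))
}

#' Factor (coded) columns of a design table
#'
#' @param design a \code{design_table} or plain data.frame; factor columns
#'   are every numeric column other than \code{exp_no} and \code{run_order}
#'   (and any response columns you have not added yet).
#' @return numeric matrix of coded levels, one column per factor.
#' @export
design_matrix <- function(design) {
  df <- as.data.frame(design)
  keep <- attr(design, "factor_cols")
  if (is.null(keep)) {
    drop <- c("exp_no", "run_order", "point_type",
              attr(design, "responses"))
    keep <- setdiff(names(df), drop)
    keep <- keep[vapply(df[keep], is.numeric, logical(1))]
  }
  if (!length(keep)) stop("no factor columns found in design", call. = FALSE)
  as.matrix(df[keep])
}

#' Generate a face-centred central composite design
#'
#' Builds the standard face-centred CCD for k factors: the 2^k full
#' factorial at coded levels +/-1, 2k axial points with one factor at +/-1
#' and the rest at 0, and \code{n_centre} replicated centre points, for
#' 2^k + 2k + n_centre runs in total. The run order is a seeded random
#' permutation recorded alongside the standard experiment number.
#'
#' @param factors list of [doe_factor()] objects (at least two).
#' @param n_centre number of centre-point replicates (>= 1). Five centre
#'   replicates with k = 2 give the classical 13-run design.
#' @param seed integer seed for run-order randomization (optional; without
#'   it the run order equals the standard order).
#' @return a \code{design_table} data.frame with columns \code{exp_no},
#'   \code{run_order}, one coded column per factor (named by its symbol)
#'   and \code{point_type} (factorial / axial / centre).
#' @examples
#' f <- list(doe_factor("Methanol", "A", 10, 20, 30, "%"),
#'           doe_factor("pH", "B", 2.5, 3.5, 4.0, "pH"))
#' d <- fccd_design(f, n_centre = 5, seed = 42)
#' table(d$point_type)
#' @export
fccd_design <- function(factors, n_centre = 5L, seed = NULL) {
  if (!is.list(factors) || length(factors) < 2L)
    stop("an FCCD needs at least 2 factors", call. = FALSE)
  if (!all(vapply(factors, inherits, logical(1), "doe_factor")))
    stop("'factors' must be a list of doe_factor objects", call. = FALSE)
  n_centre <- as.integer(n_centre)
  if (is.na(n_centre) || n_centre < 1L)
    stop("n_centre must be a positive integer", call. = FALSE)
  k <- length(factors)
  syms <- vapply(factors, `[[`, character(1), "symbol")
  if (anyDuplicated(syms)) stop("factor symbols must be unique", call. = FALSE)

  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -1
    axial[2L * i, i] <- 1
  }
  centre <- matrix(0, n_centre, k)
  m <- rbind(fact, axial, centre)
  colnames(m) <- syms
  n <- nrow(m)
  run_order <- seq_len(n)
  if (!is.null(seed))

    run_order <- withr_seed(seed, sample.int(n))
  df <- data.frame(exp_no = seq_len(n), run_order = run_order, m,
                   point_type = rep(c("factorial", "axial", "centre"),
                                    c(2L^k, 2L * k, n_centre)),
                   check.names = FALSE)
  new_design_table(df, factors = factors, type = "fccd")
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("%s design: %d runs, %d factors\n",
              toupper(attr(x, "design_type") %||% "custom"),
              nrow(x), ncol(design_matrix(x))))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard published Taguchi arrays, levels coded 1..L per column.
taguchi_l4 <- matrix(c(1, 1, 1,
                       1, 2, 2,
                       2, 1, 2,
                       2, 2, 1), 4, 3, byrow = TRUE)
taguchi_l8 <- matrix(c(1, 1, 1, 1, 1, 1, 1,
                       1, 1, 1, 2, 2, 2, 2,
                       1, 2, 2, 1, 1, 2, 2,
                       1, 2, 2, 2, 2, 1, 1,
                       2, 1, 2, 1, 2, 1, 2,
                       2, 1, 2, 2, 1, 2, 1,
                       2, 2, 1, 1, 2, 2, 1,
                       2, 2, 1, 2, 1, 1, 2), 8, 7, byrow = TRUE)
taguchi_l9 <- matrix(c(1, 1, 1, 1,
                       1, 2, 2, 2,
                       1, 3, 3, 3,
                       2, 1, 2, 3,
                       2, 2, 3, 1,
                       2, 3, 1, 2,
                       3, 1, 3, 2,
                       3, 2, 1, 3,
                       3, 3, 2, 1), 9, 4, byrow = TRUE)

#' Generate a Taguchi orthogonal screening array
#'
#' Returns the standard L4, L8 or L9 orthogonal array, truncated to the
#' requested number of factor columns and re-expressed on the coded scale
#' (-1/+1 for two-level arrays, -1/0/+1 for three-level). Every pair of
#' columns of an orthogonal array contains each combination of levels
#' equally often, which is what makes independent main-effect estimates
#' possible from so few runs.
#'
#' @param n_factors number of factors to screen.
#' @param n_levels 2 or 3 levels per factor.
#' @return a \code{design_table}; supported sizes are L4 (<= 3 two-level
#'   factors), L8 (<= 7 two-level) and L9 (<= 4 three-level).
#' @export
taguchi_oa <- function(n_factors, n_levels) {
  n_factors <- as.integer(n_factors); n_levels <- as.integer(n_levels)
  arr <- if (n_levels == 2L && n_factors >= 1L && n_factors <= 3L) taguchi_l4
  else if (n_levels == 2L && n_factors <= 7L) taguchi_l8
  else if (n_levels == 3L && n_factors >= 1L && n_factors <= 4L) taguchi_l9
  else stop(sprintf(
    "no supported orthogonal array for %d factors at %d levels (have L4, L8, L9)",
    n_factors, n_levels), call. = FALSE)
  m <- arr[, seq_len(n_factors), drop = FALSE]
  coded <- if (n_levels == 2L) c(-1, 1)[m] else c(-1, 0, 1)[m]
  coded <- matrix(coded, nrow(m), ncol(m))
  colnames(coded) <- paste0("F", seq_len(n_factors))
  df <- data.frame(exp_no = seq_len(nrow(m)), run_order = seq_len(nrow(m)),
                   coded, point_type = "factorial", check.names = FALSE)
  new_design_table(df, type = sprintf("L%d", nrow(m)))
}

#' Main-effect estimates from a screening design
#'
#' The main effect of a factor is the mean response at its high (+1) level
#' minus the mean at its low (-1) level; the sign gives the direction of
#' the effect. Effects are invariant to run order because only group means
#' enter.
#'
#' @param design a \code{design_table} (orthogonal array or any two-level
#'   design with both extreme levels present for every factor).
#' @param response numeric vector of measured responses, one per design row.
#' @return named numeric vector of effects, one per factor.
#' @export
main_effects <- function(design, response) {
  x <- design_matrix(design)
  response <- as.numeric(response)
  if (length(response) != nrow(x))
    stop("response length must equal the number of runs", call. = FALSE)
  eff <- vapply(seq_len(ncol(x)), function(j) {
    hi <- x[, j] >= 1 - 1e-9
    lo <- x[, j] <= -1 + 1e-9
    if (!any(hi) || !any(lo))
      stop(sprintf("factor '%s' is not observed at both extreme levels",
                   colnames(x)[j]), call. = FALSE)
    mean(response[hi]) - mean(response[lo])
  }, numeric(1))
  names(eff) <- colnames(x)
  eff
}
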