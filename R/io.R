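table_schemas <- list(
  design = c("exp_no", "run_order", "point_type"),
  calibration = c("conc", "signal"),
  qc = c("session", "nominal", "mean", "sd"),
  release = c("time", "value"),
  conctime = c("subject", "time", "conc")
)

#' Path to a bundled example table
#'
#' The package ships the printed study tables as plain CSV: the factor
#' definitions (\code{table1_factors.csv}), the 13-run central composite
#' design with its measured responses (\code{table2_ccd.csv}), system
#' suitability parameters (\code{table3_suitability.csv}), QC precision
#' and accuracy (\code{table4_qc.csv}), stability accuracy
#' (\code{table5_stability.csv}) and the group pharmacokinetic summary
#' (\code{table6_pk.csv}).
#'
#' @param name fixture file name; with no argument, lists the available
#'   files.
#' @return absolute file path (or a character vector of names).
#' @export
fbd_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "fbdkit")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop(sprintf("no bundled fixture '%s'; see fbd_fixture()", name),
         call. = FALSE)
  path
}

#' Load and validate a typed CSV table
#'
#' Reads a CSV (decimal point, header row) and checks it against one of
#' the package's table schemas, failing with the missing column name or
#' the row number of a non-numeric cell.
#'
#' @param path CSV file path.
#' @param schema one of \code{"design"}, \code{"calibration"},
#'   \code{"qc"}, \code{"release"}, \code{"conctime"}.
#' @return validated data.frame.
#' @export
load_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("cannot parse '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  need <- table_schemas[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing column(s) %s in %s", schema,
                 paste(missing, collapse = ", "), path), call. = FALSE)
  numeric_cols <- setdiff(need, c("point_type", "session", "subject"))
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf("column '%s' is not numeric (first bad row: %d)",
                   col, if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
  }
  df
}

#' Read a design (+ response) table from CSV
#'
#' Expects the serialization written by [write_design_table()]: columns
#' \code{exp_no}, \code{run_order}, one coded column per factor,
#' \code{point_type}, then any response columns.
#'
#' @param path CSV file path.
#' @param factors optional list of [doe_factor()] definitions to attach
#'   (enables actual-unit reporting downstream).
#' @return a \code{design_table}; response columns (those after
#'   \code{point_type}) are kept and also listed in the
#'   \code{"responses"} attribute.
#' @export
read_design_table <- function(path, factors = NULL) {
  df <- load_table(path, "design")
  ord <- names(df)
  ptype <- match("point_type", ord)
  factor_cols <- setdiff(ord[seq_len(ptype - 1L)], c("exp_no", "run_order"))
  response_cols <- if (ptype < length(ord)) ord[seq(ptype + 1L, length(ord))]
  else character()
  for (col in c(factor_cols, response_cols))
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  out <- new_design_table(df, factors = factors, type = "fccd")
  attr(out, "responses") <- response_cols
  attr(out, "factor_cols") <- factor_cols
  out
}

#' @rdname read_design_table
#' @param design a \code{design_table}, possibly carrying response columns.
#' @export
write_design_table <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

pipeline_keys <- c("design", "factors", "responses", "goals", "resolution",
                   "seed", "outdir")

#' Run the design -> fit -> optimize pipeline
#'
#' Fits the full quadratic response-surface model to every response
#' column of a design table, runs the lack-of-fit ANOVA for each, and
#' (when goals are supplied) locates the desirability optimum; all
#' results are written to the output directory along with a JSON manifest
#' recording inputs, seed and package version so a rerun with the same
#' configuration reproduces the numbers.
#'
#' @param config named list with keys \code{design} (CSV path or a
#'   \code{design_table} carrying responses), optional \code{factors}
#'   (list of [doe_factor()]), optional \code{responses} (character;
#'   default: every response column), optional \code{goals} (list of
#'   [desirability_goal()]), \code{resolution} (grid, default 201),
#'   \code{seed}, and \code{outdir} (default \code{tempdir()}). Unknown
#'   keys are rejected.
#' @return invisibly, a list with \code{fits}, \code{anova},
#'   \code{optimum} (or NULL) and the manifest; side effect: files under
#'   \code{outdir}.
#' @export
run_pipeline <- function(config) {
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$design)) stop("config$design is required", call. = FALSE)
  design <- config$design
  if (is.character(design)) {
    if (!file.exists(design))
      stop("pipeline pre-flight: design file not found: ", design,
           call. = FALSE)
    design <- read_design_table(design, factors = config$factors)
  }
  responses <- config$responses %||% attr(design, "responses")
  if (!length(responses))
    stop("no response columns found or named", call. = FALSE)
  outdir <- config$outdir %||% tempdir()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  dm_cols <- attr(design, "factor_cols")
  dsub <- if (!is.null(dm_cols))
    new_design_table(as.data.frame(design)[c("exp_no", "run_order", dm_cols,
                                             "point_type")],
                     factors = attr(design, "factors"))
  else design

  fits <- lapply(responses, function(r) {
    message(sprintf("fitting response %s over %d runs", r, nrow(design)))
    fit_rsm(dsub, as.data.frame(design)[[r]], r)
  })
  names(fits) <- responses
  coef_tab <- do.call(rbind, lapply(responses, function(r)
    data.frame(response = r, term = names(coef(fits[[r]])),
               estimate = unname(coef(fits[[r]])),
               std_error = unname(fits[[r]]$se),
               r_squared = fits[[r]]$r.squared)))
  utils::write.csv(coef_tab, file.path(outdir, "coefficients.csv"),
                   row.names = FALSE)
  anovas <- lapply(fits, stats::anova)
  for (r in responses)
    utils::write.csv(cbind(term = rownames(anovas[[r]]), anovas[[r]]),
                     file.path(outdir, sprintf("anova_%s.csv", r)),
                     row.names = FALSE)
  optimum <- NULL
  if (length(config$goals)) {
    optimum <- optimize_desirability(fits, config$goals,
                                     resolution = config$resolution %||% 201L)
    jsonlite::write_json(
      list(coded = as.list(optimum$coded),
           actual = if (!is.null(optimum$actual)) as.list(optimum$actual),
           D = optimum$D, predictions = as.list(optimum$predictions)),
      file.path(outdir, "optimum.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    design_rows = nrow(design), responses = responses,
    seed = config$seed, resolution = config$resolution %||% 201L,
    package_version = as.character(utils::packageVersion("fbdkit")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(fits = fits, anova = anovas, optimum = optimum,
                 manifest = manifest, outdir = outdir))
}
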