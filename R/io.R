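#' @name assay_io
#' @title Assay table file formats
#'
#' @description
#' All assay tables share one CSV dialect: comma-separated, `.` decimal,
#' UTF-8, with `#` comment lines. Writers prepend a comment header
#' recording package version, seed and a configuration hash so that every
#' file can be traced to the run that produced it. Readers validate
#' required columns and cell values, reporting file, line and column for
#' malformed rows, and preserve unknown columns untouched.
#'
#' Dialects (required columns; extra columns pass through):
#' \itemize{
#'   \item `timecourse.csv`: `time_min`, `fraction_cleaved`
#'     (optionally `intensity_fl`, `intensity_ccp`, `substrate`,
#'     `protease`, `temp_C`, `nacl_mM`)
#'   \item `titration.csv`: `enzyme_uM`, `fraction_cleaved`
#'     (optionally `substrate`, `protease`, `time_min`, `temp_C`, `s0_uM`)
#'   \item `standards.csv`: `known_fraction`, `intensity_fl`,
#'     `intensity_ccp`
#'   \item `grid.csv` (long): `protease`, `substrate`, `enzyme_uM`,
#'     `fraction_cleaved` (optionally `time_min`, `temp_C`)
#' }
NULL

io_header <- function(seed = NULL, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("ublcleave")),
                  error = function(e) "unknown")
  c(sprintf("# package=ublcleave version=%s", ver),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config_hash=%s", config_hash(config)))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_assay_table <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(io_header(seed, config), con)
  utils::write.table(as.data.frame(df), con, sep = ",", dec = ".",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Reads the dialect while keeping a map from data rows to file lines so
# that validation errors can name the offending line.
read_assay_table <- function(path, required, numeric_cols, fraction_cols) {
  if (!file.exists(path)) {
    stop(sprintf("parse error: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    stop(sprintf("parse error: %s: no data rows", path), call. = FALSE)
  }
  idx <- which(keep)
  df <- utils::read.csv(text = paste(lines[keep], collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  line_of_row <- idx[-1]  # first kept line is the header

  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("parse error: %s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) &
                   trimws(as.character(df[[col]])) != "NA")
    if (length(bad)) {
      stop(sprintf("parse error: %s: line %d, column '%s': non-numeric value '%s'",
                   path, line_of_row[bad[1]], col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in intersect(fraction_cols, names(df))) {
    bad <- which(is.finite(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad)) {
      stop(sprintf("parse error: %s: line %d, column '%s': value %g outside [0, 1]",
                   path, line_of_row[bad[1]], col, df[[col]][bad[1]]),
           call. = FALSE)
    }
  }
  df
}

#' Write / read a cleavage time-course table
#'
#' @param course A [time_course()] or compatible `data.frame`.
#' @param path File path.
#' @param seed,config Optional provenance recorded in the header comments.
#' @return `write_timecourse()` the path, invisibly; `read_timecourse()` a
#'   validated `data.frame` in the time-course dialect.
#' @rdname io_timecourse
#' @export
write_timecourse <- function(course, path, seed = NULL, config = NULL) {
  df <- as.data.frame(course)
  cond <- attr(course, "conditions")
  if (!is.null(cond)) {
    for (nm in c("substrate", "protease", "temp_C", "nacl_mM")) {
      if (!nm %in% names(df)) df[[nm]] <- cond[[nm]] %||% NA
    }
  }
  write_assay_table(df, path, seed, config)
}

#' @rdname io_timecourse
#' @export
read_timecourse <- function(path) {
  read_assay_table(path,
                   required = c("time_min", "fraction_cleaved"),
                   numeric_cols = c("time_min", "fraction_cleaved",
                                    "intensity_fl", "intensity_ccp",
                                    "temp_C", "nacl_mM"),
                   fraction_cols = "fraction_cleaved")
}

#' Write / read a protease titration table
#'
#' @param series A [titration_series()] or compatible `data.frame`.
#' @param path File path.
#' @param seed,config Optional provenance for the header comments.
#' @rdname io_titration
#' @export
write_titration <- function(series, path, seed = NULL, config = NULL) {
  df <- as.data.frame(series)
  cond <- attr(series, "conditions")
  if (!is.null(cond)) {
    for (nm in c("substrate", "protease", "time_min", "temp_C", "s0_uM")) {
      if (!nm %in% names(df)) df[[nm]] <- cond[[nm]] %||% NA
    }
  }
  write_assay_table(df, path, seed, config)
}

#' @rdname io_titration
#' @export
read_titration <- function(path) {
  read_assay_table(path,
                   required = c("enzyme_uM", "fraction_cleaved"),
                   numeric_cols = c("enzyme_uM", "fraction_cleaved",
                                    "time_min", "temp_C", "s0_uM"),
                   fraction_cols = "fraction_cleaved")
}

#' Write / read a cleavage-standards table
#'
#' @param standards `data.frame` with `known_fraction`, `intensity_fl`,
#'   `intensity_ccp` (as from [gen_standards()]).
#' @param path File path.
#' @param seed,config Optional provenance for the header comments.
#' @rdname io_standards
#' @export
write_standards <- function(standards, path, seed = NULL, config = NULL) {
  write_assay_table(standards, path, seed, config)
}

#' @rdname io_standards
#' @export
read_standards <- function(path) {
  read_assay_table(path,
                   required = c("known_fraction", "intensity_fl",
                                "intensity_ccp"),
                   numeric_cols = c("known_fraction", "intensity_fl",
                                    "intensity_ccp"),
                   fraction_cols = "known_fraction")
}

#' Write / read a cross-reactivity grid table (long format)
#'
#' Completeness of the grid (every protease/substrate combination
#' present) is a property of the downstream orthogonality analysis, not
#' of the file: the reader accepts partial grids and
#' [orthogonality_calls()] raises the incomplete-grid error.
#'
#' @param grid A [crossreact_grid()] or long `data.frame`.
#' @param path File path.
#' @param seed,config Optional provenance for the header comments.
#' @rdname io_grid
#' @export
write_grid <- function(grid, path, seed = NULL, config = NULL) {
  df <- if (inherits(grid, "crossreact_grid")) grid$data else grid
  write_assay_table(df, path, seed, config)
}

#' @rdname io_grid
#' @export
read_grid <- function(path) {
  read_assay_table(path,
                   required = c("protease", "substrate", "enzyme_uM",
                                "fraction_cleaved"),
                   numeric_cols = c("enzyme_uM", "fraction_cleaved",
                                    "time_min", "temp_C"),
                   fraction_cols = "fraction_cleaved")
}

#' Run configuration
#'
#' Reads a YAML key/value file holding the knobs shared by a whole run
#' and fills in package defaults. Recognised keys: `seed` (non-negative
#' integer), `near_complete_threshold`, `class_thresholds`
#' (`high`/`clear`/`trace`), `rel_tol`, `abs_tol`, `units` (must be the
#' package convention `uM_min` when given), `input_dir`, `output_dir`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Object of class `run_config` (a named list).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(units = "uM_min", seed = 1L,
              near_complete_threshold = 0.95,
              class_thresholds = as.list(default_class_thresholds()),
              rel_tol = 1e-8, abs_tol = 1e-10,
              input_dir = ".", output_dir = ".")
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop(sprintf("parse error: %s: unknown config key(s): %s",
                   path, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(user$class_thresholds)) {
      cfg$class_thresholds <- utils::modifyList(cfg$class_thresholds,
                                                user$class_thresholds)
      user$class_thresholds <- NULL
    }
    cfg <- utils::modifyList(cfg, user)
  }
  if (!identical(cfg$units, "uM_min")) {
    stop("parse error: config 'units' must be 'uM_min' (micromolar / minutes)",
         call. = FALSE)
  }
  if (cfg$seed < 0 || cfg$seed != as.integer(cfg$seed)) {
    stop("parse error: config 'seed' must be a non-negative integer",
         call. = FALSE)
  }
  th <- c(cfg$near_complete_threshold, unlist(cfg$class_thresholds))
  if (any(th <= 0 | th > 1)) {
    stop("parse error: config thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}
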