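#' Read a census series from CSV
#'
#' The canonical on-disk format: a header `year,<lang1>,<lang2>,...` followed
#' by one row per census year with the year and one fraction per language.
#' Parsing errors (malformed header, ragged rows, non-numeric cells,
#' non-monotone years, out-of-range fractions) are reported with
#' `file:line` context. Rows are normalised onto the simplex on read, with a
#' warning when a row's sum deviates from 1 by more than 1e-6.
#'
#' The format is deliberately plain (no quoting or embedded commas), so it is
#' parsed line by line to keep exact line numbers in diagnostics.
#'
#' @param path path to a CSV file.
#' @return an `observed_series`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(path, ": empty file, expected a ",
                               "'year,<language>,...' header")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < 3 || tolower(header[1]) != "year")
    stop(path, ":1: malformed header; expected 'year' followed by at ",
         "least two language names, got '", lines[1], "'")
  names <- header[-1]
  if (length(lines) < 2) stop(path, ": no data rows after the header")
  n_col <- length(header)
  years <- numeric(length(lines) - 1)
  frac <- matrix(NA_real_, length(lines) - 1, length(names))
  for (r in seq_along(years)) {
    ln <- r + 1
    cells <- trimws(strsplit(lines[ln], ",", fixed = TRUE)[[1]])
    if (length(cells) != n_col)
      stop(path, ":", ln, ": expected ", n_col, " fields, found ",
           length(cells))
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop(path, ":", ln, ": non-numeric cell '",
           cells[which(is.na(vals))[1]], "'")
    years[r] <- vals[1]
    frac[r, ] <- vals[-1]
    if (any(vals[-1] < 0) || any(vals[-1] > 1))
      stop(path, ":", ln, ": fraction out of [0, 1]")
  }
  bad <- which(diff(years) <= 0)
  if (length(bad) > 0)
    stop(path, ":", bad[1] + 2, ": years must be strictly increasing (",
         years[bad[1]], " then ", years[bad[1] + 1], ")")
  observed_series(years, frac, names)
}

#' Write a census series to CSV
#'
#' Fractions are written at full double precision so that
#' `read_series(write_series(x, f))` round-trips losslessly.
#'
#' @param series an `observed_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "observed_series"))
  header <- paste(c("year", series$names), collapse = ",")
  rows <- vapply(seq_along(series$years), function(r)
    paste(c(format_full(series$years[r]),
            format_full(series$fractions[r, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# full-precision decimal rendering (17 significant digits round-trips doubles)
format_full <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  trimws(out)
}

#' Read a census series from a spreadsheet
#'
#' Accepts the study-style spreadsheet layout: first column the census year,
#' one column per language. Requires the `readxl` package.
#'
#' @param path path to an `.xlsx` file.
#' @param sheet sheet index or name; default the first sheet.
#' @return an `observed_series`.
#' @export
read_series_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading spreadsheets requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  if (ncol(df) < 3)
    stop(path, ": expected a year column plus at least two language columns")
  observed_series(df[[1]], as.matrix(df[, -1, drop = FALSE]),
                  names(df)[-1])
}

#' Write and read a posterior ensemble as CSV
#'
#' One particle per row: `alpha`, `beta`, one utility column per language,
#' `weight`, `distance`.
#'
#' @param posterior an `abc_posterior`.
#' @param path file path.
#' @return `write_posterior()` returns `path` invisibly; `read_posterior()`
#'   returns the particle data.frame.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "abc_posterior"))
  write.csv(posterior$particles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, check.names = FALSE)
}

#' Write a sweep result or phase diagram as long-format CSV
#'
#' Sweeps are written with their grid value, per-language equilibrium
#' fractions, convergence time, convergence flag and state label; phase
#' diagrams with one row per (beta, aversion) cell.
#'
#' @param x a `sweep_result` or `phase_diagram`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  if (inherits(x, "phase_diagram")) {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "sweep_result")) {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else stop("`x` must be a sweep_result or phase_diagram")
  invisible(path)
}
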