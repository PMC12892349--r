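#' Multivariate time series container
#'
#' A `timeseries` wraps a T x N numeric matrix (rows = time points, columns =
#' regions) together with its sampling interval. The orientation is fixed:
#' rows are always time. Files whose orientation is ambiguous are the user's
#' responsibility -- nothing is auto-transposed.
#'
#' @param data Numeric matrix, T time points by N regions. T >= 2, N >= 2,
#'   all entries finite.
#' @param tr Sampling interval in seconds (repetition time). Default 1.
#' @param region_labels Optional character vector of length N.
#' @return An object of class `timeseries` with elements `data`, `tr`,
#'   `region_labels`.
#' @examples
#' ts <- timeseries(cbind(a = rnorm(50), b = rnorm(50)), tr = 2)
#' dim(ts$data)
#' @export
timeseries <- function(data, tr = 1, region_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("timeseries needs at least 2 time points and 2 regions, got ",
         nrow(data), " x ", ncol(data))
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite value at time point ", bad[1, 1], ", region ", bad[1, 2])
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number (seconds)")
  if (is.null(region_labels) && !is.null(colnames(data)))
    region_labels <- colnames(data)
  if (!is.null(region_labels)) {
    region_labels <- as.character(region_labels)
    if (length(region_labels) != ncol(data))
      stop("region_labels length (", length(region_labels),
           ") does not match number of regions (", ncol(data), ")")
    colnames(data) <- region_labels
  }
  structure(list(data = data, tr = tr, region_labels = region_labels),
            class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat("timeseries:", nrow(x$data), "time points x", ncol(x$data),
      "regions, tr =", x$tr, "s\n")
  if (!is.null(x$region_labels))
    cat("regions:", paste(utils::head(x$region_labels, 8), collapse = ", "),
        if (length(x$region_labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.timeseries <- function(x) dim(x$data)

n_timepoints <- function(ts) nrow(ts$data)
n_regions <- function(ts) ncol(ts$data)

as_timeseries <- function(x, tr = 1) {
  if (inherits(x, "timeseries")) x else timeseries(x, tr = tr)
}

guess_delimiter <- function(path) {
  switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", txt = "\t",
         "\t")
}

#' Read a time series matrix from delimited text
#'
#' Rows map to time points, columns to regions. If any token in the first row
#' is non-numeric the row is treated as a header of region labels. The table
#' must be rectangular and fully finite; offending cells are reported by
#' row and column.
#'
#' @param path Path to a CSV/TSV/TXT file.
#' @param delimiter Field delimiter; default inferred from the file
#'   extension (`,` for .csv, tab otherwise).
#' @param tr Sampling interval in seconds attached to the result.
#' @return A [timeseries].
#' @export
read_timeseries <- function(path, delimiter = NULL, tr = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- guess_delimiter(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("non-rectangular table in ", path, ": rows have ",
         paste(unique(widths), collapse = "/"), " fields")
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  labels <- NULL
  if (has_header) {
    labels <- trimws(fields[[1L]])
    fields <- fields[-1L]
    if (length(fields) == 0L) stop("no data rows in ", path)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                nrow = length(fields), byrow = TRUE)
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite value in ", path, " at data row ", bad[1, 1],
         ", column ", bad[1, 2])
  timeseries(mat, tr = tr, region_labels = labels)
}

#' Write a square matrix as delimited text
#'
#' Values are written with `format(..., digits = 17)` so that a
#' read/write round trip reproduces the matrix to within 1e-12.
#'
#' @param m Square numeric matrix (e.g. a connectivity matrix).
#' @param path Output path; delimiter inferred from extension unless given.
#' @param delimiter Field delimiter override.
#' @export
write_matrix <- function(m, path, delimiter = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop("write_matrix expects a square matrix, got ", nrow(m), " x ", ncol(m))
  if (is.null(delimiter)) delimiter <- guess_delimiter(path)
  txt <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = delimiter))
  writeLines(txt, path)
  invisible(path)
}

#' Read a square matrix from delimited text
#'
#' @param path Path to the file written by [write_matrix()] (or any square
#'   numeric table without header).
#' @param delimiter Field delimiter override.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- guess_delimiter(path)
  m <- as.matrix(utils::read.table(path, sep = delimiter, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("matrix in ", path, " is not square: ", nrow(m), " x ", ncol(m))
  m
}

#' Column-wise standardization (z-scoring)
#'
#' Centers each region to mean zero and scales it to unit variance. The
#' divisor convention matters downstream: with `ddof = 0` (population
#' variance, the default) the temporal mean of the edge time series equals
#' the Pearson correlation exactly.
#'
#' @param ts A [timeseries] or T x N matrix.
#' @param ddof Delta degrees of freedom for the variance divisor `T - ddof`;
#'   0 (default) or 1.
#' @return A [timeseries] with standardized columns.
#' @export
standardize <- function(ts, ddof = 0) {
  ts <- as_timeseries(ts)
  x <- ts$data
  stopifnot(ddof %in% c(0, 1))
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  ss <- colSums(xc^2) / (nrow(x) - ddof)
  if (any(ss <= 0)) {
    i <- which(ss <= 0)[1L]
    lab <- if (!is.null(ts$region_labels)) ts$region_labels[i] else i
    stop("region ", lab, " is constant; cannot standardize")
  }
  z <- sweep(xc, 2L, sqrt(ss), "/")
  timeseries(z, tr = ts$tr, region_labels = ts$region_labels)
}

# z-score matrix helper used by several estimators (ddof = 0)
zscore0 <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  s <- sqrt(colMeans(xc^2))
  if (any(s == 0)) {
    stop("region ", which(s == 0)[1L], " is constant; cannot standardize")
  }
  sweep(xc, 2L, s, "/")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 2nd-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion -- the standard
#' temporal-filtering step for fMRI region time series. Columns are
#' detrended (mean removed) before filtering.
#'
#' @param ts A [timeseries]; its `tr` sets the sampling rate `1/tr` Hz.
#' @param low_hz Lower band edge in Hz (0 <= low_hz < high_hz).
#' @param high_hz Upper band edge in Hz; must be below Nyquist `1/(2 tr)`.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered [timeseries] of identical shape.
#' @export
bandpass <- function(ts, low_hz, high_hz, order = 2) {
  ts <- as_timeseries(ts)
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz, got [", low_hz, ", ", high_hz, "]")
  if (high_hz >= nyq)
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz) for tr = ", ts$tr, " s")
  x <- sweep(ts$data, 2L, colMeans(ts$data))
  if (low_hz == 0) {
    flt <- signal::butter(order, high_hz / nyq, type = "low")
  } else {
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  y <- apply(x, 2L, function(col) signal::filtfilt(flt, col))
  timeseries(y, tr = ts$tr, region_labels = ts$region_labels)
}
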