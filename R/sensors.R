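## Tabulated sensor functions: cone fundamentals and colour-matching
## functions, with file reading and axis resampling.

#' Sensor functions (cone fundamentals or colour-matching functions)
#'
#' @param rows 3 x B sensitivity matrix (rows = sensor classes L,M,S or
#'   X,Y,Z bar).
#' @param axis a [spectral_axis()].
#' @param kind `"cone-fundamentals"` or `"colour-matching"`.
#' @return an object of class `sensor_functions`.
#' @export
sensor_functions <- function(rows, axis, kind = c("cone-fundamentals",
                                                  "colour-matching")) {
  kind <- match.arg(kind)
  rows <- as.matrix(rows)
  if (nrow(rows) != 3L) stop("exactly 3 sensor classes required")
  if (ncol(rows) != length(axis$wavelengths_nm)) stop("rows do not match axis")
  if (kind == "cone-fundamentals" && any(rows < 0))
    stop("cone fundamentals must be non-negative")
  structure(list(axis = axis, rows = rows, kind = kind),
            class = "sensor_functions")
}

#' Read tabulated sensor functions from a text file
#'
#' Whitespace-delimited, `#` comments, four columns: wavelength (nm) then
#' one column per sensor class. CVRL-style cone-fundamental tables in this
#' layout (e.g. Stockman-Sharpe 2 degree) can be supplied directly.
#'
#' @param path file path.
#' @param kind sensor kind, as in [sensor_functions()].
#' @return a `sensor_functions` object.
#' @export
read_sensor_functions <- function(path, kind = "cone-fundamentals") {
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 4L) stop("sensor files have wavelength + 3 value columns")
  sensor_functions(t(as.matrix(tab[, 2:4])), spectral_axis(tab[[1L]]), kind)
}

#' Built-in sensor tables
#'
#' `cie1931_cmfs()` returns the CIE 1931 2 degree colour-matching functions;
#' `hpe_cone_fundamentals()` returns the Hunt-Pointer-Estevez 2 degree cone
#' fundamentals (energy units, unit peak), the package default for LMS
#' excitations. Both are tabulated at 400-720 nm in 10 nm steps and
#' resampled by linear interpolation when `axis` differs.
#'
#' @param axis target [spectral_axis()].
#' @return a `sensor_functions` object.
#' @export
cie1931_cmfs <- function(axis = default_spectral_axis()) {
  f <- system.file("extdata", "cmf_cie1931_2deg_10nm.txt",
                   package = "coneratios", mustWork = TRUE)
  resample_sensors(read_sensor_functions(f, kind = "colour-matching"), axis)
}

#' @rdname cie1931_cmfs
#' @export
hpe_cone_fundamentals <- function(axis = default_spectral_axis()) {
  f <- system.file("extdata", "cone_hpe_2deg_10nm.txt",
                   package = "coneratios", mustWork = TRUE)
  resample_sensors(read_sensor_functions(f, kind = "cone-fundamentals"), axis)
}

#' @rdname cie1931_cmfs
#' @param sens a `sensor_functions` object to resample.
#' @export
resample_sensors <- function(sens, axis) {
  if (same_axis(sens$axis, axis)) return(sens)
  w0 <- sens$axis$wavelengths_nm
  w1 <- axis$wavelengths_nm
  if (min(w1) < min(w0) - 1e-9 || max(w1) > max(w0) + 1e-9)
    stop("target axis extends beyond the tabulated range")
  rows <- t(vapply(seq_len(3L), function(i)
    approx(w0, sens$rows[i, ], xout = w1)$y, numeric(length(w1))))
  sensor_functions(pmax(rows, 0), axis, sens$kind)
}
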