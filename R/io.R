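## File interfaces: HDF5 hyperspectral cubes, two-column SPD files,
## tabulated sensor functions.

#' Read and write hyperspectral cubes in HDF5
#'
#' Layout: dataset `reflectance` (or `radiance`), H x W x B 32-bit float;
#' dataset `wavelengths_nm` of length B; attribute `scene_id`; radiance
#' cubes carry attribute `temperature_K`.
#'
#' @param path HDF5 file path.
#' @param cube a [reflectance_cube()] or [radiance_cube()].
#' @return `read_cube()` returns a reflectance or radiance cube;
#'   `write_cube()` returns `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  name <- if (inherits(cube, "radiance_cube")) "radiance" else "reflectance"
  rhdf5::h5write(cube$data, path, name)
  rhdf5::h5write(cube$axis$wavelengths_nm, path, "wavelengths_nm")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(cube$scene_id, fid, "scene_id")
  if (inherits(cube, "radiance_cube"))
    rhdf5::h5writeAttribute(as.numeric(cube$illuminant$temperature_K), fid,
                            "temperature_K")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  ls <- rhdf5::h5ls(path)$name
  axis <- spectral_axis(as.numeric(rhdf5::h5read(path, "wavelengths_nm")))
  at <- rhdf5::h5readAttributes(path, "/")
  scene_id <- if (!is.null(at$scene_id)) as.character(at$scene_id) else "scene"
  if ("radiance" %in% ls) {
    data <- rhdf5::h5read(path, "radiance")
    T <- if (!is.null(at$temperature_K)) as.numeric(at$temperature_K) else NA_real_
    ill <- if (is.finite(T)) planckian_spd(T, axis) else
      spd(rep(1, length(axis$wavelengths_nm)), axis)
    radiance_cube(array(as.numeric(data), dim(data)), axis, ill, scene_id)
  } else {
    data <- rhdf5::h5read(path, "reflectance")
    reflectance_cube(array(as.numeric(data), dim(data)), axis, scene_id)
  }
}

#' Read a two-column spectral power distribution file
#'
#' Whitespace-delimited text, one row per band: wavelength (nm) then
#' relative power. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return an [spd()].
#' @export
read_spd <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 2L) stop("SPD files have exactly two columns")
  spd(tab[[2L]], spectral_axis(tab[[1L]]))
}
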