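#' Write an AFM force curve to CSV
#'
#' Columns `separation_um`, `force_nN`; position and replicate metadata go
#' into a JSON sidecar (`<path>.meta.json`).
#'
#' @param curve a [force_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(
    list(position_mm = attr(curve, "position_mm"),
         replicate = attr(curve, "replicate")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AFM force curve from CSV
#'
#' @param path CSV path with columns `separation_um`, `force_nN`; an
#'   optional `<path>.meta.json` sidecar supplies position/replicate.
#' @return A [force_curve()].
#' @export
read_force_curve_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  pos <- NA_real_
  rep_i <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    pos <- meta$position_mm %||% NA_real_
    rep_i <- meta$replicate %||% NA_integer_
  }
  force_curve(df$separation_um, df$force_nN, position_mm = pos,
              replicate = rep_i)
}

#' Write a gradient calibration to JSON
#' @param cal a [fit_linear_gradient()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_gradient_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "gradient_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a gradient calibration from JSON
#' @param path JSON path written by [write_gradient_calibration()].
#' @return A `gradient_calibration`.
#' @export
read_gradient_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$points <- as.data.frame(x$points)
  structure(x[c("slope", "intercept", "r2", "slope_se", "domain",
                "points", "n")],
            class = "gradient_calibration")
}

# HDF5 stack exchange (optional dependency)
need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 export requires the `rhdf5` package", call. = FALSE)
}

#' Write a multichannel stack (or QME fields) to HDF5
#'
#' Each list element becomes a dataset; `voxel_size`/`pixel_size` and any
#' scalar metadata are stored as attributes of the file root group.
#'
#' @param fields named list of numeric arrays/matrices.
#' @param path output `.h5` path.
#' @param voxel_size optional voxel/pixel size vector stored alongside.
#' @return `path`, invisibly.
#' @export
write_fields_h5 <- function(fields, path, voxel_size = NULL) {
  need_rhdf5()
  stopifnot(is.list(fields), !is.null(names(fields)))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (nm in names(fields)) rhdf5::h5write(fields[[nm]], path, nm)
  if (!is.null(voxel_size)) rhdf5::h5write(voxel_size, path, "voxel_size")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read fields written by [write_fields_h5()]
#' @param path `.h5` path.
#' @return Named list of arrays (including `voxel_size` when present).
#' @export
read_fields_h5 <- function(path) {
  need_rhdf5()
  names <- rhdf5::h5ls(path)$name
  out <- lapply(names, function(nm) rhdf5::h5read(path, nm))
  rhdf5::h5closeAll()
  setNames(out, names)
}
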