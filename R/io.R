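# File interfaces: PNG/TIFF for 2D images, NIfTI for volumes and vector
# fields, flat key=value configs, CSV traces, text parameter files.

#' Read a 2D grayscale image (PNG or TIFF)
#'
#' Color inputs are averaged over channels.  Intensities are returned as
#' read (PNG/TIFF readers yield \[0, 1\]); pass through
#' [normalize_image()] for guaranteed range.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix.
#' @export
read_image2d <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                        drop = FALSE], c(1, 2), mean)
  a
}

#' Write a 2D image as PNG or TIFF
#' @param img matrix in \[0, 1\].
#' @param path output path (.png/.tif/.tiff).
#' @export
write_image2d <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read / write a 3D volume as NIfTI
#' @param path .nii or .nii.gz path.
#' @return array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' @rdname read_volume
#' @param vol 3D array.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Write a displacement/velocity field as a NIfTI vector image
#'
#' Components are stored along the last dimension (one channel per axis).
#'
#' @param field array `c(h, w, 2)` (or `c(d1, d2, d3, 3)`).
#' @param path .nii or .nii.gz path.
#' @export
write_field <- function(field, path) {
  RNifti::writeNifti(RNifti::asNifti(field), path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored; values that parse as numbers become numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Export per-level convergence traces as CSV
#'
#' Columns: iteration, level, metric, value.
#'
#' @param traces an `energy_trace` (list of per-level vectors, coarsest
#'   first) from [multiresolution_register()].
#' @param path output CSV path.
#' @export
write_trace_csv <- function(traces, path) {
  metric <- attr(traces, "metric")
  if (is.null(metric)) metric <- "ssd"
  df <- do.call(rbind, lapply(seq_along(traces), function(l)
    data.frame(iteration = seq_along(traces[[l]]), level = l,
               metric = metric, value = traces[[l]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write affine parameters as a small text file
#' @param params an `affine_params` (or list with the same fields).
#' @param path output path.
#' @export
write_affine_params <- function(params, path) {
  tz <- if (length(params$translation) > 2)
    sprintf("tz = %.6f\n", params$translation[3]) else ""
  cat(sprintf("angle_deg = %.6f\nscale = %.6f\ntx = %.6f\nty = %.6f\n%s",
              params$rotation_deg, params$scale, params$translation[1],
              params$translation[2], tz),
      file = path)
  invisible(path)
}
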