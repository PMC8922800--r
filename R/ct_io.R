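#' CT volume container
#'
#' A `ct_volume` holds a 3D array of stored CT intensities (unsigned 12-bit
#' convention, integers in \[0, 4095\]), per-axis voxel spacing in mm, and the
#' linear rescale mapping stored values to Hounsfield units,
#' `HU = slope * stored + intercept`.
#'
#' The third array axis is the axial (slice) axis throughout the package.
#'
#' @param stored 3D array of integers in \[0, 4095\].
#' @param spacing_mm numeric length-3, positive voxel spacing in mm.
#' @param rescale_slope positive real, HU per stored unit (default 1).
#' @param rescale_intercept real HU offset (default -1024, the standard CT
#'   convention; air at stored 24 maps to -1000 HU).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(stored, spacing_mm = c(1, 1, 1),
                      rescale_slope = 1, rescale_intercept = -1024) {
  if (!is.array(stored) || length(dim(stored)) != 3L)
    stop("`stored` must be a 3D array")
  if (anyNA(stored) || any(!is.finite(stored)))
    stop("`stored` must be finite")
  if (min(stored) < 0 || max(stored) > 4095)
    stop("stored intensities must lie in [0, 4095] (unsigned 12-bit)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive reals")
  if (!is.finite(rescale_slope) || rescale_slope <= 0)
    stop("`rescale_slope` must be > 0 (HU mapping must be monotone)")
  structure(list(
    stored = stored,
    spacing_mm = spacing_mm,
    rescale_slope = rescale_slope,
    rescale_intercept = rescale_intercept
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$stored)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU = %g*v %+g\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x "),
              x$rescale_slope, x$rescale_intercept))
  invisible(x)
}

#' Label volume container
#'
#' Integer class labels aligned voxel-for-voxel with a [ct_volume()].
#' Class map: 0 = background, 1 = femur, 2 = other bone (pelvis/acetabulum).
#'
#' @param labels 3D integer array.
#' @param spacing_mm numeric length-3 positive spacing in mm.
#' @param class_map named integer-to-name map of admissible labels.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_mm = c(1, 1, 1),
                         class_map = c(`0` = "background", `1` = "femur",
                                       `2` = "other_bone")) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive reals")
  keys <- as.integer(names(class_map))
  bad <- setdiff(unique(as.integer(labels)), keys)
  if (length(bad))
    stop("labels contain values outside the class map: ", paste(bad, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing_mm = spacing_mm, class_map = class_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = names(x$class_map)))
  cat(sprintf("<label_volume> %d x %d x %d voxels (%s)\n", d[1], d[2], d[3],
              paste(sprintf("%s=%d", x$class_map, as.integer(tab)), collapse = ", ")))
  invisible(x)
}

#' Convert stored intensities to Hounsfield units
#'
#' @param vol a [ct_volume()].
#' @return 3D numeric array of HU values.
#' @export
hu_values <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  vol$rescale_slope * vol$stored + vol$rescale_intercept
}

#' Quantize Hounsfield units to stored 12-bit intensities
#'
#' `stored = round((hu - intercept) / slope)` clamped to \[0, 4095\]. With the
#' default slope 1 / intercept -1024 this is the usual CT storage mapping
#' (-1024 HU -> 0; 3071 HU -> 4095).
#'
#' @param hu numeric array or vector of finite HU values.
#' @param rescale_slope,rescale_intercept the linear HU mapping (see
#'   [ct_volume()]).
#' @return integer array of the same shape, values in \[0, 4095\].
#' @export
quantize_to_stored <- function(hu, rescale_slope = 1, rescale_intercept = -1024) {
  if (anyNA(hu) || any(!is.finite(hu))) stop("HU values must be finite")
  v <- round((hu - rescale_intercept) / rescale_slope)
  v[v < 0] <- 0
  v[v > 4095] <- 4095
  storage.mode(v) <- "integer"
  if (!is.null(dim(hu))) dim(v) <- dim(hu)
  v
}

.read_nifti3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("voxel spacing absent or non-positive in NIfTI header")
  list(data = array(as.numeric(img), dim = d), spacing = as.numeric(sp))
}

.write_nifti3d <- function(arr, spacing_mm, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write CT volumes as NIfTI
#'
#' On-disk volumes hold the stored 12-bit integers; the HU rescale mapping is
#' a package convention supplied at read time (see [ct_volume()]).
#' Write-then-read round-trips preserve stored values bitwise and spacing to
#' within 1e-6 mm.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param rescale_slope,rescale_intercept HU mapping attached on read.
#' @return [read_volume()] returns a [ct_volume()].
#' @export
read_volume <- function(path, rescale_slope = 1, rescale_intercept = -1024) {
  x <- .read_nifti3d(path)
  ct_volume(x$data, x$spacing, rescale_slope, rescale_intercept)
}

#' @param vol a [ct_volume()] to write.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  .write_nifti3d(vol$stored, vol$spacing_mm, path, datatype = "int16")
}

#' Read / write label volumes as NIfTI
#'
#' Values are validated against the class map `{0, 1, 2}` on read.
#'
#' @param path NIfTI file path.
#' @return [read_labels()] returns a [label_volume()].
#' @export
read_labels <- function(path) {
  x <- .read_nifti3d(path)
  lab <- x$data
  storage.mode(lab) <- "integer"
  label_volume(lab, x$spacing)
}

#' @param lab a [label_volume()] to write.
#' @rdname read_labels
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  .write_nifti3d(lab$labels, lab$spacing_mm, path, datatype = "uint8")
}
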