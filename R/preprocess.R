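#' Hounsfield window specification
#'
#' A window maps the HU interval `[level - width/2, level + width/2]` linearly
#' onto \[0, 1\], clamping outside. Two windows drive the pipeline: the
#' bone-highlight window (level 40, width 200) feeding the bone/soft-tissue
#' separator and the slice classifier, and the femur window (level 500,
#' width 1000) feeding the main segmentation network.
#'
#' @param level window centre in HU.
#' @param width window width in HU, must be > 0.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(level, width) {
  if (!is.finite(level) || !is.finite(width)) stop("level/width must be finite")
  if (width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Default windows: bone-highlight 40/200, femur 500/1000
#' @return named list with elements `bone` and `femur`.
#' @export
default_windows <- function() {
  list(bone = window_spec(40, 200), femur = window_spec(500, 1000))
}

#' Apply an intensity window to an HU image
#'
#' `out = clamp((hu - (level - width/2)) / width, 0, 1)`; monotone
#' nondecreasing in the input.
#'
#' @param hu numeric array of finite HU values (any shape).
#' @param w a [window_spec()].
#' @return numeric array in \[0, 1\], same shape as `hu`.
#' @export
apply_window <- function(hu, w) {
  stopifnot(inherits(w, "window_spec"))
  if (anyNA(hu) || any(!is.finite(hu))) stop("HU values must be finite")
  out <- (hu - (w$level - w$width / 2)) / w$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Resize a 2D slice
#'
#' Bilinear interpolation for images (output stays within the input range),
#' nearest-neighbour for label slices (the value set is preserved).
#'
#' @param image 2D numeric matrix.
#' @param target integer length-2 `(rows, cols)`.
#' @param is_label logical; use nearest-neighbour resampling.
#' @return resized matrix of dimension `target`.
#' @export
resize_slice <- function(image, target, is_label = FALSE) {
  if (!is.matrix(image) || any(dim(image) < 1)) stop("`image` must be a nonempty matrix")
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1)) stop("target dims must be >= 1")
  if (all(dim(image) == target)) return(image)
  out <- EBImage::resize(image, w = target[1], h = target[2],
                         filter = if (is_label) "none" else "bilinear")
  out <- matrix(as.numeric(out), target[1], target[2])
  if (is_label) storage.mode(out) <- "integer"
  out
}

#' Mid-split and mirror augmentation
#'
#' Cuts a slice down the middle and mirrors the right half so it appears as a
#' second "left" half: one rows x cols slice yields two rows x cols/2
#' half-images (e.g. 256 x 256 -> two 256 x 128). Columns index the
#' left-right image axis. Applied identically to images and label slices, at
#' training and at test time; [unsplit_and_flip()] is the inverse used to
#' reassemble half-predictions into a full slice.
#'
#' @param image 2D matrix with an even number of columns.
#' @return list with elements `left` and `right` (the mirrored right half),
#'   each of dimension rows x cols/2.
#' @export
split_and_flip <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  n <- ncol(image)
  if (n %% 2L != 0L) stop("column count must be even to split in the middle")
  half <- n %/% 2L
  left <- image[, seq_len(half), drop = FALSE]
  right <- image[, seq(n, half + 1L), drop = FALSE]  # reversed: mirrored
  list(left = left, right = right)
}

#' @param left,right the two half-images from [split_and_flip()].
#' @rdname split_and_flip
#' @export
unsplit_and_flip <- function(left, right) {
  if (!is.matrix(left) || !is.matrix(right) || !all(dim(left) == dim(right)))
    stop("halves must be matrices of equal dimension")
  cbind(left, right[, seq(ncol(right), 1L), drop = FALSE])
}

#' Bone threshold mask
#'
#' Binary mask of voxels at or above the 200 HU bone threshold used to
#' pre-segment bone from soft tissue.
#'
#' @param hu numeric array of finite HU values.
#' @param threshold_hu threshold in HU (default 200, inclusive).
#' @return integer array of 0/1, same shape.
#' @export
bone_threshold_mask <- function(hu, threshold_hu = 200) {
  if (anyNA(hu) || any(!is.finite(hu))) stop("HU values must be finite")
  m <- (hu >= threshold_hu) + 0L
  if (!is.null(dim(hu))) dim(m) <- dim(hu)
  m
}

#' Build a per-slice training dataset from a CT/label pair
#'
#' Each axial slice is windowed twice (bone 40/200 and femur 500/1000),
#' resized to the network input size, and paired with its resized label
#' slice. `has_femur` flags slices whose labels contain class 1; it is the
#' slice-classifier target and gates which slices train the main net.
#'
#' @param ct a [ct_volume()].
#' @param labels the companion [label_volume()].
#' @param input_size integer length-2 network input `(rows, cols)`.
#' @param windows list with `bone` and `femur` [window_spec()]s.
#' @param slice_stride keep every `slice_stride`-th axial slice (dataset
#'   thinning for desk-scale training; default 1 keeps all).
#' @return list of slice samples, each a list with matrices `bone`, `femur`
#'   (windowed, in \[0,1\]), `bone_mask`, `femur_mask` (0/1), and `has_femur`.
#' @export
make_slice_dataset <- function(ct, labels, input_size = c(64, 64),
                               windows = default_windows(), slice_stride = 1L) {
  stopifnot(inherits(ct, "ct_volume"), inherits(labels, "label_volume"))
  if (!all(dim(ct$stored) == dim(labels$labels)))
    stop("CT and label volumes must share shape")
  hu <- hu_values(ct)
  idx <- seq(1L, dim(hu)[3], by = as.integer(slice_stride))
  lapply(idx, function(s) {
    hs <- hu[, , s]
    ls <- labels$labels[, , s]
    bone <- resize_slice(apply_window(hs, windows$bone), input_size)
    femur <- resize_slice(apply_window(hs, windows$femur), input_size)
    lr <- resize_slice(ls, input_size, is_label = TRUE)
    list(bone = bone, femur = femur,
         bone_mask = (lr > 0L) + 0,
         femur_mask = (lr == 1L) + 0,
         has_femur = any(ls == 1L))
  })
}
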