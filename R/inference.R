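#' Scale a probability map by the slice classifier confidence
#'
#' The per-slice femur confidence acts as a multiplicative coefficient on the
#' femur segmentation map: slices unlikely to contain femur have all positive
#' segmentation responses reduced before thresholding. Gating is monotone —
#' raising the confidence never removes a pixel that survived thresholding.
#'
#' @param probs 2D probability map.
#' @param confidence scalar in \[0, 1\].
#' @return elementwise `confidence * probs`.
#' @export
gate_by_confidence <- function(probs, confidence) {
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must lie in [0, 1]")
  confidence * probs
}

#' Stack 2D masks into a label volume
#'
#' Slices are stacked along the third (axial) axis in the order given,
#' reconstructing the 3D segmentation from the per-slice predictions.
#'
#' @param masks list of integer label matrices of a common shape.
#' @param spacing_mm per-axis spacing of the resulting volume.
#' @return a [label_volume()].
#' @export
stack_slices <- function(masks, spacing_mm = c(1, 1, 1)) {
  if (length(masks) < 1L) stop("need at least one slice")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), TRUE)))
    stop("all slices must share the same shape")
  lab <- array(unlist(masks, use.names = FALSE), c(d[1], d[2], length(masks)))
  storage.mode(lab) <- "integer"
  label_volume(lab, spacing_mm)
}

#' Segment a CT volume with the assembled pipeline
#'
#' Per axial slice: the slice is converted to HU and windowed twice — at
#' level 40 / width 200 for the upward bone network and the classifier, and
#' at level 500 / width 1000 for the main femur network. Both windowed
#' slices are mid-split into mirrored halves; the upward net produces bone
#' probabilities and the fusion features, the main net (fused) produces
#' femur probabilities, and the classifier produces a per-slice femur
#' confidence that multiplies the reassembled femur map before thresholding.
#' Slices are re-stacked in their original order: femur = 1, remaining bone
#' (the upward bone mask minus the femur) = 2.
#'
#' @param ct a [ct_volume()].
#' @param pipeline an assembled `hs_pipeline` (see [assemble()]).
#' @param threshold femur decision threshold in (0, 1), default 0.5.
#' @param windows list with `bone` and `femur` [window_spec()]s.
#' @param postprocess keep only the largest 6-connected femur component,
#'   reassigning discarded voxels to the other-bone class where the bone map
#'   supports them. Off by default: the classifier gating is the intended
#'   false-positive control.
#' @return object of class `segmentation_result`: list with
#'   `per_slice_probs` (gated femur probability maps at the original slice
#'   size), `per_slice_confidence`, `labels3d` (a [label_volume()]) and
#'   `threshold`.
#' @export
segment_volume <- function(ct, pipeline, threshold = 0.5,
                           windows = default_windows(), postprocess = FALSE) {
  stopifnot(inherits(ct, "ct_volume"), inherits(pipeline, "hs_pipeline"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  d <- dim(ct$stored)
  nr <- pipeline$input_size[1]; nc <- pipeline$input_size[2]
  hu <- hu_values(ct)
  ns <- d[3]
  bone_full <- vector("list", ns)
  femur_halves <- vector("list", 2L * ns)
  bone_halves <- vector("list", 2L * ns)
  for (s in seq_len(ns)) {
    bone_img <- resize_slice(apply_window(hu[, , s], windows$bone), c(nr, nc))
    femur_img <- resize_slice(apply_window(hu[, , s], windows$femur), c(nr, nc))
    bone_full[[s]] <- bone_img
    bh <- split_and_flip(bone_img); fh <- split_and_flip(femur_img)
    bone_halves[[2L * s - 1L]] <- bh$left; bone_halves[[2L * s]] <- bh$right
    femur_halves[[2L * s - 1L]] <- fh$left; femur_halves[[2L * s]] <- fh$right
  }
  up <- network_predict(pipeline$upward, .stack4(bone_halves))
  mn <- network_predict(pipeline$main, .stack4(femur_halves),
                        fusion = up$features)
  femur_prob_h <- mn[[length(mn)]]
  conf <- network_predict(pipeline$classifier, .stack4(bone_full))
  probs <- vector("list", ns)
  masks <- vector("list", ns)
  bones <- vector("list", ns)
  for (s in seq_len(ns)) {
    fp <- unsplit_and_flip(femur_prob_h[, , 2L * s - 1L, 1],
                           femur_prob_h[, , 2L * s, 1])
    bp <- unsplit_and_flip(up$prob[, , 2L * s - 1L, 1],
                           up$prob[, , 2L * s, 1])
    fp <- resize_slice(fp, d[1:2])
    bp <- resize_slice(bp, d[1:2])
    gated <- gate_by_confidence(fp, conf[s])
    femur <- gated >= threshold
    bone <- bp >= 0.5
    m <- matrix(0L, d[1], d[2])
    m[bone & !femur] <- 2L
    m[femur] <- 1L
    probs[[s]] <- gated
    masks[[s]] <- m
    bones[[s]] <- bone
  }
  if (postprocess && any(vapply(masks, function(m) any(m == 1L), TRUE))) {
    lab3 <- array(unlist(masks, use.names = FALSE), d)
    keep <- .largest_component6(lab3 == 1L)
    drop <- lab3 == 1L & !keep
    # a discarded blob that the bone map still supports becomes other bone
    bone3 <- array(unlist(bones, use.names = FALSE), d)
    lab3[drop] <- 0L
    lab3[drop & bone3] <- 2L
    masks <- lapply(seq_len(d[3]), function(s) lab3[, , s])
  }
  structure(list(per_slice_probs = probs,
                 per_slice_confidence = conf,
                 labels3d = stack_slices(masks, ct$spacing_mm),
                 threshold = threshold),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  d <- dim(x$labels3d$labels)
  cat(sprintf(
    "<segmentation_result> %d slices (%d x %d), threshold %.2f, %d femur voxels\n",
    d[3], d[1], d[2], x$threshold, sum(x$labels3d$labels == 1L)))
  invisible(x)
}

# largest 6-connected component of a logical 3D mask (BFS over voxel indices)
.largest_component6 <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  best <- integer(0)
  for (s in which(mask)) {
    if (visited[s]) next
    comp <- integer(0)
    frontier <- s
    visited[s] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      ai <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (ax in 1:3) for (o in c(-1L, 1L)) {
        ok <- ai[, ax] + o >= 1L & ai[, ax] + o <= d[ax]
        cand <- frontier[ok] + o * strides[ax]
        cand <- cand[mask[cand] & !visited[cand]]
        if (length(cand)) {
          visited[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- array(FALSE, d)
  out[best] <- TRUE
  out
}
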