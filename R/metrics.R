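#' Voxel set with physical spacing
#'
#' A set of unique integer voxel coordinates (2D or 3D) plus per-axis spacing
#' in mm. Physical position of a voxel is `coordinate * spacing` per axis, so
#' all distance metrics incorporate the real spatial resolution.
#'
#' @param coords integer matrix, one voxel per row (2 or 3 columns).
#' @param spacing_mm per-axis spacing in mm (recycled scalar allowed).
#' @return An object of class `voxel_set`.
#' @export
voxel_set <- function(coords, spacing_mm = 1) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  coords <- as.matrix(coords)
  if (!ncol(coords) %in% c(2L, 3L)) stop("coordinates must be 2- or 3-tuples")
  if (anyDuplicated(coords)) coords <- unique(coords)
  spacing_mm <- rep_len(as.numeric(spacing_mm), ncol(coords))
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  structure(list(coords = coords, spacing_mm = spacing_mm), class = "voxel_set")
}

.vs_size <- function(a) nrow(a$coords)

.vs_key <- function(coords) {
  # collision-free integer key for set operations
  apply(coords, 1L, paste, collapse = ",")
}

#' Dice overlap coefficient
#'
#' `DOC = 2|AS n GT| / (|AS| + |GT|)` where `|.|` counts voxels. Symmetric,
#' in \[0, 1\].
#'
#' @param as_set,gt_set [voxel_set()]s (automatic segmentation and ground
#'   truth). Binary arrays of identical shape are also accepted.
#' @return Dice fraction in \[0, 1\].
#' @export
doc <- function(as_set, gt_set) {
  if (is.array(as_set) && is.array(gt_set)) {
    if (!all(dim(as_set) == dim(gt_set))) stop("arrays must share shape")
    na <- sum(as_set != 0); nb <- sum(gt_set != 0)
    if (na + nb == 0) stop("DOC undefined: both sets empty")
    return(2 * sum(as_set != 0 & gt_set != 0) / (na + nb))
  }
  stopifnot(inherits(as_set, "voxel_set"), inherits(gt_set, "voxel_set"))
  na <- .vs_size(as_set); nb <- .vs_size(gt_set)
  if (na + nb == 0) stop("DOC undefined: both sets empty")
  inter <- sum(.vs_key(as_set$coords) %in% .vs_key(gt_set$coords))
  2 * inter / (na + nb)
}

# All one-sided nearest distances from rows of A to the set B (mm), chunked
# so the pairwise matrix never exceeds ~8M doubles.
.min_dists_mm <- function(A, B, spacing_mm) {
  As <- sweep(A, 2L, spacing_mm, `*`)
  Bs <- sweep(B, 2L, spacing_mm, `*`)
  nb <- nrow(Bs)
  b2 <- rowSums(Bs^2)
  chunk <- max(1L, floor(8e6 / nb))
  out <- numeric(nrow(As))
  i <- 1L
  while (i <= nrow(As)) {
    j <- min(i + chunk - 1L, nrow(As))
    Ac <- As[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * Ac %*% t(Bs)
    d2[d2 < 0] <- 0  # numerical negatives
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

#' Distance from a voxel to a voxel set
#'
#' `d(x, A) = min over y in A of d(x, y)` with `d` the Euclidean distance of
#' voxel positions scaled by the per-axis spacing.
#'
#' @param x integer coordinate vector (or 1-row matrix).
#' @param a a nonempty [voxel_set()].
#' @return distance in mm.
#' @export
point_to_set_distance <- function(x, a) {
  stopifnot(inherits(a, "voxel_set"))
  if (.vs_size(a) == 0) stop("distance to an empty set is undefined")
  x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != ncol(a$coords)) stop("dimension mismatch")
  .min_dists_mm(x, a$coords, a$spacing_mm)
}

.check_pair <- function(a, b) {
  stopifnot(inherits(a, "voxel_set"), inherits(b, "voxel_set"))
  if (.vs_size(a) == 0 || .vs_size(b) == 0)
    stop("distance metrics are undefined for empty sets")
  if (ncol(a$coords) != ncol(b$coords)) stop("dimension mismatch")
  if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm)))
    stop("voxel sets must share spacing")
}

#' Directed Hausdorff distance
#'
#' `max over x in A of d(x, B)` in mm; equals the O(|A||B|) brute force
#' exactly (the implementation is a blocked evaluation of the same double
#' minimisation).
#'
#' @param a,b nonempty [voxel_set()]s with equal spacing.
#' @return distance in mm.
#' @export
directed_hausdorff <- function(a, b) {
  .check_pair(a, b)
  max(.min_dists_mm(a$coords, b$coords, a$spacing_mm))
}

#' Symmetric Hausdorff distance
#'
#' `HD = max(directed(A,B), directed(B,A))`.
#'
#' @inheritParams directed_hausdorff
#' @return distance in mm.
#' @export
hausdorff <- function(a, b) {
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' Mean (average symmetric) surface distance
#'
#' `( sum_{x in A} d(x,B) + sum_{y in B} d(y,A) ) / (|A| + |B|)` in mm.
#'
#' @inheritParams directed_hausdorff
#' @return distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  .check_pair(a, b)
  dab <- .min_dists_mm(a$coords, b$coords, a$spacing_mm)
  dba <- .min_dists_mm(b$coords, a$coords, a$spacing_mm)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

#' Extract the surface voxels of a labelled structure
#'
#' A voxel of the class is a surface voxel when at least one face-adjacent
#' neighbour (6-connectivity in 3D, 4-connectivity in 2D; volume boundary
#' counts as outside) does not belong to the class.
#'
#' @param mask a [label_volume()], or an integer array (2D or 3D).
#' @param class the label value whose surface is extracted (default 1).
#' @param spacing_mm spacing for plain arrays (taken from the `label_volume`
#'   otherwise).
#' @return a [voxel_set()] of surface voxel indices (1-based array indices).
#' @export
extract_surface <- function(mask, class = 1L, spacing_mm = 1) {
  if (inherits(mask, "label_volume")) {
    spacing_mm <- mask$spacing_mm
    mask <- mask$labels
  }
  d <- dim(mask)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  inside <- mask == class
  if (!any(inside)) stop("class ", class, " absent from mask")
  # pad with FALSE so the array boundary is outside
  pd <- d + 2L
  pad <- array(FALSE, pd)
  idx <- lapply(d, function(n) seq_len(n) + 1L)
  if (nd == 2L) pad[idx[[1]], idx[[2]]] <- inside
  else pad[idx[[1]], idx[[2]], idx[[3]]] <- inside
  all_nb <- array(TRUE, pd)
  for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
    sh <- .shift_arr(pad, ax, s)
    all_nb <- all_nb & sh
  }
  interior <- pad & all_nb
  surf <- pad & !interior
  w <- which(if (nd == 2L) surf[idx[[1]], idx[[2]]]
             else surf[idx[[1]], idx[[2]], idx[[3]]], arr.ind = TRUE)
  voxel_set(w, spacing_mm)
}

# shift array along axis by s, filling with FALSE
.shift_arr <- function(x, axis, s) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (s > 0) { dst[[axis]] <- (1L + s):n; src[[axis]] <- 1L:(n - s) }
  else { dst[[axis]] <- 1L:(n + s); src[[axis]] <- (1L - s):n }
  if (length(d) == 2L) out[dst[[1]], dst[[2]]] <- x[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per structure class (femur = 1, other bone = 2): Dice overlap on the full
#' voxel sets, and Hausdorff / mean surface distance on the extracted
#' surfaces, in mm (or voxel units with `units = "px"`). An empty predicted
#' class yields DOC 0 with the distance metrics flagged undefined (`NA`),
#' never infinite.
#'
#' @param pred,gt [label_volume()]s of identical shape and spacing.
#' @param classes integer labels to evaluate (default `c(1, 2)`).
#' @param units `"mm"` (physical, default) or `"px"` (unit spacing).
#' @return object of class `metric_report`: a list per class with `doc`,
#'   `directed_hd_mm` (pred-to-gt, gt-to-pred), `hd_mm`, `msd_mm`, `defined`.
#' @export
evaluate_case <- function(pred, gt, classes = c(1L, 2L), units = c("mm", "px")) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"))
  units <- match.arg(units)
  if (!all(dim(pred$labels) == dim(gt$labels))) stop("shape mismatch")
  if (!isTRUE(all.equal(pred$spacing_mm, gt$spacing_mm))) stop("spacing mismatch")
  sp <- if (units == "mm") pred$spacing_mm else rep(1, 3)
  out <- lapply(classes, function(cl) {
    p <- pred$labels == cl
    g <- gt$labels == cl
    np <- sum(p); ng <- sum(g)
    if (ng == 0 && np == 0)
      return(list(doc = NA_real_, directed_hd_mm = c(NA_real_, NA_real_),
                  hd_mm = NA_real_, msd_mm = NA_real_, defined = FALSE))
    dc <- 2 * sum(p & g) / (np + ng)
    if (np == 0 || ng == 0)
      return(list(doc = dc, directed_hd_mm = c(NA_real_, NA_real_),
                  hd_mm = NA_real_, msd_mm = NA_real_, defined = FALSE))
    ps <- extract_surface(pred$labels, cl, sp)
    gs <- extract_surface(gt$labels, cl, sp)
    dab <- directed_hausdorff(ps, gs)
    dba <- directed_hausdorff(gs, ps)
    list(doc = dc, directed_hd_mm = c(dab, dba), hd_mm = max(dab, dba),
         msd_mm = mean_surface_distance(ps, gs), defined = TRUE)
  })
  names(out) <- as.character(classes)
  structure(out, class = "metric_report", units = units)
}

#' @export
print.metric_report <- function(x, ...) {
  u <- attr(x, "units")
  cat("<metric_report> (", u, ")\n", sep = "")
  for (cl in names(x)) {
    m <- x[[cl]]
    cat(sprintf("  class %s: DOC %.4f  HD %.3f  MSD %.3f%s\n", cl,
                m$doc, m$hd_mm, m$msd_mm,
                if (!isTRUE(m$defined)) "  [distances undefined]" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(
    class = as.integer(names(x)),
    doc = vapply(x, `[[`, 0, "doc"),
    hd = vapply(x, `[[`, 0, "hd_mm"),
    msd = vapply(x, `[[`, 0, "msd_mm"),
    defined = vapply(x, `[[`, TRUE, "defined"),
    row.names = NULL
  )
}
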