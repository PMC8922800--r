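#' Hip phantom specification
#'
#' Parametric description of a procedurally generated hip-like CT volume:
#' a femur (spherical head, neck and shaft cylinders; label 1) articulating
#' with an acetabular cup plus iliac slab (label 2) inside a soft-tissue
#' body, surrounded by air. Intensities are Hounsfield means with additive
#' Gaussian noise, quantized to the stored 12-bit range. Conditions `OA`,
#' `DDH`, `FNF` and `ONFH` apply disease-like deformations to the normal
#' geometry (see [apply_disease_deformation()]).
#'
#' Invariants enforced: all shape components >= 16; positive spacing;
#' `joint_gap_mm > 0` (femur and pelvis stay disjoint); and
#' `cortical_hu > 200 > soft_tissue_hu` so that bone survives the 200 HU
#' threshold while soft tissue does not.
#'
#' @param shape integer length-3 `(rows, cols, slices)`; slices is the axial
#'   axis. Default 64 x 64 x 60, a reduced-scale stand-in for clinical
#'   512 x 512 scans with 200-600 slices; full size is supported.
#' @param spacing_mm per-axis voxel spacing in mm (default 1 mm isotropic,
#'   matching 1 mm slice thickness).
#' @param condition one of `"normal"`, `"OA"`, `"DDH"`, `"FNF"`, `"ONFH"`.
#' @param femur_head_radius_mm femoral head radius (mm); default 15% of the
#'   smallest volume extent (9 mm at the default 64 x 64 x 60 / 1 mm scale).
#' @param joint_gap_mm minimal femur-to-pelvis clearance (mm).
#' @param cortical_hu,trabecular_hu,soft_tissue_hu,air_hu tissue HU means.
#' @param noise_sd_hu Gaussian intensity noise SD (HU), >= 0.
#' @param seed integer RNG seed; identical spec + seed reproduce the volume
#'   bitwise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 60), spacing_mm = c(1, 1, 1),
                         condition = c("normal", "OA", "DDH", "FNF", "ONFH"),
                         femur_head_radius_mm = NULL, joint_gap_mm = 2,
                         cortical_hu = 1200, trabecular_hu = 300,
                         soft_tissue_hu = 40, air_hu = -1000,
                         noise_sd_hu = 30, seed = 1L) {
  condition <- match.arg(condition)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("invariant violated: all shape components must be >= 16")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("invariant violated: spacing components must be > 0")
  if (is.null(femur_head_radius_mm))
    femur_head_radius_mm <- 0.15 * min(shape * spacing_mm)
  if (!is.finite(joint_gap_mm) || joint_gap_mm <= 0)
    stop("invariant violated: joint_gap_mm must be > 0")
  if (!(cortical_hu > 200))
    stop("invariant violated: cortical_hu must exceed the 200 HU bone threshold")
  if (!(soft_tissue_hu < 200))
    stop("invariant violated: soft_tissue_hu must lie below the 200 HU bone threshold")
  if (femur_head_radius_mm <= 0) stop("invariant violated: femur_head_radius_mm must be > 0")
  if (noise_sd_hu < 0) stop("invariant violated: noise_sd_hu must be >= 0")
  structure(list(
    shape = shape, spacing_mm = spacing_mm, condition = condition,
    femur_head_radius_mm = femur_head_radius_mm, joint_gap_mm = joint_gap_mm,
    cortical_hu = cortical_hu, trabecular_hu = trabecular_hu,
    soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
    noise_sd_hu = noise_sd_hu, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# voxel-centre world coordinates (mm) as three arrays
.phantom_grid <- function(shape, spacing) {
  x <- (seq_len(shape[1]) - 0.5) * spacing[1]
  y <- (seq_len(shape[2]) - 0.5) * spacing[2]
  z <- (seq_len(shape[3]) - 0.5) * spacing[3]
  list(
    x = array(rep(x, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
    z = array(rep(z, each = shape[1] * shape[2]), shape)
  )
}

# signed-ish distance to a capped cylinder segment p0->p1 of given radius:
# <= 0 inside
.cyl_dist <- function(g, p0, p1, radius) {
  ax <- p1 - p0
  len2 <- sum(ax^2)
  t <- ((g$x - p0[1]) * ax[1] + (g$y - p0[2]) * ax[2] + (g$z - p0[3]) * ax[3]) / len2
  t[t < 0] <- 0
  t[t > 1] <- 1
  dx <- g$x - (p0[1] + t * ax[1])
  dy <- g$y - (p0[2] + t * ax[2])
  dz <- g$z - (p0[3] + t * ax[3])
  sqrt(dx^2 + dy^2 + dz^2) - radius
}

.sphere_dist <- function(g, c0, radius) {
  sqrt((g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2) - radius
}

# draw n uniforms deterministically from `seed` without disturbing the
# caller's RNG stream
.seeded_runif <- function(seed, n, min = 0, max = 1) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, min, max)
}

# landmark geometry shared by the rasterizer; extents in mm. Each case gets
# mild seeded anatomical variability (head position and radius, cup axis
# tilt, iliac position) so phantoms differ in geometry, not just in noise.
.phantom_geometry <- function(spec) {
  e <- spec$shape * spec$spacing_mm
  j <- .seeded_runif(spec$seed, 8L, -1, 1)
  rh <- spec$femur_head_radius_mm * (1 + 0.10 * j[1])
  off <- c(0.03 * e[1] * j[2], 0.03 * e[2] * j[3], 0.04 * e[3] * j[4])
  ax <- c(0.1 * j[5], 0.2 + 0.08 * j[6], 1)
  list(
    extent = e,
    head = c(0.50 * e[1], 0.42 * e[2], 0.60 * e[3]) + off,
    neck_base = c(0.50 * e[1], 0.56 * e[2], 0.46 * e[3]) + off,
    shaft_end = c(0.50 * e[1], 0.60 * e[2], 0.04 * e[3]) + off * c(1, 1, 0),
    head_r = rh, neck_r = 0.45 * rh, shaft_r = 0.55 * rh,
    cup_axis = ax / sqrt(sum(ax^2)),
    cup_thickness = 3,
    iliac_c = c((0.50 + 0.02 * j[7]) * e[1], (0.62 + 0.02 * j[8]) * e[2],
                0.90 * e[3]),
    iliac_sa = c(0.28 * e[1], 0.15 * e[2], 0.12 * e[3]),
    body_c = e[1:2] / 2, body_sa = 0.46 * e[1:2]
  )
}

#' Generate a labelled hip phantom CT volume
#'
#' Rasterizes the parametric hip geometry of `spec`, applies the requested
#' disease-like deformation to the labels, then synthesizes intensities from
#' the final labels: air outside an elliptical body, soft tissue inside,
#' trabecular bone in structure interiors and cortical bone in a ~1.5 mm
#' surface shell, plus Gaussian noise, quantized to stored 12-bit values.
#' Femur (label 1) and pelvis (label 2) are kept at least `joint_gap_mm`
#' apart; a contiguous run of superior slices contains no femur, giving the
#' slice classifier genuine negatives.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` ([ct_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- .phantom_labels_normal(spec)
  if (spec$condition != "normal")
    labels <- apply_disease_deformation(labels, spec$condition, spec$seed,
                                        joint_gap_mm = spec$joint_gap_mm)
  ct <- .phantom_intensities(spec, labels)
  list(ct = ct, labels = labels)
}

.phantom_labels_normal <- function(spec) {
  g <- .phantom_grid(spec$shape, spec$spacing_mm)
  geo <- .phantom_geometry(spec)
  # analytic distance to the femur surface: min over its three primitives
  fd <- pmin(
    .sphere_dist(g, geo$head, geo$head_r),
    .cyl_dist(g, geo$head, geo$neck_base, geo$neck_r),
    .cyl_dist(g, geo$neck_base, geo$shaft_end, geo$shaft_r)
  )
  femur <- fd <= 0
  # acetabular cup: hemispherical shell opening toward the head
  rad <- .sphere_dist(g, geo$head, 0)  # distance to head centre
  shell <- rad >= geo$head_r + spec$joint_gap_mm &
    rad <= geo$head_r + spec$joint_gap_mm + geo$cup_thickness
  dirdot <- ((g$x - geo$head[1]) * geo$cup_axis[1] +
             (g$y - geo$head[2]) * geo$cup_axis[2] +
             (g$z - geo$head[3]) * geo$cup_axis[3]) / pmax(rad, 1e-9)
  cup <- shell & dirdot >= 0.25
  iliac <- ((g$x - geo$iliac_c[1]) / geo$iliac_sa[1])^2 +
    ((g$y - geo$iliac_c[2]) / geo$iliac_sa[2])^2 +
    ((g$z - geo$iliac_c[3]) / geo$iliac_sa[3])^2 <= 1
  pelvis <- (cup | iliac) & fd >= spec$joint_gap_mm  # enforce the joint gap
  lab <- array(0L, spec$shape)
  lab[femur] <- 1L
  lab[pelvis] <- 2L
  label_volume(lab, spec$spacing_mm)
}

.phantom_intensities <- function(spec, labels) {
  g <- .phantom_grid(spec$shape, spec$spacing_mm)
  geo <- .phantom_geometry(spec)
  body <- ((g$x - geo$body_c[1]) / geo$body_sa[1])^2 +
    ((g$y - geo$body_c[2]) / geo$body_sa[2])^2 <= 1
  hu <- array(spec$air_hu, spec$shape)
  hu[body] <- spec$soft_tissue_hu
  bone <- labels$labels > 0L
  shell_vox <- max(1L, round(1.5 / min(spec$spacing_mm)))
  interior <- bone
  for (k in seq_len(shell_vox)) interior <- .erode6(interior)
  hu[bone] <- spec$cortical_hu
  hu[interior] <- spec$trabecular_hu
  set.seed(spec$seed)
  if (spec$noise_sd_hu > 0)
    hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd_hu), spec$shape)
  ct_volume(quantize_to_stored(hu), spec$spacing_mm)
}

# one step of 6-connected binary erosion (boundary treated as background)
.erode6 <- function(m) {
  out <- m
  for (ax in 1:3) for (s in c(-1L, 1L)) out <- out & .shift_arr(m, ax, s)
  out
}

# --- label-space helpers for the disease deformations ---------------------

.femur_landmarks <- function(labels) {
  sp <- labels$spacing_mm
  idx <- which(labels$labels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("labels contain no femur component")
  pos <- sweep(idx - 0.5, 2L, sp, `*`)
  zr <- range(pos[, 3])
  head_sel <- pos[, 3] >= zr[1] + 0.72 * diff(zr)
  shaft_sel <- pos[, 3] <= zr[1] + 0.40 * diff(zr)
  head_c <- colMeans(pos[head_sel, , drop = FALSE])
  shaft_c <- colMeans(pos[shaft_sel, , drop = FALSE])
  head_r <- (3 * sum(head_sel) * prod(sp) / (4 * pi))^(1 / 3)
  list(idx = idx, pos = pos, head_c = head_c, shaft_c = shaft_c,
       head_r = head_r, spacing = sp)
}

# minimal distance (mm) from candidate voxel indices to a target mask
.dist_to_mask <- function(cand_idx, mask, spacing) {
  tgt <- which(mask, arr.ind = TRUE)
  if (nrow(tgt) == 0L) return(rep(Inf, nrow(cand_idx)))
  .min_dists_mm(cand_idx, tgt, spacing)
}

#' Apply a disease-like deformation to hip labels
#'
#' Phantom analogues of the four diseased-hip categories: `OA` adds
#' osteophyte-like rim protrusions to femur and acetabulum; `ONFH` collapses
#' the superior femoral head with a crater; `FNF` inserts a background gap
#' through the femoral neck (the femur splits into head and shaft
#' components); `DDH` translates the femur superolaterally, reducing cup
#' coverage of the head; `normal` is the identity. Femur/pelvis disjointness
#' (clearance >= `joint_gap_mm`) is preserved.
#'
#' @param labels a [label_volume()] containing a femur (class 1).
#' @param condition one of `"normal"`, `"OA"`, `"DDH"`, `"FNF"`, `"ONFH"`.
#' @param seed integer seed for the (seeded, reproducible) random placements.
#' @param joint_gap_mm clearance to preserve between classes 1 and 2 (mm).
#' @return a deformed [label_volume()].
#' @export
apply_disease_deformation <- function(labels, condition, seed = 1L,
                                      joint_gap_mm = 2) {
  stopifnot(inherits(labels, "label_volume"))
  if (!is.character(condition) ||
      !condition %in% c("normal", "OA", "DDH", "FNF", "ONFH"))
    stop("unknown condition: ", paste(condition, collapse = ", "))
  if (condition == "normal") return(labels)
  if (!any(labels$labels == 1L)) stop("labels contain no femur component")
  set.seed(as.integer(seed))
  switch(condition,
    FNF = .deform_fnf(labels),
    ONFH = .deform_onfh(labels),
    DDH = .deform_ddh(labels, joint_gap_mm),
    OA = .deform_oa(labels, joint_gap_mm)
  )
}

.deform_fnf <- function(labels) {
  lm <- .femur_landmarks(labels)
  n <- lm$head_c - lm$shaft_c
  n <- n / sqrt(sum(n^2))
  t_all <- as.vector(lm$pos %*% n)
  t_head <- sum(lm$head_c * n)
  t_cut <- t_head - 1.45 * lm$head_r
  in_gap <- abs(t_all - t_cut) <= 1.0  # 2 mm fracture gap
  lab <- labels$labels
  lab[lm$idx[in_gap, , drop = FALSE]] <- 0L
  label_volume(lab, labels$spacing_mm, labels$class_map)
}

.deform_onfh <- function(labels) {
  lm <- .femur_landmarks(labels)
  up <- lm$head_c - lm$shaft_c
  up <- up / sqrt(sum(up^2))
  pole <- lm$head_c + up * lm$head_r
  d <- sqrt(colSums((t(lm$pos) - pole)^2))
  lab <- labels$labels
  lab[lm$idx[d <= 0.55 * lm$head_r, , drop = FALSE]] <- 0L
  label_volume(lab, labels$spacing_mm, labels$class_map)
}

.deform_ddh <- function(labels, joint_gap_mm) {
  lm <- .femur_landmarks(labels)
  sp <- lm$spacing
  ext <- dim(labels$labels) * sp
  # superolateral: away from the midline cup (lower y = lateral here), upward
  shift_mm <- c(0, -0.09 * ext[2], 0.04 * ext[3])
  shift_vox <- round(shift_mm / sp)
  d <- dim(labels$labels)
  new_idx <- sweep(lm$idx, 2L, shift_vox, `+`)
  ok <- new_idx[, 1] >= 1 & new_idx[, 1] <= d[1] &
    new_idx[, 2] >= 1 & new_idx[, 2] <= d[2] &
    new_idx[, 3] >= 1 & new_idx[, 3] <= d[3]
  new_idx <- new_idx[ok, , drop = FALSE]
  lab <- labels$labels
  lab[lm$idx] <- 0L
  pelvis <- lab == 2L
  land_on_pelvis <- lab[new_idx] == 2L
  clear <- .dist_to_mask(new_idx, pelvis, sp) >= joint_gap_mm
  keep <- new_idx[!land_on_pelvis & clear, , drop = FALSE]
  lab[keep] <- 1L
  label_volume(lab, labels$spacing_mm, labels$class_map)
}

.deform_oa <- function(labels, joint_gap_mm, n_bumps = 5L, bump_r = 2.2) {
  lm <- .femur_landmarks(labels)
  sp <- lm$spacing
  lab <- labels$labels
  # femoral rim osteophytes: seed points on the head equator band
  band <- lm$pos[abs(lm$pos[, 3] - lm$head_c[3]) <= 0.35 * lm$head_r &
                   sqrt(rowSums(sweep(lm$pos, 2L, lm$head_c, `-`)^2)) >=
                   0.8 * lm$head_r, , drop = FALSE]
  lab <- .add_bumps(lab, band, n_bumps, bump_r, new_class = 1L,
                    other_mask = lab == 2L, joint_gap_mm, sp)
  # acetabular rim osteophytes: pelvis voxels near the cup opening
  pel <- which(lab == 2L, arr.ind = TRUE)
  pel_pos <- sweep(pel - 0.5, 2L, sp, `*`)
  dhead <- sqrt(rowSums(sweep(pel_pos, 2L, lm$head_c, `-`)^2))
  rim <- pel_pos[dhead <= lm$head_r + joint_gap_mm + 4 &
                   pel_pos[, 3] <= lm$head_c[3] + 0.5 * lm$head_r, , drop = FALSE]
  lab <- .add_bumps(lab, rim, n_bumps, bump_r, new_class = 2L,
                    other_mask = lab == 1L, joint_gap_mm, sp)
  label_volume(lab, labels$spacing_mm, labels$class_map)
}

# grow small spherical protrusions of `new_class` from seed surface positions,
# claiming only background voxels at >= joint_gap_mm from the other structure
.add_bumps <- function(lab, seed_pos, n_bumps, bump_r, new_class,
                       other_mask, joint_gap_mm, sp) {
  if (nrow(seed_pos) == 0L) return(lab)
  pick <- seed_pos[sample.int(nrow(seed_pos), min(n_bumps, nrow(seed_pos))), ,
                   drop = FALSE]
  d <- dim(lab)
  for (i in seq_len(nrow(pick))) {
    c0 <- pick[i, ]
    lo <- pmax(ceiling((c0 - bump_r) / sp), 1)
    hi <- pmin(floor((c0 + bump_r) / sp + 1), d)
    cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    pos <- sweep(cand - 0.5, 2L, sp, `*`)
    inside <- sqrt(rowSums(sweep(pos, 2L, c0, `-`)^2)) <= bump_r
    cand <- cand[inside & lab[cand] == 0L, , drop = FALSE]
    if (nrow(cand) == 0L) next
    clear <- .dist_to_mask(cand, other_mask, sp) >= joint_gap_mm
    lab[cand[clear, , drop = FALSE]] <- new_class
  }
  lab
}

#' Write a batch of phantom cases to disk
#'
#' Generates `n` phantoms (seeds `seed, seed+1, ...`), writing paired NIfTI
#' files `case_XXXX_img.nii.gz` / `case_XXXX_lbl.nii.gz` plus a tab-separated
#' `manifest.tsv` (columns id, condition, seed) under `out_dir`.
#'
#' @param n number of cases.
#' @param condition phantom condition for every case, or `"mixed"` to cycle
#'   through all five conditions.
#' @param shape volume shape passed to [phantom_spec()].
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame.
#' @export
make_phantoms <- function(n, condition = "normal", shape = c(64, 64, 60),
                          seed = 1L, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- if (identical(condition, "mixed"))
    rep_len(c("normal", "OA", "DDH", "FNF", "ONFH"), n)
  else rep_len(condition, n)
  rows <- lapply(seq_len(n), function(i) {
    id <- sprintf("case_%04d", i)
    sp <- phantom_spec(shape = shape, condition = conds[i], seed = seed + i - 1L)
    ph <- generate_phantom(sp)
    write_volume(ph$ct, file.path(out_dir, paste0(id, "_img.nii.gz")))
    write_labels(ph$labels, file.path(out_dir, paste0(id, "_lbl.nii.gz")))
    data.frame(id = id, condition = conds[i], seed = seed + i - 1L)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
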