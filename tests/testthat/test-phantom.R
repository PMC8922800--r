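test_that("phantom_spec validates its invariants with informative errors", {
  expect_error(phantom_spec(shape = c(8, 64, 64)), ">= 16")
  expect_error(phantom_spec(spacing_mm = c(1, -1, 1)), "spacing")
  expect_error(phantom_spec(joint_gap_mm = 0), "joint_gap")
  expect_error(phantom_spec(cortical_hu = 150), "200 HU")
  expect_error(phantom_spec(soft_tissue_hu = 300), "200 HU")
  expect_error(phantom_spec(noise_sd_hu = -1), "noise")
  expect_error(phantom_spec(condition = "arthritis"), "should be one of")
})

test_that("generated phantoms satisfy the shape, label and determinism contracts", {
  sp <- phantom_spec(shape = c(64, 64, 60), seed = 7)
  ph <- generate_phantom(sp)
  expect_identical(dim(ph$ct$stored), c(64L, 64L, 60L))
  expect_identical(dim(ph$labels$labels), dim(ph$ct$stored))
  expect_true(all(ph$labels$labels %in% 0:2))
  expect_equal(ph$ct$spacing_mm, ph$labels$spacing_mm)
  # identical spec + seed: bitwise-identical volumes
  ph2 <- generate_phantom(sp)
  expect_identical(ph$ct$stored, ph2$ct$stored)
  expect_identical(ph$labels$labels, ph2$labels$labels)
  # a different seed changes the noise
  ph3 <- generate_phantom(phantom_spec(shape = c(64, 64, 60), seed = 8))
  expect_false(identical(ph$ct$stored, ph3$ct$stored))
})

test_that("every phantom has femur-positive and a contiguous run of femur-free slices", {
  for (seed in c(1, 9, 23)) {
    lab <- generate_phantom(phantom_spec(seed = seed))$labels$labels
    fem <- apply(lab == 1L, 3, any)
    expect_true(any(fem))
    expect_true(any(!fem))
    neg <- which(!fem)
    runs <- split(neg, cumsum(c(1, diff(neg) != 1)))
    expect_gte(max(lengths(runs)), 5)
  }
})

test_that("femur and pelvis stay disjoint with at least the joint gap", {
  for (cond in c("normal", "OA", "DDH", "FNF", "ONFH")) {
    ph <- generate_phantom(phantom_spec(condition = cond, seed = 3))
    lab <- ph$labels
    fs <- extract_surface(lab, 1)
    ps <- extract_surface(lab, 2)
    gap <- min(hipseg:::.min_dists_mm(fs$coords, ps$coords, fs$spacing_mm))
    expect_gte(gap, 2 - 1e-9)
  }
})

test_that("disease deformations produce their characteristic geometry", {
  norm <- generate_phantom(phantom_spec(seed = 3))
  # normal condition is the identity
  expect_identical(apply_disease_deformation(norm$labels, "normal", 1)$labels,
                   norm$labels$labels)
  expect_error(apply_disease_deformation(norm$labels, "fracture", 1), "condition")
  empty <- label_volume(array(0L, c(16, 16, 16)))
  expect_error(apply_disease_deformation(empty, "FNF", 1), "femur")
  # FNF: the femur splits into at least two connected components
  fnf <- generate_phantom(phantom_spec(condition = "FNF", seed = 3))
  expect_gte(component_count(fnf$labels$labels == 1L), 2)
  expect_equal(component_count(norm$labels$labels == 1L), 1)
  # ONFH: head volume shrinks (crater) but femur stays connected
  onfh <- generate_phantom(phantom_spec(condition = "ONFH", seed = 3))
  expect_lt(sum(onfh$labels$labels == 1L), sum(norm$labels$labels == 1L))
  expect_equal(component_count(onfh$labels$labels == 1L), 1)
  # OA: osteophytes add bone to both structures
  oa <- generate_phantom(phantom_spec(condition = "OA", seed = 3))
  expect_gt(sum(oa$labels$labels == 1L), sum(norm$labels$labels == 1L))
  expect_gt(sum(oa$labels$labels == 2L), sum(norm$labels$labels == 2L))
  # DDH: head centroid moves away from the acetabular centroid
  ddh <- generate_phantom(phantom_spec(condition = "DDH", seed = 3))
  head_centroid <- function(lab) {
    idx <- which(lab == 1L, arr.ind = TRUE)
    zr <- range(idx[, 3])
    colMeans(idx[idx[, 3] >= zr[1] + 0.72 * diff(zr), , drop = FALSE])
  }
  cup <- colMeans(which(norm$labels$labels == 2L, arr.ind = TRUE))
  d_norm <- sqrt(sum((head_centroid(norm$labels$labels) - cup)^2))
  d_ddh <- sqrt(sum((head_centroid(ddh$labels$labels) - cup)^2))
  expect_gt(d_ddh, d_norm)
})

test_that("make_phantoms writes paired NIfTI cases with a manifest", {
  td <- withr::local_tempdir()
  mf <- make_phantoms(3, condition = "mixed", shape = c(32, 32, 24),
                      seed = 11, out_dir = td)
  expect_equal(nrow(mf), 3)
  expect_true(file.exists(file.path(td, "manifest.tsv")))
  read_back <- utils::read.delim(file.path(td, "manifest.tsv"))
  expect_identical(names(read_back), c("id", "condition", "seed"))
  for (id in read_back$id) {
    ct <- read_volume(file.path(td, paste0(id, "_img.nii.gz")))
    lb <- read_labels(file.path(td, paste0(id, "_lbl.nii.gz")))
    expect_identical(dim(ct$stored), c(32L, 32L, 24L))
    expect_identical(dim(lb$labels), dim(ct$stored))
  }
})
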