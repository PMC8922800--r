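test_that("Dice overlap matches direct set counting", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE          # |AS| = 2
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1, 1] <- TRUE; b[3:4, 2, 1] <- TRUE
  expect_equal(doc(a, b), 2 * 2 / (2 + 4))                      # 2/3
  expect_equal(doc(b, b), 1)
  dis <- array(FALSE, c(4, 4, 4)); dis[4, 4, 4] <- TRUE
  expect_equal(doc(a, dis), 0)
  expect_error(doc(a & FALSE, b & FALSE), "empty")
  # voxel_set interface agrees with the array interface
  va <- voxel_set(which(a, arr.ind = TRUE)); vb <- voxel_set(which(b, arr.ind = TRUE))
  expect_equal(doc(va, vb), 2 / 3)
})

test_that("point-to-set distance uses spacing-scaled Euclidean metric", {
  a <- voxel_set(matrix(c(3, 4, 0), 1), spacing_mm = 1)
  expect_equal(point_to_set_distance(c(0, 0, 0), a), 5)
  expect_equal(point_to_set_distance(c(3, 4, 0), a), 0)
  a2 <- voxel_set(matrix(c(3, 4, 0), 1), spacing_mm = 2)
  expect_equal(point_to_set_distance(c(0, 0, 0), a2), 10)      # linear in spacing
})

test_that("Hausdorff and surface distances match hand-computed cases", {
  A <- voxel_set(matrix(c(0, 0), 1), spacing_mm = 1)
  B <- voxel_set(matrix(c(3, 4), 1), spacing_mm = 1)
  expect_equal(directed_hausdorff(A, B), 5)
  expect_equal(directed_hausdorff(B, A), 5)
  expect_equal(hausdorff(A, B), 5)
  expect_equal(mean_surface_distance(A, B), 5)                  # (5+5)/2
  # subset has zero directed distance, but not necessarily the reverse
  C <- voxel_set(rbind(c(0, 0), c(3, 4)), spacing_mm = 1)
  expect_equal(directed_hausdorff(A, C), 0)
  expect_equal(directed_hausdorff(C, A), 5)
  # unit-separated parallel segments
  s1 <- voxel_set(cbind(0:5, 0), spacing_mm = 1)
  s2 <- voxel_set(cbind(0:5, 1), spacing_mm = 1)
  expect_equal(hausdorff(s1, s2), 1)
})

test_that("all distance metrics agree exactly with O(N^2) brute force", {
  set.seed(701)
  for (rep in 1:100) {
    d3 <- sample(4:16, 3, replace = TRUE)
    sp <- sample(c(0.5, 1, 2), 3, replace = TRUE)
    ma <- random_mask(d3, p = 0.08)
    mb <- random_mask(d3, p = 0.08)
    A <- which(ma, arr.ind = TRUE); B <- which(mb, arr.ind = TRUE)
    va <- voxel_set(A, sp); vb <- voxel_set(B, sp)
    expect_equal(directed_hausdorff(va, vb), bf_directed_hausdorff(A, B, sp))
    expect_equal(hausdorff(va, vb), bf_hausdorff(A, B, sp))
    expect_equal(mean_surface_distance(va, vb), bf_msd(A, B, sp))
    expect_equal(doc(ma, mb), bf_doc(ma, mb))
    # invariants: symmetry, ordering, nonnegativity
    expect_equal(hausdorff(va, vb), hausdorff(vb, va))
    expect_gte(hausdorff(va, vb), mean_surface_distance(va, vb))
  }
})

test_that("surface extraction counts face-connected boundary voxels", {
  cube3 <- array(0L, c(5, 5, 5)); cube3[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(extract_surface(cube3, 1)$coords), 26)      # 3^3 - 1
  cube5 <- array(0L, c(7, 7, 7)); cube5[2:6, 2:6, 2:6] <- 1L
  expect_equal(nrow(extract_surface(cube5, 1)$coords), 5^3 - 3^3)
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_equal(extract_surface(single, 1)$coords,
               which(single == 1L, arr.ind = TRUE), ignore_attr = TRUE)
  # voxels on the array boundary are surface voxels
  full <- array(1L, c(2, 2, 2))
  expect_equal(nrow(extract_surface(full, 1)$coords), 8)
  expect_error(extract_surface(single, 2), "absent")
})

test_that("evaluate_case wraps the metrics per class with degenerate handling", {
  gt <- array(0L, c(12, 12, 6)); gt[4:8, 4:8, 2:4] <- 1L
  lv <- function(a, sp = c(1, 1, 1)) label_volume(a, sp)
  perfect <- evaluate_case(lv(gt), lv(gt))
  expect_equal(perfect[["1"]]$doc, 1)
  expect_equal(perfect[["1"]]$hd_mm, 0)
  expect_equal(perfect[["1"]]$msd_mm, 0)
  # dilation by one voxel at 1 mm spacing gives HD exactly 1 mm
  dil <- array(0L, c(12, 12, 6)); dil[3:9, 4:8, 2:4] <- 1L
  dil[4:8, 3:9, 2:4] <- 1L; dil[4:8, 4:8, 1:5] <- 1L
  rep1 <- evaluate_case(lv(dil), lv(gt))
  expect_equal(rep1[["1"]]$hd_mm, 1)
  # empty prediction: DOC 0, distances flagged undefined rather than infinite
  rep0 <- evaluate_case(lv(gt * 0L), lv(gt))
  expect_equal(rep0[["1"]]$doc, 0)
  expect_true(is.na(rep0[["1"]]$hd_mm))
  expect_false(rep0[["1"]]$defined)
  expect_error(evaluate_case(lv(gt), lv(gt[, , 1:5, drop = FALSE])), "shape")
  # px units equal mm at unit spacing and differ under anisotropy
  aniso <- evaluate_case(lv(dil, c(1, 1, 2)), lv(gt, c(1, 1, 2)))
  px <- evaluate_case(lv(dil, c(1, 1, 2)), lv(gt, c(1, 1, 2)), units = "px")
  expect_equal(px[["1"]]$hd_mm, 1)
  expect_gte(aniso[["1"]]$hd_mm, px[["1"]]$hd_mm)
})
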