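test_that("dice loss obeys its closed form and boundary behaviour", {
  t <- array(rbinom(200, 1, 0.3), c(10, 20))
  expect_lt(dice_loss(t, t), 1e-5)                 # perfect prediction
  expect_gt(dice_loss(1 - t, t), 1 - 1e-3)         # total miss
  # uniform 0.5 prediction against k ones on n pixels, computed directly
  n <- 200; k <- sum(t)
  p <- array(0.5, dim(t))
  expected <- 1 - (2 * 0.5 * k) / (0.5 * n + k)
  expect_equal(dice_loss(p, t), expected, tolerance = 1e-5)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("combined loss is linear in its weights and reduces to each term", {
  set.seed(21)
  p <- array(runif(64, 0.01, 0.99), c(4, 4, 4))
  t <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  ce <- combined_loss(p, t, loss_weights(a = 0, b = 1))
  di <- combined_loss(p, t, loss_weights(a = 1, b = 0))
  expect_equal(di, dice_loss(p, t))
  expect_equal(combined_loss(p, t, loss_weights(a = 1, b = 1)), di + ce)
  expect_equal(combined_loss(p, t, loss_weights(a = 2, b = 2)),
               2 * combined_loss(p, t, loss_weights(a = 1, b = 1)))
  expect_error(loss_weights(a = 0, b = 0), "a \\+ b")
  expect_error(loss_weights(a = -1), "nonnegative")
})

test_that("deep supervision weights the per-head losses", {
  set.seed(22)
  t <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  p1 <- array(runif(64), c(4, 4, 4)); p2 <- array(runif(64), c(4, 4, 4))
  w <- loss_weights(head_weights = c(0.5, 1))
  expect_equal(supervised_loss(list(p1, p2), t, w),
               0.5 * combined_loss(p1, t, w) + combined_loss(p2, t, w))
  # weight (0, 1) ignores the first head entirely
  w01 <- loss_weights(head_weights = c(0, 1))
  expect_equal(supervised_loss(list(p1, p2), t, w01), combined_loss(p2, t, w01))
  # single head with weight 1 is the plain combined loss
  w1 <- loss_weights(head_weights = 1)
  expect_equal(supervised_loss(list(p1), t, w1), combined_loss(p1, t, w1))
  # both heads perfect: loss vanishes
  expect_lt(supervised_loss(list(t, t), t, loss_weights(b = 0)), 1e-5)
  expect_error(supervised_loss(list(p1), t, w), "lengths")
})

test_that("gradients reach every parameterized layer of every network", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  w <- loss_weights()
  set.seed(31)
  xb <- array(runif(16 * 8 * 2), c(16, 8, 2, 1))
  tb <- array(rbinom(16 * 8 * 2, 1, 0.4), c(16, 8, 2, 1))
  up <- build_upward_unet(cfg)
  hipseg:::.zero_grads(up$layers)
  fw <- hipseg:::.fwd_upward(up, xb)
  g <- hipseg:::.combined_grad(hipseg:::.tp_val(fw$tape, fw$prob), tb, w)
  hipseg:::.tp_backward(fw$tape, list(list(id = fw$prob, grad = g$grad)))
  for (ly in up$layers) expect_gt(sum(abs(ly$gW)), 0)
  # both heads of the stacked hourglass receive finite nonzero gradients
  mn <- build_main_hourglass(cfg)
  hipseg:::.zero_grads(mn$layers)
  fw <- hipseg:::.fwd_main(mn, xb, xb)
  seeds <- lapply(seq_along(fw$heads), function(i) {
    gi <- hipseg:::.combined_grad(hipseg:::.tp_val(fw$tape, fw$heads[i]), tb, w)
    list(id = fw$heads[i], grad = w$head_weights[i] * gi$grad)
  })
  hipseg:::.tp_backward(fw$tape, seeds)
  for (ly in mn$layers) {
    expect_true(all(is.finite(ly$gW)))
    expect_gt(sum(abs(ly$gW)), 0)
  }
})

test_that("conv/deconv/dense gradients agree with finite differences", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  set.seed(32)
  net <- build_upward_unet(cfg)
  xb <- array(runif(16 * 8 * 2), c(16, 8, 2, 1))
  tb <- array(rbinom(16 * 8 * 2, 1, 0.4), c(16, 8, 2, 1))
  w <- loss_weights()
  lossfn <- function() {
    fw <- hipseg:::.fwd_upward(net, xb)
    hipseg:::.combined_grad(hipseg:::.tp_val(fw$tape, fw$prob), tb, w)$value
  }
  hipseg:::.zero_grads(net$layers)
  fw <- hipseg:::.fwd_upward(net, xb)
  g <- hipseg:::.combined_grad(hipseg:::.tp_val(fw$tape, fw$prob), tb, w)
  hipseg:::.tp_backward(fw$tape, list(list(id = fw$prob, grad = g$grad)))
  eps <- 1e-6
  for (nm in c("enc1_conv1", "bott_conv3", "dec1_up", "out_proj")) {
    ly <- net$layers[[nm]]
    for (k in sample(length(ly$W), 3)) {
      w0 <- ly$W[k]
      ly$W[k] <- w0 + eps; lp <- lossfn()
      ly$W[k] <- w0 - eps; lm <- lossfn()
      ly$W[k] <- w0
      fd <- (lp - lm) / (2 * eps)
      expect_equal(ly$gW[k], fd, tolerance = 1e-3)
    }
  }
})

test_that("training reduces the loss and respects stage preconditions", {
  ds <- tiny_dataset()
  cfg <- tiny_net_cfg()
  net <- train_stage("upward", ds, train_config(epochs = 4, seed = 1), cfg)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  expect_error(train_stage("upward", list(), train_config(seed = 1)), "empty")
  # a femur-free dataset cannot train the main stage
  neg <- Filter(function(s) !s$has_femur, ds)
  expect_error(train_stage("main", neg, train_config(seed = 1, stage = "main"),
                           cfg), "femur-positive")
})

test_that("classifier training separates femur from femur-free slices", {
  ds <- tiny_dataset()
  cfg <- tiny_net_cfg()
  net <- train_stage("classifier", ds,
                     train_config(epochs = 60, batch_size = 8, seed = 2,
                                  stage = "classifier"),
                     cfg)
  x <- hipseg:::.stack4(lapply(ds, `[[`, "bone"))
  conf <- network_predict(net, x)
  flags <- vapply(ds, `[[`, TRUE, "has_femur")
  acc <- mean((conf >= 0.5) == flags)
  expect_gt(acc, 0.9)  # training accuracy on its own training set
})

test_that("seeded training is exactly reproducible", {
  ds <- tiny_dataset()[1:6]
  cfg <- tiny_net_cfg()
  tc <- train_config(epochs = 2, seed = 7)
  n1 <- train_stage("upward", ds, tc, cfg)
  n2 <- train_stage("upward", ds, tc, cfg)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$layers[["out_proj"]]$W, n2$layers[["out_proj"]]$W)
})

test_that("assembly checks roles and spatial compatibility", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  up <- build_upward_unet(cfg)
  mn <- build_main_hourglass(cfg)
  cl <- build_layer_classifier(cfg)
  pipe <- assemble(up, mn, cl)
  expect_s3_class(pipe, "hs_pipeline")
  expect_error(assemble(mn, up, cl), "roles")
  other <- build_layer_classifier(network_config(in_rows = 32, in_cols = 32,
                                                 base_channels = 4))
  expect_error(assemble(up, mn, other), "size mismatch")
})
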