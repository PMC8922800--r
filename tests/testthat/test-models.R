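test_that("network_config validates divisibility and stacking", {
  expect_error(network_config(in_rows = 30), "divisible")
  expect_error(network_config(base_channels = 2), "base_channels")
  expect_error(network_config(stack_count = 0), "stack_count")
  expect_error(network_config(pool_levels = 3), "2 pooling")
  cfg <- network_config(in_rows = 32, in_cols = 32)
  expect_s3_class(cfg, "network_config")
})

test_that("the modified U-Net has 18 parameterized layers at any width", {
  for (bc in c(4, 8, 16)) {
    net <- build_upward_unet(network_config(in_rows = 16, in_cols = 16,
                                            base_channels = bc))
    expect_equal(count_parameterized_layers(net), 18)
  }
})

test_that("the slice classifier has 14 parameterized layers at any width", {
  for (bc in c(4, 8)) {
    net <- build_layer_classifier(network_config(in_rows = 16, in_cols = 16,
                                                 base_channels = bc))
    expect_equal(count_parameterized_layers(net), 14)
  }
})

test_that("a single-conv toy net counts one parameterized layer", {
  net <- hipseg:::.new_network("upward", network_config())
  hipseg:::.net_layer(net, "only", "conv3", 1L, 4L)
  expect_equal(count_parameterized_layers(net), 1)
})

test_that("segmentation outputs are probability maps aligned with the input", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  up <- build_upward_unet(cfg)
  x <- array(0, c(16, 8, 3, 1))  # three all-zero half-slices
  o <- network_predict(up, x)
  expect_identical(dim(o$prob), c(16L, 8L, 3L, 1L))
  expect_true(all(o$prob >= 0 & o$prob <= 1))
  mn <- build_main_hourglass(cfg)
  om <- network_predict(mn, x, fusion = array(0, c(16, 8, 3, 1)))
  expect_length(om, 2)  # one output head per stacked decoder
  for (h in om) {
    expect_identical(dim(h), dim(x))
    expect_true(all(h >= 0 & h <= 1))
  }
  # stack_count is adjustable and sets the head count
  mn3 <- build_main_hourglass(network_config(in_rows = 16, in_cols = 16,
                                             base_channels = 4,
                                             stack_count = 3))
  expect_length(network_predict(mn3, x, fusion = x), 3)
  cl <- build_layer_classifier(cfg)
  conf <- network_predict(cl, array(runif(16 * 16 * 5), c(16, 16, 5, 1)))
  expect_length(conf, 5)
  expect_true(all(conf >= 0 & conf <= 1))
})

test_that("total parameter count equals the layer-table arithmetic", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  for (net in list(build_upward_unet(cfg), build_main_hourglass(cfg),
                   build_layer_classifier(cfg))) {
    lt <- layer_table(net)
    expect_equal(sum(lt$kernel_rows * lt$kernel_cols * lt$in_ch * lt$out_ch +
                       lt$out_ch),
                 count_parameters(net))
  }
})

test_that("dense connections change the parameter count by a computable amount", {
  cfg1 <- network_config(in_rows = 16, in_cols = 16, base_channels = 4,
                         stack_count = 1)
  cfg2 <- network_config(in_rows = 16, in_cols = 16, base_channels = 4,
                         stack_count = 2)
  lt1 <- layer_table(build_main_hourglass(cfg1))
  lt2 <- layer_table(build_main_hourglass(cfg2))
  # second-stack encoder/decoder inputs are widened by the concatenated
  # same-resolution features of the first stack; the widening is exactly the
  # extra in_ch recorded in the layer table
  extra <- lt2[!(lt2$layer %in% lt1$layer), ]
  own <- lt2[lt2$layer %in% lt1$layer, ]
  expect_identical(own$params, lt1$params)
  expect_equal(sum(lt2$params), sum(lt1$params) + sum(extra$params))
  expect_true(any(extra$in_ch > lt1$in_ch[match(sub("hg2", "hg1", extra$layer),
                                                lt1$layer)]))
})

test_that("networks reject malformed inputs", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  mn <- build_main_hourglass(cfg)
  expect_error(network_predict(mn, array(0, c(16, 8, 1, 1)),
                               fusion = array(0, c(16, 4, 1, 1))), "fusion")
  expect_error(build_layer_classifier(network_config(in_rows = 24,
                                                     in_cols = 24)),
               "divisible by 16")
})

test_that("checkpoint save/load restores weights and predictions", {
  cfg <- network_config(in_rows = 16, in_cols = 16, base_channels = 4)
  set.seed(10)
  net <- build_upward_unet(cfg)
  x <- array(runif(16 * 8 * 2), c(16, 8, 2, 1))
  before <- network_predict(net, x)$prob
  td <- withr::local_tempdir()
  f <- file.path(td, "up.rds")
  save_network(net, f)
  net2 <- load_network(f)
  expect_equal(network_predict(net2, x)$prob, before)
  expect_equal(count_parameterized_layers(net2), 18)
})
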