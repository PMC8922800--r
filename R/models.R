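#' Network configuration
#'
#' Shared configuration for the three networks. `in_rows`/`in_cols` is the
#' full slice size fed to the pipeline (the two segmentation networks operate
#' on `in_rows x in_cols/2` half-images after the mid-split augmentation, and
#' are fully convolutional, so the size mainly fixes divisibility);
#' `base_channels` scales the channel widths; `stack_count` is the number of
#' hourglasses stacked in the main segmentation network and can be adjusted
#' for tasks of different complexity; `pool_levels` is fixed at the two
#' 2 x 2 pooling / two up-sample deconvolution stages of the encoder-decoder;
#' `fusion_channels` is the width of the bone feature map fused from the
#' upward network into the main network (1: the bone probability map, so
#' ground-truth bone masks can stand in for it during training).
#'
#' @param in_rows,in_cols input slice size; both divisible by
#'   `2^pool_levels`, and `in_cols` even (mid-split).
#' @param base_channels channel width multiplier, >= 4.
#' @param stack_count number of stacked hourglasses in the main net, >= 1.
#' @param pool_levels encoder depth (2).
#' @param fusion_channels channels of the fused bone feature map.
#' @return object of class `network_config`.
#' @export
network_config <- function(in_rows = 64, in_cols = 64, base_channels = 8,
                           stack_count = 2, pool_levels = 2,
                           fusion_channels = 1) {
  if (base_channels < 4) stop("base_channels must be >= 4")
  if (stack_count < 1) stop("stack_count must be >= 1")
  if (pool_levels != 2)
    stop("the encoder-decoder uses exactly 2 pooling and 2 deconvolution stages")
  if (in_rows %% 2^pool_levels != 0 || in_cols %% 2^pool_levels != 0)
    stop("input size must be divisible by 2^pool_levels")
  if (in_cols %% 2 != 0) stop("in_cols must be even (mid-split augmentation)")
  structure(list(in_rows = as.integer(in_rows), in_cols = as.integer(in_cols),
                 base_channels = as.integer(base_channels),
                 stack_count = as.integer(stack_count),
                 pool_levels = as.integer(pool_levels),
                 fusion_channels = as.integer(fusion_channels)),
            class = "network_config")
}

# fetch-or-create a named layer; layers materialize on the first forward
# pass, which guarantees the builder and the forward wiring agree
.net_layer <- function(net, name, kind, a, b) {
  ly <- net$layers[[name]]
  if (is.null(ly)) {
    ly <- switch(kind, conv3 = .new_conv(3L, a, b), conv1 = .new_conv(1L, a, b),
                 deconv = .new_deconv(a, b), dense = .new_dense(a, b))
    net$order <- c(net$order, name)
    net$layers[[name]] <- ly
  } else if (ly$in_ch != a || ly$out_ch != b) {
    stop("layer ", name, " rebuilt with mismatched channels")
  }
  ly
}

.new_network <- function(role, cfg) {
  net <- new.env(parent = emptyenv())
  net$role <- role
  net$cfg <- cfg
  net$layers <- list()
  net$order <- character(0)
  class(net) <- "hs_network"
  net
}

#' @export
print.hs_network <- function(x, ...) {
  cat(sprintf("<hs_network role=%s> %d parameterized layers, %d parameters\n",
              x$role, count_parameterized_layers(x),
              sum(vapply(x$layers, .layer_param_count, 0))))
  invisible(x)
}

# conv3 -> relu block helper
.cbr <- function(tp, id, net, name, cin, cout) {
  .tp_relu(tp, .tp_conv(tp, id, .net_layer(net, name, "conv3", cin, cout)))
}

# --- upward bone/soft-tissue separator (modified 2D U-Net) -----------------

#' Build the modified 2D U-Net bone/soft-tissue separator
#'
#' Encoder-decoder with exactly two 2 x 2 max-pooling stages and two
#' up-sample deconvolution stages, three 3 x 3 convolutions per resolution
#' block (five blocks), skip concatenations, and a final 1 x 1 projection
#' with sigmoid output: 15 convolutions + 2 deconvolutions + 1 projection =
#' 18 parameterized layers (pooling layers carry no weights and are not
#' counted). The forward pass returns the per-pixel bone probability map and
#' the full-resolution fusion feature map passed to the main segmentation
#' network.
#'
#' @param cfg a [network_config()].
#' @return an `hs_network` handle with role `"upward"`.
#' @export
build_upward_unet <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  net <- .new_network("upward", cfg)
  dummy <- array(0, c(cfg$in_rows, max(cfg$in_cols %/% 2L, 4L), 1, 1))
  .fwd_upward(net, dummy)
  net
}

.fwd_upward <- function(net, x) {
  c0 <- net$cfg$base_channels
  tp <- .tape_new()
  id <- .tp_input(tp, x)
  e1 <- .cbr(tp, id, net, "enc1_conv1", 1L, c0)
  e1 <- .cbr(tp, e1, net, "enc1_conv2", c0, c0)
  e1 <- .cbr(tp, e1, net, "enc1_conv3", c0, c0)
  p1 <- .tp_pool(tp, e1)
  e2 <- .cbr(tp, p1, net, "enc2_conv1", c0, 2L * c0)
  e2 <- .cbr(tp, e2, net, "enc2_conv2", 2L * c0, 2L * c0)
  e2 <- .cbr(tp, e2, net, "enc2_conv3", 2L * c0, 2L * c0)
  p2 <- .tp_pool(tp, e2)
  bt <- .cbr(tp, p2, net, "bott_conv1", 2L * c0, 4L * c0)
  bt <- .cbr(tp, bt, net, "bott_conv2", 4L * c0, 4L * c0)
  bt <- .cbr(tp, bt, net, "bott_conv3", 4L * c0, 4L * c0)
  u1 <- .tp_relu(tp, .tp_deconv(tp, bt, .net_layer(net, "dec1_up", "deconv",
                                                   4L * c0, 2L * c0)))
  d1 <- .tp_concat(tp, c(u1, e2))
  d1 <- .cbr(tp, d1, net, "dec1_conv1", 4L * c0, 2L * c0)
  d1 <- .cbr(tp, d1, net, "dec1_conv2", 2L * c0, 2L * c0)
  d1 <- .cbr(tp, d1, net, "dec1_conv3", 2L * c0, 2L * c0)
  u2 <- .tp_relu(tp, .tp_deconv(tp, d1, .net_layer(net, "dec2_up", "deconv",
                                                   2L * c0, c0)))
  d2 <- .tp_concat(tp, c(u2, e1))
  d2 <- .cbr(tp, d2, net, "dec2_conv1", 2L * c0, c0)
  d2 <- .cbr(tp, d2, net, "dec2_conv2", c0, c0)
  d2 <- .cbr(tp, d2, net, "dec2_conv3", c0, c0)
  pr <- .tp_sigmoid(tp, .tp_conv(tp, d2, .net_layer(net, "out_proj", "conv1",
                                                    c0, net$cfg$fusion_channels)))
  list(tape = tp, prob = pr, features = pr)
}

# --- main densely-connected stacked-hourglass femur segmenter --------------

#' Build the densely-connected stacked-hourglass femur segmentation network
#'
#' `stack_count` encoder-decoder hourglasses, each with two 2 x 2 pooling and
#' two up-sample deconvolution stages. Every resolution block receives the
#' channel-wise concatenation of all earlier same-resolution block outputs
#' across the whole stack (dense connections), including the network input
#' (slice plus fused bone feature map) at full resolution. Each decoder ends
#' in its own 1 x 1 sigmoid head; all heads are trained (intermediate deep
#' supervision) and the last head is the prediction.
#'
#' @param cfg a [network_config()].
#' @return an `hs_network` handle with role `"main"`.
#' @export
build_main_hourglass <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  net <- .new_network("main", cfg)
  hw <- max(cfg$in_cols %/% 2L, 4L)
  .fwd_main(net, array(0, c(cfg$in_rows, hw, 1, 1)),
            array(0, c(cfg$in_rows, hw, cfg$fusion_channels, 1)))
  net
}

.fwd_main <- function(net, x, fusion) {
  cfg <- net$cfg
  c0 <- cfg$base_channels
  if (!all(dim(x)[1:3] == dim(fusion)[1:3]) ||
      dim(fusion)[4] != cfg$fusion_channels)
    stop("fusion feature map must match the input slice batch")
  tp <- .tape_new()
  xin <- .tp_input(tp, x)
  fin <- .tp_input(tp, fusion)
  inp <- .tp_concat(tp, c(xin, fin))
  in_ch <- 1L + cfg$fusion_channels
  full <- list(list(id = inp, ch = in_ch))
  half <- list()
  quarter <- list()
  chs <- function(fs) sum(vapply(fs, `[[`, 0L, "ch"))
  cat_of <- function(fs) .tp_concat(tp, vapply(fs, `[[`, 0L, "id"))
  heads <- integer(0)
  for (h in seq_len(cfg$stack_count)) {
    nm <- function(s) sprintf("hg%d_%s", h, s)
    a <- .cbr(tp, cat_of(full), net, nm("encA1"), chs(full), c0)
    a <- .cbr(tp, a, net, nm("encA2"), c0, c0)
    full <- c(full, list(list(id = a, ch = c0)))
    pb <- .tp_pool(tp, a)
    half_in <- c(list(list(id = pb, ch = c0)), half)
    b <- .cbr(tp, cat_of(half_in), net, nm("encB1"), chs(half_in), 2L * c0)
    b <- .cbr(tp, b, net, nm("encB2"), 2L * c0, 2L * c0)
    half <- c(half, list(list(id = b, ch = 2L * c0)))
    pc <- .tp_pool(tp, b)
    q_in <- c(list(list(id = pc, ch = 2L * c0)), quarter)
    cc <- .cbr(tp, cat_of(q_in), net, nm("encC1"), chs(q_in), 2L * c0)
    cc <- .cbr(tp, cc, net, nm("encC2"), 2L * c0, 2L * c0)
    quarter <- c(quarter, list(list(id = cc, ch = 2L * c0)))
    u1 <- .tp_relu(tp, .tp_deconv(tp, cc, .net_layer(net, nm("decB_up"),
                                                     "deconv", 2L * c0, 2L * c0)))
    db_in <- c(list(list(id = u1, ch = 2L * c0)), half)
    db <- .cbr(tp, cat_of(db_in), net, nm("decB1"), chs(db_in), 2L * c0)
    db <- .cbr(tp, db, net, nm("decB2"), 2L * c0, 2L * c0)
    half <- c(half, list(list(id = db, ch = 2L * c0)))
    u2 <- .tp_relu(tp, .tp_deconv(tp, db, .net_layer(net, nm("decA_up"),
                                                     "deconv", 2L * c0, c0)))
    da_in <- c(list(list(id = u2, ch = c0)), full)
    da <- .cbr(tp, cat_of(da_in), net, nm("decA1"), chs(da_in), c0)
    da <- .cbr(tp, da, net, nm("decA2"), c0, c0)
    full <- c(full, list(list(id = da, ch = c0)))
    heads <- c(heads, .tp_sigmoid(tp, .tp_conv(tp, da, .net_layer(
      net, nm("head"), "conv1", c0, 1L))))
  }
  list(tape = tp, heads = heads)
}

# --- slice classifier ------------------------------------------------------

#' Build the femur slice classifier
#'
#' Convolutional trunk of six blocks of two 3 x 3 convolutions (12
#' convolutions) with 2 x 2 max-pooling after the first four blocks, a
#' global-average pool, and two fully connected layers ending in a sigmoid:
#' 12 + 2 = 14 parameterized layers. The scalar output is the confidence
#' that the input slice contains femur.
#'
#' @param cfg a [network_config()]; `in_rows`/`in_cols` must be divisible by
#'   16 (four pooling stages).
#' @return an `hs_network` handle with role `"classifier"`.
#' @export
build_layer_classifier <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$in_rows %% 16L != 0L || cfg$in_cols %% 16L != 0L)
    stop("classifier input size must be divisible by 16")
  net <- .new_network("classifier", cfg)
  .fwd_classifier(net, array(0, c(cfg$in_rows, cfg$in_cols, 1, 1)))
  net
}

.fwd_classifier <- function(net, x) {
  c0 <- net$cfg$base_channels
  plan <- c(c0, 2L * c0, 2L * c0, 4L * c0, 4L * c0, 4L * c0)
  tp <- .tape_new()
  id <- .tp_input(tp, x)
  cin <- 1L
  for (blk in seq_along(plan)) {
    id <- .cbr(tp, id, net, sprintf("blk%d_conv1", blk), cin, plan[blk])
    id <- .cbr(tp, id, net, sprintf("blk%d_conv2", blk), plan[blk], plan[blk])
    cin <- plan[blk]
    if (blk <= 4L) id <- .tp_pool(tp, id)
  }
  g <- .tp_gap(tp, id)
  fc1 <- .tp_relu(tp, .tp_dense(tp, g, .net_layer(net, "fc1", "dense",
                                                  cin, 2L * c0)))
  out <- .tp_sigmoid(tp, .tp_dense(tp, fc1, .net_layer(net, "fc2", "dense",
                                                       2L * c0, 1L)))
  list(tape = tp, out = out)
}

# --- introspection and forward wrappers ------------------------------------

#' Count parameterized layers of a network
#'
#' Counts layers carrying trainable weights: convolutions, up-sample
#' deconvolutions and fully connected layers. Pooling, activations,
#' concatenations and the global average pool carry no weights and are not
#' counted. The count is invariant to the channel-width configuration.
#'
#' @param net an `hs_network` handle.
#' @return integer layer count (18 for the modified U-Net, 14 for the
#'   classifier with the default decomposition).
#' @export
count_parameterized_layers <- function(net) {
  stopifnot(inherits(net, "hs_network"))
  length(net$layers)
}

#' Total trainable parameter count
#' @param net an `hs_network` handle.
#' @return integer number of scalar weights and biases.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "hs_network"))
  sum(vapply(net$layers, .layer_param_count, 0))
}

#' Per-layer weight shape table
#'
#' One row per parameterized layer in creation order, with the kernel size
#' and channel fan so the total parameter count can be verified externally as
#' `sum(kernel_rows * kernel_cols * in_ch * out_ch + out_ch)`.
#'
#' @param net an `hs_network` handle.
#' @return data.frame with columns layer, kind, kernel_rows, kernel_cols,
#'   in_ch, out_ch, params.
#' @export
layer_table <- function(net) {
  stopifnot(inherits(net, "hs_network"))
  rows <- lapply(net$order, function(nm) {
    ly <- net$layers[[nm]]
    kr <- switch(ly$kind, conv = ly$kh, deconv = 2L, dense = 1L)
    kc <- switch(ly$kind, conv = ly$kh, deconv = 2L, dense = 1L)
    data.frame(layer = nm, kind = ly$kind, kernel_rows = kr, kernel_cols = kc,
               in_ch = ly$in_ch, out_ch = ly$out_ch,
               params = .layer_param_count(ly))
  })
  do.call(rbind, rows)
}

# forward dispatch used by training and inference; returns tape + output ids
.net_forward <- function(net, x, fusion = NULL) {
  switch(net$role,
         upward = .fwd_upward(net, x),
         main = .fwd_main(net, x, fusion),
         classifier = .fwd_classifier(net, x),
         stop("unknown network role"))
}

#' Run a network forward on a batch
#'
#' @param net an `hs_network` handle.
#' @param x input batch, array `(rows, cols, batch, 1)`.
#' @param fusion fusion feature batch (main network only).
#' @return role-dependent: upward — list of `prob` and `features` arrays;
#'   main — list of per-head probability arrays (last = prediction);
#'   classifier — numeric vector of per-slice confidences in \[0, 1\].
#' @export
network_predict <- function(net, x, fusion = NULL) {
  stopifnot(inherits(net, "hs_network"))
  fw <- .net_forward(net, x, fusion)
  switch(net$role,
         upward = list(prob = .tp_val(fw$tape, fw$prob),
                       features = .tp_val(fw$tape, fw$features)),
         main = lapply(fw$heads, function(i) .tp_val(fw$tape, i)),
         classifier = as.vector(.tp_val(fw$tape, fw$out)))
}

#' Save / load network weights
#'
#' Checkpoints store the configuration and per-layer weights; loading
#' rebuilds the architecture and restores the weights.
#'
#' @param net an `hs_network` handle.
#' @param path file path (`.rds`).
#' @return [load_network()] returns the restored `hs_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "hs_network"))
  params <- lapply(net$layers, function(ly) list(W = ly$W, b = ly$b))
  saveRDS(list(role = net$role, cfg = unclass(net$cfg), params = params,
               history = net$history), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  st <- readRDS(path)
  cfg <- do.call(network_config, st$cfg)
  net <- switch(st$role,
                upward = build_upward_unet(cfg),
                main = build_main_hourglass(cfg),
                classifier = build_layer_classifier(cfg))
  for (nm in names(st$params)) {
    net$layers[[nm]]$W <- st$params[[nm]]$W
    net$layers[[nm]]$b <- st$params[[nm]]$b
  }
  net$history <- st$history
  net
}
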