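#' Loss weights
#'
#' Weights of the combined loss `L = a * diceLoss + b * crossEntropy` and the
#' per-decoder head weights of the intermediate supervision. Defaults:
#' `a = 1`, `b = 1`, `head_weights = c(0.5, 1)` (the final decoder carries
#' full weight, the intermediate decoder half).
#'
#' @param a nonnegative Dice-term weight.
#' @param b nonnegative cross-entropy-term weight.
#' @param head_weights nonnegative per-head weights, one per stacked decoder.
#' @param pos_weight positive-class weight in the cross-entropy term (class
#'   imbalance control; default 1).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(a = 1, b = 1, head_weights = c(0.5, 1),
                         pos_weight = 1) {
  if (a < 0 || b < 0) stop("loss weights must be nonnegative")
  if (a + b <= 0) stop("a + b must be > 0")
  if (any(head_weights < 0)) stop("head weights must be nonnegative")
  if (pos_weight <= 0) stop("pos_weight must be > 0")
  structure(list(a = a, b = b, head_weights = head_weights,
                 pos_weight = pos_weight), class = "loss_weights")
}

.dice_eps <- 1e-6

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1e-6`,
#' computed over all elements. Zero for a perfect binary prediction (within
#' eps), values in \[0, 1\]; favours overall shape integrity.
#'
#' @param pred probability array in \[0, 1\].
#' @param target binary array of the same shape.
#' @return scalar loss.
#' @export
dice_loss <- function(pred, target) {
  if (!all(.dim2(pred) == .dim2(target))) stop("shape mismatch")
  1 - (2 * sum(pred * target) + .dice_eps) /
    (sum(pred) + sum(target) + .dice_eps)
}

.dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# value + gradient of the Dice loss wrt pred
.dice_grad <- function(pred, target) {
  num <- 2 * sum(pred * target) + .dice_eps
  den <- sum(pred) + sum(target) + .dice_eps
  list(value = 1 - num / den, grad = -(2 * target * den - num) / den^2)
}

# mean binary cross-entropy, value + gradient wrt pred
.bce_grad <- function(pred, target, pos_weight = 1) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  n <- length(p)
  value <- -sum(pos_weight * target * log(p) + (1 - target) * log(1 - p)) / n
  grad <- (-pos_weight * target / p + (1 - target) / (1 - p)) / n
  if (!is.null(dim(pred))) dim(grad) <- dim(pred)
  list(value = value, grad = grad)
}

#' Combined Dice + cross-entropy loss
#'
#' `a * dice_loss + b * mean pixel-wise cross-entropy`; linear in `(a, b)`.
#'
#' @param pred probability array in \[0, 1\].
#' @param target binary array of the same shape.
#' @param w a [loss_weights()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  if (!all(.dim2(pred) == .dim2(target))) stop("shape mismatch")
  w$a * dice_loss(pred, target) +
    w$b * .bce_grad(pred, target, w$pos_weight)$value
}

.combined_grad <- function(pred, target, w) {
  d <- .dice_grad(pred, target)
  ce <- .bce_grad(pred, target, w$pos_weight)
  list(value = w$a * d$value + w$b * ce$value,
       grad = w$a * d$grad + w$b * ce$grad)
}

#' Deep-supervision loss over the stacked decoder heads
#'
#' `sum_i head_weights[i] * combined_loss(head_outputs[[i]], target, w)`:
#' every decoder output of the stacked hourglass is supervised against the
#' same target.
#'
#' @param head_outputs list of per-head probability arrays.
#' @param target binary target array.
#' @param w a [loss_weights()]; `length(head_weights)` must equal the number
#'   of heads.
#' @return scalar loss.
#' @export
supervised_loss <- function(head_outputs, target, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  if (length(head_outputs) != length(w$head_weights))
    stop("head_outputs and head_weights lengths differ")
  sum(vapply(seq_along(head_outputs), function(i)
    w$head_weights[i] * combined_loss(head_outputs[[i]], target, w), 0))
}

#' Training configuration
#'
#' Desk-scale defaults (the clinical-scale regime of 30,000 iterations over
#' 10 epochs is out of scope): Adam, learning rate 1e-3.
#'
#' @param epochs positive integer.
#' @param batch_size positive integer.
#' @param learning_rate positive real.
#' @param seed integer RNG seed; with single-threaded deterministic
#'   execution, a fixed seed reproduces the loss trajectory exactly.
#' @param stage one of `"upward"`, `"main"`, `"classifier"`.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 16, learning_rate = 1e-3,
                         seed = 1L, stage = c("upward", "main", "classifier")) {
  stage <- match.arg(stage)
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 stage = stage), class = "train_config")
}

# stack a list of matrices into a (H, W, N, 1) tensor
.stack4 <- function(mats) {
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(d[1], d[2], length(mats), 1))
}

# halves of every slice matrix in a list (left then mirrored right, per slice)
.halves_of <- function(mats) {
  out <- vector("list", 2L * length(mats))
  for (i in seq_along(mats)) {
    h <- split_and_flip(mats[[i]])
    out[[2L * i - 1L]] <- h$left
    out[[2L * i]] <- h$right
  }
  out
}

#' Train one pipeline stage
#'
#' The three networks are trained independently and assembled afterwards
#' ([assemble()]). Stage inputs follow the benchmark-feeding regime:
#' * `upward` — bone-windowed half-slices against the ground-truth bone mask
#'   (all slices).
#' * `main` — femur-windowed half-slices with the *ground-truth* bone mask as
#'   the fusion input, against the femur mask; only slices whose ground-truth
#'   `has_femur` flag is true are fed (at test time the upward net's
#'   predicted features and the classifier's confidence replace both).
#' * `classifier` — full bone-windowed slices against the `has_femur` flag.
#'
#' @param stage `"upward"`, `"main"` or `"classifier"`.
#' @param dataset nonempty list of slice samples from [make_slice_dataset()].
#' @param cfg a [train_config()].
#' @param net_cfg a [network_config()].
#' @param weights a [loss_weights()].
#' @param verbose print per-epoch losses.
#' @return a trained `hs_network`; `$history` holds the per-epoch mean loss.
#' @export
train_stage <- function(stage, dataset, cfg = train_config(stage = stage),
                        net_cfg = network_config(), weights = loss_weights(),
                        verbose = FALSE) {
  stage <- match.arg(stage, c("upward", "main", "classifier"))
  if (length(dataset) == 0L) stop("dataset is empty")
  set.seed(cfg$seed)
  if (stage == "main") {
    dataset <- Filter(function(s) isTRUE(s$has_femur), dataset)
    if (length(dataset) == 0L)
      stop("main stage requires femur-positive slices (has_femur)")
  }
  if (stage == "upward") {
    x <- .stack4(.halves_of(lapply(dataset, `[[`, "bone")))
    y <- .stack4(.halves_of(lapply(dataset, `[[`, "bone_mask")))
    net <- build_upward_unet(net_cfg)
    w <- loss_weights(weights$a, weights$b, head_weights = 1,
                      pos_weight = weights$pos_weight)
  } else if (stage == "main") {
    x <- .stack4(.halves_of(lapply(dataset, `[[`, "femur")))
    fus <- .stack4(.halves_of(lapply(dataset, `[[`, "bone_mask")))
    y <- .stack4(.halves_of(lapply(dataset, `[[`, "femur_mask")))
    net <- build_main_hourglass(net_cfg)
    w <- loss_weights(weights$a, weights$b,
                      head_weights = rep_len(weights$head_weights,
                                             net_cfg$stack_count),
                      pos_weight = weights$pos_weight)
  } else {
    x <- .stack4(lapply(dataset, `[[`, "bone"))
    yv <- vapply(dataset, function(s) as.numeric(s$has_femur), 0)
    net <- build_layer_classifier(net_cfg)
    w <- weights
  }
  n <- dim(x)[3]
  layers <- net$layers
  step <- 0L
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , sel, , drop = FALSE]
      .zero_grads(layers)
      if (stage == "classifier") {
        fw <- .fwd_classifier(net, xb)
        pred <- .tp_val(fw$tape, fw$out)
        tb <- matrix(yv[sel], 1L)
        g <- .bce_grad(pred, tb, w$pos_weight)
        loss <- g$value
        seeds <- list(list(id = fw$out, grad = g$grad))
      } else if (stage == "upward") {
        fw <- .fwd_upward(net, xb)
        pred <- .tp_val(fw$tape, fw$prob)
        tb <- y[, , sel, , drop = FALSE]
        g <- .combined_grad(pred, tb, w)
        loss <- g$value
        seeds <- list(list(id = fw$prob, grad = g$grad))
      } else {
        fw <- .fwd_main(net, xb, fus[, , sel, , drop = FALSE])
        tb <- y[, , sel, , drop = FALSE]
        loss <- 0
        seeds <- vector("list", length(fw$heads))
        for (i in seq_along(fw$heads)) {
          g <- .combined_grad(.tp_val(fw$tape, fw$heads[i]), tb, w)
          loss <- loss + w$head_weights[i] * g$value
          seeds[[i]] <- list(id = fw$heads[i], grad = w$head_weights[i] * g$grad)
        }
      }
      .tp_backward(fw$tape, seeds)
      step <- step + 1L
      .adam_step(layers, cfg$learning_rate, step)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    hist[ep] <- ep_loss / nb
    if (verbose) message(sprintf("[%s] epoch %d/%d loss %.5f",
                                 stage, ep, cfg$epochs, hist[ep]))
  }
  net$history <- data.frame(epoch = seq_len(cfg$epochs), loss = hist)
  net
}

#' Assemble the trained networks into the inference pipeline
#'
#' At test time the upward network's predicted bone features replace the
#' ground-truth fusion input used in training, and the classifier confidence
#' gates the main network's femur map (see [segment_volume()]).
#'
#' @param upward,main,classifier trained `hs_network` handles with matching
#'   spatial configuration.
#' @return callable pipeline of class `hs_pipeline`.
#' @export
assemble <- function(upward, main, classifier) {
  stopifnot(inherits(upward, "hs_network"), inherits(main, "hs_network"),
            inherits(classifier, "hs_network"))
  if (upward$role != "upward" || main$role != "main" ||
      classifier$role != "classifier")
    stop("networks must have roles upward/main/classifier")
  same <- function(a, b) a$in_rows == b$in_rows && a$in_cols == b$in_cols
  if (!same(upward$cfg, main$cfg) || !same(upward$cfg, classifier$cfg))
    stop("input size mismatch between networks")
  if (upward$cfg$fusion_channels != main$cfg$fusion_channels)
    stop("fusion channel mismatch between upward and main networks")
  structure(list(upward = upward, main = main, classifier = classifier,
                 input_size = c(upward$cfg$in_rows, upward$cfg$in_cols)),
            class = "hs_pipeline")
}

#' @export
print.hs_pipeline <- function(x, ...) {
  cat(sprintf("<hs_pipeline> input %dx%d; layers: upward %d, main %d, classifier %d\n",
              x$input_size[1], x$input_size[2],
              count_parameterized_layers(x$upward),
              count_parameterized_layers(x$main),
              count_parameterized_layers(x$classifier)))
  invisible(x)
}
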