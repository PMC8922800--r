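# Minimal CNN engine on BLAS matrix operations.
#
# Feature tensors are dense arrays of dimension (rows, cols, batch, channels);
# fully-connected activations are (features, batch) matrices. The layout puts
# channels last so that im2col patch matrices and layer outputs reshape to and
# from matrices without any aperm copies: convolutions are a single gather
# plus one BLAS matrix product. Gradients are computed by a reverse pass over
# a lightweight tape recorded during the forward pass: the data gradient of a
# stride-1 'same' convolution is itself a convolution with the spatially
# flipped, channel-transposed kernel, so forward and backward share one code
# path. All operations are single-threaded deterministic apart from BLAS,
# which is deterministic for a fixed thread count.

# --- parameterized layers --------------------------------------------------

# conv: W is (kh*kw*in_ch) x out_ch, rows ordered kernel-position fastest
.new_conv <- function(kh, in_ch, out_ch) {
  k <- kh * kh * in_ch
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"; ly$kh <- kh; ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$W <- matrix(stats::rnorm(k * out_ch, 0, sqrt(2 / k)), k, out_ch)
  ly$b <- numeric(out_ch)
  ly
}

# transposed 2x2 stride-2 convolution ("up-sample deconvolution");
# W is (4*in_ch) x out_ch, rows grouped by the 4 output sub-positions
.new_deconv <- function(in_ch, out_ch) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "deconv"; ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$W <- matrix(stats::rnorm(4 * in_ch * out_ch, 0, sqrt(2 / (4 * in_ch))),
                 4 * in_ch, out_ch)
  ly$b <- numeric(out_ch)
  ly
}

.new_dense <- function(in_f, out_f) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "dense"; ly$in_ch <- in_f; ly$out_ch <- out_f
  ly$W <- matrix(stats::rnorm(in_f * out_f, 0, sqrt(2 / in_f)), in_f, out_f)
  ly$b <- numeric(out_f)
  ly
}

.layer_param_count <- function(ly) length(ly$W) + length(ly$b)

.zero_grads <- function(layers) {
  for (ly in layers) { ly$gW <- ly$W * 0; ly$gb <- ly$b * 0 }
  invisible(NULL)
}

# Adam update; t is the 1-based step counter
.adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in layers) {
    if (is.null(ly$mW)) { ly$mW <- ly$W * 0; ly$vW <- ly$W * 0
                          ly$mb <- ly$b * 0; ly$vb <- ly$b * 0 }
    ly$mW <- beta1 * ly$mW + (1 - beta1) * ly$gW
    ly$vW <- beta2 * ly$vW + (1 - beta2) * ly$gW^2
    ly$mb <- beta1 * ly$mb + (1 - beta1) * ly$gb
    ly$vb <- beta2 * ly$vb + (1 - beta2) * ly$gb^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    ly$W <- ly$W - lr * (ly$mW / c1) / (sqrt(ly$vW / c2) + eps)
    ly$b <- ly$b - lr * (ly$mb / c1) / (sqrt(ly$vb / c2) + eps)
  }
  invisible(NULL)
}

# --- im2col machinery ------------------------------------------------------

# patch matrix (H*W*N) x (kh*kh*C) matching the conv weight row order;
# the gather itself is compiled (src/im2col.cpp)
.im2col <- function(x, kh) {
  d <- dim(x)
  if (kh == 1L) {
    dim(x) <- c(d[1] * d[2] * d[3], d[4])
    return(x)
  }
  .im2col_cpp(x, d[1], d[2], d[3], d[4], kh)
}

# stride-1 'same' convolution of x (H,W,N,C) with weight matrix Wm
.conv_core <- function(x, Wm, bvec, kh) {
  d <- dim(x)
  Fh <- ncol(Wm)
  Y <- .im2col(x, kh) %*% Wm
  if (any(bvec != 0)) Y <- Y + rep(bvec, each = nrow(Y))
  dim(Y) <- c(d[1], d[2], d[3], Fh)
  Y
}

# weight matrix for the data gradient: spatial flip + channel transpose
.conv_back_weight <- function(ly) {
  K <- ly$kh * ly$kh
  Wb <- array(ly$W, c(K, ly$in_ch, ly$out_ch))
  Wb <- Wb[K:1, , , drop = FALSE]
  Wb <- aperm(Wb, c(1, 3, 2))
  dim(Wb) <- c(K * ly$out_ch, ly$in_ch)
  Wb
}

# --- tape ------------------------------------------------------------------

.tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list(); tp$inputs <- list(); tp$backfns <- list(); tp$n <- 0L
  tp
}

.tp_push <- function(tp, val, inputs = integer(0), backfn = NULL) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  tp$inputs[[tp$n]] <- inputs
  tp$backfns[[tp$n]] <- backfn
  tp$n
}

.tp_val <- function(tp, id) tp$vals[[id]]

.tp_input <- function(tp, x) .tp_push(tp, x)

# reverse pass; seeds is list(id = , grad = ) entries
.tp_backward <- function(tp, seeds) {
  grads <- vector("list", tp$n)
  for (s in seeds) {
    g <- grads[[s$id]]
    grads[[s$id]] <- if (is.null(g)) s$grad else g + s$grad
  }
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$backfns[[i]])) next
    gs <- tp$backfns[[i]](g)
    ins <- tp$inputs[[i]]
    for (j in seq_along(ins)) {
      if (is.null(gs[[j]])) next
      old <- grads[[ins[j]]]
      grads[[ins[j]]] <- if (is.null(old)) gs[[j]] else old + gs[[j]]
    }
    grads[[i]] <- NA  # release memory held by consumed gradients
  }
  grads
}

.tp_conv <- function(tp, id, ly) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x)
  G <- .im2col(x, ly$kh)  # kept for the weight gradient in the reverse pass
  Y <- G %*% ly$W
  if (any(ly$b != 0)) Y <- Y + rep(ly$b, each = nrow(Y))
  dim(Y) <- c(d[1], d[2], d[3], ly$out_ch)
  .tp_push(tp, Y, id, function(gy) {
    dim(gy) <- c(d[1] * d[2] * d[3], ly$out_ch)
    ly$gW <- ly$gW + crossprod(G, gy)
    ly$gb <- ly$gb + colSums(gy)
    dim(gy) <- c(d[1], d[2], d[3], ly$out_ch)
    list(.conv_core(gy, .conv_back_weight(ly), numeric(ly$in_ch), ly$kh))
  })
}

.tp_deconv <- function(tp, id, ly) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  Fh <- ly$out_ch
  Xm <- x
  dim(Xm) <- c(H * W * N, C)
  y <- array(0, c(2L * H, 2L * W, N, Fh))
  ro <- seq(1L, 2L * H, 2L); co <- seq(1L, 2L * W, 2L)
  for (p in 1:4) {
    dr <- (p - 1L) %% 2L; dc <- (p - 1L) %/% 2L
    Yp <- Xm %*% ly$W[(p - 1L) * C + seq_len(C), , drop = FALSE]
    Yp <- Yp + rep(ly$b, each = nrow(Yp))
    dim(Yp) <- c(H, W, N, Fh)
    y[ro + dr, co + dc, , ] <- Yp
  }
  .tp_push(tp, y, id, function(gy) {
    dXm <- matrix(0, H * W * N, C)
    for (p in 1:4) {
      dr <- (p - 1L) %% 2L; dc <- (p - 1L) %/% 2L
      gyp <- gy[ro + dr, co + dc, , , drop = FALSE]
      dim(gyp) <- c(H * W * N, Fh)
      rows <- (p - 1L) * C + seq_len(C)
      ly$gW[rows, ] <- ly$gW[rows, ] + crossprod(Xm, gyp)
      ly$gb <- ly$gb + colSums(gyp)
      dXm <- dXm + gyp %*% t(ly$W[rows, , drop = FALSE])
    }
    dim(dXm) <- c(H, W, N, C)
    list(dXm)
  })
}

.tp_pool <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x); H <- d[1]; W <- d[2]
  r1 <- seq(1L, H, 2L); r2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  x11 <- x[r1, c1, , , drop = FALSE]; x21 <- x[r2, c1, , , drop = FALSE]
  x12 <- x[r1, c2, , , drop = FALSE]; x22 <- x[r2, c2, , , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  .tp_push(tp, m, id, function(gy) {
    w11 <- x11 == m
    w21 <- (x21 == m) & !w11
    w12 <- (x12 == m) & !w11 & !w21
    w22 <- !w11 & !w21 & !w12
    dx <- array(0, d)
    dx[r1, c1, , ] <- gy * w11
    dx[r2, c1, , ] <- gy * w21
    dx[r1, c2, , ] <- gy * w12
    dx[r2, c2, , ] <- gy * w22
    list(dx)
  })
}

.tp_relu <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  y <- x; y[y < 0] <- 0
  .tp_push(tp, y, id, function(gy) list(gy * (x > 0)))
}

.tp_sigmoid <- function(tp, id) {
  force(id)
  y <- 1 / (1 + exp(-tp$vals[[id]]))
  .tp_push(tp, y, id, function(gy) list(gy * y * (1 - y)))
}

# channel-wise concatenation of feature tensors
.tp_concat <- function(tp, ids) {
  ids <- as.integer(ids)
  if (length(ids) == 1L) return(ids[[1]])
  xs <- lapply(ids, function(i) tp$vals[[i]])
  chs <- vapply(xs, function(x) dim(x)[4], 0L)
  d1 <- dim(xs[[1]])
  y <- array(0, c(d1[1], d1[2], d1[3], sum(chs)))
  off <- 0L
  for (x in xs) {
    y[, , , off + seq_len(dim(x)[4])] <- x
    off <- off + dim(x)[4]
  }
  .tp_push(tp, y, ids, function(gy) {
    out <- vector("list", length(chs))
    off <- 0L
    for (j in seq_along(chs)) {
      out[[j]] <- gy[, , , off + seq_len(chs[j]), drop = FALSE]
      off <- off + chs[j]
    }
    out
  })
}

# global average pool: (H,W,N,C) -> (C,N)
.tp_gap <- function(tp, id) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- t(matrix(colMeans(xm), d[3], d[4]))
  .tp_push(tp, y, id, function(gy) {
    dx <- array(rep(as.vector(t(gy)), each = d[1] * d[2]) / (d[1] * d[2]), d)
    list(dx)
  })
}

.tp_dense <- function(tp, id, ly) {
  force(id)
  x <- tp$vals[[id]]
  y <- crossprod(ly$W, x) + ly$b
  .tp_push(tp, y, id, function(gy) {
    ly$gW <- ly$gW + x %*% t(gy)
    ly$gb <- ly$gb + rowSums(gy)
    list(ly$W %*% gy)
  })
}
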