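# Brute-force reference implementations and small fixture builders shared by
# the test files. The oracles deliberately use plain double loops and set
# arithmetic so they are independent of the package's vectorised code paths.

# O(|A||B|) nearest-neighbour distances, one loop per point
bf_min_dists <- function(A, B, spacing) {
  vapply(seq_len(nrow(A)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
      if (d < best) best <- d
    }
    best
  }, 0)
}

bf_directed_hausdorff <- function(A, B, spacing) max(bf_min_dists(A, B, spacing))

bf_hausdorff <- function(A, B, spacing) {
  max(bf_directed_hausdorff(A, B, spacing), bf_directed_hausdorff(B, A, spacing))
}

bf_msd <- function(A, B, spacing) {
  (sum(bf_min_dists(A, B, spacing)) + sum(bf_min_dists(B, A, spacing))) /
    (nrow(A) + nrow(B))
}

bf_doc <- function(a_arr, b_arr) {
  2 * sum(a_arr & b_arr) / (sum(a_arr) + sum(b_arr))
}

# random sparse 3D mask with at least one voxel
random_mask <- function(dim3, p = 0.1) {
  m <- array(stats::runif(prod(dim3)) < p, dim3)
  if (!any(m)) m[sample(length(m), 1L)] <- TRUE
  m
}

# flood-fill count of 6-connected components of a 3D mask
component_count <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  nc <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in which(mask)) {
    if (visited[start]) next
    nc <- nc + 1L
    stack <- start
    visited[start] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ai <- arrayInd(v, d)
      for (ax in 1:3) for (o in c(-1L, 1L)) {
        n <- ai
        n[ax] <- n[ax] + o
        if (n[ax] < 1L || n[ax] > d[ax]) next
        li <- 1L + sum((n - 1L) * strides)
        if (mask[li] && !visited[li]) {
          visited[li] <- TRUE
          stack <- c(stack, li)
        }
      }
    }
  }
  nc
}

# one cached small phantom pair reused across test files
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(seed = 42))
    cache
  }
})

# tiny slice dataset + network config for fast training tests
tiny_net_cfg <- function() network_config(in_rows = 32, in_cols = 32,
                                          base_channels = 4)

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(phantom_spec(shape = c(32, 32, 24), seed = 5))
      cache <<- make_slice_dataset(ph$ct, ph$labels, input_size = c(32, 32))
    }
    cache
  }
})

# two-phantom variant with enough variety for the end-to-end inference test
tiny_dataset2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- list()
      for (s in c(5, 15)) {
        ph <- generate_phantom(phantom_spec(shape = c(32, 32, 24), seed = s))
        ds <- c(ds, make_slice_dataset(ph$ct, ph$labels,
                                       input_size = c(32, 32)))
      }
      cache <<- ds
    }
    cache
  }
})
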