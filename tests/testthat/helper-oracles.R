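# Independent oracles used across the suite. These are written from first
# principles (closed-form summation, elementwise loops) and never call the
# code paths they check.

# Closed-form learnable-parameter count of an SRN-style trunk + head:
# convolutions contribute k^2*cin*cout weights + cout biases; 1x1 projection
# skips appear at channel transitions of residual blocks after the stem;
# the head contributes feature_dim*classes + classes.
oracle_srn_params <- function(layer_counts,
                              channels = c(32, 32, 64, 128, 256, 512),
                              in_ch = 3, classes = 4, residual = TRUE) {
  total <- 0
  cin <- in_ch
  for (b in seq_along(layer_counts)) {
    k <- if (b == 1) 7 else 3
    block_in <- cin
    for (l in seq_len(layer_counts[b])) {
      total <- total + k^2 * cin * channels[b] + channels[b]
      cin <- channels[b]
    }
    if (residual && b > 1 && block_in != cin) {
      total <- total + block_in * cin + cin
    }
  }
  total + cin * classes + classes
}

# Multi-branch oracle: B independent trunks without their own heads plus one
# fused head over the concatenated features.
oracle_ms_params <- function(layer_counts, n_branches, classes = 4) {
  trunk_with_head <- oracle_srn_params(layer_counts, classes = classes)
  trunk <- trunk_with_head - (512 * classes + classes)
  n_branches * trunk + (n_branches * 512 * classes + classes)
}

# Elementwise binary cross-entropy oracle (scalar loop, no vectorized reuse
# of the package formula).
oracle_bce <- function(pred, truth, eps = 1e-7) {
  stopifnot(identical(dim(pred), dim(truth)))
  total <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- min(max(pred[i, j], eps), 1 - eps)
      total <- total - (truth[i, j] * log(p) + (1 - truth[i, j]) * log(1 - p))
    }
  }
  total / (nrow(pred) * ncol(pred))
}

# Brute-force per-image, per-class confusion counting.
oracle_confusion <- function(pred, truth) {
  C <- ncol(truth)
  out <- data.frame(tp = integer(C), tn = integer(C), fp = integer(C),
                    fn = integer(C))
  for (j in seq_len(C)) {
    for (i in seq_len(nrow(truth))) {
      p <- pred[i, j]; y <- truth[i, j]
      if (p == 1 && y == 1) out$tp[j] <- out$tp[j] + 1
      if (p == 0 && y == 0) out$tn[j] <- out$tn[j] + 1
      if (p == 1 && y == 0) out$fp[j] <- out$fp[j] + 1
      if (p == 0 && y == 1) out$fn[j] <- out$fn[j] + 1
    }
  }
  out
}

# Pull one named tensor out of a network's flat parameter vector.
tensor_slice <- function(net, tensor) {
  lay <- param_layout(net)
  row <- lay[lay$tensor == tensor, ]
  stopifnot(nrow(row) == 1)
  seq.int(row$offset, length.out = row$size)
}

# Zero a whole block's main-path convolutions (weights and biases).
zero_block_main_path <- function(net, branch, block) {
  w <- get_weights(net)
  lay <- param_layout(net)
  pre <- sprintf("branch%d.block%d.conv", branch, block)
  for (i in which(startsWith(lay$tensor, pre))) {
    w[seq.int(lay$offset[i], length.out = lay$size[i])] <- 0
  }
  set_weights(net, w)
  invisible(net)
}

# Block output map (post-ReLU, pre-pool) via the engine's capture mechanism;
# gradient part is ignored.
block_activation <- function(net, image_array, block, branch = 1L) {
  octsrn:::.net_gradcam(net$ptr, image_array, as.integer(branch),
                        as.integer(block), 1L)$activations
}

# 2x2 stride-2 floor max-pool, reference implementation.
ref_maxpool2 <- function(a) {
  H <- dim(a)[1] %/% 2; W <- dim(a)[2] %/% 2; C <- dim(a)[3]
  out <- array(0, c(H, W, C))
  for (c in seq_len(C)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        out[i, j, c] <- max(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
      }
    }
  }
  out
}

make_gray_batch <- function(side, n, seed = 1) {
  set.seed(seed)
  array(runif(side * side * n), c(side, side, 1, n))
}

tiny_phantom_config <- function(side = 96, seed = 1, ...) {
  phantom_config(side = side, seed = seed, ...)
}
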