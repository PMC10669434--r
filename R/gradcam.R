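# Grad-CAM: gradient-weighted class activation maps against a block's
# feature maps, upsampled to the input and max-normalized.

#' Grad-CAM heatmap for one class
#'
#' Computes the gradient of the chosen class logit with respect to the
#' activations of a target block (default: the output of the last, deepest
#' convolutional block, pre-pooling), global-average-pools the gradient into
#' per-channel weights, forms the weighted activation sum, rectifies,
#' bilinearly upsamples to the input size and normalizes the maximum to 1
#' (a map that is identically zero stays zero). For multi-scale networks the
#' gradient flows from the shared fused logit through the concatenation, so
#' each branch gets its own map against the same prediction.
#'
#' @param net A built network.
#' @param image Grayscale matrix in `[0, 1]`; resized to the branch size.
#' @param class_index Class to explain (1..C, order amd/erm/me/normal).
#' @param branch Branch index (1 for single-scale networks).
#' @param block Target block (1-6; default 6, the deepest).
#' @return A `heatmap` object: `values` (matrix in `[0, 1]`, same size as the
#'   resized input), `class_index`, `branch`, `branch_size`.
#' @export
grad_cam <- function(net, image, class_index, branch = 1L, block = 6L) {
  stopifnot(inherits(net, "oct_net"))
  if (class_index < 1L || class_index > net$num_classes) {
    stop("class_index out of range", call. = FALSE)
  }
  if (branch < 1L || branch > n_branches(net)) stop("invalid branch", call. = FALSE)
  side <- net$branch_sizes[branch]
  if (nrow(image) != side || ncol(image) != side) {
    image <- .resize_bilinear(image, side, side)
  }
  cin <- net_in_channels(net)
  x <- array(0, c(side, side, cin))
  for (c in seq_len(cin)) x[, , c] <- image
  res <- .net_gradcam(net$ptr, x, as.integer(branch), as.integer(block),
                      as.integer(class_index))
  act <- res$activations; grad <- res$gradients
  w <- apply(grad, 3, mean)
  map <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_along(w)) map <- map + w[c] * act[, , c]
  map[map < 0] <- 0
  map <- .resize_bilinear(map, side, side)
  map[map < 0] <- 0
  if (max(map) > 0) map <- map / max(map)
  structure(list(values = map, class_index = as.integer(class_index),
                 branch = as.integer(branch), branch_size = side,
                 block = as.integer(block)),
            class = "heatmap")
}

#' Render a heatmap overlay to a PNG file
#'
#' Blends a blue-to-red colormapped heatmap over the grayscale image
#' (opacity proportional to heat) and writes an RGB PNG. Deterministic: the
#' same inputs produce identical files. For multi-scale networks call once
#' per branch; `suffix_branch` appends the branch size to the file name.
#'
#' @param image Grayscale matrix in `[0, 1]` (resized to the heatmap size if
#'   needed).
#' @param heatmap A [grad_cam()] result.
#' @param path Output PNG path.
#' @param alpha Maximum overlay opacity.
#' @param suffix_branch Append `_<branch size>` before the extension.
#' @return The written path, invisibly.
#' @export
render_overlay <- function(image, heatmap, path, alpha = 0.45,
                           suffix_branch = FALSE) {
  stopifnot(inherits(heatmap, "heatmap"))
  h <- heatmap$values
  if (nrow(image) != nrow(h) || ncol(image) != ncol(h)) {
    image <- .resize_bilinear(image, nrow(h), ncol(h))
  }
  ramp <- grDevices::colorRamp(c("#0000a0", "#00c0ff", "#ffff00", "#ff2000"))
  cols <- ramp(as.vector(h)) / 255
  out <- array(0, c(nrow(h), ncol(h), 3))
  a <- alpha * as.vector(h)
  for (ch in 1:3) {
    out[, , ch] <- matrix((1 - a) * as.vector(image) + a * cols[, ch],
                          nrow(h), ncol(h))
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  if (suffix_branch) {
    path <- sub("(\\.[A-Za-z]+)$", sprintf("_%d\\1", heatmap$branch_size), path)
  }
  png::writePNG(out, path)
  invisible(path)
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap: class %d, branch %d (%d px), block %d, max %.3f\n",
              x$class_index, x$branch, x$branch_size, x$block, max(x$values)))
  invisible(x)
}
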