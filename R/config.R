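#' Disease classes predicted by the networks
#'
#' Order is fixed throughout the package: age-related macular degeneration
#' (AMD), epiretinal membrane (ERM), macular edema (ME), and Normal. Labels
#' are multi-hot: any subset of the three diseases may be present, and Normal
#' is an explicit fourth output that is 1 exactly when no disease is present.
#' @export
oct_classes <- c("amd", "erm", "me", "normal")

#' Specify one convolutional layer
#'
#' @param kernel_size Side of the square kernel; one of 1, 3, 5, 7.
#' @param out_channels Number of filters (> 0).
#' @param stride Convolution stride (>= 1; the SRN family uses 1 throughout).
#' @param has_bias Whether the layer has an additive bias term.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kernel_size, out_channels, stride = 1L, has_bias = TRUE) {
  kernel_size <- as.integer(kernel_size)
  out_channels <- as.integer(out_channels)
  stride <- as.integer(stride)
  if (!kernel_size %in% c(1L, 3L, 5L, 7L)) {
    stop("kernel_size must be one of 1, 3, 5, 7", call. = FALSE)
  }
  if (out_channels <= 0L) stop("out_channels must be positive", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(
    list(kernel_size = kernel_size, out_channels = out_channels,
         stride = stride, has_bias = isTRUE(has_bias)),
    class = "layer_spec"
  )
}

#' Specify one convolutional block
#'
#' A block is a stack of convolutions followed (optionally) by a 2x2 stride-2
#' max-pool. When `residual` is on, the block input is added to the output of
#' the last convolution before the final rectifier (identity skip if channels
#' match, 1x1 projection with bias otherwise).
#'
#' @param layers List of [layer_spec()] objects (at least one).
#' @param residual Add a skip connection from block input to block output.
#' @param followed_by_pool Apply the 2x2 max-pool after the block.
#' @return A `block_spec` list.
#' @export
block_spec <- function(layers, residual = FALSE, followed_by_pool = TRUE) {
  if (length(layers) < 1L) stop("a block needs at least one layer", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "layer_spec"))) {
    stop("layers must be layer_spec objects", call. = FALSE)
  }
  structure(
    list(layers = layers, residual = isTRUE(residual),
         followed_by_pool = isTRUE(followed_by_pool)),
    class = "block_spec"
  )
}

# Block plan of the SRN family: six blocks, channel widths fixed at
# 32/32/64/128/256/512, a single 7x7 stem and 3x3 convolutions elsewhere.
# The variant name equals the total number of convolutions.
srn_layer_plan <- function(variant) {
  switch(variant,
    "8-layer"  = c(1L, 2L, 2L, 1L, 1L, 1L),
    "10-layer" = c(1L, 3L, 2L, 2L, 1L, 1L),
    "12-layer" = c(1L, 3L, 3L, 2L, 2L, 1L),
    stop("unknown SRN variant '", variant,
         "' (expected one of 8-layer, 10-layer, 12-layer)", call. = FALSE)
  )
}

srn_channel_plan <- c(32L, 32L, 64L, 128L, 256L, 512L)

#' Configure a sparse residual network (SRN)
#'
#' Builds the architectural genotype of one SRN variant: six convolutional
#' blocks with channel widths 32/32/64/128/256/512, a 7x7 stem, 3x3
#' convolutions elsewhere, each block followed by a 2x2 stride-2 max-pool,
#' and global average pooling into a 512-dimensional feature ahead of the
#' classifier head.
#'
#' @param variant One of `"8-layer"`, `"10-layer"`, `"12-layer"`; per-block
#'   layer counts are (1,2,2,1,1,1), (1,3,2,2,1,1) and (1,3,3,2,2,1).
#' @param residual Use skip connections (identity, or 1x1 projection with bias
#'   at the four channel transitions). The stem block never carries a skip.
#' @param in_channels Input channels; grayscale B-scans are replicated to 3.
#' @param num_classes Number of sigmoid outputs (default 4: AMD/ERM/ME/Normal).
#' @param normalization Reserved switch for per-channel normalization layers;
#'   the SRN family is defined without them and only `FALSE` is supported.
#' @return An `srn_config` object.
#' @examples
#' cfg <- srn_config("12-layer")
#' count_parameters(cfg)$parameter_count_millions  # 2.59
#' @export
srn_config <- function(variant = c("12-layer", "8-layer", "10-layer"),
                       residual = TRUE, in_channels = 3L, num_classes = 4L,
                       normalization = FALSE) {
  variant <- match.arg(variant)
  counts <- srn_layer_plan(variant)
  if (isTRUE(normalization)) {
    stop("normalization layers are not part of the SRN definition and are not supported",
         call. = FALSE)
  }
  blocks <- vector("list", 6L)
  for (b in seq_len(6L)) {
    k <- if (b == 1L) 7L else 3L
    layers <- replicate(counts[b], layer_spec(k, srn_channel_plan[b]),
                        simplify = FALSE)
    blocks[[b]] <- block_spec(layers, residual = residual && b > 1L)
  }
  structure(
    list(variant_name = variant, blocks = blocks,
         in_channels = as.integer(in_channels), feature_dim = 512L,
         num_classes = as.integer(num_classes), residual = isTRUE(residual),
         normalization = FALSE),
    class = "srn_config"
  )
}

#' Configure a multi-scale SRN (MS-SRN)
#'
#' One independent SRN trunk per input scale; the classifier heads of the
#' trunks are discarded, the per-branch 512-features are concatenated and a
#' single fully connected layer (with bias) maps the fused feature to the
#' class logits. Default branches are the local 448 and global 224 scales.
#'
#' @param branch_sizes Input side length in pixels for each branch (>= 1).
#' @param variant SRN variant used for every trunk.
#' @inheritParams srn_config
#' @return An `ms_srn_config` object.
#' @export
ms_srn_config <- function(branch_sizes = c(448L, 224L),
                          variant = "12-layer", residual = TRUE,
                          in_channels = 3L, num_classes = 4L) {
  if (length(branch_sizes) < 1L) stop("at least one branch is required", call. = FALSE)
  branch_sizes <- as.integer(branch_sizes)
  for (s in branch_sizes) check_input_side(s)
  cfg <- srn_config(variant, residual = residual, in_channels = in_channels,
                    num_classes = num_classes)
  structure(
    list(branch_sizes = branch_sizes, branch_config = cfg,
         fused_dim = 512L * length(branch_sizes),
         num_classes = as.integer(num_classes)),
    class = "ms_srn_config"
  )
}

# Six 2x2 floor-mode pools need at least one pixel left at the deepest
# block; the canonical sides 112/224/448 all rely on floor mode.
check_input_side <- function(side) {
  side <- as.integer(side)
  if (is.na(side) || side < 64L) {
    stop("input side must be at least 64 pixels (six 2x2 pooling stages)",
         call. = FALSE)
  }
  invisible(side)
}

#' @export
print.srn_config <- function(x, ...) {
  counts <- vapply(x$blocks, function(b) length(b$layers), integer(1))
  cat("SRN config:", x$variant_name,
      if (x$residual) "(residual)" else "(plain)", "\n")
  cat("  layers per block:", paste(counts, collapse = "/"),
      " channels:", paste(srn_channel_plan, collapse = "/"), "\n")
  cat("  in_channels:", x$in_channels, " classes:", x$num_classes, "\n")
  invisible(x)
}

#' @export
print.ms_srn_config <- function(x, ...) {
  cat("MS-SRN config:", length(x$branch_sizes), "branch(es) at",
      paste(x$branch_sizes, collapse = ", "), "px;",
      x$branch_config$variant_name, "trunks; fused dim", x$fused_dim, "\n")
  invisible(x)
}

#' Replace convolution kernels by factorized stacks (or merge them back)
#'
#' Applies a kernel substitution rule to every block of an SRN configuration.
#' The canonical rule replaces each 5x5 convolution by two stacked 3x3
#' convolutions with the same number of filters, preserving the 5x5 receptive
#' field while shrinking the weight count of the unit by a factor 18/25 (for
#' equal input/output width). The inverse rule merges consecutive runs of
#' layers whose kernels match `from` into a single layer, and is only valid
#' when the run is channel-homogeneous after its first layer so that the
#' merged layer reproduces the unit's input/output channels.
#'
#' @param config An `srn_config`.
#' @param from Integer vector of kernel sizes identifying the unit to replace
#'   (e.g. `5`, or `c(3, 3)` for the inverse direction).
#' @param to Integer vector of kernel sizes to substitute (e.g. `c(3, 3)`,
#'   or `5`).
#' @return A new `srn_config` with substituted blocks.
#' @export
substitute_kernels <- function(config, from = 5L, to = c(3L, 3L)) {
  stopifnot(inherits(config, "srn_config"))
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) < 1L || length(to) < 1L) stop("empty substitution rule", call. = FALSE)
  nf <- length(from)
  out <- config
  for (b in seq_along(config$blocks)) {
    layers <- config$blocks[[b]]$layers
    res <- list()
    i <- 1L
    while (i <= length(layers)) {
      run <- seq.int(i, length.out = nf)
      matches <- max(run) <= length(layers) &&
        all(vapply(layers[run], `[[`, integer(1), "kernel_size") == from)
      if (matches && nf > 1L) {
        # merging: all layers after the first must keep the channel width of
        # the unit's output, otherwise the merged layer would change channels
        outs <- vapply(layers[run], `[[`, integer(1), "out_channels")
        matches <- length(unique(outs[-1L])) <= 1L && all(outs[-1L] == outs[nf])
      }
      if (matches) {
        unit_out <- layers[[max(run)]]$out_channels
        first_bias <- layers[[i]]$has_bias
        repl <- lapply(seq_along(to), function(j) {
          layer_spec(to[j], unit_out, has_bias = first_bias)
        })
        res <- c(res, repl)
        i <- i + nf
      } else {
        res <- c(res, layers[i])
        i <- i + 1L
      }
    }
    outs_before <- layers[[length(layers)]]$out_channels
    outs_after <- res[[length(res)]]$out_channels
    if (outs_before != outs_after) {
      stop("substitution would change the block's output channels", call. = FALSE)
    }
    out$blocks[[b]] <- block_spec(res, residual = config$blocks[[b]]$residual,
                                  followed_by_pool = config$blocks[[b]]$followed_by_pool)
  }
  out
}
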