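# Construction of evaluable networks on top of the compiled engine, plus
# parameter plumbing (initialization, checkpoints, flat parameter access).

# Canonical tensor sequence of a network: one entry per learnable tensor, in
# the exact order the engine flattens parameters. Used for seeded
# initialization; parameter counts for built networks are taken from the
# engine's own traversal.
param_plan <- function(branch_cfgs, num_classes) {
  tensors <- list()
  add <- function(name, n, fan_in, kind) {
    tensors[[length(tensors) + 1L]] <<- list(name = name, n = n,
                                             fan_in = fan_in, kind = kind)
  }
  for (br in seq_along(branch_cfgs)) {
    cfg <- branch_cfgs[[br]]
    cin <- cfg$in_channels
    for (b in seq_along(cfg$blocks)) {
      block <- cfg$blocks[[b]]
      block_in <- cin
      for (l in seq_along(block$layers)) {
        ly <- block$layers[[l]]
        k <- ly$kernel_size; cout <- ly$out_channels
        nm <- sprintf("branch%d.block%d.conv%d", br, b, l)
        add(paste0(nm, ".weight"), k * k * cin * cout, k * k * cin, "conv_weight")
        add(paste0(nm, ".bias"), cout, NA_integer_, "bias")
        cin <- cout
      }
      if (block$residual && block_in != cin) {
        nm <- sprintf("branch%d.block%d.proj", br, b)
        add(paste0(nm, ".weight"), block_in * cin, block_in, "conv_weight")
        add(paste0(nm, ".bias"), cin, NA_integer_, "bias")
      }
    }
  }
  fin <- sum(vapply(branch_cfgs, function(cfg) {
    last <- cfg$blocks[[length(cfg$blocks)]]
    last$layers[[length(last$layers)]]$out_channels
  }, integer(1)))
  add("head.weight", fin * num_classes, fin, "head_weight")
  add("head.bias", num_classes, NA_integer_, "bias")
  tensors
}

# Kaiming fan-in initialization for convolution weights, uniform
# +/- 1/sqrt(fan_in) for the head, zero biases. Driven entirely by R's RNG so
# builds are reproducible from a single integer seed.
init_params <- function(plan, seed) {
  set.seed(seed)
  unlist(lapply(plan, function(t) {
    switch(t$kind,
      conv_weight = stats::rnorm(t$n, sd = sqrt(2 / t$fan_in)),
      head_weight = stats::runif(t$n, -1 / sqrt(t$fan_in), 1 / sqrt(t$fan_in)),
      bias = numeric(t$n)
    )
  }), use.names = FALSE)
}

engine_plan <- function(branch_cfgs, in_channels, num_classes) {
  list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    branches = lapply(branch_cfgs, function(cfg) {
      list(blocks = lapply(cfg$blocks, function(b) {
        list(
          kernels = vapply(b$layers, `[[`, integer(1), "kernel_size"),
          channels = vapply(b$layers, `[[`, integer(1), "out_channels"),
          residual = b$residual
        )
      }))
    })
  )
}

#' Build an SRN network from a configuration
#'
#' Instantiates the compiled network: stride-1 convolutions each followed by a
#' rectifier, a 2x2 stride-2 floor-mode max-pool after every block, skip
#' connections per the configuration (added before the block's pool, rectifier
#' after the addition), global average pooling to a 512-feature, and a
#' fully connected sigmoid head.
#'
#' @param config An [srn_config()].
#' @param input_side Nominal input side in pixels used for summaries; forward
#'   evaluation accepts any side of at least 64 pixels.
#' @param seed Integer seed for weight initialization (Kaiming fan-in normal
#'   for convolutions, uniform for the head, zero biases).
#' @return An `srn_net` object.
#' @examples
#' net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 1)
#' x <- array(runif(64 * 64), c(64, 64, 1, 1))
#' p <- predict(net, x)          # 1 x 4 sigmoid probabilities
#' @export
build_srn <- function(config, input_side = 224L, seed = 1L) {
  stopifnot(inherits(config, "srn_config"))
  check_input_side(input_side)
  ptr <- .net_create(engine_plan(list(config), config$in_channels, config$num_classes))
  plan <- param_plan(list(config), config$num_classes)
  .net_set_params(ptr, init_params(plan, seed))
  structure(
    list(ptr = ptr, config = config, branch_sizes = as.integer(input_side),
         num_classes = config$num_classes, fused_dim = 512L, seed = seed),
    class = c("srn_net", "oct_net")
  )
}

#' Build a multi-scale SRN (MS-SRN) from a configuration
#'
#' One independently initialized SRN trunk per branch (classifier heads
#' discarded), feature concatenation, and a single fully connected sigmoid
#' head over the fused feature.
#'
#' @param config An [ms_srn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `ms_srn_net` object.
#' @export
build_ms_srn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ms_srn_config"))
  if (length(config$branch_sizes) < 1L) stop("empty branch list", call. = FALSE)
  branch_cfgs <- rep(list(config$branch_config), length(config$branch_sizes))
  ptr <- .net_create(engine_plan(branch_cfgs, config$branch_config$in_channels,
                                 config$num_classes))
  plan <- param_plan(branch_cfgs, config$num_classes)
  .net_set_params(ptr, init_params(plan, seed))
  structure(
    list(ptr = ptr, config = config, branch_sizes = config$branch_sizes,
         num_classes = config$num_classes, fused_dim = config$fused_dim,
         seed = seed),
    class = c("ms_srn_net", "oct_net")
  )
}

n_branches <- function(net) length(net$branch_sizes)

`%||%` <- function(a, b) if (is.null(a)) b else a

# replicate a (H, W, 1, N) array across channels
replicate_channels <- function(a, cin) {
  d <- dim(a)
  if (d[3] == cin) return(a)
  if (d[3] != 1L) stop("cannot replicate multi-channel input", call. = FALSE)
  out <- array(0, c(d[1], d[2], cin, d[4]))
  for (c in seq_len(cin)) out[, , c, ] <- a[, , 1L, ]
  out
}

#' Forward-evaluate a network
#'
#' @param object An `srn_net` or `ms_srn_net`.
#' @param x A single image matrix, an `(H, W, C, N)` array, or a list with one
#'   array per branch (multi-scale networks). Pixel values in `[0, 1]`;
#'   grayscale inputs are replicated across the input channels.
#' @param type `"prob"` for sigmoid probabilities (N x C matrix), or
#'   `"feature"` for the pooled (fused) feature matrix.
#' @param ... Unused.
#' @return A numeric matrix.
#' @export
predict.oct_net <- function(object, x, type = c("prob", "feature"), ...) {
  type <- match.arg(type)
  xs <- prepare_inputs(object, x)
  out <- .net_forward(object$ptr, xs)
  m <- if (type == "prob") out$probabilities else out$features
  if (type == "prob") colnames(m) <- oct_classes[seq_len(ncol(m))]
  m
}

prepare_inputs <- function(net, x) {
  if (!is.list(x)) x <- list(x)
  if (length(x) != n_branches(net)) {
    stop(sprintf("expected %d branch input(s), got %d", n_branches(net), length(x)),
         call. = FALSE)
  }
  cin <- if (!is.null(net$config$in_channels)) net$config$in_channels
         else net$config$branch_config$in_channels
  lapply(x, function(a) {
    d <- dim(a)
    if (is.null(d)) stop("inputs must be image arrays", call. = FALSE)
    if (length(d) == 2L) a <- array(a, c(d, 1L, 1L))
    if (length(dim(a)) == 3L) a <- array(a, c(dim(a)[1:2], 1L, dim(a)[3]))
    d <- dim(a)
    if (d[1] < 64L || d[2] < 64L) {
      stop("input side must be at least 64 pixels", call. = FALSE)
    }
    replicate_channels(a, cin)
  })
}

#' Flat parameter access
#'
#' `get_weights()` returns every learnable scalar of the network as one
#' numeric vector in the engine's canonical tensor order; `set_weights()`
#' writes such a vector back. [param_layout()] names the slices.
#'
#' @param net A built network.
#' @param weights Numeric vector as returned by `get_weights()`.
#' @return `get_weights()` a numeric vector; `set_weights()` the network,
#'   invisibly.
#' @export
get_weights <- function(net) .net_get_params(net$ptr)

#' @rdname get_weights
#' @export
set_weights <- function(net, weights) {
  .net_set_params(net$ptr, weights)
  invisible(net)
}

#' @rdname get_weights
#' @export
param_layout <- function(net) .net_param_layout(net$ptr)

#' Save / load a network checkpoint
#'
#' A checkpoint stores the serialized configuration together with the full
#' flat parameter vector, so `load_checkpoint()` reconstructs an identical
#' network (same architecture, same weights).
#'
#' @param net A built network.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()` the path invisibly; `load_checkpoint()` the
#'   rebuilt network.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(config = net$config, branch_sizes = net$branch_sizes,
               params = get_weights(net), package_version = "0.1.0"),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- if (inherits(ck$config, "ms_srn_config")) {
    build_ms_srn(ck$config, seed = 1L)
  } else {
    build_srn(ck$config, input_side = ck$branch_sizes[1], seed = 1L)
  }
  set_weights(net, ck$params)
  net
}

#' @export
print.oct_net <- function(x, ...) {
  cat(if (inherits(x, "ms_srn_net")) "MS-SRN network" else "SRN network", "\n")
  cat("  branches:", paste(x$branch_sizes, collapse = ", "), "px\n")
  n <- .net_nparams(x$ptr)
  cat(sprintf("  parameters: %s (%.2f M)\n", format(n, big.mark = ","), n / 1e6))
  invisible(x)
}
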