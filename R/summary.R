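# Learnable-parameter and multiply-accumulate (MAC) accounting.

#' Count learnable parameters
#'
#' Counts every learnable scalar: convolution weights, all biases (including
#' the 1x1 skip projections), and the fully connected head. For built
#' networks the count is taken by traversing the engine's actual tensors; for
#' configurations it is computed from the architectural plan.
#'
#' @param x An `srn_config`, `ms_srn_config`, or a built network.
#' @return A `model_summary` list with `parameter_count` (integer) and
#'   `parameter_count_millions` (rounded to 2 decimals).
#' @examples
#' count_parameters(srn_config("8-layer"))$parameter_count   # 1804932
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

new_model_summary <- function(n, macs = NA_real_, input_side = NA_integer_) {
  structure(
    list(parameter_count = n,
         parameter_count_millions = round(n / 1e6, 2),
         mac_count = macs, input_side = input_side),
    class = "model_summary"
  )
}

#' @export
count_parameters.srn_config <- function(x) {
  plan <- param_plan(list(x), x$num_classes)
  new_model_summary(sum(vapply(plan, `[[`, numeric(1), "n")))
}

#' @export
count_parameters.ms_srn_config <- function(x) {
  branch_cfgs <- rep(list(x$branch_config), length(x$branch_sizes))
  plan <- param_plan(branch_cfgs, x$num_classes)
  new_model_summary(sum(vapply(plan, `[[`, numeric(1), "n")))
}

#' @export
count_parameters.oct_net <- function(x) new_model_summary(.net_nparams(x$ptr))

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("parameters: %s (%.2f M)",
              format(x$parameter_count, big.mark = ","),
              x$parameter_count_millions))
  if (!is.na(x$mac_count)) {
    cat(sprintf("; MACs at %d px: %s", x$input_side,
                format(x$mac_count, big.mark = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Multiply-accumulate cost of a convolution
#'
#' `kernel^2 * in_channels * out_channels` per output position, times the
#' number of output positions. The unit is one MAC (one multiply plus one
#' add); no convention for converting to "FLOPs" is applied.
#'
#' @param kernel_size Square kernel side.
#' @param in_channels,out_channels Channel counts.
#' @param out_positions Number of spatial output positions (1 gives the
#'   per-position cost, useful for comparing kernel choices).
#' @return MAC count (numeric).
#' @examples
#' conv_macs(3, 32, 32, 112^2)            # 115605504
#' conv_macs(5, 16, 16, 1) / conv_macs(3, 16, 16, 1)  # 25/9
#' @export
conv_macs <- function(kernel_size, in_channels, out_channels, out_positions = 1) {
  as.numeric(kernel_size)^2 * in_channels * out_channels * out_positions
}

#' Count multiply-accumulate operations at a given input size
#'
#' Sums `kernel^2 * cin * cout * output_positions` over every convolution
#' (including 1x1 skip projections) plus the fully connected head. Pooling
#' and activations are not counted. Reported as MACs; printed "FLOPs" figures
#' elsewhere may follow a different convention and are not asserted against.
#'
#' @param x A configuration or built network, or a list of [layer_spec()]
#'   objects forming a plain convolution stack.
#' @param input_side Input side length in pixels.
#' @param in_channels Input channels (only needed for plain layer lists).
#' @return Total MAC count (numeric).
#' @export
count_macs <- function(x, input_side = 224L, in_channels = 3L) {
  UseMethod("count_macs")
}

#' @export
count_macs.srn_config <- function(x, input_side = 224L, in_channels = NULL) {
  side <- as.integer(input_side)
  check_input_side(side)
  cin <- x$in_channels
  total <- 0
  for (b in seq_along(x$blocks)) {
    block <- x$blocks[[b]]
    block_in <- cin
    for (ly in block$layers) {
      total <- total + conv_macs(ly$kernel_size, cin, ly$out_channels, side^2)
      cin <- ly$out_channels
    }
    if (block$residual && block_in != cin) {
      total <- total + conv_macs(1L, block_in, cin, side^2)
    }
    if (block$followed_by_pool) side <- side %/% 2L
  }
  total + x$feature_dim * x$num_classes
}

#' @export
count_macs.ms_srn_config <- function(x, input_side = NULL, in_channels = NULL) {
  sides <- if (is.null(input_side)) x$branch_sizes else as.integer(input_side)
  if (length(sides) == 1L) sides <- rep(sides, length(x$branch_sizes))
  trunk <- x$branch_config
  per_branch <- vapply(seq_along(sides), function(i) {
    count_macs(trunk, sides[i]) - trunk$feature_dim * trunk$num_classes
  }, numeric(1))
  sum(per_branch) + x$fused_dim * x$num_classes
}

#' @export
count_macs.srn_net <- function(x, input_side = x$branch_sizes[1], in_channels = NULL) {
  count_macs(x$config, input_side)
}

#' @export
count_macs.ms_srn_net <- function(x, input_side = NULL, in_channels = NULL) {
  count_macs(x$config, input_side)
}

#' @export
count_macs.list <- function(x, input_side = 1L, in_channels = 3L) {
  if (!all(vapply(x, inherits, logical(1), "layer_spec"))) {
    stop("list method expects layer_spec objects", call. = FALSE)
  }
  cin <- in_channels
  total <- 0
  for (ly in x) {
    total <- total + conv_macs(ly$kernel_size, cin, ly$out_channels,
                               as.numeric(input_side)^2)
    cin <- ly$out_channels
  }
  total
}

#' Summarize model sizes
#'
#' One row per model: name, exact parameter count, parameters in millions
#' (2 decimals) and MACs at the stated input side.
#'
#' @param variants Character vector of SRN variants (e.g. `"8-layer"`), may
#'   be empty.
#' @param ms_branches Optional integer vector of branch sizes; adds an MS-SRN
#'   row evaluated at those sizes.
#' @param resnets Optional integer vector of reference residual-network
#'   depths (18 and/or 101).
#' @param input_side Input side for MAC accounting of single-scale models.
#' @param num_classes Classifier width.
#' @param residual Whether the SRN variants use skip connections.
#' @return A data.frame.
#' @examples
#' summarize_models(c("8-layer", "10-layer", "12-layer"), ms_branches = c(448, 224))
#' @export
summarize_models <- function(variants = c("8-layer", "10-layer", "12-layer"),
                             ms_branches = NULL, resnets = NULL,
                             input_side = 224L, num_classes = 4L,
                             residual = TRUE) {
  rows <- list()
  for (v in variants) {
    cfg <- srn_config(v, residual = residual, num_classes = num_classes)
    n <- count_parameters(cfg)$parameter_count
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("SRN-", sub("-layer", "", v), if (!residual) " (plain)" else ""),
      input_side = input_side, parameters = n, params_M = round(n / 1e6, 2),
      macs = count_macs(cfg, input_side))
  }
  if (!is.null(ms_branches)) {
    cfg <- ms_srn_config(branch_sizes = ms_branches, num_classes = num_classes)
    n <- count_parameters(cfg)$parameter_count
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("MS-SRN (", paste(ms_branches, collapse = "+"), ")"),
      input_side = NA_integer_, parameters = n, params_M = round(n / 1e6, 2),
      macs = count_macs(cfg))
  }
  for (d in resnets) {
    s <- count_reference_resnet(d, num_classes = num_classes,
                                input_side = input_side)
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("ResNet-", d), input_side = input_side,
      parameters = s$parameter_count, params_M = s$parameter_count_millions,
      macs = s$mac_count)
  }
  if (!length(rows)) stop("no models requested", call. = FALSE)
  do.call(rbind, rows)
}
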