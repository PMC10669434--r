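# Reference residual-network topologies (basic-block ResNet-18, bottleneck
# ResNet-101), used only for parameter/MAC accounting against the SRN family.
# Standard ImageNet layout: 7x7/64 stride-2 stem, 3x3 stride-2 max-pool, four
# stages, global average pooling, fully connected output. Convolutions carry
# no bias; every convolution is followed by batch normalization whose scale
# and shift are the learnable pairs counted here.

resnet_stage_plan <- function(depth) {
  switch(as.character(depth),
    "18" = list(block = "basic", reps = c(2L, 2L, 2L, 2L), expansion = 1L),
    "101" = list(block = "bottleneck", reps = c(3L, 4L, 23L, 3L), expansion = 4L),
    stop("unsupported reference depth ", depth, " (expected 18 or 101)",
         call. = FALSE)
  )
}

# Returns a data.frame of every learnable tensor with its parameter count and
# MAC cost at the given input side.
resnet_tensor_table <- function(depth, num_classes = 1000L, input_side = 224L) {
  plan <- resnet_stage_plan(depth)
  widths <- c(64L, 128L, 256L, 512L)
  rows <- list()
  add <- function(name, params, macs) {
    rows[[length(rows) + 1L]] <<- data.frame(tensor = name, params = params,
                                             macs = macs)
  }
  conv <- function(name, k, cin, cout, side_out) {
    add(paste0(name, ".conv"), k^2 * cin * cout, conv_macs(k, cin, cout, side_out^2))
    add(paste0(name, ".bn"), 2 * cout, 0)
  }
  side <- input_side %/% 2L            # stem stride 2
  conv("stem", 7L, 3L, 64L, side)
  side <- side %/% 2L                  # 3x3 max-pool stride 2
  cin <- 64L
  for (s in seq_len(4L)) {
    w <- widths[s]
    cout <- w * plan$expansion
    for (r in seq_len(plan$reps[s])) {
      stride <- if (s > 1L && r == 1L) 2L else 1L
      if (stride == 2L) side <- side %/% 2L
      nm <- sprintf("stage%d.block%d", s, r)
      if (plan$block == "basic") {
        conv(paste0(nm, ".conv1"), 3L, cin, w, side)
        conv(paste0(nm, ".conv2"), 3L, w, w, side)
      } else {
        conv(paste0(nm, ".conv1"), 1L, cin, w, if (stride == 2L) side * 2L else side)
        conv(paste0(nm, ".conv2"), 3L, w, w, side)   # stride lives on conv2
        conv(paste0(nm, ".conv3"), 1L, w, cout, side)
      }
      if (r == 1L && cin != cout || (r == 1L && stride == 2L)) {
        conv(paste0(nm, ".downsample"), 1L, cin, cout, side)
      }
      cin <- cout
    }
  }
  add("fc", cin * num_classes + num_classes, cin * num_classes)
  do.call(rbind, rows)
}

#' Parameter and MAC count of a reference residual network
#'
#' Constructs the canonical 18-layer (basic-block) or 101-layer (bottleneck)
#' residual topology with its final layer replaced by a `num_classes`-way
#' output, and counts learnable scalars: convolution weights, the per-channel
#' scale/shift pairs of each normalization layer, and the output layer's
#' weights and bias.
#'
#' @param depth 18 or 101.
#' @param num_classes Output width (default 4).
#' @param input_side Input side for the MAC count (default 224).
#' @return A `model_summary`.
#' @examples
#' count_reference_resnet(18)$parameter_count_millions   # 11.18
#' @export
count_reference_resnet <- function(depth, num_classes = 4L, input_side = 224L) {
  tab <- resnet_tensor_table(depth, num_classes = as.integer(num_classes),
                             input_side = as.integer(input_side))
  new_model_summary(sum(tab$params), sum(tab$macs), as.integer(input_side))
}
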