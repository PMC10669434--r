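# SRN/MS-SRN construction, parameter accounting, MAC accounting, kernel
# substitution and the reference residual networks.

test_that("SRN variant parameter counts match the closed-form oracle and the printed roundings", {
  plans <- list("8-layer" = c(1, 2, 2, 1, 1, 1),
                "10-layer" = c(1, 3, 2, 2, 1, 1),
                "12-layer" = c(1, 3, 3, 2, 2, 1))
  expected_m <- c("8-layer" = 1.80, "10-layer" = 1.96, "12-layer" = 2.59)
  frozen <- c("8-layer" = 1804932, "10-layer" = 1961764, "12-layer" = 2588772)
  for (v in names(plans)) {
    oracle <- oracle_srn_params(plans[[v]])
    expect_identical(oracle, frozen[[v]])
    s <- count_parameters(srn_config(v))
    expect_equal(s$parameter_count, oracle)
    expect_equal(s$parameter_count_millions, expected_m[[v]])
    # engine traversal of the built network agrees with the analytic count
    net <- build_srn(srn_config(v), input_side = 64, seed = 1)
    expect_equal(count_parameters(net)$parameter_count, oracle)
  }
  plain <- count_parameters(srn_config("12-layer", residual = FALSE))
  expect_equal(plain$parameter_count,
               oracle_srn_params(c(1, 3, 3, 2, 2, 1), residual = FALSE))
  expect_identical(plain$parameter_count, 2413732)
  expect_equal(plain$parameter_count_millions, 2.41)
})

test_that("residual minus plain difference is exactly the four 1x1 projections", {
  res <- count_parameters(srn_config("12-layer"))$parameter_count
  plain <- count_parameters(srn_config("12-layer", residual = FALSE))$parameter_count
  proj_weights <- 32 * 64 + 64 * 128 + 128 * 256 + 256 * 512
  proj_biases <- 64 + 128 + 256 + 512
  expect_equal(proj_weights, 174080)
  expect_equal(res - plain, proj_weights + proj_biases)
})

test_that("MS-SRN parameter count matches the multi-branch oracle and 5.18 M", {
  s <- count_parameters(ms_srn_config(branch_sizes = c(448, 224)))
  expect_equal(s$parameter_count, oracle_ms_params(c(1, 3, 3, 2, 2, 1), 2))
  expect_identical(s$parameter_count, 5177540)
  expect_equal(s$parameter_count_millions, 5.18)
  # one-branch degeneracy: equals the standalone SRN-12 count
  one <- count_parameters(ms_srn_config(branch_sizes = 224))
  expect_equal(one$parameter_count,
               count_parameters(srn_config("12-layer"))$parameter_count)
  # three branches: 3 x headless trunk + fused head
  three <- count_parameters(ms_srn_config(branch_sizes = c(112, 224, 448)))
  expect_equal(three$parameter_count, oracle_ms_params(c(1, 3, 3, 2, 2, 1), 3))
  expect_equal(three$parameter_count,
               3 * (2588772 - 2052) + (1536 * 4 + 4))
  # built network traversal agrees
  net <- build_ms_srn(ms_srn_config(branch_sizes = c(64, 128)), seed = 1)
  expect_equal(count_parameters(net)$parameter_count, 5177540)
})

test_that("single-layer parameter arithmetic is exact", {
  # one 3x3 conv 32->32 with bias, via a built network's layout
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 1)
  lay <- param_layout(net)
  w <- lay[lay$tensor == "branch1.block2.conv1.weight", "size"]
  b <- lay[lay$tensor == "branch1.block2.conv1.bias", "size"]
  expect_equal(w + b, 9248)
  expect_equal(lay[lay$tensor == "head.weight", "size"] +
                 lay[lay$tensor == "head.bias", "size"], 2052)
})

test_that("forward contract: 512-feature and C logits for any side >= 64", {
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 2)
  for (side in c(64, 96, 128)) {
    x <- make_gray_batch(side, 2, seed = side)
    f <- predict(net, x, type = "feature")
    p <- predict(net, x)
    expect_identical(dim(f), c(2L, 512L))
    expect_identical(dim(p), c(2L, 4L))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(predict(net, make_gray_batch(32, 1)), "at least 64")
})

test_that("block output sides halve at each stage (floor pooling)", {
  net <- build_srn(srn_config("8-layer"), input_side = 128, seed = 1)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  for (b in 1:6) {
    act <- block_activation(net, x, block = b)
    expect_equal(dim(act)[1], 128 %/% 2^(b - 1))
  }
})

test_that("builds are deterministic given config and seed", {
  x <- make_gray_batch(64, 2, seed = 9)
  n1 <- build_srn(srn_config("10-layer"), input_side = 64, seed = 5)
  n2 <- build_srn(srn_config("10-layer"), input_side = 64, seed = 5)
  expect_identical(get_weights(n1), get_weights(n2))
  expect_identical(predict(n1, x), predict(n2, x))
  n3 <- build_srn(srn_config("10-layer"), input_side = 64, seed = 6)
  expect_false(identical(get_weights(n1), get_weights(n3)))
})

test_that("residual passthrough: zeroed main path reproduces the (projected) skip", {
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))

  # identity-skip block (block 2, 32 -> 32): zeroed convs give
  # out = relu(0 + input) = input, since the input is already post-ReLU
  zero_block_main_path(net, 1, 2)
  in2 <- ref_maxpool2(block_activation(net, x, block = 1))
  out2 <- block_activation(net, x, block = 2)
  expect_equal(out2, in2, tolerance = 1e-6)

  # projection-skip block (block 3, 32 -> 64): out = relu(proj(input))
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 3)
  zero_block_main_path(net, 1, 3)
  w <- get_weights(net)
  in3 <- ref_maxpool2(block_activation(net, x, block = 2))
  pw <- matrix(w[tensor_slice(net, "branch1.block3.proj.weight")], 32, 64)
  pb <- w[tensor_slice(net, "branch1.block3.proj.bias")]
  d <- dim(in3)
  flat <- matrix(in3, d[1] * d[2], d[3])
  proj <- flat %*% pw
  proj <- sweep(proj, 2, pb, "+")
  proj[proj < 0] <- 0
  expected <- array(proj, c(d[1], d[2], 64L))
  out3 <- block_activation(net, x, block = 3)
  expect_equal(out3, expected, tolerance = 1e-5)
})

test_that("kernel substitution factorizes and round-trips", {
  cfg <- srn_config("8-layer")
  # identity rule leaves the config unchanged
  same <- substitute_kernels(cfg, from = 3L, to = 3L)
  expect_equal(same, cfg)
  # merge 3x3 pairs into 5x5 units, then factorize back
  merged <- substitute_kernels(cfg, from = c(3L, 3L), to = 5L)
  k2 <- vapply(merged$blocks[[2]]$layers, `[[`, integer(1), "kernel_size")
  expect_identical(k2, 5L)
  restored <- substitute_kernels(merged, from = 5L, to = c(3L, 3L))
  for (b in 1:6) {
    expect_identical(
      vapply(restored$blocks[[b]]$layers, `[[`, integer(1), "kernel_size"),
      vapply(cfg$blocks[[b]]$layers, `[[`, integer(1), "kernel_size"))
    expect_identical(
      vapply(restored$blocks[[b]]$layers, `[[`, integer(1), "out_channels"),
      vapply(cfg$blocks[[b]]$layers, `[[`, integer(1), "out_channels"))
  }
  # weight factor of one channel-homogeneous unit: 18/25 (weights, equal filters)
  n <- 32
  w5 <- conv_macs(5, n, n, 1)
  w33 <- conv_macs(3, n, n, 1) + conv_macs(3, n, n, 1)
  expect_equal(w33 / w5, 18 / 25)
})

test_that("MAC accounting: closed forms, ratios, additivity and quadratic scaling", {
  expect_equal(conv_macs(3, 32, 32, 112^2), 115605504)
  expect_equal(conv_macs(5, 16, 16, 1) / conv_macs(3, 16, 16, 1), 25 / 9,
               tolerance = 1e-12)
  stack33 <- list(layer_spec(3, 16), layer_spec(3, 16))
  expect_equal(conv_macs(5, 16, 16, 1) / count_macs(stack33, 1, in_channels = 16),
               25 / 18, tolerance = 1e-12)
  # additive over layers
  l1 <- list(layer_spec(3, 8)); l2 <- list(layer_spec(5, 4))
  both <- list(layer_spec(3, 8), layer_spec(5, 4))
  expect_equal(count_macs(l1, 10, in_channels = 2) +
                 count_macs(l2, 10, in_channels = 8),
               count_macs(both, 10, in_channels = 2))
  # conv cost scales quadratically with the input side
  cfg <- srn_config("8-layer")
  head_macs <- 512 * 4
  m1 <- count_macs(cfg, 128) - head_macs
  m2 <- count_macs(cfg, 256) - head_macs
  expect_equal(m2 / m1, 4, tolerance = 1e-9)
})

test_that("reference residual networks reproduce canonical counts", {
  r18 <- count_reference_resnet(18)
  expect_equal(r18$parameter_count_millions, 11.18)
  # canonical 1000-class counts of the published topologies
  expect_identical(count_reference_resnet(18, 1000)$parameter_count, 11689512)
  expect_identical(count_reference_resnet(101, 1000)$parameter_count, 44549160)
  ratio <- 100 * count_parameters(srn_config("12-layer"))$parameter_count /
    count_reference_resnet(101)$parameter_count
  expect_equal(round(ratio, 1), 6.1)
  expect_error(count_reference_resnet(50), "unsupported")
})

test_that("invalid configurations are rejected", {
  expect_error(srn_config("9-layer"))
  expect_error(layer_spec(4, 16), "kernel_size")
  expect_error(layer_spec(3, 0), "out_channels")
  expect_error(ms_srn_config(branch_sizes = integer()), "at least one branch")
  expect_error(build_srn(srn_config("8-layer"), input_side = 32), "at least 64")
  expect_error(srn_config("8-layer", normalization = TRUE), "normalization")
})
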