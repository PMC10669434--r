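# Multi-label loss, splitting, augmentation, and the SGD training loop.

test_that("multi-label loss reproduces analytic values", {
  # perfect prediction -> 0 after clamping (up to the clamp epsilon)
  y <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_lt(multi_label_loss(y, y), 1e-6)
  # uniform 0.5 predictions force log(2) regardless of the labels
  for (lab in list(c(1, 0, 0, 0), c(0, 1, 1, 0), c(0, 0, 0, 1))) {
    expect_equal(multi_label_loss(rep(0.5, 4), lab), log(2), tolerance = 1e-12)
  }
  # hand-computed elementwise case
  got <- multi_label_loss(c(0.8, 0.1, 0.2, 0.1), c(1, 0, 0, 0))
  expect_equal(got, -(log(0.8) + log(0.9) + log(0.8) + log(0.9)) / 4,
               tolerance = 1e-12)
  expect_error(multi_label_loss(matrix(0.5, 2, 4), matrix(0, 2, 3)), "shape")
})

test_that("loss equals the elementwise oracle and is positive off-target", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    pred <- matrix(runif(n * 4), n, 4)
    truth <- matrix(rbinom(n * 4, 1, 0.4), n, 4)
    expect_equal(multi_label_loss(pred, truth), oracle_bce(pred, truth),
                 tolerance = 1e-12)
  }
  expect_gt(multi_label_loss(matrix(0.4, 1, 4), matrix(c(1, 0, 0, 0), 1, 4)), 0)
})

test_that("split is a deterministic stratified partition with floor on the test side", {
  man <- data.frame(
    path = sprintf("img%03d.png", 1:100),
    amd = rep(c(1, 0), c(30, 70)), erm = 0, me = 0,
    normal = rep(c(0, 1), c(30, 70)),
    patient_id = rep(sprintf("P%02d", 1:20), each = 5)
  )
  s1 <- split_dataset(man, 0.8, seed = 4)
  expect_identical(sort(unique(s1$split)), c("test", "train"))
  expect_equal(sum(s1$split == "test"), 20)
  expect_equal(sum(s1$split == "train"), 80)
  # per-combination train fraction within one record of 80%
  for (combo in unique(paste(man$amd, man$normal))) {
    idx <- paste(man$amd, man$normal) == combo
    expect_lte(abs(sum(s1$split[idx] == "train") - 0.8 * sum(idx)), 1)
  }
  expect_identical(split_dataset(man, 0.8, seed = 4)$split, s1$split)
  expect_false(identical(split_dataset(man, 0.8, seed = 5)$split, s1$split))
  # patient-level split keeps whole patients on one side
  sp <- split_dataset(man, 0.8, seed = 4, by_patient = TRUE)
  sides <- tapply(sp$split, sp$patient_id, function(x) length(unique(x)))
  expect_true(all(sides == 1))
  expect_error(split_dataset(man[0, ], 0.8, 1), "empty")
})

test_that("augmentation: identity at zero magnitude, involution, determinism", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(augment_image(img, rotation_degrees = 0, flip_probability = 0),
                   img)
  flipped_twice <- img[, rev(seq_len(ncol(img)))][, rev(seq_len(ncol(img)))]
  expect_identical(flipped_twice, img)
  set.seed(12); a1 <- augment_image(img)
  set.seed(12); a2 <- augment_image(img)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("one SGD step updates the head by the hand-computed gradient", {
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 8)
  x <- make_gray_batch(64, 4, seed = 2)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  f <- predict(net, x, type = "feature")
  p <- unname(predict(net, x))
  w0 <- get_weights(net)
  hw <- tensor_slice(net, "head.weight")
  hb <- tensor_slice(net, "head.bias")
  lr <- 0.01
  octsrn:::.net_train_batch(net$ptr,
                            list(octsrn:::replicate_channels(x, 3)),
                            y, lr, 0, 0, 1e-7)
  w1 <- get_weights(net)
  dlogit <- (p - y) / (4 * 4)
  gW <- t(f) %*% dlogit                       # fin x C
  expect_equal(w1[hw], w0[hw] - lr * as.vector(gW), tolerance = 1e-5)
  expect_equal(w1[hb], w0[hb] - lr * colSums(dlogit), tolerance = 1e-5)
})

test_that("training is deterministic and loss decreases on a tiny easy problem", {
  cfg <- tiny_phantom_config(side = 64, seed = 21, speckle_contrast = 0.15)
  ds <- generate_dataset(60, cfg, seed = 21)
  images <- lapply(ds$samples, `[[`, "image")
  tc <- train_config(epochs = 3L, batch_size = 16L)
  run <- function(seed) {
    net <- build_srn(srn_config("8-layer"), input_side = 64, seed = seed)
    fit(net, ds$manifest, tc, seed = seed, images = images)
  }
  r1 <- run(5)
  expect_equal(nrow(r1$log), 3L)
  expect_lte(r1$log$train_loss[3], r1$log$train_loss[1])
  r2 <- run(5)
  expect_identical(get_weights(r1$net), get_weights(r2$net))
  expect_identical(r1$log, r2$log)
  r3 <- run(6)
  expect_false(identical(get_weights(r1$net), get_weights(r3$net)))
})

test_that("run_seeds aggregates mean +/- std in the conventional format", {
  expect_equal(format_mean_sd(c(0.974, 0.9744, 0.9736)), "97.40 ± 0.04")
  cfg <- tiny_phantom_config(side = 64, seed = 33)
  ds <- generate_dataset(40, cfg, seed = 33)
  images <- lapply(ds$samples, `[[`, "image")
  tc <- train_config(epochs = 1L, batch_size = 16L)
  runs <- run_seeds(function(s) build_srn(srn_config("8-layer"),
                                          input_side = 64, seed = s),
                    ds$manifest, tc, seeds = c(2, 3), images = images)
  expect_equal(nrow(runs$per_seed), 2L)
  agg <- runs$aggregate
  expect_equal(agg$mean[agg$metric == "mu_acc"], mean(runs$per_seed$mu_acc))
  expect_error(run_seeds(identity, ds$manifest, tc, seeds = 1), "at least 2")
})

test_that("multi-scale networks train end-to-end with shared augmentation draws", {
  cfg <- tiny_phantom_config(side = 96, seed = 44)
  ds <- generate_dataset(32, cfg, seed = 44)
  images <- lapply(ds$samples, `[[`, "image")
  tc <- train_config(epochs = 2L, batch_size = 8L)
  run <- function(seed) {
    net <- build_ms_srn(ms_srn_config(branch_sizes = c(96, 64),
                                      variant = "8-layer"), seed = seed)
    fit(net, ds$manifest, tc, seed = seed, images = images)
  }
  r1 <- run(3)
  expect_true(all(is.finite(r1$log$train_loss)))
  expect_identical(dim(predict(r1$net, list(
    array(images[[1]], c(96, 96, 1, 1)),
    array(octsrn:::.resize_bilinear(images[[1]], 64L, 64L), c(64, 64, 1, 1))
  ))), c(1L, 4L))
  r2 <- run(3)
  expect_identical(get_weights(r1$net), get_weights(r2$net))
})

test_that("divergent training aborts with a diagnostic", {
  net <- build_srn(srn_config("8-layer"), input_side = 64, seed = 1)
  w <- get_weights(net)
  w[tensor_slice(net, "head.weight")] <- 1e30
  w[tensor_slice(net, "head.bias")] <- 1e30
  set_weights(net, w)
  x <- make_gray_batch(64, 2)
  y <- matrix(0, 2, 4); y[, 4] <- 1
  expect_error(
    octsrn:::.net_train_batch(net$ptr, list(octsrn:::replicate_channels(x, 3)),
                              y, 0.003, 0.9, 1e-4, 0),
    "non-finite")
})
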