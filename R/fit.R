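# SGD training loop, evaluation, and multi-seed orchestration.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with batch size 64, learning
#' rate 0.003, momentum 0.9, weight decay 1e-4, 200 epochs, an 80/20
#' image-level split, random rotation within +/-10 degrees and
#' horizontal/vertical flips with probability 0.5 each, sigmoid threshold 0.5
#' for binarization, and five seeds for mean +/- std reporting. Scale
#' `epochs` down for desk-size experiments.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate (constant schedule).
#' @param epochs Training epochs.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coupled into the SGD update.
#' @param seeds Integer seeds for [run_seeds()].
#' @param split_fraction Train fraction of the dataset.
#' @param rotation_degrees Augmentation rotation magnitude (degrees).
#' @param flip_probability Per-axis flip probability.
#' @param probability_threshold Sigmoid threshold for binarizing predictions.
#' @param eps Probability clamp used inside the loss.
#' @param by_patient Split at patient granularity (leakage-safe) instead of
#'   the default image granularity.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 0.003,
                         epochs = 200L, momentum = 0.9, weight_decay = 1e-4,
                         seeds = 1:5, split_fraction = 0.8,
                         rotation_degrees = 10, flip_probability = 0.5,
                         probability_threshold = 0.5, eps = 1e-7,
                         by_patient = FALSE) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (probability_threshold <= 0 || probability_threshold >= 1) {
    stop("probability_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "train_config")
}

apply_augment <- function(image, ang, fh, fv, bg = 0) {
  if (fh) image <- image[, rev(seq_len(ncol(image)))]
  if (fv) image <- image[rev(seq_len(nrow(image))), ]
  if (ang != 0) image <- .rotate_bilinear(image, ang, bg)
  image
}

# Resolve manifest rows into per-branch lists of side x side matrices.
# `images` may carry in-memory matrices (one per manifest row) to avoid IO;
# otherwise images are read from manifest$path.
branch_image_cache <- function(net, manifest, images = NULL) {
  sides <- net$branch_sizes
  n <- nrow(manifest)
  get_raw <- function(i) {
    if (!is.null(images)) images[[i]] else load_image(manifest$path[i])
  }
  lapply(sides, function(s) {
    lapply(seq_len(n), function(i) {
      img <- get_raw(i)
      if (nrow(img) != s || ncol(img) != s) img <- .resize_bilinear(img, s, s)
      img
    })
  })
}

# Stack a list of matrices into the (H, W, C, N) array the engine expects,
# replicating grayscale across input channels.
stack_batch <- function(mats, cin) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]]); n <- length(mats)
  a <- array(0, c(h, w, cin, n))
  for (i in seq_len(n)) for (c in seq_len(cin)) a[, , c, i] <- mats[[i]]
  a
}

net_in_channels <- function(net) {
  if (!is.null(net$config$in_channels)) net$config$in_channels
  else net$config$branch_config$in_channels
}

predict_cached <- function(net, cache, idx, batch_size = 64L,
                           type = "prob") {
  cin <- net_in_channels(net)
  out <- NULL
  for (start in seq(1L, length(idx), by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1L, length(idx))]
    xs <- lapply(cache, function(br) stack_batch(br[take], cin))
    p <- predict(net, xs, type = type)
    out <- rbind(out, p)
  }
  out
}

#' Train a network with SGD
#'
#' Runs the full seeded pipeline on a manifest: 80/20 split (unless the
#' manifest already carries a `split` column), per-epoch shuffling, rotation
#' and flip augmentation applied consistently across branches, mini-batch SGD
#' with momentum and weight decay on the multi-label sigmoid loss, per-epoch
#' test metrics, and retention of the checkpoint with the best micro-average
#' accuracy. Everything is deterministic given `(seed, config, manifest)`;
#' non-finite loss aborts with a diagnostic.
#'
#' @param net A built network (its current weights are the starting point).
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param config A [train_config()].
#' @param seed Integer seed driving the split, shuffling and augmentation.
#' @param images Optional list of in-memory grayscale matrices aligned with
#'   the manifest rows (skips file IO).
#' @param verbose Print one line per epoch.
#' @return An `srn_fit` list: the trained `net` (restored to its best
#'   checkpoint), `log` (per-epoch loss and test metrics), `best_epoch`,
#'   `best_weights`, and the evaluation `report` of the best checkpoint.
#' @export
fit <- function(net, manifest, config = train_config(), seed = 1L,
                images = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "oct_net"), inherits(config, "train_config"))
  validate_manifest(manifest)
  if (!"split" %in% names(manifest)) {
    manifest <- split_dataset(manifest, config$split_fraction, seed = seed,
                              by_patient = config$by_patient)
  }
  set.seed(seed + 1L)
  cin <- net_in_channels(net)
  if (ncol(label_matrix(manifest)) != net$num_classes) {
    stop("manifest classes do not match the network head", call. = FALSE)
  }
  cache <- branch_image_cache(net, manifest, images)
  train_idx <- which(manifest$split == "train")
  test_idx <- which(manifest$split == "test")
  if (!length(train_idx)) stop("no training records", call. = FALSE)
  labels <- label_matrix(manifest)

  log_rows <- vector("list", config$epochs)
  best <- list(mu_acc = -Inf, weights = NULL, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    total_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      aug <- lapply(take, function(i) {
        list(fh = stats::runif(1) < config$flip_probability,
             fv = stats::runif(1) < config$flip_probability,
             ang = if (config$rotation_degrees > 0) {
               stats::runif(1, -config$rotation_degrees, config$rotation_degrees)
             } else 0)
      })
      xs <- lapply(cache, function(br) {
        mats <- lapply(seq_along(take), function(j) {
          a <- aug[[j]]
          apply_augment(br[[take[j]]], a$ang, a$fh, a$fv)
        })
        stack_batch(mats, cin)
      })
      loss <- .net_train_batch(net$ptr, xs, labels[take, , drop = FALSE],
                               config$learning_rate, config$momentum,
                               config$weight_decay, config$eps)
      total_loss <- total_loss + loss; nb <- nb + 1L
    }
    row <- data.frame(epoch = epoch, train_loss = total_loss / nb,
                      mu_acc = NA_real_, mu_sen = NA_real_, mu_spe = NA_real_)
    if (length(test_idx)) {
      probs <- predict_cached(net, cache, test_idx, config$batch_size)
      pred <- (probs >= config$probability_threshold) * 1
      mu <- micro_average(confusion_counts(pred, labels[test_idx, , drop = FALSE]))
      row$mu_acc <- mu[["mu_acc"]]; row$mu_sen <- mu[["mu_sen"]]
      row$mu_spe <- mu[["mu_spe"]]
      if (!is.na(row$mu_acc) && row$mu_acc > best$mu_acc) {
        best <- list(mu_acc = row$mu_acc, weights = get_weights(net),
                     epoch = epoch)
      }
    }
    log_rows[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  test muAcc %s", epoch,
                      row$train_loss,
                      ifelse(is.na(row$mu_acc), "-", sprintf("%.4f", row$mu_acc))))
    }
  }
  if (!is.null(best$weights)) set_weights(net, best$weights)
  report <- if (length(test_idx)) {
    probs <- predict_cached(net, cache, test_idx, config$batch_size)
    pred <- (probs >= config$probability_threshold) * 1
    metric_report(pred, labels[test_idx, , drop = FALSE],
                  patient = manifest$patient_id[test_idx])
  } else NULL
  structure(
    list(net = net, log = do.call(rbind, log_rows), best_epoch = best$epoch,
         best_weights = best$weights, report = report, manifest = manifest,
         config = config, seed = seed),
    class = "srn_fit"
  )
}

#' Evaluate a network on a manifest split
#'
#' Binarizes sigmoid outputs at the configured threshold and reports
#' per-class, micro-averaged and patient-level metrics.
#'
#' @param net A built (trained) network.
#' @param manifest Manifest data.frame; with a `split` column, only the
#'   `split` rows are used.
#' @param split Which split tag to evaluate (default `"test"`); ignored when
#'   the manifest has no split column.
#' @param threshold Sigmoid binarization threshold.
#' @param images Optional in-memory images aligned with the manifest rows.
#' @param batch_size Prediction batch size.
#' @return A [metric_report()].
#' @export
evaluate_model <- function(net, manifest, split = "test", threshold = 0.5,
                           images = NULL, batch_size = 64L) {
  validate_manifest(manifest)
  idx <- if ("split" %in% names(manifest)) which(manifest$split == split)
         else seq_len(nrow(manifest))
  if (!length(idx)) stop("no records in split '", split, "'", call. = FALSE)
  cache <- branch_image_cache(net, manifest, images)
  probs <- predict_cached(net, cache, idx, batch_size)
  pred <- (probs >= threshold) * 1
  metric_report(pred, label_matrix(manifest)[idx, , drop = FALSE],
                patient = manifest$patient_id[idx])
}

#' Repeat an experiment across seeds and aggregate mean +/- std
#'
#' For every seed the network is rebuilt (seeded initialization), the
#' dataset re-split, and training re-run; per-seed micro-average metrics and
#' patient-level accuracy are collected and reported as mean +/- std in the
#' conventional 2-decimal percent format.
#'
#' @param build Function `seed -> network` (e.g. wrapping [build_srn()]).
#' @param manifest Manifest data.frame (without a split column; the split is
#'   re-drawn per seed).
#' @param config A [train_config()].
#' @param seeds Integer vector of at least 2 seeds (default from `config`).
#' @param images Optional in-memory images.
#' @param verbose Passed to [fit()].
#' @return A `seed_runs` list: `per_seed` data.frame, `aggregate` data.frame
#'   (mean, sd, formatted), and the list of fit `reports`.
#' @export
run_seeds <- function(build, manifest, config = train_config(),
                      seeds = config$seeds, images = NULL, verbose = FALSE) {
  if (length(seeds) < 2L) stop("need at least 2 seeds for mean +/- std", call. = FALSE)
  rows <- list(); reports <- list()
  for (s in seeds) {
    net <- build(s)
    fres <- fit(net, manifest, config, seed = s, images = images,
                verbose = verbose)
    rep <- fres$report
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, mu_acc = rep$micro[["mu_acc"]], mu_sen = rep$micro[["mu_sen"]],
      mu_spe = rep$micro[["mu_spe"]], patient_level = rep$patient_level,
      best_epoch = fres$best_epoch)
    reports[[length(reports) + 1L]] <- rep
  }
  per_seed <- do.call(rbind, rows)
  metrics <- c("mu_acc", "mu_sen", "mu_spe", "patient_level")
  aggregate <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_seed[[m]]
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               formatted = format_mean_sd(v))
  }))
  structure(list(per_seed = per_seed, aggregate = aggregate,
                 reports = reports, seeds = seeds),
            class = "seed_runs")
}

#' @export
print.seed_runs <- function(x, ...) {
  cat("Across-seed results (", length(x$seeds), " seeds):\n", sep = "")
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %-14s %s\n", x$aggregate$metric[i], x$aggregate$formatted[i]))
  }
  invisible(x)
}
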