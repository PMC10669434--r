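# Per-class and micro-averaged diagnostic metrics, patient-level exact-match
# accuracy, and the across-seed significance test.

check_binary_matrix <- function(m, what) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (!all(m %in% c(0, 1))) stop(what, " must be binary (0/1)", call. = FALSE)
  m
}

#' Per-class confusion counts for multi-label predictions
#'
#' Elementwise comparison of binarized predictions against multi-hot labels:
#' for every class, the counts of true positives, true negatives, false
#' positives and false negatives. Their sum equals the number of images for
#' each class.
#'
#' @param predicted Binary matrix (N x C) of thresholded predictions.
#' @param truth Binary matrix (N x C) of labels.
#' @return A `confusion_counts` data.frame with one row per class.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- check_binary_matrix(predicted, "predictions")
  truth <- check_binary_matrix(truth, "labels")
  if (!identical(dim(predicted), dim(truth))) {
    stop("predictions and labels must have the same shape", call. = FALSE)
  }
  C <- ncol(truth)
  cls <- colnames(truth) %||% oct_classes[seq_len(C)]
  if (is.null(cls) || length(cls) != C) cls <- paste0("class", seq_len(C))
  out <- data.frame(
    class = cls,
    tp = colSums(predicted == 1 & truth == 1),
    tn = colSums(predicted == 0 & truth == 0),
    fp = colSums(predicted == 1 & truth == 0),
    fn = colSums(predicted == 0 & truth == 1),
    row.names = NULL
  )
  class(out) <- c("confusion_counts", "data.frame")
  out
}

ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class accuracy, sensitivity and specificity
#'
#' Applies Acc = (TP + TN) / (TP + FP + TN + FN), Sen = TP / (TP + FN),
#' Spe = TN / (TN + FP) to each class. A ratio with a zero denominator is
#' reported as `NA` (absent), not as 0 or 1.
#'
#' @param counts A [confusion_counts()] data.frame.
#' @return A data.frame with columns class, acc, sen, spe.
#' @export
per_class_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts") ||
              all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  data.frame(
    class = counts$class,
    acc = ratio_or_na(counts$tp + counts$tn,
                      counts$tp + counts$fp + counts$tn + counts$fn),
    sen = ratio_or_na(counts$tp, counts$tp + counts$fn),
    spe = ratio_or_na(counts$tn, counts$tn + counts$fp),
    row.names = NULL
  )
}

#' Micro-averaged metrics
#'
#' Pools TP/TN/FP/FN over all classes, then applies the accuracy,
#' sensitivity and specificity formulas once to the pooled counts.
#'
#' @param counts A [confusion_counts()] data.frame.
#' @return Named numeric vector `c(mu_acc, mu_sen, mu_spe)`.
#' @export
micro_average <- function(counts) {
  tp <- sum(counts$tp); tn <- sum(counts$tn)
  fp <- sum(counts$fp); fn <- sum(counts$fn)
  c(mu_acc = ratio_or_na(tp + tn, tp + tn + fp + fn),
    mu_sen = ratio_or_na(tp, tp + fn),
    mu_spe = ratio_or_na(tn, tn + fp))
}

#' Patient-level (exact-match) accuracy
#'
#' An image counts as correct only when its entire predicted label vector
#' equals the ground truth — detecting two of three co-occurring diseases is
#' incorrect. With a `patient` grouping, accuracy is computed over patients,
#' a patient being correct only when every one of their images is an exact
#' match.
#'
#' @param predicted,truth Binary matrices (N x C).
#' @param patient Optional vector of patient identifiers (length N) switching
#'   to per-patient granularity; default is per image.
#' @return Fraction in `[0, 1]`.
#' @export
patient_level_accuracy <- function(predicted, truth, patient = NULL) {
  predicted <- check_binary_matrix(predicted, "predictions")
  truth <- check_binary_matrix(truth, "labels")
  if (!identical(dim(predicted), dim(truth))) {
    stop("predictions and labels must have the same shape", call. = FALSE)
  }
  exact <- rowSums(predicted != truth) == 0
  if (is.null(patient)) return(mean(exact))
  all_ok <- tapply(exact, patient, all)
  mean(all_ok)
}

#' Two-sample Student t-test for across-seed metric comparisons
#'
#' Unpaired, two-sided, equal-variance t-test between two groups of per-seed
#' metric values, the protocol used to compare methods run under multiple
#' seeds. Significance is declared at p <= 0.05 (inclusive). When both groups
#' have zero variance the test statistic is degenerate: equal means give
#' p = 1 by convention, distinct means p = 0.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each) of per-seed
#'   metric values.
#' @param metric Optional metric name carried into the result.
#' @param alpha Significance level (default 0.05, inclusive).
#' @return A `significance_result` list with `t`, `p`, `df`, `significant`.
#' @export
metric_t_test <- function(group_a, group_b, metric = NA_character_,
                          alpha = 0.05) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per group", call. = FALSE)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(
    list(metric = metric, t = t, p = p, df = df,
         mean_a = mean(a), mean_b = mean(b),
         significant = p <= alpha, alpha = alpha),
    class = "significance_result"
  )
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %d, p = %.4g (%s at alpha = %g)%s\n",
              x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha,
              if (!is.na(x$metric)) paste0(" [", x$metric, "]") else ""))
  invisible(x)
}

#' Full metric report for one evaluated split
#'
#' Bundles per-class metrics, micro-averages and patient-level exact-match
#' accuracy computed from binarized predictions.
#'
#' @param predicted,truth Binary matrices (N x C).
#' @param patient Optional patient identifiers for the grouped exact-match
#'   variant (the per-image value is always reported).
#' @return A `metric_report` list.
#' @export
metric_report <- function(predicted, truth, patient = NULL) {
  counts <- confusion_counts(predicted, truth)
  rep <- list(
    counts = counts,
    per_class = per_class_metrics(counts),
    micro = micro_average(counts),
    patient_level = patient_level_accuracy(predicted, truth),
    n_images = nrow(check_binary_matrix(truth, "labels"))
  )
  if (!is.null(patient)) {
    rep$patient_level_grouped <- patient_level_accuracy(predicted, truth, patient)
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (", x$n_images, " images)\n", sep = "")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-7s acc %.4f  sen %s  spe %s\n", pc$class[i], pc$acc[i],
                ifelse(is.na(pc$sen[i]), "   -  ", sprintf("%.4f", pc$sen[i])),
                ifelse(is.na(pc$spe[i]), "   -  ", sprintf("%.4f", pc$spe[i]))))
  }
  cat(sprintf("  micro   acc %.4f  sen %.4f  spe %.4f\n",
              x$micro["mu_acc"], x$micro["mu_sen"], x$micro["mu_spe"]))
  cat(sprintf("  patient-level (exact match): %.4f\n", x$patient_level))
  invisible(x)
}

#' Aggregate per-seed metric values as "mean +/- std"
#'
#' @param values Numeric vector of per-seed values (fractions in `[0, 1]`).
#' @param percent Format as percentages with 2 decimals (the conventional
#'   reporting style), otherwise raw values with 4 decimals.
#' @return A string such as `"97.40 ± 0.04"`.
#' @export
format_mean_sd <- function(values, percent = TRUE) {
  m <- mean(values); s <- stats::sd(values)
  if (percent) sprintf("%.2f ± %.2f", 100 * m, 100 * s)
  else sprintf("%.4f ± %.4f", m, s)
}
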