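# Dataset manifests, deterministic stratified splitting, image loading and
# augmentation.

#' Read / write a dataset manifest
#'
#' The manifest CSV has columns `path, amd, erm, me, normal, patient_id`
#' (plus optional `eye_id` and `split`). Multi-hot labels must satisfy the
#' dataset convention: `normal` is 1 exactly when no disease is marked.
#'
#' @param path CSV file path.
#' @param manifest Manifest data.frame.
#' @return `read_manifest()` the validated data.frame; `write_manifest()` the
#'   path, invisibly.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("path", "amd", "erm", "me", "normal")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  lab <- as.matrix(m[, c("amd", "erm", "me", "normal")])
  if (!all(lab %in% c(0, 1))) stop("manifest labels must be 0/1", call. = FALSE)
  bad <- (rowSums(lab[, 1:3, drop = FALSE]) == 0) != (lab[, 4] == 1)
  if (any(bad)) {
    stop("label consistency violated: normal must be 1 exactly when no disease is present",
         call. = FALSE)
  }
  paths <- m$path[!is.na(m$path)]
  if (anyDuplicated(paths)) stop("manifest paths must be unique", call. = FALSE)
  if ("split" %in% names(m) && !all(m$split %in% c("train", "test"))) {
    stop("split tags must be 'train' or 'test'", call. = FALSE)
  }
  invisible(m)
}

label_matrix <- function(manifest) {
  as.matrix(manifest[, c("amd", "erm", "me", "normal")])
}

# Largest-remainder allocation of a total across group quotas. The small
# epsilon guards floor() against binary round-off (0.2 * 100 < 20).
allocate_counts <- function(sizes, fraction, total) {
  quota <- sizes * fraction
  base <- floor(quota + 1e-9)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    take <- ord[seq_len(min(rem, length(ord)))]
    base[take] <- base[take] + 1
  }
  pmin(base, sizes)
}

#' Deterministic stratified train/test split
#'
#' Assigns every manifest record to `train` or `test`. The test side receives
#' `floor((1 - split_fraction) * n)` records overall (floor documented on the
#' test side); within that total, records are stratified by exact label
#' combination with largest-remainder rounding, so each combination's train
#' fraction is within one record of the target where group sizes permit.
#' With `by_patient`, whole patients are assigned to one side (leakage-safe),
#' stratified by the patient's modal label combination.
#'
#' @param manifest Manifest data.frame.
#' @param split_fraction Train fraction in (0, 1), default 0.8.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @param by_patient Split at patient granularity instead of image granularity.
#' @return The manifest with a `split` column.
#' @export
split_dataset <- function(manifest, split_fraction = 0.8, seed = 1L,
                          by_patient = FALSE) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  set.seed(seed)
  combo <- apply(label_matrix(manifest), 1, paste, collapse = "")
  if (by_patient) {
    if (is.null(manifest$patient_id)) stop("by_patient split needs patient_id", call. = FALSE)
    pats <- unique(manifest$patient_id)
    pat_combo <- vapply(pats, function(p) {
      tab <- table(combo[manifest$patient_id == p])
      names(tab)[which.max(tab)]
    }, character(1))
    unit_id <- match(manifest$patient_id, pats)
    units <- seq_along(pats); unit_combo <- pat_combo
  } else {
    unit_id <- seq_len(nrow(manifest))
    units <- unit_id; unit_combo <- combo
  }
  n_units <- length(units)
  n_test <- floor((1 - split_fraction) * n_units + 1e-9)
  groups <- split(units, unit_combo)
  sizes <- vapply(groups, length, integer(1))
  quotas <- allocate_counts(sizes, 1 - split_fraction, n_test)
  test_units <- unlist(lapply(seq_along(groups), function(g) {
    if (quotas[g] == 0L) return(integer())
    sample(groups[[g]], quotas[g])
  }), use.names = FALSE)
  manifest$split <- ifelse(unit_id %in% test_units, "test", "train")
  manifest
}

#' Load an image as a grayscale matrix on the unit interval
#'
#' PNG images are read with the `png` package; color images are averaged to
#' one channel; values are left in `[0, 1]`.
#'
#' @param path PNG file path.
#' @param side Optional target side; images are bilinearly resized to
#'   `side x side`.
#' @return A numeric matrix.
#' @export
load_image <- function(path, side = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  if (!is.null(side) && !(nrow(img) == side && ncol(img) == side)) {
    img <- .resize_bilinear(img, as.integer(side), as.integer(side))
  }
  img
}

#' Randomly rotate and flip an image
#'
#' Applies a uniform random rotation in `[-rotation_degrees,
#' +rotation_degrees]` (bilinear, background-filled) and independent
#' horizontal and vertical flips, each with probability `flip_probability`.
#' Draws come from R's RNG stream, so augmentation is reproducible under
#' `set.seed()`. With both magnitudes zero the image is returned unchanged.
#'
#' @param image Numeric matrix in `[0, 1]`, already at its target size.
#' @param rotation_degrees Maximum absolute rotation (default 10).
#' @param flip_probability Per-axis flip probability (default 0.5).
#' @param bg Fill value for pixels rotated in from outside the frame.
#' @return A matrix of the same shape with pixel range preserved.
#' @export
augment_image <- function(image, rotation_degrees = 10, flip_probability = 0.5,
                          bg = 0) {
  if (flip_probability > 0) {
    if (stats::runif(1) < flip_probability) image <- image[, rev(seq_len(ncol(image)))]
    if (stats::runif(1) < flip_probability) image <- image[rev(seq_len(nrow(image))), ]
  }
  if (rotation_degrees > 0) {
    ang <- stats::runif(1, -rotation_degrees, rotation_degrees)
    image <- .rotate_bilinear(image, ang, bg)
  }
  image
}
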