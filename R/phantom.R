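# Synthetic OCT B-scan phantoms: a curved bright retinal band over a dark
# background with multiplicative speckle, plus three injectable lesion types
# with known coordinates — drusen-like bumps at the outer band (AMD), a thin
# bright membrane hovering above the inner surface (ERM), and dark fluid
# cavities inside the band (ME). Every sample carries its multi-hot label and
# lesion bounding boxes, so classifiers and heatmaps can be validated against
# generator ground truth.

#' Configure the OCT phantom generator
#'
#' All geometry is expressed as a fraction of the image side, so `side` acts
#' as a resolution knob rather than a difficulty knob: rendering at 256 and
#' rendering at 512 followed by 2x downsampling look alike. Default lesion
#' probabilities approximate the marginal prevalences of a large multi-label
#' OCT cohort (AMD 0.221, ERM 0.281, ME 0.109); lesions are sampled
#' independently, so multi-disease images occur.
#'
#' @param side Image side in pixels (square).
#' @param band_center,band_thickness Vertical centre and thickness of the
#'   retinal band (fractions of the side).
#' @param curvature Amplitude of the parabolic curvature of the inner surface.
#' @param tilt_range Maximum random tilt of the band.
#' @param fovea_depth,fovea_width Central foveal dip geometry.
#' @param background Background intensity in `[0, 1]`.
#' @param speckle_contrast Standard deviation of the unit-mean multiplicative
#'   gamma speckle field (0 disables speckle).
#' @param p_amd,p_erm,p_me Independent per-image lesion probabilities.
#' @param drusen_count,drusen_width,drusen_height Ranges for drusen number
#'   and size (widths/heights as fractions of the side).
#' @param erm_thickness,erm_gap,erm_span Membrane thickness (1-3 px at
#'   side 512 by default, so it nearly vanishes at coarse scales but stays
#'   visible at fine ones), gap to the retinal surface, and horizontal span.
#' @param me_count,me_radius_u,me_radius_d Ranges for cavity number and
#'   elliptical radii (horizontal as a side fraction, vertical as a fraction
#'   of the band thickness).
#' @param frames_per_patient Consecutive images assigned to one patient by
#'   [generate_dataset()].
#' @param seed Default seed for [generate_phantom()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(side = 512L,
                           band_center = 0.45, band_thickness = 0.22,
                           curvature = 0.05, tilt_range = 0.03,
                           fovea_depth = 0.045, fovea_width = 0.07,
                           background = 0.06, speckle_contrast = 0.18,
                           p_amd = 0.2207, p_erm = 0.2813, p_me = 0.1091,
                           drusen_count = c(2L, 4L),
                           drusen_width = c(0.08, 0.16),
                           drusen_height = c(0.05, 0.09),
                           erm_thickness = c(1 / 512, 3 / 512),
                           erm_gap = c(0.014, 0.04),
                           erm_span = c(0.55, 0.9),
                           me_count = c(2L, 5L),
                           me_radius_u = c(0.05, 0.11),
                           me_radius_d = c(0.25, 0.45),
                           frames_per_patient = 6L, seed = 1L) {
  if (any(c(p_amd, p_erm, p_me) < 0) || any(c(p_amd, p_erm, p_me) > 1)) {
    stop("lesion probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (band_thickness <= 0 || side < 32L) stop("invalid phantom geometry", call. = FALSE)
  structure(as.list(environment()), class = "phantom_config")
}

# Draw every random quantity of one phantom (label, geometry, lesion
# parameters) from the current RNG stream.
draw_phantom_params <- function(config) {
  rng1 <- function(r) stats::runif(1, r[1], r[2])
  p <- list(
    tilt = stats::runif(1, -config$tilt_range, config$tilt_range),
    center = config$band_center + stats::runif(1, -0.03, 0.03),
    thickness = config$band_thickness * stats::runif(1, 0.92, 1.08),
    fovea_u = stats::runif(1, 0.42, 0.58),
    layer_phase = stats::runif(1, 0, 2 * pi),
    amd = stats::runif(1) < config$p_amd,
    erm = stats::runif(1) < config$p_erm,
    me = stats::runif(1) < config$p_me
  )
  if (p$amd) {
    nd <- sample(config$drusen_count[1]:config$drusen_count[2], 1)
    p$drusen <- lapply(seq_len(nd), function(i) {
      list(u = stats::runif(1, 0.12, 0.88),
           width = rng1(config$drusen_width),
           height = rng1(config$drusen_height))
    })
  }
  if (p$erm) {
    span <- rng1(config$erm_span)
    u0 <- stats::runif(1, 0.05, 0.95 - span)
    p$membrane <- list(u0 = u0, u1 = u0 + span,
                       gap = rng1(config$erm_gap),
                       thickness = rng1(config$erm_thickness),
                       wobble_phase = stats::runif(1, 0, 2 * pi))
  }
  if (p$me) {
    nc <- sample(config$me_count[1]:config$me_count[2], 1)
    p$cavities <- lapply(seq_len(nc), function(i) {
      list(u = stats::runif(1, 0.15, 0.85),
           d = stats::runif(1, 0.3, 0.72),
           ru = rng1(config$me_radius_u),
           rd = rng1(config$me_radius_d))
    })
  }
  p
}

# Apply small frame-to-frame jitter to patient-level anatomy (used to emulate
# consecutive frames of one eye's scan).
jitter_phantom_params <- function(p) {
  p$tilt <- p$tilt + stats::runif(1, -0.004, 0.004)
  p$center <- p$center + stats::runif(1, -0.006, 0.006)
  p$layer_phase <- p$layer_phase + stats::runif(1, -0.3, 0.3)
  p
}

mask_box <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  c(row_min = min(ij[, 1]), row_max = max(ij[, 1]),
    col_min = min(ij[, 2]), col_max = max(ij[, 2]))
}

# Deterministic rendering of drawn parameters (speckle is the only remaining
# RNG consumer). Returns image, multi-hot label and lesion boxes.
render_phantom <- function(config, p) {
  s <- config$side
  u <- (seq_len(s) - 0.5) / s
  v <- (seq_len(s) - 0.5) / s
  vtop <- p$center - p$thickness / 2 +
    config$curvature * (4 * (u - 0.5)^2 - 1) +
    p$tilt * (u - 0.5) +
    config$fovea_depth * exp(-(u - p$fovea_u)^2 / (2 * config$fovea_width^2))
  V <- matrix(v, s, s)
  TopM <- matrix(vtop, s, s, byrow = TRUE)
  D <- (V - TopM) / p$thickness          # depth within the band, 0 = surface

  img <- matrix(config$background, s, s)
  inband <- D >= 0 & D <= 1
  # layered reflectivity profile: bright nerve-fiber layer, banded plexiform
  # interior, bright RPE floor, exponentially fading choroid
  prof <- 0.52 + 0.07 * cos(2 * pi * 3.5 * D + p$layer_phase)
  prof[D < 0.08] <- 0.88
  prof[D >= 0.86 & D <= 1] <- 0.95
  img[inband] <- prof[inband]
  chor <- D > 1 & D < 1.5
  img[chor] <- config$background + 0.22 * exp(-(D[chor] - 1) * 7)

  boxes <- list()
  U <- matrix(u, s, s, byrow = TRUE)
  BotM <- TopM + p$thickness

  if (isTRUE(p$amd)) {
    for (dr in p$drusen) {
      sig <- dr$width / 4
      bump <- dr$height * exp(-(u - dr$u)^2 / (2 * sig^2))
      BumpM <- matrix(bump, s, s, byrow = TRUE)
      m <- V > BotM & V <= BotM + BumpM & BumpM > dr$height * 0.05
      if (any(m)) {
        img[m] <- 0.88
        boxes[[length(boxes) + 1L]] <- c(class = "amd", as.list(mask_box(m)))
      }
    }
  }
  if (isTRUE(p$erm)) {
    mb <- p$membrane
    gap <- mb$gap + 0.004 * sin(2 * pi * 3 * u + mb$wobble_phase)
    vm <- vtop - gap
    VmM <- matrix(vm, s, s, byrow = TRUE)
    span <- U >= mb$u0 & U <= mb$u1
    m <- span & abs(V - VmM) <= mb$thickness / 2 + 0.5 / s
    if (any(m)) {
      img[m] <- 0.82
      # the hypo-reflective slit between membrane and surface is part of the
      # lesion's signature; include it in the box
      slit <- span & V > VmM & V < TopM
      boxes[[length(boxes) + 1L]] <- c(class = "erm", as.list(mask_box(m | slit)))
    }
  }
  if (isTRUE(p$me)) {
    for (cv in p$cavities) {
      vc <- matrix(vtop + cv$d * p$thickness, s, s, byrow = TRUE)
      rv <- cv$rd * p$thickness
      m <- ((U - cv$u) / cv$ru)^2 + ((V - vc) / rv)^2 <= 1 & inband
      if (any(m)) {
        img[m] <- img[m] * 0.14 + 0.02
        boxes[[length(boxes) + 1L]] <- c(class = "me", as.list(mask_box(m)))
      }
    }
  }

  if (config$speckle_contrast > 0) {
    k <- 1 / config$speckle_contrast^2
    speckle <- matrix(stats::rgamma(s * s, shape = k, rate = k), s, s)
    img <- img * speckle
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  label <- c(amd = 0L, erm = 0L, me = 0L, normal = 0L)
  if (length(boxes)) {
    present <- unique(vapply(boxes, `[[`, character(1), "class"))
    label[present] <- 1L
  }
  if (sum(label[1:3]) == 0L) label["normal"] <- 1L
  boxes_df <- if (length(boxes)) {
    do.call(rbind, lapply(boxes, function(b) {
      data.frame(class = b$class, row_min = b$row_min, row_max = b$row_max,
                 col_min = b$col_min, col_max = b$col_max)
    }))
  } else {
    data.frame(class = character(), row_min = integer(), row_max = integer(),
               col_min = integer(), col_max = integer())
  }
  list(image = img, label = label, boxes = boxes_df)
}

#' Generate one OCT phantom
#'
#' Renders a curved multi-layer retinal band with multiplicative speckle and
#' independently sampled lesions. The returned label is consistent with the
#' lesion boxes by construction: a class is 1 exactly when at least one
#' lesion of that class was rendered, and `normal` is 1 exactly when there
#' are no lesion boxes.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed (defaults to `config$seed`); the same seed
#'   reproduces the sample exactly.
#' @return A `phantom_sample` list: `image` (side x side matrix in `[0, 1]`),
#'   `label` (named multi-hot vector over amd/erm/me/normal), `boxes`
#'   (data.frame of lesion bounding boxes in pixel coordinates).
#' @examples
#' ph <- generate_phantom(phantom_config(side = 128), seed = 7)
#' ph$label
#' @export
generate_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  p <- draw_phantom_params(config)
  out <- render_phantom(config, p)
  structure(c(out, list(seed = seed, patient_id = NA_character_,
                        eye_id = NA_character_)),
            class = "phantom_sample")
}

#' Generate a phantom dataset with a manifest
#'
#' Samples `n` phantoms. Images are grouped into consecutive per-patient
#' blocks (`frames_per_patient` frames per patient) sharing anatomy with
#' small frame-to-frame jitter, emulating consecutive frames of one eye's
#' scan; lesion presence is drawn independently per frame, so per-class
#' prevalences follow the configured probabilities binomially. With `dir`
#' set, 8-bit grayscale PNGs, a manifest CSV
#' (`path,amd,erm,me,normal,patient_id`) and a side-car JSON of lesion boxes
#' are written; otherwise images stay in memory.
#'
#' @param n Number of images.
#' @param config A [phantom_config()].
#' @param dir Optional output directory (created if missing).
#' @param seed Integer seed for the whole dataset.
#' @return A list with `manifest` (data.frame), `samples` (list of in-memory
#'   samples when `dir` is `NULL`), and `boxes` (per-image box tables).
#' @export
generate_dataset <- function(n, config, dir = NULL, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"), n > 0)
  set.seed(seed)
  write_files <- !is.null(dir)
  if (write_files && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", n)
  samples <- if (write_files) NULL else vector("list", n)
  boxes <- vector("list", n)
  fpp <- max(1L, as.integer(config$frames_per_patient))
  base_params <- NULL
  for (i in seq_len(n)) {
    patient <- (i - 1L) %/% fpp + 1L
    frame <- (i - 1L) %% fpp + 1L
    if (frame == 1L) base_params <- draw_phantom_params(config)
    p <- if (frame == 1L) base_params else jitter_phantom_params(base_params)
    # lesion presence and shapes are per-frame draws
    fresh <- draw_phantom_params(config)
    p$amd <- fresh$amd; p$erm <- fresh$erm; p$me <- fresh$me
    p$drusen <- fresh$drusen
    p$membrane <- fresh$membrane
    p$cavities <- fresh$cavities
    out <- render_phantom(config, p)
    pid <- sprintf("P%04d", patient)
    eye <- if (patient %% 2L == 0L) "OS" else "OD"
    path <- NA_character_
    if (write_files) {
      path <- file.path(dir, sprintf("phantom_%05d.png", i))
      png::writePNG(out$image, path)
    } else {
      samples[[i]] <- out
    }
    rows[[i]] <- data.frame(
      path = path, amd = out$label[["amd"]], erm = out$label[["erm"]],
      me = out$label[["me"]], normal = out$label[["normal"]],
      patient_id = pid, eye_id = eye
    )
    boxes[[i]] <- out$boxes
  }
  manifest <- do.call(rbind, rows)
  if (write_files) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(seq_len(n), function(i) {
        list(path = manifest$path[i], boxes = boxes[[i]])
      }),
      file.path(dir, "boxes.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(manifest = manifest, samples = samples, boxes = boxes, config = config,
       seed = seed)
}
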