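# Synthetic clinical-photograph generator.
#
# Emulates the appearance regime the segmenter must handle: a textured
# skin-like background (multi-octave smooth noise, mild vignette),
# low-contrast lesions with fuzzy boundaries (anisotropic superellipse
# supports, reddish-brown tint, Gaussian-blurred edges; the ground
# truth mask is the sharp pre-blur support, mirroring rough clinical
# annotations), and distractors that are deliberately NOT in the mask:
# dark hair-like curves and sharp high-contrast benign spots. Every
# scene is bitwise-deterministic given its seed.

#' Synthetic scene configuration
#'
#' @param height,width scene size in pixels.
#' @param px_per_mm spatial scale (5 px/mm, the scale the network sees).
#' @param n_lesions inclusive integer range of lesion counts.
#' @param lesion_diameter_mm lesion major-diameter range in mm (AK spans
#'   a few millimeters to 1-2 cm).
#' @param contrast range of the mean luminance offset of a lesion
#'   against the local background, in `(0, 1)`; AK is a low-contrast
#'   target.
#' @param boundary_softness_px Gaussian blur sigma range applied to the
#'   lesion edge (fuzzy boundaries); capped at a fifth of the lesion
#'   minor radius.
#' @param n_hairs range of hair-like dark curve counts.
#' @param n_spots range of sharp benign-spot counts (seborrheic
#'   keratosis / lentigo confusers).
#' @param noise_sd amplitude of the background texture.
#' @param tone optional fixed RGB skin tone (length 3); drawn per seed
#'   when `NULL`.
#' @param seed RNG seed; also determines the patient identifier
#'   (`seed %/% 1000`), so consecutive seed blocks form patients.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(height = 256L, width = 256L, px_per_mm = 5,
                         n_lesions = c(1L, 3L),
                         lesion_diameter_mm = c(4, 16),
                         contrast = c(0.15, 0.30),
                         boundary_softness_px = c(1.5, 3),
                         n_hairs = c(2L, 5L), n_spots = c(1L, 4L),
                         noise_sd = 0.03, tone = NULL, seed = 1L) {
  stopifnot(height > 0, width > 0, px_per_mm > 0,
            all(n_lesions >= 0), diff(range(n_lesions)) >= 0,
            all(lesion_diameter_mm > 0),
            all(contrast > 0), all(contrast < 1),
            all(boundary_softness_px > 0))
  structure(list(height = as.integer(height), width = as.integer(width),
                 px_per_mm = px_per_mm,
                 n_lesions = as.integer(range(n_lesions)),
                 lesion_diameter_mm = range(lesion_diameter_mm),
                 contrast = range(contrast),
                 boundary_softness_px = range(boundary_softness_px),
                 n_hairs = as.integer(range(n_hairs)),
                 n_spots = as.integer(range(n_spots)),
                 noise_sd = noise_sd, tone = tone, seed = as.integer(seed)),
            class = "scene_config")
}

# Smooth multi-octave noise field with unit-free sd `sd`.
.octave_noise <- function(h, w, sd) {
  acc <- matrix(0, h, w)
  wsum <- 0
  for (cells in c(4L, 8L, 16L, 32L)) {
    g <- matrix(stats::rnorm(cells * cells), cells, cells)
    up <- resize_array(g, h, w, "bilinear")
    wt <- 1 / cells
    acc <- acc + wt * up
    wsum <- wsum + wt^2
  }
  acc / sqrt(wsum) * sd
}

# Linear pixel indices of a rotated superellipse support.
.superellipse_support <- function(h, w, center, a, b, theta, p) {
  r0 <- max(1L, floor(center[1] - max(a, b) - 1)); r1 <- min(h, ceiling(center[1] + max(a, b) + 1))
  c0 <- max(1L, floor(center[2] - max(a, b) - 1)); c1 <- min(w, ceiling(center[2] + max(a, b) + 1))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - center[1], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2])
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- abs(u)^p + abs(v)^p <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  rr + (cc - 1L) * h
}

.runif_int <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

#' Generate one synthetic annotated scene
#'
#' Deterministic given `config$seed`: the same seed reproduces the image
#' and mask bitwise. The mask marks exactly the sharp lesion supports;
#' distractors avoid lesion pixels by construction and are never in the
#' mask. The configured contrast is realized as the mean luminance
#' offset over the annotated support (the edge blur is compensated).
#'
#' @param config a [scene_config()].
#' @return an [annotated_image()] with `patient_id` derived from the
#'   seed block and `pixel_scale = px_per_mm`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width
  pid <- sprintf("P%03d", config$seed %/% 1000L)
  with_seed(config$seed, {
    tone <- config$tone
    if (is.null(tone)) {
      t0 <- stats::runif(1)
      tone <- c(0.80, 0.62, 0.54) + (t0 - 0.5) * 0.12 +
        stats::rnorm(3, sd = 0.015)
    }
    img <- array(rep(tone, each = h * w), c(h, w, 3))
    noise <- .octave_noise(h, w, config$noise_sd)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 + noise)
    # mild vignette, as in ring-flash photography
    ry <- (seq_len(h) - (h + 1) / 2) / (h / 2)
    rx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
    vig <- 1 - 0.03 * outer(ry^2, rep(1, w)) - 0.03 * outer(rep(1, h), rx^2)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vig
    mask <- matrix(0L, h, w)
    n_target <- .runif_int(config$n_lesions)
    centers <- matrix(numeric(0), 0, 3)  # row, col, radius
    placed <- 0L
    lesions <- list()
    if (n_target > 0) {
      for (k in seq_len(n_target)) {
        ok <- FALSE
        for (try in seq_len(20L)) {
          diam <- stats::runif(1, config$lesion_diameter_mm[1],
                               config$lesion_diameter_mm[2]) * config$px_per_mm
          a <- diam / 2
          b <- a * stats::runif(1, 0.6, 1)
          rad <- max(a, b)
          if (2 * rad + 6 > min(h, w)) next
          ctr <- c(stats::runif(1, rad + 3, h - rad - 3),
                   stats::runif(1, rad + 3, w - rad - 3))
          if (nrow(centers) > 0 &&
              any(sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2) <
                  0.95 * (centers[, 3] + rad))) next
          theta <- stats::runif(1, 0, pi)
          pexp <- stats::runif(1, 1.7, 3)
          px <- .superellipse_support(h, w, ctr, a, b, theta, pexp)
          if (!length(px)) next
          centers <- rbind(centers, c(ctr, rad))
          lesions[[length(lesions) + 1L]] <-
            list(px = px, softness = min(
              stats::runif(1, config$boundary_softness_px[1],
                           config$boundary_softness_px[2]), min(a, b) / 5),
              contrast = stats::runif(1, config$contrast[1], config$contrast[2]))
          ok <- TRUE
          break
        }
        if (!ok) message(sprintf(
          "scene seed %d: placed %d of %d lesions (no room left)",
          config$seed, length(lesions), n_target))
      }
    }
    # reddish-brown direction scaled to a unit luminance drop
    dir_rgb <- c(0.25, -0.45, -0.30)
    dir_lum <- sum(c(0.299, 0.587, 0.114) * dir_rgb)  # negative: darker
    for (le in lesions) {
      support <- matrix(0, h, w)
      support[le$px] <- 1
      alpha <- EBImage::gblur(support, sigma = le$softness)
      alpha <- as.matrix(alpha)
      # compensate edge blur so the mean offset over the support is exact
      scale <- le$contrast / abs(dir_lum) / mean(alpha[le$px])
      for (ch in 1:3) img[, , ch] <- img[, , ch] + alpha * dir_rgb[ch] * scale
      mask[le$px] <- 1L
    }
    # hair-like dark curves (kept off lesion pixels)
    for (k in seq_len(.runif_int(config$n_hairs))) {
      p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      p2 <- p0 + c(stats::runif(1, -0.6, 0.6) * h, stats::runif(1, -0.6, 0.6) * w)
      p1 <- (p0 + p2) / 2 + c(stats::runif(1, -0.2, 0.2) * h,
                              stats::runif(1, -0.2, 0.2) * w)
      tt <- seq(0, 1, length.out = 4L * as.integer(max(abs(p2 - p0)) + 2))
      pr <- round((1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1])
      pc <- round((1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2])
      keep <- pr >= 1 & pr <= h - 1 & pc >= 1 & pc <= w - 1
      pr <- pr[keep]; pc <- pc[keep]
      idx <- unique(c(pr + (pc - 1) * h, pr + 1 + (pc - 1) * h, pr + pc * h))
      idx <- idx[mask[idx] == 0]  # distractors avoid lesions by construction
      dark <- stats::runif(1, 0.35, 0.55)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[idx] <- pl[idx] * dark; img[, , ch] <- pl
      }
    }
    # sharp benign spots: high-contrast discs with crisp edges
    for (k in seq_len(.runif_int(config$n_spots))) {
      rad <- stats::runif(1, 2, 6)
      ctr <- c(stats::runif(1, rad + 1, h - rad - 1),
               stats::runif(1, rad + 1, w - rad - 1))
      px <- .superellipse_support(h, w, ctr, rad, rad, 0, 2)
      px <- px[mask[px] == 0]
      if (!length(px)) next
      spot_col <- if (stats::runif(1) < 0.7) c(0.28, 0.18, 0.12) else c(0.95, 0.88, 0.80)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[px] <- 0.15 * pl[px] + 0.85 * spot_col[ch]
        img[, , ch] <- pl
      }
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    annotated_image(img, mask, pid, pixel_scale = config$px_per_mm)
  })
}

#' Generate a multi-patient synthetic dataset
#'
#' Patients occupy consecutive seed blocks of 1000; each patient has a
#' fixed skin tone (drawn from the patient seed) shared by all of their
#' images, so per-patient appearance is correlated and patient-level
#' splitting is meaningful.
#'
#' @param n_patients,images_per_patient positive counts.
#' @param config a [scene_config()]; its `seed` selects the first
#'   patient block.
#' @return list with `images` (list of [annotated_image()]s) and
#'   `index` (data.frame with `stem`, `patient_id`, `seed`).
#' @export
generate_dataset <- function(n_patients, images_per_patient, config = scene_config()) {
  stopifnot(n_patients >= 1, images_per_patient >= 1)
  images <- list()
  idx <- NULL
  for (p in seq_len(n_patients)) {
    pseed <- config$seed + (p - 1L) * 1000L
    tone <- with_seed(pseed, {
      t0 <- stats::runif(1)
      c(0.80, 0.62, 0.54) + (t0 - 0.5) * 0.12 + stats::rnorm(3, sd = 0.015)
    })
    for (q in seq_len(images_per_patient)) {
      cfg_i <- config
      cfg_i$seed <- pseed + q
      cfg_i$tone <- tone
      im <- generate_scene(cfg_i)
      stem <- sprintf("img_%03d_%02d", p, q)
      images[[length(images) + 1L]] <- im
      idx <- rbind(idx, data.frame(stem = stem, patient_id = im$patient_id,
                                   seed = cfg_i$seed, stringsAsFactors = FALSE))
    }
  }
  list(images = images, index = idx)
}
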