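# Crop extraction from annotated photographs.
#
# Training and evaluation crops are square lesion boxes: one box
# centered on every connected annotated region, plus seeded
# translation-shifted copies that vary the perilesional context. The
# pipeline mirrors wide-field practice: photographs are first rescaled
# by 0.5, fixed-side boxes (512 px by default) are cut, and each crop
# is rescaled by 0.5 again (to 256 px) before entering the network.
# Dataset splits are made at the patient level so no patient
# contributes to two splits.

#' Annotated image container
#'
#' @param image (h, w, 3) RGB array with values in `[0, 1]`.
#' @param mask (h, w) 0/1 lesion mask.
#' @param patient_id nonempty patient identifier; splits are by patient.
#' @param pixel_scale optional pixels-per-mm scale.
#' @return object of class `annotated_image`.
#' @export
annotated_image <- function(image, mask, patient_id, pixel_scale = NULL) {
  image <- as_hwc(image)
  if (is.null(dim(mask))) stop("mask must be a matrix")
  if (!all(dim(image)[1:2] == dim(mask))) {
    stop("image and mask spatial shapes differ")
  }
  if (!is.character(patient_id) || !nzchar(patient_id)) {
    stop("patient_id must be a nonempty string")
  }
  mask <- .as_binary(mask)
  structure(list(image = image, mask = mask, patient_id = patient_id,
                 pixel_scale = pixel_scale),
            class = "annotated_image")
}

# Resize an (h, w[, c]) array; masks use nearest-neighbor so they stay
# binary. EBImage indexes (x, y); both axes are passed explicitly.
resize_array <- function(x, new_h, new_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  y <- EBImage::resize(x, w = new_h, h = new_w, filter = filt)
  y <- as.array(y)
  if (length(dim(x)) == 2L && length(dim(y)) > 2L) dim(y) <- dim(y)[1:2]
  y
}

#' Rescale an annotated image by 0.5
#'
#' Halves both image (bilinear) and mask (nearest-neighbor, so the mask
#' stays binary) and halves the pixel scale.
#'
#' @param img an [annotated_image()].
#' @return the rescaled `annotated_image`.
#' @export
rescale_half <- function(img) {
  stopifnot(inherits(img, "annotated_image"))
  d <- dim(img$mask)
  nh <- ceiling(d[1] / 2); nw <- ceiling(d[2] / 2)
  annotated_image(resize_array(img$image, nh, nw, "bilinear"),
                  round(resize_array(img$mask, nh, nw, "nearest")),
                  img$patient_id,
                  if (is.null(img$pixel_scale)) NULL else img$pixel_scale / 2)
}

.clamp_origin <- function(center, side, limit) {
  org <- round(center - side / 2)
  min(max(org, 1L), limit - side + 1L)
}

#' Lesion-centered crop boxes
#'
#' One square box per connected annotated region, centered on the region
#' centroid (or the nearest region pixel when the centroid of a
#' non-convex region falls outside it) and clamped so the box lies
#' inside the image. Boxes are ordered by region label, which is
#' deterministic.
#'
#' @param img an [annotated_image()].
#' @param side box side length in pixels at the current scale.
#' @param connectivity region connectivity (default 8).
#' @return list of `crop_spec` objects (`origin = c(row, col)`, `side`,
#'   `offset_index = 0`, `region` pixel indices); empty list for an
#'   empty mask.
#' @export
lesion_boxes <- function(img, side, connectivity = 8) {
  stopifnot(inherits(img, "annotated_image"))
  d <- dim(img$mask)
  side <- as.integer(side)
  if (side > min(d)) {
    stop(sprintf("box side %d exceeds image size %d x %d", side, d[1], d[2]))
  }
  regs <- extract_regions(img$mask, connectivity)
  lapply(regs$regions, function(px) {
    rows <- ((px - 1L) %% d[1]) + 1L
    cols <- ((px - 1L) %/% d[1]) + 1L
    cr <- mean(rows); cc <- mean(cols)
    at <- round(cr) + (round(cc) - 1L) * d[1]
    if (!(at %in% px)) {
      # centroid outside the region: snap to the nearest region pixel
      i <- which.min((rows - cr)^2 + (cols - cc)^2)
      cr <- rows[i]; cc <- cols[i]
    }
    structure(list(origin = c(.clamp_origin(cr, side, d[1]),
                              .clamp_origin(cc, side, d[2])),
                   side = side, offset_index = 0L, region = px),
              class = "crop_spec")
  })
}

#' Translation-augmented crop boxes
#'
#' Adds `n_offsets` boxes whose origins are the lesion-centered origin
#' plus seeded uniform integer shifts in `[-max_shift, max_shift]^2`,
#' clamped to the image. Every augmented box must still intersect the
#' source region; shifts failing that after `max_retries` draws are
#' skipped with a warning. Deterministic given `seed`.
#'
#' @param spec a lesion-centered `crop_spec` from [lesion_boxes()].
#' @param img the [annotated_image()] the spec was derived from.
#' @param n_offsets number of augmented boxes (0 gives only the center
#'   crop).
#' @param max_shift maximum absolute shift per axis, in pixels (default
#'   `side / 4`).
#' @param seed RNG seed.
#' @param max_retries draws per offset before giving up.
#' @return list of `crop_spec`s: the input spec followed by the
#'   augmented ones (`offset_index` 1..n).
#' @export
translation_augment <- function(spec, img, n_offsets, max_shift = NULL,
                                seed = 1L, max_retries = 20L) {
  stopifnot(inherits(spec, "crop_spec"), inherits(img, "annotated_image"))
  if (n_offsets < 0) stop("n_offsets must be >= 0")
  if (is.null(max_shift)) max_shift <- spec$side %/% 4L
  d <- dim(img$mask)
  out <- list(spec)
  if (n_offsets == 0L) return(out)
  region_mask <- logical(prod(d))
  region_mask[spec$region] <- TRUE
  with_seed(seed, {
    for (k in seq_len(n_offsets)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        sh <- round(stats::runif(2, -max_shift, max_shift))
        org <- c(min(max(spec$origin[1] + sh[1], 1L), d[1] - spec$side + 1L),
                 min(max(spec$origin[2] + sh[2], 1L), d[2] - spec$side + 1L))
        rows <- org[1]:(org[1] + spec$side - 1L)
        cols <- org[2]:(org[2] + spec$side - 1L)
        idx <- rep(rows, times = length(cols)) +
          (rep(cols, each = length(rows)) - 1L) * d[1]
        if (any(region_mask[idx])) {
          out[[length(out) + 1L]] <- structure(
            list(origin = org, side = spec$side, offset_index = k,
                 region = spec$region), class = "crop_spec")
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warning(sprintf(
          "offset %d: no shift intersecting the source region after %d draws; skipped",
          k, max_retries))
      }
    }
  })
  out
}

#' Cut crop windows and rescale them to the network input size
#'
#' Cuts each spec's `side x side` window from image and mask, then
#' rescales to `final_side` (the second 0.5x stage when
#' `final_side = side / 2`): image bilinear, mask nearest-neighbor.
#'
#' @param img an [annotated_image()].
#' @param specs list of `crop_spec`s.
#' @param final_side output side in pixels; `final_side = side` skips
#'   the rescale.
#' @return list of crop pairs: `list(image, mask, origin, side,
#'   offset_index, patient_id)`.
#' @export
extract_crops <- function(img, specs, final_side) {
  stopifnot(inherits(img, "annotated_image"))
  final_side <- as.integer(final_side)
  lapply(specs, function(sp) {
    stopifnot(inherits(sp, "crop_spec"))
    rows <- sp$origin[1]:(sp$origin[1] + sp$side - 1L)
    cols <- sp$origin[2]:(sp$origin[2] + sp$side - 1L)
    im <- img$image[rows, cols, , drop = FALSE]
    mk <- img$mask[rows, cols, drop = FALSE]
    if (final_side != sp$side) {
      im <- resize_array(im, final_side, final_side, "bilinear")
      mk <- round(resize_array(mk, final_side, final_side, "nearest"))
    }
    list(image = im, mask = mk, origin = sp$origin, side = sp$side,
         offset_index = sp$offset_index, patient_id = img$patient_id)
  })
}

#' Assign whole patients to train/validation/test splits
#'
#' Seeded deterministic assignment: patients are shuffled under `seed`
#' and allocated to splits by the largest-remainder rule on
#' `fractions`, so every patient lands in exactly one split.
#'
#' @param images list of [annotated_image()]s.
#' @param fractions named numeric `c(train, val, test)` summing to 1.
#' @param seed RNG seed.
#' @return object of class `split_manifest`: data.frame with
#'   `patient_id` and `split`, with per-split patient/image counts as
#'   attributes.
#' @export
split_by_patient <- function(images, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions))) names(fractions) <- c("train", "val", "test")[seq_along(fractions)]
  pids <- unique(vapply(images, `[[`, character(1), "patient_id"))
  nsplit <- sum(fractions > 0)
  if (length(pids) < nsplit) {
    stop(sprintf("%d patients cannot fill %d splits", length(pids), nsplit))
  }
  pids <- sort(pids)
  pids <- with_seed(seed, sample(pids))
  base <- floor(fractions * length(pids))
  rem <- length(pids) - sum(base)
  if (rem > 0) {
    frac_part <- fractions * length(pids) - base
    add <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  split <- rep(names(fractions), times = base)
  man <- data.frame(patient_id = pids, split = split,
                    stringsAsFactors = FALSE)
  man <- man[order(man$patient_id), ]
  rownames(man) <- NULL
  imgs_per <- table(vapply(images, `[[`, character(1), "patient_id"))
  counts <- vapply(names(fractions), function(s) {
    sum(imgs_per[man$patient_id[man$split == s]], na.rm = TRUE)
  }, numeric(1))
  # leakage guard: each patient in exactly one split
  stopifnot(!anyDuplicated(man$patient_id))
  structure(man, class = c("split_manifest", "data.frame"),
            n_patients = table(man$split), n_images = counts, seed = seed)
}

#' Save / load a split manifest as JSON
#'
#' @param manifest a `split_manifest`.
#' @param path JSON file path.
#' @return `save_manifest`: `path` invisibly; `load_manifest`: the
#'   restored `split_manifest`.
#' @export
save_manifest <- function(manifest, path) {
  jsonlite::write_json(list(seed = attr(manifest, "seed"),
                            assignment = as.data.frame(manifest)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$assignment
  structure(man, class = c("split_manifest", "data.frame"),
            seed = obj$seed)
}

#' Full crop-extraction pipeline for a set of annotated images
#'
#' Applies the two-stage pipeline to every image: rescale by 0.5, cut
#' lesion boxes of `side` pixels (translation-augmented for train/val
#' images, lesion-centered only for test images), rescale crops to
#' `final_side`.
#'
#' @param images list of [annotated_image()]s.
#' @param manifest a `split_manifest` covering the images' patients.
#' @param side box side at extraction scale (after the first 0.5x).
#' @param final_side network input side (second 0.5x when `side / 2`).
#' @param n_offsets translation offsets per lesion for train/val images.
#' @param max_shift maximum shift (default `side / 4`).
#' @param seed RNG seed for augmentation.
#' @return list with one element per split, each a list of crop pairs.
#' @export
build_crop_sets <- function(images, manifest, side = 512L, final_side = 256L,
                            n_offsets = 8L, max_shift = NULL, seed = 1L) {
  splits <- split(seq_along(images),
                  manifest$split[match(vapply(images, `[[`, character(1), "patient_id"),
                                       manifest$patient_id)])
  out <- lapply(names(splits), function(sname) {
    crops <- list()
    for (ii in splits[[sname]]) {
      half <- rescale_half(images[[ii]])
      if (sum(half$mask) == 0) next
      boxes <- lesion_boxes(half, side)
      specs <- list()
      for (bi in seq_along(boxes)) {
        if (sname == "test") {
          specs <- c(specs, boxes[bi])
        } else {
          specs <- c(specs, translation_augment(
            boxes[[bi]], half, n_offsets, max_shift,
            seed = seed + ii * 131L + bi))
        }
      }
      crops <- c(crops, extract_crops(half, specs, final_side))
    }
    crops
  })
  names(out) <- names(splits)
  out
}
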