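# Disk formats: PNG images and masks, 16-bit PNG probability maps,
# CSV indices. Dataset layout: <dir>/images/<stem>.png,
# <dir>/masks/<stem>.png (single channel, nonzero = lesion) and
# <dir>/index.csv with columns stem, patient_id.

#' Write an annotated dataset to the images/masks/index.csv layout
#'
#' @param dataset a list with `images` (list of [annotated_image()]s)
#'   and `index` (data.frame with `stem`, `patient_id`), as produced by
#'   [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    stem <- dataset$index$stem[i]
    png::writePNG(dataset$images[[i]]$image,
                  file.path(dir, "images", paste0(stem, ".png")))
    png::writePNG(dataset$images[[i]]$mask + 0,
                  file.path(dir, "masks", paste0(stem, ".png")))
  }
  utils::write.csv(dataset$index[, c("stem", "patient_id")],
                   file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an annotated dataset from the images/masks/index.csv layout
#'
#' Masks are binarized as nonzero = lesion.
#'
#' @param dir dataset directory.
#' @param pixel_scale optional px/mm recorded on every image.
#' @return list with `images` and `index` (see [write_dataset()]).
#' @export
read_dataset <- function(dir, pixel_scale = NULL) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         colClasses = c(stem = "character",
                                        patient_id = "character"))
  images <- lapply(seq_len(nrow(idx)), function(i) {
    im <- png::readPNG(file.path(dir, "images", paste0(idx$stem[i], ".png")))
    mk <- png::readPNG(file.path(dir, "masks", paste0(idx$stem[i], ".png")))
    if (length(dim(mk)) == 3L) mk <- mk[, , 1]
    annotated_image(im, (mk > 0) * 1L, idx$patient_id[i], pixel_scale)
  })
  list(images = images, index = idx)
}

#' Write a probability map as a 16-bit PNG
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prob_map <- function(prob, path) {
  EBImage::writeImage(EBImage::Image(prob), path, type = "png", bits = 16L)
  invisible(path)
}

#' Read a probability map written by [write_prob_map()]
#'
#' @param path PNG path.
#' @return probability matrix in `[0, 1]`.
#' @export
read_prob_map <- function(path) {
  as.matrix(EBImage::readImage(path))
}

#' Write crop pairs as paired PNGs with a manifest CSV
#'
#' @param crops list of crop pairs (see [extract_crops()]).
#' @param dir output directory; images land in `crops/`, masks in
#'   `crop_masks/`, plus `crops.csv`.
#' @return the manifest data.frame, invisibly.
#' @export
write_crops <- function(crops, dir) {
  dir.create(file.path(dir, "crops"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "crop_masks"), recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    stem <- sprintf("crop_%05d", i)
    png::writePNG(cr$image, file.path(dir, "crops", paste0(stem, ".png")))
    png::writePNG(cr$mask, file.path(dir, "crop_masks", paste0(stem, ".png")))
    data.frame(stem = stem, patient_id = cr$patient_id %||% NA_character_,
               origin_row = cr$origin[1], origin_col = cr$origin[2],
               side = cr$side, offset_index = cr$offset_index,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(dir, "crops.csv"), row.names = FALSE)
  invisible(man)
}

#' Score directories of predicted and ground-truth mask PNGs
#'
#' Pairs files by name: every PNG in `pred_dir` is scored against the
#' same-named PNG in `gt_dir`.
#'
#' @param pred_dir,gt_dir directories of mask PNGs (nonzero = lesion).
#' @param connectivity region connectivity for the adapted scores.
#' @return list with `per_pair` (data.frame of per-file metrics) and
#'   `aggregate` (see [aggregate_metrics()]).
#' @export
score_mask_dirs <- function(pred_dir, gt_dir, connectivity = 8) {
  files <- sort(list.files(pred_dir, pattern = "\\.png$"))
  if (!length(files)) stop("no PNG masks found in ", pred_dir)
  reports <- lapply(files, function(f) {
    rd <- function(p) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      (m > 0) * 1L
    }
    pred <- rd(file.path(pred_dir, f))
    gt <- rd(file.path(gt_dir, f))
    adapted_scores(extract_regions(gt, connectivity), pred, gt)
  })
  per_pair <- do.call(rbind, lapply(seq_along(files), function(i) {
    r <- reports[[i]]
    data.frame(file = files[i], dice = r$dice, iou = r$iou, aprec = r$aprec,
               arec = r$arec, af1 = r$af1, tpc = r$tpc, n_regions = r$n_regions)
  }))
  list(per_pair = per_pair, aggregate = aggregate_metrics(reports))
}
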