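# Wide-field inference.
#
# Photographs larger than the network input are zero-padded to a
# multiple of the tile stride, cut into model-sized tiles, predicted
# tile by tile, and the per-tile probabilities are placed back at their
# origins (averaged where tiles overlap). The padding is removed so the
# probability map matches the input size exactly. The default is
# non-overlapping tiles (pure mosaicking); overlap with uniform
# averaging is available for seam suppression.

#' Plan the padding and tile grid for an image
#'
#' Computes the minimal, symmetric-as-possible zero padding so that
#' tiles of `tile_side` with stride `tile_side - overlap` cover the
#' padded frame exactly, and the list of tile origins. When the total
#' padding on an axis is odd, the extra pixel goes to the bottom/right.
#'
#' @param height,width input image size in pixels.
#' @param tile_side tile (= network input) side.
#' @param overlap pixels shared by adjacent tiles; `0 <= overlap <
#'   tile_side`.
#' @return object of class `tiling_plan`: `pad` (top, bottom, left,
#'   right), `tiles` (matrix of row/col origins on the padded frame),
#'   `tile_side`, `overlap`, `padded` (padded height, width) and the
#'   original `size`.
#' @export
plan_tiling <- function(height, width, tile_side = 256L, overlap = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  tile_side <- as.integer(tile_side); overlap <- as.integer(overlap)
  if (height < 1L || width < 1L) stop("image dimensions must be positive")
  if (overlap < 0L || overlap >= tile_side) stop("need tile_side > overlap >= 0")
  stride <- tile_side - overlap
  plan_axis <- function(n) {
    k <- if (n <= tile_side) 1L else as.integer(ceiling((n - tile_side) / stride)) + 1L
    padded <- (k - 1L) * stride + tile_side
    pad <- padded - n
    c(k = k, lo = pad %/% 2L, hi = pad - pad %/% 2L, padded = padded)
  }
  pr <- plan_axis(height); pc <- plan_axis(width)
  origins <- as.matrix(expand.grid(
    row = seq.int(1L, by = stride, length.out = pr["k"]),
    col = seq.int(1L, by = stride, length.out = pc["k"])))
  structure(list(pad = c(top = unname(pr["lo"]), bottom = unname(pr["hi"]),
                         left = unname(pc["lo"]), right = unname(pc["hi"])),
                 tiles = origins, tile_side = tile_side, overlap = overlap,
                 padded = c(unname(pr["padded"]), unname(pc["padded"])),
                 size = c(height, width)),
            class = "tiling_plan")
}

#' Tiled prediction of a wide-field image
#'
#' Zero-pads the image per `plan`, predicts every tile, accumulates the
#' per-tile probabilities at their origins (averaging overlapped
#' pixels), and crops the padding away.
#'
#' @param img (h, w, 3) RGB array in `[0, 1]`.
#' @param model an `aku_model`, or any function mapping a
#'   `(tile_side, tile_side, 3)` array to a probability matrix of the
#'   same spatial size (used for stub models in tests).
#' @param plan a [plan_tiling()] for `dim(img)`; computed automatically
#'   when `NULL`.
#' @param overlap used when `plan` is `NULL`.
#' @return probability matrix of the input's spatial size, values in
#'   `[0, 1]`.
#' @export
predict_wide <- function(img, model, plan = NULL, overlap = 0L) {
  img <- as_hwc(img)
  d <- dim(img)
  if (inherits(model, "aku_model")) {
    side <- model$config$input_side
    fun <- function(tile) model_forward(model, tile, training = FALSE)$prob
  } else if (is.function(model)) {
    fun <- model
    side <- if (is.null(plan)) 256L else plan$tile_side
  } else stop("model must be an aku_model or a function")
  if (is.null(plan)) plan <- plan_tiling(d[1], d[2], side, overlap)
  if (inherits(model, "aku_model") && plan$tile_side != model$config$input_side) {
    stop(sprintf("plan tile side %d does not match model input side %d",
                 plan$tile_side, model$config$input_side))
  }
  padded <- array(0, c(plan$padded[1], plan$padded[2], d[3]))
  padded[plan$pad["top"] + seq_len(d[1]),
         plan$pad["left"] + seq_len(d[2]), ] <- img
  acc <- matrix(0, plan$padded[1], plan$padded[2])
  cnt <- matrix(0, plan$padded[1], plan$padded[2])
  ts <- plan$tile_side
  for (i in seq_len(nrow(plan$tiles))) {
    r <- plan$tiles[i, "row"]; cc <- plan$tiles[i, "col"]
    tile <- padded[r:(r + ts - 1L), cc:(cc + ts - 1L), , drop = FALSE]
    p <- fun(tile)
    if (!all(dim(p)[1:2] == ts)) {
      stop("model output size does not match the tile size")
    }
    acc[r:(r + ts - 1L), cc:(cc + ts - 1L)] <-
      acc[r:(r + ts - 1L), cc:(cc + ts - 1L)] + p
    cnt[r:(r + ts - 1L), cc:(cc + ts - 1L)] <-
      cnt[r:(r + ts - 1L), cc:(cc + ts - 1L)] + 1
  }
  prob <- acc / cnt
  prob[plan$pad["top"] + seq_len(d[1]), plan$pad["left"] + seq_len(d[2]),
       drop = FALSE]
}

#' Detect lesion regions in a probability map
#'
#' Binarizes at `threshold`, removes connected components smaller than
#' `min_area_px`, and returns the cleaned mask together with the
#' surviving regions. `min_area_px = 0` (default) is pure thresholding.
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param threshold binarization cut in `[0, 1]`.
#' @param min_area_px minimum component area in pixels.
#' @param connectivity component connectivity.
#' @return list with `mask` (0/1 matrix) and `regions`
#'   (a `lesion_regions`).
#' @export
detect_regions <- function(prob, threshold = 0.5, min_area_px = 0L,
                           connectivity = 8) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  mask <- binarize_prob(prob, threshold)
  regs <- extract_regions(mask, connectivity)
  if (min_area_px > 0 && regs$n > 0) {
    keep <- vapply(regs$regions, length, integer(1)) >= min_area_px
    for (px in regs$regions[!keep]) mask[px] <- 0L
    regs$regions <- regs$regions[keep]
    regs$n <- length(regs$regions)
  }
  list(mask = mask, regions = regs)
}
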