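# Crop extraction, translation augmentation, patient-level splitting.

mk_img <- function(h, w, mask = NULL, pid = "P001", scale = 5) {
  img <- array(runif(h * w * 3, 0.4, 0.6), c(h, w, 3))
  if (is.null(mask)) mask <- matrix(0L, h, w)
  annotated_image(img, mask, pid, scale)
}

test_that("rescaling halves both channels coherently and keeps masks binary", {
  set.seed(51)
  m <- matrix(0L, 100, 150); m[30:60, 40:90] <- 1L
  img <- mk_img(100, 150, m)
  half <- rescale_half(img)
  expect_equal(dim(half$mask), c(50L, 75L))
  expect_equal(dim(half$image)[1:2], c(50L, 75L))
  expect_true(all(half$mask %in% c(0L, 1L)))
  expect_equal(half$pixel_scale, 2.5)
  # two applications quarter the side
  expect_equal(dim(rescale_half(half)$mask), c(25L, 38L))
  # area shrinks by ~4x and the lesion's center stays covered
  expect_lt(abs(sum(half$mask) - sum(m) / 4) / (sum(m) / 4), 0.2)
  expect_equal(half$mask[23, 33], 1L)
})

test_that("lesion boxes are centered, clamped, and one per region", {
  m <- matrix(0L, 100, 100); m[41:60, 41:60] <- 1L
  img <- mk_img(100, 100, m)
  bx <- lesion_boxes(img, 32L)
  expect_length(bx, 1L)
  expect_equal(bx[[1]]$origin, c(34, 34))  # round(centroid 50.5 - side/2)
  # corner blob: box clamped inside bounds and still contains the blob
  mc <- matrix(0L, 100, 100); mc[1:6, 1:6] <- 1L
  bc <- lesion_boxes(mk_img(100, 100, mc), 32L)[[1]]
  expect_equal(bc$origin, c(1, 1))
  expect_true(all(mc[bc$origin[1]:(bc$origin[1] + 31),
                     bc$origin[2]:(bc$origin[2] + 31)] == mc[1:32, 1:32]))
  # K disjoint regions -> K boxes, counted against the region oracle
  set.seed(52)
  for (i in 1:5) {
    mm <- matrix(0L, 80, 80)
    k <- sample(1:4, 1)
    for (b in seq_len(k)) {
      r <- 10 + (b - 1) * 20
      mm[r:(r + 5), r:(r + 5)] <- 1L
    }
    expect_length(lesion_boxes(mk_img(80, 80, mm), 20L), k)
  }
  expect_length(lesion_boxes(mk_img(40, 40), 20L), 0L)
})

test_that("translation augmentation is seeded, bounded, and lesion-preserving", {
  m <- matrix(0L, 120, 120); m[50:70, 50:70] <- 1L
  img <- mk_img(120, 120, m)
  bx <- lesion_boxes(img, 48L)[[1]]
  expect_length(translation_augment(bx, img, 0L), 1L)
  a1 <- translation_augment(bx, img, 5L, seed = 9L)
  a2 <- translation_augment(bx, img, 5L, seed = 9L)
  expect_equal(lapply(a1, `[[`, "origin"), lapply(a2, `[[`, "origin"))
  expect_length(a1, 6L)
  # every augmented window still intersects the source region
  for (rep in 1:200) {
    sp <- translation_augment(bx, img, 5L, max_shift = 30L, seed = 1000L + rep)
    for (s in sp) {
      win <- m[s$origin[1]:(s$origin[1] + 47), s$origin[2]:(s$origin[2] + 47)]
      expect_gt(sum(win), 0)
    }
  }
})

test_that("crops are cut, rescaled and co-registered with their masks", {
  # lesion pixels get a unique color so the mask can be recomputed
  m <- matrix(0L, 100, 100); m[30:50, 40:70] <- 1L
  img <- array(0.5, c(100, 100, 3))
  img[, , 1][m == 1] <- 1  # pure red marker
  ai <- annotated_image(img, m, "P007")
  specs <- lesion_boxes(ai, 40L)
  cr <- extract_crops(ai, specs, 40L)[[1]]      # no second rescale
  expect_equal(dim(cr$image)[1:2], c(40L, 40L))
  recomputed <- (cr$image[, , 1] == 1) * 1L
  expect_identical(recomputed, cr$mask + 0L)
  half <- extract_crops(ai, specs, 20L)[[1]]    # second 0.5x stage
  expect_equal(dim(half$mask), c(20L, 20L))
  expect_true(all(half$mask %in% c(0L, 1L)))
  # an all-lesion image yields an all-ones crop mask
  all1 <- annotated_image(array(0.5, c(50, 50, 3)),
                          matrix(1L, 50, 50), "P008")
  sp <- list(structure(list(origin = c(5L, 5L), side = 20L,
                            offset_index = 0L, region = which(matrix(TRUE, 50, 50))),
                       class = "crop_spec"))
  expect_true(all(extract_crops(all1, sp, 20L)[[1]]$mask == 1))
})

test_that("patients are split whole, deterministically, without leakage", {
  imgs <- lapply(1:20, function(i) {
    mk_img(20, 20, pid = sprintf("P%02d", (i - 1) %/% 2 + 1))
  })
  man <- split_by_patient(imgs, c(train = 0.8, val = 0.1, test = 0.1), seed = 3L)
  expect_equal(unname(as.vector(attr(man, "n_patients"))[match(
    c("train", "val", "test"), names(attr(man, "n_patients")))]), c(8, 1, 1))
  expect_false(anyDuplicated(man$patient_id) > 0)
  man2 <- split_by_patient(imgs, c(train = 0.8, val = 0.1, test = 0.1), seed = 3L)
  expect_identical(as.data.frame(man), as.data.frame(man2))
  expect_error(split_by_patient(imgs[1:2], c(train = 0.4, val = 0.3, test = 0.3)),
               "cannot fill")
  expect_error(split_by_patient(imgs, c(0.5, 0.2)), "sum to 1")
  # JSON round trip
  pth <- tempfile(fileext = ".json")
  save_manifest(man, pth)
  man3 <- load_manifest(pth)
  expect_equal(man3$patient_id, man$patient_id)
  expect_equal(man3$split, man$split)
})

test_that("test-split crops are lesion-centered only", {
  set.seed(53)
  sc <- scene_config(height = 128L, width = 128L, n_lesions = c(1L, 1L),
                     lesion_diameter_mm = c(5, 8), seed = 1L)
  ds <- generate_dataset(5L, 1L, sc)
  man <- split_by_patient(ds$images, c(train = 0.6, val = 0.2, test = 0.2),
                          seed = 1L)
  cs <- build_crop_sets(ds$images, man, side = 48L, final_side = 48L,
                        n_offsets = 3L, seed = 1L)
  expect_true(all(vapply(cs$test, `[[`, integer(1), "offset_index") == 0L))
  expect_true(any(vapply(cs$train, `[[`, integer(1), "offset_index") > 0L))
  # no patient appears in two crop sets
  pids <- lapply(cs, function(s) unique(vapply(s, `[[`, character(1), "patient_id")))
  expect_length(intersect(pids$train, pids$test), 0L)
  expect_length(intersect(pids$train, pids$val), 0L)
})
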