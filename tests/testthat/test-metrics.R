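# Pixel-overlap and region-tolerant metrics.

test_that("Dice and IoU reproduce hand-counted overlap cases", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  expect_equal(dice_coef(a, a), 1)
  expect_equal(iou_coef(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(dice_coef(a, b), 0)
  # 2x2 block vs the same block shifted one column: overlap 2 px
  s <- matrix(0L, 6, 6); s[2:3, 3:4] <- 1L
  expect_equal(dice_coef(a, s), 0.5)
  expect_equal(iou_coef(a, s), 2 / 6)
  # empty-vs-empty convention
  e <- matrix(0L, 6, 6)
  expect_equal(dice_coef(e, e), 1)
  expect_equal(iou_coef(e, e), 1)
  expect_error(dice_coef(a, matrix(0L, 5, 6)), "shapes differ")
})

test_that("Dice and IoU satisfy the algebraic identity on random masks", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_blob_mask(16, 16, runif(1, 0.1, 0.6))
    b <- random_blob_mask(16, 16, runif(1, 0.1, 0.6))
    d <- dice_coef(a, b); j <- iou_coef(a, b)
    expect_gte(d, j)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("region extraction respects connectivity and conserves pixels", {
  e <- matrix(0L, 5, 5)
  expect_equal(extract_regions(e)$n, 0L)
  # two blobs touching only diagonally
  m <- matrix(0L, 5, 5); m[1:2, 1:2] <- 1L; m[3:4, 3:4] <- 1L
  expect_equal(extract_regions(m, connectivity = 8)$n, 1L)
  expect_equal(extract_regions(m, connectivity = 4)$n, 2L)
  set.seed(42)
  for (i in 1:10) {
    mm <- random_blob_mask(20, 20, runif(1, 0.1, 0.5))
    regs <- extract_regions(mm)
    expect_equal(sum(lengths(regs$regions)), sum(mm))
    expect_false(anyDuplicated(unlist(regs$regions)) > 0)
  }
})

test_that("flood-fill labeling agrees with independent implementations", {
  set.seed(43)
  for (i in 1:8) {
    mm <- random_blob_mask(18, 18, runif(1, 0.1, 0.5))
    for (conn in c(4, 8)) {
      lab <- label_components(mm, conn)
      want <- oracle_label(mm, conn)
      # same partition: component count and co-membership
      expect_equal(max(lab), length(setdiff(unique(as.vector(want)), 0L)))
      expect_equal(outer(lab[mm == 1], lab[mm == 1], "=="),
                   outer(want[mm == 1], want[mm == 1], "=="))
    }
    # EBImage's labeling is the 4-connectivity cross-check
    expect_equal(max(label_components(mm, 4)),
                 max(EBImage::bwlabel(mm)))
  }
})

test_that("adapted scores implement the region-intersection rule", {
  gt <- matrix(0L, 10, 10); gt[1:3, 1:3] <- 1L; gt[7:9, 7:9] <- 1L
  regs <- extract_regions(gt)
  # prediction covers exactly one of two regions
  pred <- matrix(0L, 10, 10); pred[1:3, 1:3] <- 1L
  r <- adapted_scores(regs, pred, gt)
  expect_equal(r$arec, 0.5)
  expect_equal(r$aprec, 1.0)
  expect_equal(r$af1, 2 / 3)
  expect_equal(r$tpc, 1L)
  # a single-pixel graze still counts the region as detected
  graze <- matrix(0L, 10, 10); graze[3, 3] <- 1L; graze[9, 9] <- 1L
  rg <- adapted_scores(regs, graze, gt)
  expect_equal(rg$arec, 1)
  expect_equal(rg$aprec, 1)
  expect_gte(rg$af1, rg$dice)  # region tolerance forgives rough extent
  # sentinels
  empty <- matrix(0L, 10, 10)
  re <- adapted_scores(regs, empty, gt)
  expect_equal(re$arec, 0)
  expect_true(is.na(re$aprec))
  expect_true(is.na(re$af1))
  rn <- adapted_scores(extract_regions(empty), pred, empty)
  expect_true(is.na(rn$arec))
  expect_error(adapted_scores(regs, pred, pred), "inconsistent")
})

test_that("adapted scores agree with the brute-force oracle on random masks", {
  set.seed(44)
  for (i in 1:30) {
    gt <- random_blob_mask(24, 24, runif(1, 0.05, 0.4))
    pred <- random_blob_mask(24, 24, runif(1, 0.05, 0.4))
    r <- adapted_scores(extract_regions(gt), pred, gt)
    o <- oracle_scores(pred, gt)
    expect_equal(r$dice, o$dice, tolerance = 1e-12)
    expect_equal(r$iou, o$iou, tolerance = 1e-12)
    expect_equal(r$tpc, o$tpc)
    expect_equal(r$n_regions, o$n)
    expect_equal(r$arec, o$arec, tolerance = 1e-12)
    expect_equal(r$aprec, o$aprec, tolerance = 1e-12)
  }
})

test_that("growing a prediction inside the truth never hurts TPC or the aPrec numerator", {
  set.seed(45)
  gt <- random_blob_mask(20, 20, 0.35)
  regs <- extract_regions(gt)
  pred <- matrix(0L, 20, 20)
  inside <- which(gt == 1)
  prev_tp <- 0; prev_tpc <- 0L
  for (px in sample(inside)) {
    pred[px] <- 1L
    r <- adapted_scores(regs, pred, gt)
    expect_gte(r$tp, prev_tp)
    expect_gte(r$tpc, prev_tpc)
    prev_tp <- r$tp; prev_tpc <- r$tpc
  }
  expect_equal(prev_tpc, regs$n)
})

test_that("evaluate_pair binarizes and applies the empty-mask conventions", {
  gt <- matrix(0L, 8, 8); gt[3:5, 3:5] <- 1L
  r <- evaluate_pair(gt + 0, gt, threshold = 0.5)
  expect_equal(r$dice, 1); expect_equal(r$iou, 1); expect_equal(r$af1, 1)
  rz <- evaluate_pair(matrix(0, 8, 8), gt)
  expect_equal(rz$dice, 0); expect_equal(rz$arec, 0)
  expect_true(is.na(rz$aprec))
  pm <- matrix(runif(64, 0.2, 0.8), 8, 8)
  expect_equal(sum(binarize_prob(pm, 0)), 64)
  expect_equal(sum(binarize_prob(pm, 1)), 0)
  expect_error(evaluate_pair(pm, gt, threshold = 1.5), "threshold")
})

test_that("aggregation averages defined entries and reports exclusions", {
  gt <- matrix(0L, 8, 8); gt[2:4, 2:4] <- 1L
  full <- evaluate_pair(gt + 0, gt)
  none <- evaluate_pair(matrix(0, 8, 8), gt)
  agg <- aggregate_metrics(list(full, none))
  expect_equal(agg$mean[agg$metric == "dice"], 0.5)
  expect_equal(agg$n_excluded[agg$metric == "aprec"], 1L)
  expect_equal(agg$n[agg$metric == "aprec"], 1L)
  expect_equal(agg$mean[agg$metric == "aprec"], 1)
})
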