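# The convLSTM recurrence and its patch plumbing.

test_that("patch splitting is a lossless bijection", {
  set.seed(21)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  ps <- split_to_patches(x, c(2, 2))
  expect_length(ps$patches, 4L)
  expect_equal(dim(ps$patches[[1]]), c(2L, 2L, 2L))
  # raster order: patch 2 is the top-right block
  expect_equal(ps$patches[[2]], x[1:2, 3:4, , drop = FALSE])
  expect_identical(reassemble_patches(ps), x)

  ps1 <- split_to_patches(x, c(1, 1))
  expect_length(ps1$patches, 1L)
  expect_equal(ps1$patches[[1]], x)

  for (i in 1:5) {
    h <- sample(c(4, 6, 12), 1); w <- sample(c(4, 6, 8), 1)
    y <- array(rnorm(h * w * 3), c(h, w, 3))
    grid <- c(sample(c(1, 2), 1), sample(c(1, 2), 1))
    expect_identical(reassemble_patches(split_to_patches(y, grid)), y)
  }
  expect_error(split_to_patches(x, c(3, 2)), "does not divide")
})

test_that("zero parameters give half-open gates and zero state", {
  p <- convlstm_params(2, 3, spatial = c(4, 4), init = "zero")
  st <- convlstm_step(array(rnorm(4 * 4 * 2), c(4, 4, 2)),
                      convlstm_zero_state(p), p)
  expect_equal(st$cell, array(0, c(4, 4, 3)))
  expect_equal(st$hidden, array(0, c(4, 4, 3)))
  # the fused map is then identically zero too
  out <- convlstm_fuse(array(rnorm(16), c(4, 4, 1)),
                       array(rnorm(16), c(4, 4, 1)), c(2, 2),
                       convlstm_params(2, 3, spatial = c(2, 2), init = "zero"))
  expect_equal(out, array(0, c(4, 4, 3)))
})

test_that("a saturated forget gate preserves the cell state", {
  p <- convlstm_params(1, 1, spatial = c(3, 3), init = "zero")
  p$b[2] <- 50        # forget bias -> sigmoid saturates at 1
  p$b[1] <- -50       # input gate closed: candidate contributes nothing
  st <- list(hidden = array(0, c(3, 3, 1)),
             cell = array(rnorm(9), c(3, 3, 1)))
  st2 <- convlstm_step(array(rnorm(9), c(3, 3, 1)), st, p)
  expect_equal(st2$cell, st$cell, tolerance = 1e-12)
})

test_that("one step agrees with the literal equation oracle", {
  set.seed(22)
  # scalar case: 1x1 spatial, 1x1 kernels, hand-picked weights
  p <- convlstm_params(1, 1, spatial = c(1, 1), kernel = 1L, init = "zero")
  p$Wx[] <- c(0.3, -0.2, 0.5, 0.1)
  p$Wh[] <- c(-0.4, 0.2, 0.3, -0.1)
  p$b <- c(0.05, -0.05, 0.2, 0.1)
  p$Wci[] <- 0.7; p$Wcf[] <- -0.3; p$Wco[] <- 0.4
  st <- list(hidden = array(0.3, c(1, 1, 1)), cell = array(-0.5, c(1, 1, 1)))
  x <- array(0.8, c(1, 1, 1))
  got <- convlstm_step(x, st, p)
  want <- oracle_convlstm_step(x, st, p)
  expect_equal(got$hidden, want$hidden, tolerance = 1e-6)
  expect_equal(got$cell, want$cell, tolerance = 1e-6)

  # random 3x3 instances with 3x3 kernels and nonzero peepholes
  for (i in 1:10) {
    cin <- sample(1:3, 1); K <- sample(1:3, 1)
    p <- convlstm_params(cin, K, spatial = c(3, 3), kernel = 3L,
                         init = "he", seed = 100L + i)
    p$Wci[] <- rnorm(length(p$Wci), sd = 0.5)
    p$Wcf[] <- rnorm(length(p$Wcf), sd = 0.5)
    p$Wco[] <- rnorm(length(p$Wco), sd = 0.5)
    st <- list(hidden = array(rnorm(9 * K), c(3, 3, K)),
               cell = array(rnorm(9 * K), c(3, 3, K)))
    x <- array(rnorm(9 * cin), c(3, 3, cin))
    got <- convlstm_step(x, st, p)
    want <- oracle_convlstm_step(x, st, p)
    expect_equal(got$hidden, want$hidden, tolerance = 1e-6)
    expect_equal(got$cell, want$cell, tolerance = 1e-6)
  }
})

test_that("gate activations and hidden outputs stay in their ranges", {
  set.seed(23)
  for (i in 1:5) {
    p <- convlstm_params(2, 2, spatial = c(4, 4), init = "he", seed = i)
    st <- list(hidden = array(rnorm(32), c(4, 4, 2)),
               cell = array(rnorm(32), c(4, 4, 2)))
    st2 <- convlstm_step(array(rnorm(32, sd = 2), c(4, 4, 2)), st, p)
    expect_true(all(abs(st2$hidden) < 1))
  }
})

test_that("fusion equals manual split-iterate-reassemble", {
  set.seed(24)
  p <- convlstm_params(4, 3, spatial = c(3, 2), init = "he", seed = 9)
  xe <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  xd <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  got <- convlstm_fuse(xe, xd, c(2, 2), p)
  x <- array(c(xe, xd), c(6, 4, 4))
  ps <- split_to_patches(x, c(2, 2))
  st <- convlstm_zero_state(p)
  hs <- vector("list", 4)
  for (t in 1:4) {
    st <- convlstm_step(ps$patches[[t]], st, p)
    hs[[t]] <- st$hidden
  }
  want <- reassemble_patches(structure(
    list(patches = hs, grid = c(2, 2), order = "row-major",
         dim = c(6, 4, 3)), class = "patch_sequence"))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(dim(got), c(6L, 4L, 3L))
})

test_that("a (1, 1) grid degenerates to a single step over the whole map", {
  set.seed(25)
  p <- convlstm_params(2, 2, spatial = c(4, 4), init = "he", seed = 7)
  xe <- array(rnorm(16), c(4, 4, 1)); xd <- array(rnorm(16), c(4, 4, 1))
  got <- convlstm_fuse(xe, xd, c(1, 1), p)
  st <- convlstm_step(array(c(xe, xd), c(4, 4, 2)),
                      convlstm_zero_state(p), p)
  expect_equal(got, st$hidden, tolerance = 1e-12)
})

test_that("step rejects mismatched shapes", {
  p <- convlstm_params(2, 2, spatial = c(4, 4), init = "zero")
  st <- convlstm_zero_state(p)
  expect_error(convlstm_step(array(0, c(2, 2, 2)), st, p), "spatial")
  expect_error(convlstm_step(array(0, c(4, 4, 5)), st, p), "channels")
})
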