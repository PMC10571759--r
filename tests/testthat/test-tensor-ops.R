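# The network layers carry hand-derived gradients; every layer's
# backward pass is validated here against central finite differences.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("convolution forward matches the naive loop oracle", {
  set.seed(1)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  W <- matrix(rnorm(9 * 2 * 3), 18, 3)
  b <- rnorm(3)
  got <- akuseg:::conv2d_fwd(x, W, b)$out
  want <- conv_same_oracle(x, W, 3)
  for (oc in 1:3) want[, , oc] <- want[, , oc] + b[oc]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  W <- matrix(rnorm(18 * 3), 18, 3)
  b <- rnorm(3)
  fw <- akuseg:::conv2d_fwd(x, W, b)
  bw <- akuseg:::conv2d_bwd(fw$cache, cos(fw$out))
  expect_lt(max(abs(bw$gx - num_grad(function(v)
    sum(sin(akuseg:::conv2d_fwd(array(v, dim(x)), W, b)$out)), x))), 1e-6)
  expect_lt(max(abs(bw$gW - array(num_grad(function(v)
    sum(sin(akuseg:::conv2d_fwd(x, matrix(v, 18, 3), b)$out)),
    as.numeric(W)), dim(W)))), 1e-6)
  expect_lt(max(abs(bw$gb - num_grad(function(v)
    sum(sin(akuseg:::conv2d_fwd(x, W, v)$out)), b))), 1e-6)
})

test_that("max pooling and transposed convolution gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  fw <- akuseg:::maxpool2_fwd(x)
  gx <- akuseg:::maxpool2_bwd(fw$cache, cos(fw$out))
  expect_lt(max(abs(gx - num_grad(function(v)
    sum(sin(akuseg:::maxpool2_fwd(array(v, dim(x)))$out)), x))), 1e-6)

  xu <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  W <- matrix(rnorm(2 * 12), 2, 12)
  b <- rnorm(3)
  fu <- akuseg:::upconv2_fwd(xu, W, b)
  expect_equal(dim(fu$out), c(6L, 8L, 3L))
  bu <- akuseg:::upconv2_bwd(fu$cache, cos(fu$out))
  expect_lt(max(abs(bu$gx - num_grad(function(v)
    sum(sin(akuseg:::upconv2_fwd(array(v, dim(xu)), W, b)$out)), xu))), 1e-6)
  expect_lt(max(abs(bu$gW - array(num_grad(function(v)
    sum(sin(akuseg:::upconv2_fwd(xu, matrix(v, 2, 12), b)$out)),
    as.numeric(W)), dim(W)))), 1e-6)
})

test_that("batch normalization gradients match finite differences", {
  set.seed(4)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  gm <- runif(3, 0.5, 1.5); bt <- rnorm(3)
  fw <- akuseg:::bn_fwd(x, gm, bt, numeric(3), rep(1, 3), training = TRUE)
  bw <- akuseg:::bn_bwd(fw$cache, cos(fw$out))
  obj <- function(xx, g, b) {
    sum(sin(akuseg:::bn_fwd(xx, g, b, numeric(3), rep(1, 3), TRUE)$out))
  }
  expect_lt(max(abs(bw$gx - num_grad(function(v)
    obj(array(v, dim(x)), gm, bt), x))), 1e-6)
  expect_lt(max(abs(bw$ggamma - num_grad(function(v) obj(x, v, bt), gm))), 1e-6)
  expect_lt(max(abs(bw$gbeta - num_grad(function(v) obj(x, gm, v), bt))), 1e-6)
  # running moments accumulate toward the batch statistics
  expect_equal(fw$rm, 0.1 * colMeans(matrix(x, 20, 3)), tolerance = 1e-12)
})

test_that("full model backward matches finite differences on a micro network", {
  cfg <- aku_model_config(input_side = 8L, base_filters = 2L,
                          convs_per_block = c(1L, 1L, 1L, 1L),
                          convlstm_grid = c(2L, 2L), seed = 5L)
  m <- build_model(cfg)
  set.seed(11)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  fw <- akuseg:::model_forward(m, x, training = TRUE, keep_cache = TRUE)
  G <- akuseg:::model_backward(m, fw$cache, (fw$prob - y) / 64)
  eps <- 1e-6
  loss_with <- function(mm) bce_loss(akuseg:::model_forward(mm, x, training = TRUE)$prob, y)
  probes <- list(
    list(get = function(P) P$enc[[1]][[1]]$W,
         set = function(P, v) { P$enc[[1]][[1]]$W <- v; P },
         gg = G$enc[[1]][[1]]$W),
    list(get = function(P) P$dec[[2]]$clstm$Wx,
         set = function(P, v) { P$dec[[2]]$clstm$Wx <- v; P },
         gg = G$dec[[2]]$clstm$Wx),
    list(get = function(P) P$dec[[1]]$clstm$Wco,
         set = function(P, v) { P$dec[[1]]$clstm$Wco <- v; P },
         gg = G$dec[[1]]$clstm$Wco),
    list(get = function(P) P$dec[[1]]$bn1$gamma,
         set = function(P, v) { P$dec[[1]]$bn1$gamma <- v; P },
         gg = G$dec[[1]]$bn1$gamma),
    list(get = function(P) P$dec[[3]]$up$W,
         set = function(P, v) { P$dec[[3]]$up$W <- v; P },
         gg = G$dec[[3]]$up$W),
    list(get = function(P) P$head$W,
         set = function(P, v) { P$head$W <- v; P },
         gg = G$head$W))
  for (pr in probes) {
    pv <- pr$get(m$params)
    for (i in sample(length(pv), min(3, length(pv)))) {
      m1 <- m; p1 <- pv; p1[i] <- pv[i] + eps; m1$params <- pr$set(m1$params, p1)
      m2 <- m; p2 <- pv; p2[i] <- pv[i] - eps; m2$params <- pr$set(m2$params, p2)
      fd <- (loss_with(m1) - loss_with(m2)) / (2 * eps)
      expect_lt(abs(fd - pr$gg[i]), 1e-6)
    }
  }
})
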