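# Dense tensor primitives for the segmentation network.
#
# All feature maps are plain (h, w, c) double arrays. Convolutions are
# evaluated as im2col matrix products so the heavy lifting runs in BLAS;
# each *_fwd returns its output together with the cache its *_bwd needs.
# Gradients are hand-derived and validated against finite differences in
# the test suite.

# ---- im2col / col2im ------------------------------------------------------

pad_hw <- function(x, p) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  xp
}

# (h, w, c) -> (h*w, k*k*c) patch matrix under same-padding.
# Column blocks iterate kernel offsets column-major (di fast), each block
# holding all input channels for that offset.
im2col <- function(x, k) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]
  if (k == 1L) return(matrix(x, h * w, cc))
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  cols <- matrix(0, h * w, k * k * cc)
  col <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      s <- xp[(di + 1L):(di + h), (dj + 1L):(dj + w), ]
      dim(s) <- c(h * w, cc)
      cols[, col:(col + cc - 1L)] <- s
      col <- col + cc
    }
  }
  cols
}

# Adjoint of im2col: scatter-add patch-matrix gradients back to the input.
col2im <- function(cols, h, w, cc, k) {
  if (k == 1L) return(array(cols, c(h, w, cc)))
  p <- (k - 1L) %/% 2L
  gp <- array(0, c(h + 2L * p, w + 2L * p, cc))
  col <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      s <- cols[, col:(col + cc - 1L)]
      dim(s) <- c(h, w, cc)
      gp[(di + 1L):(di + h), (dj + 1L):(dj + w), ] <-
        gp[(di + 1L):(di + h), (dj + 1L):(dj + w), ] + s
      col <- col + cc
    }
  }
  gp[(p + 1L):(p + h), (p + 1L):(p + w), , drop = FALSE]
}

# ---- convolution (same padding, stride 1) ---------------------------------

# W: (k*k*cin) x cout weight matrix, b: length-cout bias.
conv2d_fwd <- function(x, W, b) {
  d <- dim(x)
  k <- as.integer(round(sqrt(nrow(W) / d[3])))
  stopifnot(k * k * d[3] == nrow(W))
  cols <- im2col(x, k)
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], ncol(W))),
       cache = list(cols = cols, W = W, d = d, k = k))
}

conv2d_bwd <- function(cache, gy) {
  d <- cache$d
  gym <- gy
  dim(gym) <- c(d[1] * d[2], ncol(cache$W))
  list(gx = col2im(gym %*% t(cache$W), d[1], d[2], d[3], cache$k),
       gW = crossprod(cache$cols, gym),
       gb = colSums(gym))
}

# ---- ReLU -----------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, gy) gy * cache

# ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  # ties routed to the first maximal cell in (a, b, cc, dd) order
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !(m1 | m2)
  m4 <- (dd == y) & !(m1 | m2 | m3)
  list(out = y, cache = list(m = list(m1, m2, m3, m4), d = d))
}

maxpool2_bwd <- function(cache, gy) {
  d <- cache$d
  gx <- array(0, d)
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  gx[i1, j1, ] <- gy * cache$m[[1]]
  gx[i2, j1, ] <- gy * cache$m[[2]]
  gx[i1, j2, ] <- gy * cache$m[[3]]
  gx[i2, j2, ] <- gy * cache$m[[4]]
  gx
}

# ---- transposed convolution, kernel 2, stride 2 ---------------------------

# Each input pixel emits a 2x2 output block. W: cin x (4*cout); the four
# column blocks are the output quadrants in (odd,odd), (even,odd),
# (odd,even), (even,even) row/column order.
upconv2_fwd <- function(x, W, b) {
  d <- dim(x); cin <- d[3]; cout <- ncol(W) %/% 4L
  stopifnot(nrow(W) == cin)
  xm <- matrix(x, d[1] * d[2], cin)
  y4 <- xm %*% W
  out <- array(0, c(2L * d[1], 2L * d[2], cout))
  i1 <- seq.int(1L, 2L * d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * d[2], 2L); j2 <- j1 + 1L
  blk <- function(q) array(y4[, ((q - 1L) * cout + 1L):(q * cout)], c(d[1], d[2], cout))
  out[i1, j1, ] <- blk(1L); out[i2, j1, ] <- blk(2L)
  out[i1, j2, ] <- blk(3L); out[i2, j2, ] <- blk(4L)
  out <- out + rep(b, each = 4L * d[1] * d[2])
  list(out = out, cache = list(xm = xm, W = W, d = d, cout = cout))
}

upconv2_bwd <- function(cache, gy) {
  d <- cache$d; cout <- cache$cout
  i1 <- seq.int(1L, 2L * d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * d[2], 2L); j2 <- j1 + 1L
  n <- d[1] * d[2]
  g4 <- cbind(matrix(gy[i1, j1, , drop = FALSE], n, cout),
              matrix(gy[i2, j1, , drop = FALSE], n, cout),
              matrix(gy[i1, j2, , drop = FALSE], n, cout),
              matrix(gy[i2, j2, , drop = FALSE], n, cout))
  list(gx = array(g4 %*% t(cache$W), d),
       gW = crossprod(cache$xm, g4),
       gb = colSums(matrix(gy, ncol = cout)))
}

# ---- batch normalization (per-channel over spatial positions) -------------

# Training-mode statistics are computed over the h*w positions of the
# sample being processed; exponential running moments serve inference.
bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    rm_new <- momentum * rm + (1 - momentum) * mu
    rv_new <- momentum * rv + (1 - momentum) * v
  } else {
    mu <- rm; v <- rv
    xc <- xm - rep(mu, each = n)
    rm_new <- rm; rv_new <- rv
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = array(y, d), rm = rm_new, rv = rv_new,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                    training = training))
}

bn_bwd <- function(cache, gy) {
  d <- cache$d; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  gxhat <- gym * rep(cache$gamma, each = n)
  if (cache$training) {
    gx <- (gxhat - rep(colMeans(gxhat), each = n) -
             cache$xhat * rep(colMeans(gxhat * cache$xhat), each = n)) *
      rep(cache$istd, each = n)
  } else {
    gx <- gxhat * rep(cache$istd, each = n)
  }
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}
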