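# Convolutional LSTM skip fusion.
#
# A skip connection fuses the encoder feature map with the upsampled
# decoder map by concatenating them channel-wise, splitting the result
# into an n x m grid of patches, and running a convolutional LSTM over
# the patch sequence in raster order; the per-step hidden outputs are
# reassembled into a feature map of the same spatial extent. The gates
# use 2-D convolutions for input and hidden transitions and elementwise
# (Hadamard) peephole weights on the cell state; the output gate peeks
# at the freshly updated cell state.

#' Split a feature map into an n x m patch sequence
#'
#' Tiles an (h, w, c) feature map into a sequence of `n * m` patches of
#' size `(h/n, w/m, c)`. The tiling is lossless: [reassemble_patches()]
#' restores the input exactly. Grid dimensions must divide the spatial
#' dimensions.
#'
#' @param x numeric array (h, w, c); a matrix is treated as single-channel.
#' @param grid integer vector `c(n, m)`: patch rows and columns.
#' @param order scan order mapping grid position (i, j) to sequence step;
#'   only `"row-major"` (j fastest) is currently defined.
#' @return An object of class `patch_sequence`: a list with `patches`
#'   (list of arrays in scan order), `grid`, `order` and the original `dim`.
#' @examples
#' x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
#' ps <- split_to_patches(x, c(2, 2))
#' stopifnot(identical(reassemble_patches(ps), x))
#' @export
split_to_patches <- function(x, grid, order = "row-major") {
  x <- as_hwc(x)
  d <- dim(x)
  n <- as.integer(grid[1]); m <- as.integer(grid[2])
  if (n < 1L || m < 1L) stop("grid dimensions must be positive")
  if (d[1] %% n != 0L || d[2] %% m != 0L) {
    stop(sprintf("grid (%d, %d) does not divide feature map %d x %d",
                 n, m, d[1], d[2]))
  }
  order <- match.arg(order, "row-major")
  hp <- d[1] %/% n; wp <- d[2] %/% m
  patches <- vector("list", n * m)
  t <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      patches[[t]] <- x[((i - 1L) * hp + 1L):(i * hp),
                        ((j - 1L) * wp + 1L):(j * wp), , drop = FALSE]
      t <- t + 1L
    }
  }
  structure(list(patches = patches, grid = c(n, m), order = order, dim = d),
            class = "patch_sequence")
}

#' Reassemble a patch sequence into a feature map
#'
#' Inverse of [split_to_patches()]: places each patch back at its grid
#' position and returns the original (h, w, c) array.
#'
#' @param ps a `patch_sequence`.
#' @return numeric array with the sequence's original dimensions.
#' @export
reassemble_patches <- function(ps) {
  stopifnot(inherits(ps, "patch_sequence"))
  d <- ps$dim
  n <- ps$grid[1]; m <- ps$grid[2]
  dpatch <- dim(ps$patches[[1]])
  hp <- dpatch[1]; wp <- dpatch[2]
  out <- array(0, c(d[1], d[2], dpatch[3]))
  t <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[((i - 1L) * hp + 1L):(i * hp),
          ((j - 1L) * wp + 1L):(j * wp), ] <- ps$patches[[t]]
      t <- t + 1L
    }
  }
  out
}

#' Construct convolutional LSTM parameters
#'
#' Creates the parameter set of one convLSTM unit: 2-D convolution
#' kernels for the input path (`Wx`, input channels -> K per gate) and
#' the hidden path (`Wh`, K -> K per gate), per-gate biases `b`, and
#' elementwise peephole weights `Wci`, `Wcf`, `Wco` with the spatial
#' shape of the state. `Wx` and `Wh` store the four gate kernels as
#' column blocks in (input, forget, candidate, output) order.
#'
#' @param input_channels channels of the patch fed to the unit.
#' @param hidden_channels K, channels of hidden and cell state.
#' @param spatial `c(h_p, w_p)` patch shape (fixes the peephole shape).
#' @param kernel odd convolution kernel size shared by all gate paths.
#' @param init `"he"` for seeded He-scaled Gaussian kernels (forget-gate
#'   bias initialized to 1, peepholes to 0) or `"zero"` for all-zero
#'   parameters.
#' @param seed RNG seed used when `init = "he"`.
#' @return An object of class `convlstm_params`.
#' @export
convlstm_params <- function(input_channels, hidden_channels, spatial,
                            kernel = 3L, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  k <- as.integer(kernel)
  if (k %% 2L != 1L) stop("kernel size must be odd")
  K <- as.integer(hidden_channels)
  cin <- as.integer(input_channels)
  hp <- as.integer(spatial[1]); wp <- as.integer(spatial[2])
  shp <- c(hp, wp, K)
  if (init == "zero") {
    Wx <- matrix(0, k * k * cin, 4L * K)
    Wh <- matrix(0, k * k * K, 4L * K)
    b <- numeric(4L * K)
  } else {
    Wx <- with_seed(seed, matrix(stats::rnorm(k * k * cin * 4L * K,
                                              sd = sqrt(1 / (k * k * cin))),
                                 k * k * cin, 4L * K))
    Wh <- with_seed(seed + 1L, matrix(stats::rnorm(k * k * K * 4L * K,
                                                   sd = sqrt(1 / (k * k * K))),
                                      k * k * K, 4L * K))
    b <- numeric(4L * K)
    b[(K + 1L):(2L * K)] <- 1  # forget gate opens near 1 at start of training
  }
  structure(list(Wx = Wx, Wh = Wh, b = b,
                 Wci = array(0, shp), Wcf = array(0, shp), Wco = array(0, shp),
                 K = K, input_channels = cin, kernel = k, spatial = c(hp, wp)),
            class = "convlstm_params")
}

#' Zero initial convLSTM state
#'
#' @param params a `convlstm_params`.
#' @return list with all-zero `hidden` and `cell` arrays of shape
#'   (h_p, w_p, K).
#' @export
convlstm_zero_state <- function(params) {
  shp <- c(params$spatial, params$K)
  list(hidden = array(0, shp), cell = array(0, shp))
}

.gate_cols <- function(z, K, g) z[, ((g - 1L) * K + 1L):(g * K), drop = FALSE]

#' One convolutional LSTM step
#'
#' Advances the recurrence by one patch: computes input gate
#' `i = sigmoid(Wxi*P + Whi*H + Wci.c + bi)`, forget gate
#' `f = sigmoid(Wxf*P + Whf*H + Wcf.c + bf)`, cell update
#' `c' = f.c + i.tanh(Wxc*P + Whc*H + bc)`, output gate
#' `o = sigmoid(Wxo*P + Who*H + Wco.c' + bo)` (peephole on the new cell
#' state) and hidden output `H' = o.tanh(c')`, where `*` is same-padded
#' 2-D convolution and `.` the Hadamard product.
#'
#' @param p_t input patch (h_p, w_p, input_channels).
#' @param state list with `hidden` and `cell` (h_p, w_p, K) arrays, e.g.
#'   from [convlstm_zero_state()].
#' @param params a `convlstm_params`.
#' @param keep_cache retain intermediates for backpropagation (internal).
#' @return the new state (`hidden`, `cell`), same shapes as the input state.
#' @export
convlstm_step <- function(p_t, state, params, keep_cache = FALSE) {
  p_t <- as_hwc(p_t)
  dp <- dim(p_t)
  if (!all(dim(state$hidden)[1:2] == dp[1:2])) {
    stop("patch spatial shape does not match convLSTM state")
  }
  if (dp[3] != params$input_channels) {
    stop(sprintf("patch has %d channels, parameters expect %d",
                 dp[3], params$input_channels))
  }
  K <- params$K
  colsP <- im2col(p_t, params$kernel)
  colsH <- im2col(state$hidden, params$kernel)
  z <- colsP %*% params$Wx + colsH %*% params$Wh
  z <- z + rep(params$b, each = nrow(z))
  shp <- c(dp[1], dp[2], K)
  zi <- array(.gate_cols(z, K, 1L), shp)
  zf <- array(.gate_cols(z, K, 2L), shp)
  zg <- array(.gate_cols(z, K, 3L), shp)
  zo <- array(.gate_cols(z, K, 4L), shp)
  i_g <- sigmoid(zi + params$Wci * state$cell)
  f_g <- sigmoid(zf + params$Wcf * state$cell)
  g <- tanh(zg)
  c_new <- f_g * state$cell + i_g * g
  o_g <- sigmoid(zo + params$Wco * c_new)
  tanh_c <- tanh(c_new)
  h_new <- o_g * tanh_c
  out <- list(hidden = h_new, cell = c_new)
  if (keep_cache) {
    attr(out, "cache") <- list(colsP = colsP, colsH = colsH,
                               i = i_g, f = f_g, g = g, o = o_g,
                               c_prev = state$cell, c_new = c_new,
                               tanh_c = tanh_c, dp = dp)
  }
  out
}

# Backward pass of one step. gH/gc: gradients flowing into this step's
# hidden/cell outputs. Returns gradients for the patch, the previous
# state, and every parameter block.
convlstm_step_bwd <- function(cache, params, gH, gc_in) {
  K <- params$K
  go_pre <- gH * cache$tanh_c * cache$o * (1 - cache$o)
  gc <- gc_in + gH * cache$o * (1 - cache$tanh_c^2) + go_pre * params$Wco
  gi_pre <- gc * cache$g * cache$i * (1 - cache$i)
  gf_pre <- gc * cache$c_prev * cache$f * (1 - cache$f)
  gg_pre <- gc * cache$i * (1 - cache$g^2)
  gc_prev <- gc * cache$f + gi_pre * params$Wci + gf_pre * params$Wcf
  hw <- cache$dp[1] * cache$dp[2]
  gz <- cbind(matrix(gi_pre, hw, K), matrix(gf_pre, hw, K),
              matrix(gg_pre, hw, K), matrix(go_pre, hw, K))
  list(gP = col2im(gz %*% t(params$Wx), cache$dp[1], cache$dp[2],
                   cache$dp[3], params$kernel),
       gH_prev = col2im(gz %*% t(params$Wh), cache$dp[1], cache$dp[2],
                        K, params$kernel),
       gc_prev = gc_prev,
       gWx = crossprod(cache$colsP, gz),
       gWh = crossprod(cache$colsH, gz),
       gb = colSums(gz),
       gWci = gi_pre * cache$c_prev,
       gWcf = gf_pre * cache$c_prev,
       gWco = go_pre * cache$c_new)
}

#' Fuse encoder and decoder feature maps through a convLSTM
#'
#' Channel-concatenates the encoder skip map with the upsampled decoder
#' map, splits the result into an n x m patch grid, runs the convLSTM
#' over the patches in raster scan order from a zero initial state, and
#' places every step's hidden output back at its grid position. The
#' fused map has the spatial shape of the inputs and K channels.
#'
#' @param x_enc encoder feature map (h, w, c_enc).
#' @param x_dec_up upsampled decoder feature map (h, w, c_dec), same
#'   spatial shape.
#' @param grid `c(n, m)` patch grid; must divide the spatial dimensions.
#' @param params `convlstm_params` with
#'   `input_channels = c_enc + c_dec` and `spatial = c(h/n, w/m)`.
#' @param keep_cache retain intermediates for backpropagation (internal).
#' @return fused feature map (h, w, K).
#' @export
convlstm_fuse <- function(x_enc, x_dec_up, grid, params, keep_cache = FALSE) {
  x <- cbind_channels(as_hwc(x_enc), as_hwc(x_dec_up))
  ps <- split_to_patches(x, grid)
  state <- convlstm_zero_state(params)
  nT <- length(ps$patches)
  hidden <- vector("list", nT)
  caches <- if (keep_cache) vector("list", nT) else NULL
  for (t in seq_len(nT)) {
    state <- convlstm_step(ps$patches[[t]], state, params,
                           keep_cache = keep_cache)
    hidden[[t]] <- state$hidden
    if (keep_cache) caches[[t]] <- attr(state, "cache")
  }
  hs <- structure(list(patches = hidden, grid = ps$grid, order = ps$order,
                       dim = c(ps$dim[1], ps$dim[2], params$K)),
                  class = "patch_sequence")
  out <- reassemble_patches(hs)
  if (keep_cache) {
    attr(out, "cache") <- list(steps = caches, grid = ps$grid,
                               dim_in = ps$dim,
                               c_enc = dim(as_hwc(x_enc))[3])
  }
  out
}

# Backward pass through the fused skip: BPTT over the patch sequence in
# reverse scan order. Returns gradients w.r.t. both input maps and the
# accumulated parameter gradients.
convlstm_fuse_bwd <- function(cache, params, gy) {
  gps <- split_to_patches(gy, cache$grid)
  nT <- length(gps$patches)
  K <- params$K
  gWx <- matrix(0, nrow(params$Wx), ncol(params$Wx))
  gWh <- matrix(0, nrow(params$Wh), ncol(params$Wh))
  gb <- numeric(length(params$b))
  gWci <- array(0, dim(params$Wci)); gWcf <- gWci; gWco <- gWci
  gH_carry <- array(0, c(params$spatial, K))
  gc_carry <- gH_carry
  gpatches <- vector("list", nT)
  for (t in rev(seq_len(nT))) {
    res <- convlstm_step_bwd(cache$steps[[t]], params,
                             gps$patches[[t]] + gH_carry, gc_carry)
    gpatches[[t]] <- res$gP
    gH_carry <- res$gH_prev
    gc_carry <- res$gc_prev
    gWx <- gWx + res$gWx; gWh <- gWh + res$gWh; gb <- gb + res$gb
    gWci <- gWci + res$gWci; gWcf <- gWcf + res$gWcf; gWco <- gWco + res$gWco
  }
  gx <- reassemble_patches(structure(
    list(patches = gpatches, grid = cache$grid, order = "row-major",
         dim = cache$dim_in), class = "patch_sequence"))
  ce <- cache$c_enc
  list(g_enc = gx[, , seq_len(ce), drop = FALSE],
       g_dec = gx[, , (ce + 1L):dim(gx)[3], drop = FALSE],
       gWx = gWx, gWh = gWh, gb = gb,
       gWci = gWci, gWcf = gWcf, gWco = gWco)
}
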