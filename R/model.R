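# AKU-Net: U-Net encoder-decoder with convLSTM-fused skip connections.
#
# The encoder follows the first four VGG16 convolution blocks (3x3
# convolutions + ReLU, 2x2 max pooling between blocks, channel widths
# doubling from `base_filters`). The decoder upsamples with stride-2
# transposed convolutions; each skip connection is fused through a
# convolutional LSTM (or plain concatenation for the baseline U-Net),
# and every decoder convolution is followed by batch normalization and
# ReLU. A 1x1 convolution with a sigmoid yields per-pixel foreground
# probabilities.

#' Model configuration
#'
#' Describes the architecture: input side, encoder widths, the convLSTM
#' patch grid and hidden channels per skip level, and whether skips are
#' fused by convLSTM or plain concatenation (the baseline U-Net).
#'
#' @param input_side square input side in pixels; must be divisible by
#'   `2^(encoder_blocks - 1)` and, at every skip level `l`, by
#'   `grid * 2^(l-1)`.
#' @param base_filters channels of the first encoder block; block `l`
#'   uses `base_filters * 2^(l-1)` (64 gives the VGG16 widths
#'   64/128/256/512).
#' @param encoder_blocks number of encoder blocks (4, the VGG16 transfer
#'   scheme).
#' @param convs_per_block convolutions per encoder block; the default
#'   `c(2, 2, 3, 3)` mirrors the first four VGG16 blocks.
#' @param convlstm_grid `c(n, m)` patch grid of the skip fusion.
#' @param convlstm_kernel gate convolution kernel size (odd).
#' @param convlstm_hidden hidden channels K per skip level (levels
#'   1..encoder_blocks-1); default is half the concatenated skip
#'   channels, i.e. the encoder width at that level.
#' @param skip_fusion `"convlstm"` (AKU-Net) or `"concat"` (baseline
#'   U-Net with identical encoder/decoder).
#' @param bn_decoder apply batch normalization after decoder convolutions.
#' @param pretrained_encoder initialize the encoder from locally stored
#'   VGG16 weights when `pretrained_weights` names a readable RDS file;
#'   otherwise seeded random initialization is used (never a download).
#' @param pretrained_weights optional path to an RDS file holding encoder
#'   kernels in the layout produced by [build_encoder()].
#' @param threshold probability cut used when binarizing predictions.
#' @param seed seed for weight initialization.
#' @return object of class `aku_config`.
#' @export
aku_model_config <- function(input_side = 256L, base_filters = 64L,
                             encoder_blocks = 4L,
                             convs_per_block = c(2L, 2L, 3L, 3L),
                             convlstm_grid = c(4L, 4L),
                             convlstm_kernel = 3L,
                             convlstm_hidden = NULL,
                             skip_fusion = c("convlstm", "concat"),
                             bn_decoder = TRUE,
                             pretrained_encoder = FALSE,
                             pretrained_weights = NULL,
                             threshold = 0.5,
                             seed = 1L) {
  skip_fusion <- match.arg(skip_fusion)
  input_side <- as.integer(input_side)
  encoder_blocks <- as.integer(encoder_blocks)
  if (encoder_blocks < 2L) stop("need at least two encoder blocks")
  if (length(convs_per_block) == 1L) {
    convs_per_block <- rep(as.integer(convs_per_block), encoder_blocks)
  }
  if (length(convs_per_block) != encoder_blocks) {
    stop("convs_per_block must have one entry per encoder block")
  }
  # three 2x2 poolings between four blocks: every pooled side must be even
  side <- input_side
  for (l in seq_len(encoder_blocks - 1L)) {
    if (side %% 2L != 0L) {
      stop(sprintf(paste0("configuration error: input_side %d is not ",
                          "divisible at encoder level %d (side %d is odd)"),
                   input_side, l + 1L, side))
    }
    side <- side %/% 2L
  }
  grid <- as.integer(convlstm_grid)
  if (length(grid) != 2L || any(grid < 1L)) stop("convlstm_grid must be c(n, m)")
  ch <- as.integer(base_filters) * 2L^(seq_len(encoder_blocks) - 1L)
  if (is.null(convlstm_hidden)) convlstm_hidden <- ch[seq_len(encoder_blocks - 1L)]
  convlstm_hidden <- as.integer(convlstm_hidden)
  if (length(convlstm_hidden) != encoder_blocks - 1L) {
    stop("convlstm_hidden must have one entry per skip level")
  }
  if (skip_fusion == "convlstm") {
    for (l in seq_len(encoder_blocks - 1L)) {
      hl <- input_side %/% 2L^(l - 1L)
      if (hl %% grid[1] != 0L || hl %% grid[2] != 0L) {
        stop(sprintf(paste0("configuration error: convLSTM grid (%d, %d) does ",
                            "not divide the %dx%d feature map at skip level %d"),
                     grid[1], grid[2], hl, hl, l))
      }
    }
  }
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(list(input_side = input_side,
                 base_filters = as.integer(base_filters),
                 encoder_blocks = encoder_blocks,
                 convs_per_block = as.integer(convs_per_block),
                 channels = ch,
                 convlstm_grid = grid,
                 convlstm_kernel = as.integer(convlstm_kernel),
                 convlstm_hidden = convlstm_hidden,
                 skip_fusion = skip_fusion,
                 bn_decoder = isTRUE(bn_decoder),
                 pretrained_encoder = isTRUE(pretrained_encoder),
                 pretrained_weights = pretrained_weights,
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "aku_config")
}

.he_mat <- function(nr, nc, fan_in, seed) {
  with_seed(seed, matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc))
}

#' Build the VGG16-style encoder
#'
#' Creates the encoder parameters: four convolution blocks producing
#' skip outputs at full, 1/2, 1/4 and 1/8 resolution with widths
#' `base_filters * 2^(l-1)`. If `pretrained_encoder` is set and
#' `pretrained_weights` points to a readable RDS file, the kernels are
#' loaded from it; otherwise they are seeded He-initialized (tests never
#' require a download).
#'
#' @param config an [aku_model_config()].
#' @return object of class `aku_encoder` holding the per-block
#'   convolution parameters; run it with [encoder_forward()].
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "aku_config"))
  L <- config$encoder_blocks
  blocks <- vector("list", L)
  s <- config$seed
  for (l in seq_len(L)) {
    ncv <- config$convs_per_block[l]
    layers <- vector("list", ncv)
    for (j in seq_len(ncv)) {
      cin <- if (l == 1L && j == 1L) 3L else if (j == 1L) config$channels[l - 1L] else config$channels[l]
      cout <- config$channels[l]
      layers[[j]] <- list(W = .he_mat(9L * cin, cout, 9L * cin, s), b = numeric(cout))
      s <- s + 1L
    }
    blocks[[l]] <- layers
  }
  if (config$pretrained_encoder && !is.null(config$pretrained_weights) &&
      file.exists(config$pretrained_weights)) {
    loaded <- readRDS(config$pretrained_weights)
    for (l in seq_along(blocks)) {
      for (j in seq_along(blocks[[l]])) {
        cand <- loaded[[l]][[j]]
        if (!is.null(cand) && all(dim(cand$W) == dim(blocks[[l]][[j]]$W))) {
          blocks[[l]][[j]] <- cand
        }
      }
    }
  }
  structure(list(blocks = blocks, config = config), class = "aku_encoder")
}

#' Run the encoder, returning all skip feature maps
#'
#' @param encoder an `aku_encoder` or `aku_model`.
#' @param x input image array (input_side, input_side, 3), values in
#'   `[0, 1]`.
#' @return list of `encoder_blocks` feature maps, level `l` at
#'   `input_side / 2^(l-1)` resolution.
#' @export
encoder_forward <- function(encoder, x) {
  blocks <- if (inherits(encoder, "aku_model")) encoder$params$enc else encoder$blocks
  cur <- as_hwc(x)
  skips <- vector("list", length(blocks))
  for (l in seq_along(blocks)) {
    for (j in seq_along(blocks[[l]])) {
      cur <- relu_fwd(conv2d_fwd(cur, blocks[[l]][[j]]$W, blocks[[l]][[j]]$b)$out)$out
    }
    skips[[l]] <- cur
    if (l < length(blocks)) cur <- maxpool2_fwd(cur)$out
  }
  skips
}

# convlstm_params view over a decoder level's trainable leaves
.clp_view <- function(model, l) {
  cfg <- model$config
  p <- model$params$dec[[l]]$clstm
  hl <- cfg$input_side %/% 2L^(l - 1L)
  structure(list(Wx = p$Wx, Wh = p$Wh, b = p$b,
                 Wci = p$Wci, Wcf = p$Wcf, Wco = p$Wco,
                 K = cfg$convlstm_hidden[l],
                 input_channels = 2L * cfg$channels[l],
                 kernel = cfg$convlstm_kernel,
                 spatial = c(hl %/% cfg$convlstm_grid[1],
                             hl %/% cfg$convlstm_grid[2])),
            class = "convlstm_params")
}

#' Build the segmentation network
#'
#' Assembles the full model: VGG16-style encoder, transposed-convolution
#' upsampling, convLSTM skip fusion (or plain concatenation when
#' `skip_fusion = "concat"`), batch-normalized decoder convolutions and
#' a sigmoid 1x1 head mapping (S, S, 3) images to (S, S) foreground
#' probabilities.
#'
#' @param config an [aku_model_config()].
#' @return object of class `aku_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "aku_config"))
  L <- config$encoder_blocks
  ch <- config$channels
  enc <- build_encoder(config)$blocks
  dec <- vector("list", L - 1L)
  bn <- list(dec = vector("list", L - 1L))
  s <- config$seed + 1000L
  for (l in seq_len(L - 1L)) {
    lev <- list()
    # upsample ch[l+1] -> ch[l]
    lev$up <- list(W = .he_mat(ch[l + 1L], 4L * ch[l], ch[l + 1L], s),
                   b = numeric(ch[l]))
    s <- s + 1L
    bnlev <- list()
    if (config$bn_decoder) {
      bnlev$up <- list(rm = numeric(ch[l]), rv = rep(1, ch[l]))
      lev$up_bn <- list(gamma = rep(1, ch[l]), beta = numeric(ch[l]))
    }
    if (config$skip_fusion == "convlstm") {
      hl <- config$input_side %/% 2L^(l - 1L)
      cp <- convlstm_params(2L * ch[l], config$convlstm_hidden[l],
                            spatial = c(hl %/% config$convlstm_grid[1],
                                        hl %/% config$convlstm_grid[2]),
                            kernel = config$convlstm_kernel, seed = s)
      s <- s + 2L
      lev$clstm <- list(Wx = cp$Wx, Wh = cp$Wh, b = cp$b,
                        Wci = cp$Wci, Wcf = cp$Wcf, Wco = cp$Wco)
      cin1 <- config$convlstm_hidden[l]
    } else {
      cin1 <- 2L * ch[l]
    }
    lev$conv1 <- list(W = .he_mat(9L * cin1, ch[l], 9L * cin1, s), b = numeric(ch[l]))
    s <- s + 1L
    lev$conv2 <- list(W = .he_mat(9L * ch[l], ch[l], 9L * ch[l], s), b = numeric(ch[l]))
    s <- s + 1L
    if (config$bn_decoder) {
      lev$bn1 <- list(gamma = rep(1, ch[l]), beta = numeric(ch[l]))
      lev$bn2 <- list(gamma = rep(1, ch[l]), beta = numeric(ch[l]))
      bnlev$bn1 <- list(rm = numeric(ch[l]), rv = rep(1, ch[l]))
      bnlev$bn2 <- list(rm = numeric(ch[l]), rv = rep(1, ch[l]))
    }
    dec[[l]] <- lev
    bn$dec[[l]] <- bnlev
  }
  head <- list(W = .he_mat(ch[1], 1L, ch[1], s), b = numeric(1))
  structure(list(config = config,
                 params = list(enc = enc, dec = dec, head = head),
                 bn = bn),
            class = "aku_model")
}

# Full forward pass. Returns prob (h, w) matrix, optionally the cache
# needed by model_backward, and updated BN running moments.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  P <- model$params
  B <- model$bn
  L <- cfg$encoder_blocks
  x <- as_hwc(x)
  if (!all(dim(x)[1:2] == cfg$input_side) || dim(x)[3] != 3L) {
    stop(sprintf("model expects a (%d, %d, 3) input", cfg$input_side, cfg$input_side))
  }
  cache <- list(enc = vector("list", L), pool = vector("list", L - 1L),
                dec = vector("list", L - 1L))
  skips <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    ncv <- cfg$convs_per_block[l]
    cc <- vector("list", ncv)
    for (j in seq_len(ncv)) {
      cf <- conv2d_fwd(cur, P$enc[[l]][[j]]$W, P$enc[[l]][[j]]$b)
      rf <- relu_fwd(cf$out)
      cur <- rf$out
      if (keep_cache) cc[[j]] <- list(conv = cf$cache, relu = rf$cache)
    }
    skips[[l]] <- cur
    if (keep_cache) cache$enc[[l]] <- cc
    if (l < L) {
      pf <- maxpool2_fwd(cur)
      cur <- pf$out
      if (keep_cache) cache$pool[[l]] <- pf$cache
    }
  }
  run_bn <- function(xin, bnpar, bnstate, tag, lc) {
    bf <- bn_fwd(xin, bnpar$gamma, bnpar$beta, bnstate$rm, bnstate$rv, training)
    list(out = bf$out, state = list(rm = bf$rm, rv = bf$rv), cache = bf$cache)
  }
  for (l in seq.int(L - 1L, 1L)) {
    lev <- P$dec[[l]]
    dcc <- list()
    uf <- upconv2_fwd(cur, lev$up$W, lev$up$b)
    cur <- uf$out
    if (keep_cache) dcc$up <- uf$cache
    if (cfg$bn_decoder) {
      bf <- run_bn(cur, lev$up_bn, B$dec[[l]]$up)
      cur <- bf$out
      B$dec[[l]]$up <- bf$state
      if (keep_cache) dcc$up_bn <- bf$cache
    }
    rf <- relu_fwd(cur)
    cur <- rf$out
    if (keep_cache) dcc$up_relu <- rf$cache
    if (cfg$skip_fusion == "convlstm") {
      fused <- convlstm_fuse(skips[[l]], cur, cfg$convlstm_grid,
                             .clp_view(model, l), keep_cache = keep_cache)
      if (keep_cache) {
        dcc$fuse <- attr(fused, "cache")
        attr(fused, "cache") <- NULL
      }
      cur <- fused
    } else {
      cur <- cbind_channels(skips[[l]], cur)
    }
    for (cv in c("conv1", "conv2")) {
      cf <- conv2d_fwd(cur, lev[[cv]]$W, lev[[cv]]$b)
      cur <- cf$out
      if (keep_cache) dcc[[cv]] <- cf$cache
      if (cfg$bn_decoder) {
        bnm <- sub("conv", "bn", cv)
        bf <- run_bn(cur, lev[[bnm]], B$dec[[l]][[bnm]])
        cur <- bf$out
        B$dec[[l]][[bnm]] <- bf$state
        if (keep_cache) dcc[[paste0(bnm, "_c")]] <- bf$cache
      }
      rf <- relu_fwd(cur)
      cur <- rf$out
      if (keep_cache) dcc[[paste0(cv, "_relu")]] <- rf$cache
    }
    cache$dec[[l]] <- dcc
  }
  hf <- conv2d_fwd(cur, P$head$W, P$head$b)
  prob <- sigmoid(hf$out[, , 1])
  if (keep_cache) cache$head <- hf$cache
  list(prob = prob, cache = if (keep_cache) cache else NULL, bn = B)
}

# Backward pass from dL/dlogits (h, w) to a gradient structure mirroring
# model$params.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  P <- model$params
  L <- cfg$encoder_blocks
  G <- list(enc = vector("list", L), dec = vector("list", L - 1L), head = NULL)
  hb <- conv2d_bwd(cache$head, array(dlogits, c(dim(dlogits), 1L)))
  G$head <- list(W = hb$gW, b = hb$gb)
  g <- hb$gx
  gskip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    lev <- P$dec[[l]]
    dcc <- cache$dec[[l]]
    gl <- list()
    for (cv in c("conv2", "conv1")) {
      g <- relu_bwd(dcc[[paste0(cv, "_relu")]], g)
      if (cfg$bn_decoder) {
        bnm <- sub("conv", "bn", cv)
        bb <- bn_bwd(dcc[[paste0(bnm, "_c")]], g)
        gl[[bnm]] <- list(gamma = bb$ggamma, beta = bb$gbeta)
        g <- bb$gx
      }
      cb <- conv2d_bwd(dcc[[cv]], g)
      gl[[cv]] <- list(W = cb$gW, b = cb$gb)
      g <- cb$gx
    }
    if (cfg$skip_fusion == "convlstm") {
      fb <- convlstm_fuse_bwd(dcc$fuse, .clp_view(model, l), g)
      gl$clstm <- list(Wx = fb$gWx, Wh = fb$gWh, b = fb$gb,
                       Wci = fb$gWci, Wcf = fb$gWcf, Wco = fb$gWco)
      gskip[[l]] <- fb$g_enc
      g <- fb$g_dec
    } else {
      ce <- cfg$channels[l]
      gskip[[l]] <- g[, , seq_len(ce), drop = FALSE]
      g <- g[, , (ce + 1L):dim(g)[3], drop = FALSE]
    }
    g <- relu_bwd(dcc$up_relu, g)
    if (cfg$bn_decoder) {
      bb <- bn_bwd(dcc$up_bn, g)
      gl$up_bn <- list(gamma = bb$ggamma, beta = bb$gbeta)
      g <- bb$gx
    }
    ub <- upconv2_bwd(dcc$up, g)
    gl$up <- list(W = ub$gW, b = ub$gb)
    g <- ub$gx
    G$dec[[l]] <- gl
    if (l < L - 1L) {
      # grad flowing into the next-deeper decoder input: handled by loop
    }
  }
  # g now holds the gradient at skips[[L]] (the bridge)
  gskip[[L]] <- g
  gcur <- gskip[[L]]
  for (l in seq.int(L, 1L)) {
    if (l < L) {
      gcur <- maxpool2_bwd(cache$pool[[l]], gcur) + gskip[[l]]
    }
    ncv <- cfg$convs_per_block[l]
    gl <- vector("list", ncv)
    for (j in seq.int(ncv, 1L)) {
      cc <- cache$enc[[l]][[j]]
      gcur <- relu_bwd(cc$relu, gcur)
      cb <- conv2d_bwd(cc$conv, gcur)
      gl[[j]] <- list(W = cb$gW, b = cb$gb)
      gcur <- cb$gx
    }
    G$enc[[l]] <- gl
  }
  G
}

#' Predict foreground probabilities for one model-sized image
#'
#' @param object an `aku_model`.
#' @param image `(input_side, input_side, 3)` array in `[0, 1]`.
#' @param type `"prob"` for the probability map, `"mask"` for the map
#'   binarized at the configured threshold.
#' @param ... unused.
#' @return numeric (prob) or integer 0/1 (mask) matrix of the input size.
#' @export
predict.aku_model <- function(object, image, type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  prob <- model_forward(object, image, training = FALSE)$prob
  if (type == "prob") prob else binarize_prob(prob, object$config$threshold)
}

#' Binarize a probability map
#'
#' @param prob numeric matrix of probabilities in `[0, 1]`.
#' @param threshold cut in `[0, 1]`; pixels with `prob > threshold`
#'   become foreground.
#' @return integer 0/1 matrix.
#' @export
binarize_prob <- function(prob, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  m <- (prob > threshold) * 1L
  dim(m) <- dim(prob)
  m
}

#' Number of trainable parameters, by component
#'
#' @param model an `aku_model`.
#' @return named numeric vector with per-component and total counts; the
#'   `recurrent` entry counts convLSTM weights (0 for the concat baseline).
#' @export
count_params <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  rec <- sum(vapply(model$params$dec, function(lev) {
    if (is.null(lev$clstm)) 0 else cnt(lev$clstm)
  }, numeric(1)))
  tot <- cnt(model$params)
  c(total = tot, recurrent = rec, feedforward = tot - rec)
}

#' Save / load model weights
#'
#' Weights (and BN running moments) are serialized as RDS, the
#' configuration as YAML, in `dir`.
#'
#' @param model an `aku_model`.
#' @param dir output directory (created if needed).
#' @return `save_model`: `dir`, invisibly. `load_model`: the restored
#'   `aku_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(params = model$params, bn = model$bn),
          file.path(dir, "weights.rds"))
  cfg <- model$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "model_config.yaml"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgl <- yaml::yaml.load_file(file.path(dir, "model_config.yaml"))
  cfg <- aku_model_config(
    input_side = cfgl$input_side, base_filters = cfgl$base_filters,
    encoder_blocks = cfgl$encoder_blocks,
    convs_per_block = cfgl$convs_per_block,
    convlstm_grid = cfgl$convlstm_grid,
    convlstm_kernel = cfgl$convlstm_kernel,
    convlstm_hidden = cfgl$convlstm_hidden,
    skip_fusion = cfgl$skip_fusion, bn_decoder = cfgl$bn_decoder,
    threshold = cfgl$threshold, seed = cfgl$seed)
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(config = cfg, params = w$params, bn = w$bn),
            class = "aku_model")
}
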