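# Independent oracles used to validate the implementation. These are
# deliberately naive (explicit loops, fixpoint iteration) and share no
# code with the package's computational paths.

# Naive same-padded convolution: quadruple loop over output positions,
# kernel offsets and channels, using the package's weight-matrix layout
# (offset blocks column-major di-fast, channels within block).
conv_same_oracle <- function(x, W, outch_total) {
  d <- dim(x)
  k <- as.integer(round(sqrt(nrow(W) / d[3])))
  pad <- (k - 1L) %/% 2L
  out <- array(0, c(d[1], d[2], outch_total))
  for (oc in seq_len(outch_total)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- 0
      for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) for (ch in seq_len(d[3])) {
        ii <- i + di - pad; jj <- j + dj - pad
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
          acc <- acc + x[ii, jj, ch] * W[(dj * k + di) * d[3] + ch, oc]
        }
      }
      out[i, j, oc] <- acc
    }
  }
  out
}

# Literal transcription of the convLSTM recurrence: input gate
# i = sigma(Wxi*P + Whi*H + Wci.c + bi), forget gate with Wcf.c, cell
# c' = f.c + i.tanh(Wxc*P + Whc*H + bc), output gate peeking at the NEW
# cell state, H' = o.tanh(c').
oracle_convlstm_step <- function(p_t, state, params) {
  K <- params$K
  zx <- conv_same_oracle(p_t, params$Wx, 4L * K)
  zh <- conv_same_oracle(state$hidden, params$Wh, 4L * K)
  z <- zx + zh
  for (g in seq_len(4L * K)) z[, , g] <- z[, , g] + params$b[g]
  sg <- function(v) 1 / (1 + exp(-v))
  gi <- z[, , 1:K, drop = FALSE]
  gf <- z[, , (K + 1L):(2L * K), drop = FALSE]
  gg <- z[, , (2L * K + 1L):(3L * K), drop = FALSE]
  go <- z[, , (3L * K + 1L):(4L * K), drop = FALSE]
  i_t <- sg(gi + params$Wci * state$cell)
  f_t <- sg(gf + params$Wcf * state$cell)
  c_t <- f_t * state$cell + i_t * tanh(gg)
  o_t <- sg(go + params$Wco * c_t)
  list(hidden = o_t * tanh(c_t), cell = c_t)
}

# Connected-component labeling by label propagation to a fixpoint:
# every foreground pixel starts with a unique id and repeatedly adopts
# the minimum id in its neighborhood. Independent of the package's
# frontier flood fill.
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask == 1] <- seq_len(sum(mask == 1))
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (mask[i, j] != 1) next
      best <- lab[i, j]
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs[r, 1]; jj <- j + offs[r, 2]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj] == 1) {
          best <- min(best, lab[ii, jj])
        }
      }
      if (best < lab[i, j]) { lab[i, j] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

# Brute-force pixel/region scoring: explicit loops over pixels for
# TP/FP/FN and over regions for the intersection counts.
oracle_scores <- function(pred, gt, connectivity = 8) {
  h <- nrow(gt); w <- ncol(gt)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
    if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
    if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1
  }
  lab <- oracle_label(gt, connectivity)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  tpc <- 0L
  for (id in ids) {
    hit <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (lab[i, j] == id && pred[i, j] == 1) hit <- TRUE
    }
    if (hit) tpc <- tpc + 1L
  }
  n <- length(ids)
  dice <- if (2 * tp + fn + fp == 0) 1 else 2 * tp / (2 * tp + fn + fp)
  iou <- if (tp + fn + fp == 0) 1 else tp / (tp + fn + fp)
  arec <- if (n > 0) tpc / n else NA_real_
  aprec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  list(dice = dice, iou = iou, tpc = tpc, n = n, arec = arec, aprec = aprec)
}

# Blobby random binary mask: thresholded smoothed noise (plus a chance
# of being empty or full to exercise edge conventions).
random_blob_mask <- function(h, w, p_fg = 0.3) {
  z <- matrix(stats::rnorm(h * w), h, w)
  k <- matrix(1 / 9, 3, 3)
  zs <- z
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    zs[i, j] <- sum(z[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
  }
  (zs > stats::quantile(zs, 1 - p_fg)) * 1L
}
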