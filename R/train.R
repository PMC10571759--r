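# Training: pixel-averaged binary cross-entropy, AdamW optimization,
# seeded shuffled mini-batches with per-epoch validation and
# best-validation-Dice model selection.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight decay applied to convolution
#'   kernels (not biases or normalization parameters).
#' @param batch_size mini-batch size.
#' @param epochs full passes over the training crops ("iterations" in the
#'   sense of training epochs; 100 gradient steps could not traverse a
#'   16k-crop training pool at batch 32).
#' @param seed RNG seed controlling shuffling.
#' @param select model selection rule: `"best_val_dice"` keeps the
#'   weights of the epoch with the highest validation Dice, `"last"`
#'   the final weights.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 1e-6,
                         batch_size = 32L, epochs = 100L, seed = 1L,
                         select = c("best_val_dice", "last")) {
  select <- match.arg(select)
  if (learning_rate < 0 || weight_decay < 0) stop("rates must be nonnegative")
  if (batch_size < 1L || epochs < 1L) stop("batch_size and epochs must be positive")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 select = select),
            class = "train_config")
}

#' Pixel-averaged binary cross-entropy
#'
#' `L(p, y) = -y log p - (1 - y) log(1 - p)`, averaged over all pixels.
#' Predictions are clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param pred_prob numeric array of foreground probabilities.
#' @param gt 0/1 ground-truth array of the same shape.
#' @param eps clipping constant.
#' @return mean per-pixel loss (a single number).
#' @export
bce_loss <- function(pred_prob, gt, eps = 1e-7) {
  dp <- dim(pred_prob) %||% length(pred_prob)
  dg <- dim(gt) %||% length(gt)
  if (!identical(as.integer(dp), as.integer(dg))) {
    stop("prediction and ground truth shapes differ")
  }
  p <- pmin(pmax(pred_prob, eps), 1 - eps)
  mean(-gt * log(p) - (1 - gt) * log(1 - p))
}

# ---- nested parameter-list arithmetic -------------------------------------

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

acc_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

# ---- AdamW ----------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0), how = "replace")
}

# decoupled weight decay applies to kernels only
.decay_leaf <- function(name) name %in% c("W", "Wx", "Wh")

adam_update <- function(params, grads, state, t, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !all(c("m", "v") %in% names(s))) {
      nms <- names(p) %||% rep("", length(p))
      for (i in seq_along(p)) {
        gi <- if (nzchar(nms[i]) && !is.null(names(g))) g[[nms[i]]] else g[[i]]
        r <- walk(p[[i]], gi, s[[i]])
        p[[i]] <- r$p; s[[i]] <- r$s
        if (.decay_leaf(nms[i]) && is.numeric(p[[i]])) {
          p[[i]] <- p[[i]] - lr * wd * p[[i]]
        }
      }
      list(p = p, s = s)
    } else {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
    }
  }
  walk(params, grads, state)
}

# ---- Dice on binarized prediction (training diagnostics) -------------------

.val_dice <- function(model, crops) {
  ds <- vapply(crops, function(cr) {
    pr <- model_forward(model, cr$image, training = FALSE)$prob
    dice_coef(binarize_prob(pr, model$config$threshold), cr$mask)
  }, numeric(1))
  mean(ds)
}

#' Train the segmentation network
#'
#' Seeded, shuffled mini-batch training with pixel-averaged binary
#' cross-entropy and AdamW (`learning_rate = 0.001`,
#' `weight_decay = 1e-6` by default). Per-epoch training loss,
#' validation loss and validation Dice are logged; with
#' `select = "best_val_dice"` the weights of the best validation epoch
#' are restored at the end.
#'
#' @param model an `aku_model` from [build_model()].
#' @param train_crops list of crops, each `list(image = (S, S, 3) array,
#'   mask = (S, S) 0/1 matrix)`; optionally a `patient_id` element.
#' @param val_crops held-out crops in the same format, or `NULL`.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return the trained model, with a `history` data.frame attached
#'   (`model$history`: epoch, train_loss, val_loss, val_dice).
#' @export
fit_akunet <- function(model, train_crops, val_crops = NULL,
                       config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "aku_model"), inherits(config, "train_config"))
  if (length(train_crops) == 0L) stop("no training crops supplied")
  # patient-level leakage guard when provenance is recorded on the crops
  tp <- unique(unlist(lapply(train_crops, `[[`, "patient_id")))
  vp <- unique(unlist(lapply(val_crops, `[[`, "patient_id")))
  if (length(tp) && length(vp) && length(intersect(tp, vp))) {
    stop("train and validation crops share patients: ",
         paste(intersect(tp, vp), collapse = ", "))
  }
  npix <- model$config$input_side^2
  opt <- adam_init(model$params)
  t_step <- 0L
  n <- length(train_crops)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dice = numeric())
  best <- list(dice = -Inf, params = NULL, bn = NULL)
  for (epoch in seq_len(config$epochs)) {
    idx <- with_seed(config$seed * 10000L + epoch, sample.int(n))
    ep_losses <- numeric(0)
    for (start in seq.int(1L, n, by = config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (i in bidx) {
        cr <- train_crops[[i]]
        fw <- model_forward(model, cr$image, training = TRUE, keep_cache = TRUE)
        model$bn <- fw$bn
        p <- fw$prob
        loss <- bce_loss(p, cr$mask)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (sample %d); aborting",
                       epoch, i))
        }
        bloss <- bloss + loss
        # d(BCE)/d(logit) with the sigmoid folded in, averaged over pixels
        dlogits <- (p - cr$mask) / npix / length(bidx)
        g <- model_backward(model, fw$cache, dlogits)
        grads <- if (is.null(grads)) g else acc_grads(grads, g)
      }
      ep_losses <- c(ep_losses, bloss / length(bidx))
      t_step <- t_step + 1L
      upd <- adam_update(model$params, grads, opt, t_step,
                         lr = config$learning_rate, wd = config$weight_decay)
      model$params <- upd$p
      opt <- upd$s
    }
    vl <- NA_real_; vd <- NA_real_
    if (length(val_crops)) {
      vl <- mean(vapply(val_crops, function(cr) {
        bce_loss(model_forward(model, cr$image, training = FALSE)$prob, cr$mask)
      }, numeric(1)))
      vd <- .val_dice(model, val_crops)
      if (config$select == "best_val_dice" && vd > best$dice) {
        best <- list(dice = vd, params = model$params, bn = model$bn)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(ep_losses), val_loss = vl, val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f dice %.3f",
                      epoch, mean(ep_losses), vl, vd))
    }
  }
  if (config$select == "best_val_dice" && !is.null(best$params)) {
    model$params <- best$params
    model$bn <- best$bn
  }
  model$history <- history
  model
}
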