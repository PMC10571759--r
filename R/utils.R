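# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards so library calls never
# perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 3-D (h, w, c) array coercion: promote a matrix to a single-channel array.
as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# Channel concatenation of two (h, w, c) arrays.
cbind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:2] == db[1:2])) {
    stop("channel concatenation requires matching spatial shapes: ",
         paste(da[1:2], collapse = "x"), " vs ", paste(db[1:2], collapse = "x"))
  }
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# Luminance of an (h, w, 3) RGB array (Rec. 601 weights).
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
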