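# Weight initialization and thin R-side wrappers over the compiled engine.
#
# Weights live in named R lists of double arrays in a fixed order; the engine
# reinterprets their column-major memory directly, so order and dims matter.

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

conv_init <- function(k, cin, cout) {
  list(w = glorot(c(k, k, cin, cout), k * k * cin, k * k * cout),
       b = numeric(cout))
}

dense_init <- function(nin, nout) {
  list(w = glorot(c(nin, nout), nin, nout), b = numeric(nout))
}

encoder_init_weights <- function() {
  ch <- c(1, 16, 32, 64, 128)
  w <- list()
  for (i in 1:4) {
    a <- conv_init(3, ch[i], ch[i + 1]); b <- conv_init(3, ch[i + 1], ch[i + 1])
    w[[paste0("conv", i, "a_w")]] <- a$w; w[[paste0("conv", i, "a_b")]] <- a$b
    w[[paste0("conv", i, "b_w")]] <- b$w; w[[paste0("conv", i, "b_b")]] <- b$b
  }
  dd <- c(2048, 128, 64, 32, 1)
  for (i in 1:4) {
    d <- dense_init(dd[i], dd[i + 1])
    w[[paste0("dense", i, "_w")]] <- d$w; w[[paste0("dense", i, "_b")]] <- d$b
  }
  w
}

unet_init_weights <- function() {
  w <- list()
  add_conv <- function(w, nm, k, cin, cout) {
    p <- conv_init(k, cin, cout)
    w[[paste0(nm, "_w")]] <- p$w; w[[paste0(nm, "_b")]] <- p$b
    w
  }
  add_tconv <- function(w, nm, cin, cout) {
    # 2x2 stride-2 transpose conv; fans follow the 2x2 kernel
    w[[paste0(nm, "_w")]] <- glorot(c(2, 2, cin, cout), 4 * cin, 4 * cout)
    w[[paste0(nm, "_b")]] <- numeric(cout)
    w
  }
  w <- add_conv(w, "enc1a", 3, 1, 16);  w <- add_conv(w, "enc1b", 3, 16, 16)
  w <- add_conv(w, "enc2a", 3, 16, 32); w <- add_conv(w, "enc2b", 3, 32, 32)
  w <- add_conv(w, "bott_a", 3, 32, 64); w <- add_conv(w, "bott_b", 3, 64, 64)
  w <- add_tconv(w, "up1", 64, 32)
  w <- add_conv(w, "dec1a", 3, 64, 32); w <- add_conv(w, "dec1b", 3, 32, 32)
  w <- add_tconv(w, "up2", 32, 16)
  w <- add_conv(w, "dec2a", 3, 32, 16); w <- add_conv(w, "dec2b", 3, 16, 16)
  w <- add_conv(w, "out", 1, 16, 1)
  # Head bias starts at the background-prior logit instead of 0. Lesion
  # pixels are a tiny minority of every tile, and a sigmoid head that opens
  # at p = 0.5 makes the first Dice-loss steps slam every activation
  # downward hard enough to kill the ReLU stack outright; starting near the
  # background rate removes that transient.
  w$out_b <- -4
  w
}

#' Count trainable parameters of a model
#'
#' @param model An object of class `rpe_classifier` or `rpe_unet`.
#' @return Integer total across all weight and bias tensors.
#' @export
n_parameters <- function(model) {
  stopifnot(is.list(model$weights))
  sum(vapply(model$weights, length, integer(1)))
}

# stack a list of HxW matrices into the (H*W) x n column layout the engine uses
stack_slices <- function(slices, side) {
  n <- length(slices)
  x <- matrix(0, side * side, n)
  for (i in seq_len(n)) {
    s <- slices[[i]]
    if (!identical(dim(s), c(side, side)))
      abort(sprintf("expected %d x %d inputs.", side, side))
    x[, i] <- as.numeric(s)
  }
  x
}

make_perms <- function(epochs, n) {
  p <- matrix(0L, max(epochs, 1L), n)
  for (e in seq_len(nrow(p))) p[e, ] <- sample.int(n)
  p
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
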