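# Plain-R double-precision reference implementations of the two networks.
# Deliberately independent of the compiled engine: activations are (H*W x C)
# matrices, convolutions go through an explicit im2col, and everything stays
# in double precision, so it serves both as a forward-pass oracle and as the
# basis for kink-free finite-difference gradient checks.

ref_im2col3 <- function(A, H, W, Cin) {
  K <- matrix(0, H * W, 9 * Cin)
  for (ci in seq_len(Cin)) {
    m <- matrix(A[, ci], H, W)
    pad <- matrix(0, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- m
    for (kw in 0:2) for (kh in 0:2) {
      K[, kh + 3 * kw + 9 * (ci - 1) + 1] <-
        as.vector(pad[(1:H) + kh, (1:W) + kw])
    }
  }
  K
}

ref_conv3 <- function(A, H, W, w, b, leak = 0) {
  cin <- dim(w)[3]; cout <- dim(w)[4]
  K <- ref_im2col3(A, H, W, cin)
  Y <- K %*% matrix(w, 9 * cin, cout)
  Y <- sweep(Y, 2, b, "+")
  Y[Y < 0] <- leak * Y[Y < 0]
  Y
}

ref_pool <- function(A, H, W, s) {
  C <- ncol(A)
  Ho <- H / s; Wo <- W / s
  P <- matrix(-Inf, Ho * Wo, C)
  for (ci in seq_len(C)) {
    m <- matrix(A[, ci], H, W)
    acc <- matrix(-Inf, Ho, Wo)
    for (dh in seq_len(s)) for (dw in seq_len(s))
      acc <- pmax(acc, m[seq(dh, H, s), seq(dw, W, s)])
    P[, ci] <- as.vector(acc)
  }
  P
}

ref_tconv2 <- function(A, H, W, w, b) {
  cin <- dim(w)[3]; cout <- dim(w)[4]
  H2 <- 2 * H; W2 <- 2 * W
  Y <- matrix(0, H2 * W2, cout)
  hh <- rep(seq_len(H), W); ww <- rep(seq_len(W), each = H)
  for (kh in 0:1) for (kw in 0:1) {
    Wo <- matrix(w[kh + 1, kw + 1, , ], cin, cout)
    dst <- (2 * hh - 2 + kh) + H2 * (2 * ww - 2 + kw) + 1
    Y[dst, ] <- A %*% Wo
  }
  sweep(Y, 2, b, "+")
}

ref_sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass of the slice classifier; x is a 128x128 matrix
ref_encoder_forward <- function(w, x) {
  A <- matrix(as.numeric(x), 128 * 128, 1)
  sp <- c(128, 64, 32, 16); ps <- c(2, 2, 2, 4)
  for (i in 1:4) {
    A <- ref_conv3(A, sp[i], sp[i], w[[paste0("conv", i, "a_w")]],
                   w[[paste0("conv", i, "a_b")]])
    A <- ref_conv3(A, sp[i], sp[i], w[[paste0("conv", i, "b_w")]],
                   w[[paste0("conv", i, "b_b")]])
    A <- ref_pool(A, sp[i], sp[i], ps[i])
  }
  z <- as.numeric(A)
  for (i in 1:4) {
    z <- as.numeric(t(w[[paste0("dense", i, "_w")]]) %*% z +
                      w[[paste0("dense", i, "_b")]])
    if (i < 4) z <- pmax(z, 0)
  }
  ref_sigmoid(z)
}

ref_encoder_loss <- function(w, xs, ys) {
  p <- vapply(xs, function(x) ref_encoder_forward(w, x), numeric(1))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-(ys * log(p) + (1 - ys) * log(1 - p)))
}

# forward pass of the tile U-Net; x is a 64x64 matrix; returns 4096 probs
ref_unet_forward <- function(w, x) {
  lk <- 0.01  # leaky slope of the tile U-Net
  A <- matrix(as.numeric(x), 64 * 64, 1)
  A <- ref_conv3(A, 64, 64, w$enc1a_w, w$enc1a_b, lk)
  A <- ref_conv3(A, 64, 64, w$enc1b_w, w$enc1b_b, lk)
  skip1 <- A
  A <- ref_pool(A, 64, 64, 2)
  A <- ref_conv3(A, 32, 32, w$enc2a_w, w$enc2a_b, lk)
  A <- ref_conv3(A, 32, 32, w$enc2b_w, w$enc2b_b, lk)
  skip2 <- A
  A <- ref_pool(A, 32, 32, 2)
  A <- ref_conv3(A, 16, 16, w$bott_a_w, w$bott_a_b, lk)
  A <- ref_conv3(A, 16, 16, w$bott_b_w, w$bott_b_b, lk)
  A <- ref_tconv2(A, 16, 16, w$up1_w, w$up1_b)
  A <- cbind(A, skip2)
  A <- ref_conv3(A, 32, 32, w$dec1a_w, w$dec1a_b, lk)
  A <- ref_conv3(A, 32, 32, w$dec1b_w, w$dec1b_b, lk)
  A <- ref_tconv2(A, 32, 32, w$up2_w, w$up2_b)
  A <- cbind(A, skip1)
  A <- ref_conv3(A, 64, 64, w$dec2a_w, w$dec2a_b, lk)
  A <- ref_conv3(A, 64, 64, w$dec2b_w, w$dec2b_b, lk)
  z <- A %*% matrix(w$out_w, 16, 1) + w$out_b
  ref_sigmoid(pmin(pmax(as.numeric(z), -15), 15))
}

ref_dice_loss <- function(p, q, eps = 1) {
  1 - (2 * sum(p * q) + eps) / (sum(p) + sum(q) + eps)
}

ref_unet_loss <- function(w, xs, qs, eps = 1) {
  mean(mapply(function(x, q) ref_dice_loss(ref_unet_forward(w, x),
                                           as.numeric(q), eps), xs, qs))
}
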