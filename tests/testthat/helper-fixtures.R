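# Small in-code fixtures shared across tests.

tiny_mask <- function(dim, positives = NULL, spacing = c(1, 1, 1)) {
  m <- array(0L, dim)
  if (!is.null(positives)) m[positives] <- 1L
  binary_mask(m, spacing)
}

random_mask <- function(dim, p = 0.2, spacing = c(1, 1, 1)) {
  binary_mask(array(as.integer(runif(prod(dim)) < p), dim), spacing)
}

random_volume <- function(dim, spacing = c(4.8, 0.5, 0.5), id = "rv") {
  image_volume(array(rnorm(prod(dim)), dim), spacing, id = id)
}

# a quick, easy phantom for learning tests (small in-plane keeps slices cheap)
easy_phantom <- function(seed, in_plane = 64L) {
  generate_phantom(phantom_spec(in_plane = in_plane, lesion_contrast = 3,
                                seed = seed))
}

# brute-force Youden maximizer over a dense threshold grid (independent of
# the midpoint-candidate scan in the implementation)
brute_youden_j <- function(scores, labels) {
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9, scores,
                        min(scores) - 1, max(scores) + 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  max(vapply(grid, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / npos + sum(!pred & labels == 0) / nneg - 1
  }, numeric(1)))
}

# exhaustive pairwise AUROC: P(score_pos > score_neg) + 0.5 P(tie)
pairwise_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
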