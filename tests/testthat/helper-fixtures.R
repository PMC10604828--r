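# Small in-code fixtures shared across test files.

# Constant-valued RGB image.
const_image <- function(h = 8, w = 8, value = 100) {
  array(value, dim = c(h, w, 3))
}

# Deterministic gradient image with distinct pixel values.
gradient_image <- function(h = 8, w = 8) {
  plane <- outer(seq_len(h), seq_len(w), function(y, x) (y * 17 + x * 5) %% 256)
  array(rep(plane, 3), dim = c(h, w, 3))
}

# Tiny dataset of constant images with per-record distinct intensities, so
# records are identifiable across partitioning.
tiny_dataset <- function(n_per_class = c(5, 5), h = 2, w = 2) {
  n <- sum(n_per_class)
  image_dataset(lapply(seq_len(n), function(i) const_image(h, w, i)),
                rep(c("normal", "lesion"), n_per_class))
}

# Held-out logistic probe on pooled mean-intensity features; returns
# accuracy in percent. Independent of the package's classifiers.
probe_accuracy <- function(dataset, seed = 1) {
  feats <- t(vapply(dataset$images, function(img) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    h <- nrow(gray); w <- ncol(gray)
    qs <- c(mean(gray), stats::sd(gray),
            mean(gray[1:(h %/% 2), ]), mean(gray[(h %/% 2 + 1):h, ]),
            stats::quantile(gray, 0.1))
    unname(qs)
  }, numeric(5)))
  y <- as.integer(dataset$labels == dataset$labels[[1]])
  set.seed(seed)
  idx <- sample(seq_along(y))
  half <- length(y) %/% 2
  tr <- idx[seq_len(half)]; te <- idx[-seq_len(half)]
  df <- data.frame(y = y, feats)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ],
                                     family = stats::binomial()))
  pred <- as.integer(suppressWarnings(
    stats::predict(fit, df[te, ], type = "response")) > 0.5)
  100 * mean(pred == y[te])
}
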