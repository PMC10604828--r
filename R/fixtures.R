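#' Seeded two-class synthetic histology-like image set
#'
#' Generates a binary image collection with the same shape contract as the
#' histopathology patches the pipeline targets: 8-bit RGB arrays,
#' directory-per-class writable, with a controllable class signal. Class
#' \code{"normal"} images are a textured background (smooth intensity
#' gradient plus seeded sinusoidal texture); class \code{"lesion"} images
#' add dark elliptical blobs (a cartoon of elevated nuclei density) whose
#' amplitude is proportional to \code{separability}. At separability 0 the
#' two classes are draws from the same distribution. Pixelwise Gaussian
#' noise with standard deviation \code{noise_sd} is added to every image.
#' Fully deterministic for a given spec.
#'
#' @param n_per_class Length-2 integer vector of class sizes
#'   (\code{c(normal, lesion)}).
#' @param size \code{c(height, width)}, default \code{c(128, 128)}.
#' @param separability Signal strength in \code{[0, 1]}.
#' @param noise_sd Intensity-unit noise level (8-bit scale), default 8.
#' @param seed Integer seed.
#' @param class_names Labels for the two classes.
#' @return An \code{image_dataset} with \code{sum(n_per_class)} images.
#' @export
make_synthetic_imageset <- function(n_per_class = c(60, 60),
                                    size = c(128, 128), separability = 1,
                                    noise_sd = 8, seed = 1,
                                    class_names = c("normal", "lesion")) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L),
            separability >= 0, separability <= 1)
  local_seed(seed)
  h <- size[1]; w <- size[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  make_one <- function(with_blobs) {
    base <- 150 + 40 * (xx / w - 0.5) * stats::runif(1, -1, 1) +
      40 * (yy / h - 0.5) * stats::runif(1, -1, 1)
    tex <- 12 * sin(2 * pi * (xx / w) * stats::runif(1, 2, 6) +
                      stats::runif(1, 0, 2 * pi)) +
      12 * sin(2 * pi * (yy / h) * stats::runif(1, 2, 6) +
                 stats::runif(1, 0, 2 * pi))
    plane <- base + tex
    if (with_blobs && separability > 0) {
      for (b in seq_len(6)) {
        cy <- stats::runif(1, 0.15, 0.85) * h
        cx <- stats::runif(1, 0.15, 0.85) * w
        ry <- stats::runif(1, 0.05, 0.12) * h
        rx <- stats::runif(1, 0.05, 0.12) * w
        mask <- exp(-(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2))
        plane <- plane - separability * 80 * mask
      }
    }
    img <- array(0, dim = c(h, w, 3))
    # purple-ish tint so channels differ, as stained tissue patches do
    img[, , 1] <- plane * 0.9
    img[, , 2] <- plane * 0.7
    img[, , 3] <- plane * 1.0
    img <- img + array(stats::rnorm(h * w * 3, sd = noise_sd), dim = c(h, w, 3))
    round(pmin(pmax(img, 0), 255))
  }
  images <- c(lapply(seq_len(n_per_class[1]), function(i) make_one(FALSE)),
              lapply(seq_len(n_per_class[2]), function(i) make_one(TRUE)))
  labels <- rep(class_names, n_per_class)
  image_dataset(images, labels,
                provenance = sprintf("synthetic:%s:%d", labels,
                                     seq_along(labels)))
}

#' Benchmark objectives on the unit hypercube
#'
#' Standard optimizer test functions rescaled to \code{[0,1]^D} with the
#' optimum (value 0) at the center, returned as fitness callables to
#' maximize:
#' \itemize{
#'   \item \code{sphere}: \code{-sum((x - 0.5)^2)}
#'   \item \code{rastrigin}: \code{-(10 D + sum(z^2 - 10 cos(2 pi z)))} with
#'     \code{z = 10.24 (x - 0.5)}
#' }
#'
#' @param name \code{"sphere"} or \code{"rastrigin"}.
#' @param D Dimension (>= 1).
#' @return A function taking a numeric vector of length \code{D} (or a list
#'   coercible to one) and returning the fitness.
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin"), D = 5) {
  name <- match.arg(name)
  stopifnot(D >= 1)
  if (name == "sphere") {
    function(x) {
      x <- unlist(x, use.names = FALSE)
      -sum((x - 0.5)^2)
    }
  } else {
    function(x) {
      x <- unlist(x, use.names = FALSE)
      z <- 10.24 * (x - 0.5)
      -(10 * D + sum(z^2 - 10 * cos(2 * pi * z)))
    }
  }
}

#' Raw continuous search space
#'
#' A D-dimensional space of continuous \code{[0, 1]} spans whose decoded
#' configuration is the numeric vector itself; used to run the optimizers
#' directly on benchmark objectives.
#'
#' @param D Dimension.
#' @return A \code{search_space}-shaped list with a pass-through decoder
#'   contract (use \code{raw_decode} as the \code{decode} argument of
#'   \code{\link{run_optimizer}}).
#' @export
raw_space <- function(D) {
  spans <- lapply(seq_len(D), function(i)
    hyperparameter_span(paste0("x", i), "continuous", lower = 0, upper = 1))
  structure(list(spans = spans, D = D, includes_augmentation = FALSE),
            class = "search_space")
}

#' @rdname raw_space
#' @param vector Numeric position vector.
#' @param space Ignored.
#' @export
raw_decode <- function(vector, space) vector
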