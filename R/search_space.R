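#' Hyperparameter span
#'
#' A single dimension of the configuration search space. A span is either a
#' finite ordered set of options (categorical, stepped-numeric or boolean) or
#' a continuous interval. Stepped-numeric spans enumerate
#' \code{floor((upper - lower)/step) + 1} options.
#'
#' @param name Identifier for the hyperparameter.
#' @param kind One of \code{"categorical"}, \code{"stepped"},
#'   \code{"continuous"}, \code{"boolean"}.
#' @param options Ordered vector of admissible values (categorical/boolean).
#' @param lower,upper Bounds (continuous and stepped spans).
#' @param step Numeric increment (stepped spans only).
#' @return An object of class \code{hyperparameter_span}.
#' @export
hyperparameter_span <- function(name, kind, options = NULL,
                                lower = NULL, upper = NULL, step = NULL) {
  kind <- match.arg(kind, c("categorical", "stepped", "continuous", "boolean"))
  if (kind %in% c("categorical", "boolean")) {
    if (is.null(options) || length(options) < 2L)
      stop("span '", name, "': categorical/boolean spans need >= 2 options")
    if (kind == "boolean" && length(options) != 2L)
      stop("span '", name, "': boolean spans have exactly 2 options")
  } else if (kind == "stepped") {
    if (is.null(lower) || is.null(upper) || is.null(step) || step <= 0)
      stop("span '", name, "': stepped spans need lower, upper and step > 0")
    options <- seq(lower, upper, by = step)
    stopifnot(length(options) == floor((upper - lower) / step) + 1L)
  } else {
    if (is.null(lower) || is.null(upper) || !(lower < upper))
      stop("span '", name, "': continuous spans need lower < upper")
    options <- NULL
  }
  structure(list(name = name, kind = kind, options = options,
                 lower = lower, upper = upper, step = step),
            class = "hyperparameter_span")
}

#' Number of discrete options of a span
#' @param span A \code{hyperparameter_span}.
#' @return Integer count, or \code{NA} for continuous spans.
#' @export
span_length <- function(span) {
  if (span$kind == "continuous") return(NA_integer_)
  length(span$options)
}

#' @export
print.hyperparameter_span <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<span> %s: continuous [%g, %g]\n", x$name, x$lower, x$upper))
  } else {
    cat(sprintf("<span> %s: %s, %d options\n", x$name, x$kind,
                length(x$options)))
  }
  invisible(x)
}

# Canonical option orderings of the study's configuration table.
.loss_options <- c("categorical cross-entropy", "categorical hinge", "poisson",
                   "squared hinge", "kl divergence", "hinge")
.optimizer_options <- c("adam", "nadam", "adagrad", "adadelta", "sgd",
                        "sgd nesterov", "ftrl", "rmsprop centered", "adamax",
                        "rmsprop", "adam amsgrad")
.scaling_options <- c("normalize", "standard", "minmax", "maxabs")

#' Build the default transfer-learning search space
#'
#' Constructs the ordered hyperparameter space searched by the optimizers:
#' loss function, batch size, dropout, transfer-learning learn ratio,
#' parameter optimizer, scaling technique, the augmentation on/off gate and
#' (when augmentation is searched) the eight augmentation hyperparameters.
#' The space has 15 dimensions with augmentation and 7 without.
#'
#' @param include_augmentation Include the eight augmentation spans?
#' @return An object of class \code{search_space}: a list with \code{spans}
#'   (ordered list of \code{hyperparameter_span}), \code{D} and
#'   \code{includes_augmentation}.
#' @examples
#' space <- build_default_space(TRUE)
#' space$D            # 15
#' span_length(space$spans[[2]])  # 12 batch-size options: 4, 8, ..., 48
#' @export
build_default_space <- function(include_augmentation = TRUE) {
  spans <- list(
    hyperparameter_span("loss_function", "categorical", options = .loss_options),
    hyperparameter_span("batch_size", "stepped", lower = 4, upper = 48, step = 4),
    hyperparameter_span("dropout", "continuous", lower = 0, upper = 0.6),
    hyperparameter_span("tl_learn_ratio", "stepped", lower = 1, upper = 100, step = 1),
    hyperparameter_span("parameter_optimizer", "categorical",
                        options = .optimizer_options),
    hyperparameter_span("scaling_technique", "categorical",
                        options = .scaling_options),
    hyperparameter_span("apply_augmentation", "boolean", options = c("yes", "no"))
  )
  if (include_augmentation) {
    spans <- c(spans, list(
      hyperparameter_span("rotation_deg", "stepped", lower = 0, upper = 45, step = 1),
      hyperparameter_span("width_shift", "continuous", lower = 0, upper = 0.25),
      hyperparameter_span("height_shift", "continuous", lower = 0, upper = 0.25),
      hyperparameter_span("shear", "continuous", lower = 0, upper = 0.25),
      hyperparameter_span("zoom", "continuous", lower = 0, upper = 0.25),
      hyperparameter_span("horizontal_flip", "boolean", options = c("yes", "no")),
      hyperparameter_span("vertical_flip", "boolean", options = c("yes", "no")),
      hyperparameter_span("brightness", "continuous", lower = 0.5, upper = 2.0)
    ))
  }
  structure(list(spans = spans, D = length(spans),
                 includes_augmentation = include_augmentation),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> D = %d (%s augmentation spans)\n", x$D,
              if (x$includes_augmentation) "with" else "without"))
  for (s in x$spans) print(s)
  invisible(x)
}

#' Create a random population of normalized solution vectors
#'
#' Each solution is a vector in the unit hypercube \eqn{[0,1]^D}; elements are
#' drawn uniformly between the lower and upper bounds (0 and 1). The same
#' seed always yields the same population.
#'
#' @param n_solutions Number of solutions (at least 2).
#' @param space A \code{search_space} (its \code{D} sets the dimensionality).
#' @param seed Integer seed.
#' @return A numeric \code{n_solutions x D} matrix.
#' @export
init_population <- function(n_solutions, space, seed) {
  if (n_solutions < 2L) stop("invalid population: n_solutions must be >= 2")
  local_seed(seed)
  matrix(stats::runif(n_solutions * space$D), nrow = n_solutions, ncol = space$D)
}

#' Decode one normalized element against a span
#'
#' Discrete spans (categorical, stepped, boolean) use the span-index mapping:
#' the 1-based index is \code{clamp(ceiling(value * Length), 1, Length)} where
#' \code{Length} is the number of options; the element value 0 clamps to the
#' first option. Continuous spans map linearly to
#' \code{lower + value * (upper - lower)}. Boolean spans are 2-option
#' categoricals ordered \code{c("yes", "no")}, so 0 decodes to "yes".
#'
#' For the single-element brightness span the decoder returns a pair
#' \code{c(low, high)} with \code{low = 0.5 + value * 1.5} and
#' \code{high = low + value * (2 - low)}, a deterministic widening rule that
#' degenerates to \code{c(0.5, 0.5)} at value 0.
#'
#' @param value Numeric in \code{[0, 1]}.
#' @param span A \code{hyperparameter_span}.
#' @return The concrete decoded value (option, number, or brightness pair).
#' @examples
#' batch <- hyperparameter_span("batch_size", "stepped",
#'                              lower = 4, upper = 48, step = 4)
#' decode_element(0.75, batch)  # index 9 of 12 -> 36
#' @export
decode_element <- function(value, span) {
  if (!is.finite(value) || value < 0 || value > 1)
    stop("decode domain error: value must lie in [0, 1], got ", value)
  if (span$kind == "continuous") {
    if (identical(span$name, "brightness")) {
      low <- span$lower + value * (span$upper - span$lower)
      return(c(low = low, high = low + value * (span$upper - low)))
    }
    return(span$lower + value * (span$upper - span$lower))
  }
  len <- length(span$options)
  idx <- min(max(ceiling(value * len), 1L), len)
  span$options[[idx]]
}

#' Decode a full solution vector into a named configuration
#'
#' Applies \code{\link{decode_element}} index by index in span order. When the
#' augmentation gate (index 7) decodes to "no", the augmentation spans
#' (indices 8-15) are skipped and absent from the result.
#'
#' @param vector Numeric vector of length \code{space$D} in \code{[0,1]}.
#' @param space A \code{search_space}.
#' @return An object of class \code{decoded_configuration}: a named list with
#'   \code{loss_function}, \code{batch_size}, \code{dropout},
#'   \code{tl_learn_ratio}, \code{parameter_optimizer},
#'   \code{scaling_technique}, \code{apply_augmentation} (logical) and, when
#'   augmentation is on, an \code{augmentation} sub-list (see
#'   \code{\link{augmentation_config}}).
#' @export
decode_solution <- function(vector, space) {
  if (length(vector) != space$D)
    stop("decode error: vector length ", length(vector),
         " does not match space dimensionality ", space$D)
  raw <- lapply(seq_len(space$D), function(i)
    decode_element(vector[[i]], space$spans[[i]]))
  names(raw) <- vapply(space$spans, `[[`, "", "name")
  cfg <- list(
    loss_function = raw$loss_function,
    batch_size = raw$batch_size,
    dropout = raw$dropout,
    tl_learn_ratio = raw$tl_learn_ratio,
    parameter_optimizer = raw$parameter_optimizer,
    scaling_technique = raw$scaling_technique,
    apply_augmentation = identical(raw$apply_augmentation, "yes")
  )
  if (space$includes_augmentation && cfg$apply_augmentation) {
    cfg$augmentation <- augmentation_config(
      rotation_deg = raw$rotation_deg,
      width_shift = raw$width_shift,
      height_shift = raw$height_shift,
      shear = raw$shear,
      zoom = raw$zoom,
      brightness = unname(raw$brightness),
      horizontal_flip = identical(raw$horizontal_flip, "yes"),
      vertical_flip = identical(raw$vertical_flip, "yes"))
  }
  structure(cfg, class = "decoded_configuration")
}

#' @export
print.decoded_configuration <- function(x, ...) {
  cat("<decoded_configuration>\n")
  cat(sprintf("  loss: %s | batch: %d | dropout: %.3f | TL ratio: %d%%\n",
              x$loss_function, x$batch_size, x$dropout, x$tl_learn_ratio))
  cat(sprintf("  optimizer: %s | scaling: %s | augmentation: %s\n",
              x$parameter_optimizer, x$scaling_technique,
              if (x$apply_augmentation) "yes" else "no"))
  invisible(x)
}

#' Clip a solution vector to the unit hypercube
#'
#' Repair step applied after optimizer position updates: each element is
#' replaced by \code{min(1, max(0, element))}. Idempotent.
#'
#' @param vector Numeric vector (or matrix of row vectors).
#' @return The clipped object, same shape.
#' @export
clip_to_bounds <- function(vector) {
  out <- pmin(1, pmax(0, vector))
  dim(out) <- dim(vector)
  out
}

#' Write / read a search space as a YAML config
#'
#' One entry per span with its kind and options/bounds/step, in span order.
#'
#' @param space A \code{search_space}.
#' @param path File path.
#' @return \code{write_search_space} returns \code{path} invisibly;
#'   \code{read_search_space} returns the reconstructed \code{search_space}.
#' @export
write_search_space <- function(space, path) {
  entries <- lapply(space$spans, function(s) {
    e <- list(name = s$name, kind = s$kind)
    if (s$kind == "continuous") {
      e$lower <- s$lower; e$upper <- s$upper
    } else if (s$kind == "stepped") {
      e$lower <- s$lower; e$upper <- s$upper; e$step <- s$step
    } else {
      e$options <- as.list(s$options)
    }
    e
  })
  yaml::write_yaml(list(includes_augmentation = space$includes_augmentation,
                        spans = entries), path)
  invisible(path)
}

#' @rdname write_search_space
#' @export
read_search_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  spans <- lapply(cfg$spans, function(e) {
    if (e$kind %in% c("categorical", "boolean")) {
      hyperparameter_span(e$name, e$kind, options = unlist(e$options))
    } else if (e$kind == "stepped") {
      hyperparameter_span(e$name, "stepped", lower = e$lower, upper = e$upper,
                          step = e$step)
    } else {
      hyperparameter_span(e$name, "continuous", lower = e$lower, upper = e$upper)
    }
  })
  structure(list(spans = spans, D = length(spans),
                 includes_augmentation = isTRUE(cfg$includes_augmentation)),
            class = "search_space")
}

# Strip S3 classes recursively so plain serializers accept the object.
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}

# Seed the session RNG for the calling function, restoring the previous state
# when the caller exits.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  set.seed(seed)
  invisible()
}
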