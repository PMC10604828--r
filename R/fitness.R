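#' Fitness backend contract
#'
#' A backend turns a decoded configuration plus a partitioned dataset into
#' classification evidence. It is a list with fields \code{name},
#' \code{needs_data} (does it read the images at all?) and
#' \code{evaluate(configuration, data, epochs, seed)} returning a list with
#' \code{counts} (\code{confusion_counts}), \code{truth} (labels of the
#' evaluated samples), \code{probabilities} (n x 2 matrix, columns in sorted
#' class order), \code{score} (accuracy percentage) and optionally
#' \code{batch_sizes} (instrumentation). Deterministic backends must return
#' identical results for identical arguments.
#'
#' @name fitness_backend
NULL

#' Designated optimum of the analytic surrogate backend
#'
#' @return A named list giving the surrogate's optimal option for each of
#'   the five scored spans: loss function, batch size, parameter optimizer,
#'   scaling technique and the augmentation gate.
#' @export
surrogate_optimum <- function() {
  list(loss_function = "poisson",        # option 3 of 6
       batch_size = 24,                  # option 6 of 12
       parameter_optimizer = "sgd",      # option 5 of 11
       scaling_technique = "minmax",     # option 3 of 4
       apply_augmentation = FALSE)       # option 2 of 2
}

# Index of a decoded value within its span's option list.
.option_index <- function(value, options) {
  idx <- match(value, options)
  if (is.na(idx)) stop("configuration error: value '", value,
                       "' not in options [", paste(options, collapse = ", "), "]")
  idx
}

# Per-span index distances between a configuration and the surrogate
# optimum, over the five scored spans.
.surrogate_index_distances <- function(config) {
  opt <- surrogate_optimum()
  batch_options <- seq(4, 48, by = 4)
  c(loss = abs(.option_index(config$loss_function, .loss_options) -
                 .option_index(opt$loss_function, .loss_options)),
    batch = abs(.option_index(config$batch_size, batch_options) -
                  .option_index(opt$batch_size, batch_options)),
    optimizer = abs(.option_index(config$parameter_optimizer,
                                  .optimizer_options) -
                      .option_index(opt$parameter_optimizer,
                                    .optimizer_options)),
    scaling = abs(.option_index(config$scaling_technique, .scaling_options) -
                    .option_index(opt$scaling_technique, .scaling_options)),
    augmentation = abs(as.integer(config$apply_augmentation) -
                         as.integer(opt$apply_augmentation)))
}

#' Discrete distance to the surrogate optimum
#'
#' Maximum per-span option-index distance between a decoded configuration
#' and \code{\link{surrogate_optimum}} over the five scored spans.
#'
#' @param config A \code{decoded_configuration}.
#' @return Non-negative integer; 0 at the optimum.
#' @export
surrogate_distance <- function(config) {
  max(.surrogate_index_distances(config))
}

#' Analytic surrogate fitness backend
#'
#' A deterministic data-free backend for desk-scale optimizer testing. Its
#' score is a known function of the decoded configuration, peaked (100) at
#' \code{\link{surrogate_optimum}} and decreasing linearly with the mean
#' normalized option-index distance over the five coarse discrete spans
#' (loss, batch size, parameter optimizer, scaling technique, augmentation
#' gate); the fine-grained and continuous spans are neutral so the
#' landscape has an exhaustively enumerable discrete optimum. The returned
#' confusion evidence is synthesized to be consistent with the score.
#'
#' @return A fitness backend (see \code{\link{fitness_backend}}).
#' @export
surrogate_backend <- function() {
  lengths <- c(loss = 6, batch = 12, optimizer = 11, scaling = 4,
               augmentation = 2)
  evaluate <- function(configuration, data = NULL, epochs = 5, seed = 1) {
    d <- .surrogate_index_distances(configuration) / (lengths - 1)
    score <- 100 * (1 - mean(d))
    n_per <- 100L
    n_correct <- round(score / 100 * n_per)
    truth <- rep(c("normal", "lesion"), each = n_per)
    correct <- rep(c(rep(TRUE, n_correct), rep(FALSE, n_per - n_correct)), 2)
    predicted <- ifelse(correct, truth,
                        ifelse(truth == "normal", "lesion", "normal"))
    counts <- micro_confusion(truth, predicted)
    p_pos <- ifelse((truth == "lesion") == correct, 0.9, 0.1)
    probabilities <- cbind(lesion = p_pos, normal = 1 - p_pos)
    list(counts = counts, truth = truth, probabilities = probabilities,
         score = score, batch_sizes = integer())
  }
  list(name = "surrogate", needs_data = FALSE, evaluate = evaluate)
}

# --- tiny trainable classifier backend -----------------------------------

# Parameter-optimizer update rules (one step). `state` is an environment
# keyed by parameter name holding per-rule accumulators.
.optimizer_step <- function(name, param, grad, state, key, t) {
  g <- grad
  get0s <- function(suffix) {
    k <- paste0(key, ".", suffix)
    if (is.null(state[[k]])) state[[k]] <- array(0, dim = dim(param))
    state[[k]]
  }
  set0s <- function(suffix, value) state[[paste0(key, ".", suffix)]] <- value
  switch(name,
    "sgd" = param - 0.1 * g,
    "sgd nesterov" = {
      m <- 0.9 * get0s("m") + g
      set0s("m", m)
      param - 0.1 * (g + 0.9 * m)
    },
    "adam" = {
      m <- 0.9 * get0s("m") + 0.1 * g
      v <- 0.999 * get0s("v") + 0.001 * g^2
      set0s("m", m); set0s("v", v)
      mh <- m / (1 - 0.9^t); vh <- v / (1 - 0.999^t)
      param - 0.02 * mh / (sqrt(vh) + 1e-8)
    },
    "adam amsgrad" = {
      m <- 0.9 * get0s("m") + 0.1 * g
      v <- 0.999 * get0s("v") + 0.001 * g^2
      vmax <- pmax(get0s("vmax"), v)
      set0s("m", m); set0s("v", v); set0s("vmax", vmax)
      mh <- m / (1 - 0.9^t)
      param - 0.02 * mh / (sqrt(vmax / (1 - 0.999^t)) + 1e-8)
    },
    "nadam" = {
      m <- 0.9 * get0s("m") + 0.1 * g
      v <- 0.999 * get0s("v") + 0.001 * g^2
      set0s("m", m); set0s("v", v)
      mh <- m / (1 - 0.9^(t + 1)); vh <- v / (1 - 0.999^t)
      param - 0.02 * (0.9 * mh + 0.1 * g / (1 - 0.9^t)) / (sqrt(vh) + 1e-8)
    },
    "adamax" = {
      m <- 0.9 * get0s("m") + 0.1 * g
      u <- pmax(0.999 * get0s("u"), abs(g))
      set0s("m", m); set0s("u", u)
      param - 0.02 * (m / (1 - 0.9^t)) / (u + 1e-8)
    },
    "adagrad" = {
      a <- get0s("a") + g^2
      set0s("a", a)
      param - 0.1 * g / (sqrt(a) + 1e-8)
    },
    "adadelta" = {
      a <- 0.95 * get0s("a") + 0.05 * g^2
      dacc <- get0s("d")
      upd <- sqrt(dacc + 1e-6) / sqrt(a + 1e-6) * g
      set0s("a", a); set0s("d", 0.95 * dacc + 0.05 * upd^2)
      param - 1.0 * upd
    },
    "rmsprop" = {
      a <- 0.9 * get0s("a") + 0.1 * g^2
      set0s("a", a)
      param - 0.02 * g / (sqrt(a) + 1e-8)
    },
    "rmsprop centered" = {
      a <- 0.9 * get0s("a") + 0.1 * g^2
      mg <- 0.9 * get0s("mg") + 0.1 * g
      set0s("a", a); set0s("mg", mg)
      param - 0.02 * g / (sqrt(pmax(a - mg^2, 0)) + 1e-8)
    },
    "ftrl" = {
      # FTRL-proximal with L1 = 0, L2 = 1e-4, alpha = 0.5, beta = 1
      n <- get0s("n"); z <- get0s("z")
      n_new <- n + g^2
      sigma <- (sqrt(n_new) - sqrt(n)) / 0.5
      z <- z + g - sigma * param
      set0s("n", n_new); set0s("z", z)
      -z / ((1 + sqrt(n_new)) / 0.5 + 1e-4)
    },
    stop("configuration error: unsupported parameter optimizer '", name,
         "'; supported: ", paste(.optimizer_options, collapse = ", ")))
}

# Gradient of the configured loss with respect to the softmax output p,
# given one-hot truth y (vectors of length K). CE/KL short-circuit to the
# logit gradient p - y downstream.
.loss_grad_p <- function(loss, p, y) {
  switch(loss,
    "poisson" = 1 - y / pmax(p, 1e-8),
    "hinge" = {
      ypm <- 2 * y - 1
      -ypm * as.numeric(1 - ypm * p > 0) / length(p)
    },
    "squared hinge" = {
      ypm <- 2 * y - 1
      -2 * ypm * pmax(1 - ypm * p, 0) / length(p)
    },
    "categorical hinge" = {
      pos <- sum(y * p)
      negs <- (1 - y) * p
      j <- which.max(negs)
      g <- numeric(length(p))
      if (1 + negs[j] - pos > 0) {
        g <- g - y
        g[j] <- g[j] + 1
      }
      g
    },
    stop("configuration error: unsupported loss '", loss, "'; supported: ",
         paste(.loss_options, collapse = ", ")))
}

# Mean pooled convolutional features from a fixed seeded filter bank: the
# frozen "pretrained" representation the trainable head sits on.
.conv_features <- function(images, n_filters = 4, grid = 4, filter_seed = 42) {
  local_seed(filter_seed)
  filters <- lapply(seq_len(n_filters), function(i)
    matrix(stats::rnorm(9), 3, 3))
  feats <- vapply(images, function(img) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    h <- nrow(gray); w <- ncol(gray)
    core <- 2:(h - 1); corw <- 2:(w - 1)
    unlist(lapply(filters, function(f) {
      conv <- matrix(0, h - 2, w - 2)
      for (dy in -1:1) for (dx in -1:1)
        conv <- conv + f[dy + 2, dx + 2] * gray[core + dy, corw + dx]
      conv <- pmax(conv, 0)  # ReLU
      # average-pool onto a grid x grid summary
      ob <- cut(seq_len(nrow(conv)), grid, labels = FALSE)
      wb <- cut(seq_len(ncol(conv)), grid, labels = FALSE)
      as.vector(vapply(seq_len(grid), function(gy)
        vapply(seq_len(grid), function(gx)
          mean(conv[ob == gy, wb == gx]), numeric(1)), numeric(grid)))
    }))
  }, numeric(n_filters * grid * grid))
  t(feats)
}

#' Small trainable classifier backend
#'
#' A compact two-layer softmax classifier over a frozen, seeded
#' convolutional feature bank, honoring the searched hyperparameters: the
#' decoded batch size drives the minibatch partition, the dropout rate is
#' applied (inverted) to the hidden activations during training, the loss
#' function and parameter optimizer select the training objective and
#' update rule, and the transfer-learning learn ratio fixes the percentage
#' of hidden units whose input weights are trainable (the rest stay at
#' their initialization, playing the part of frozen pretrained layers).
#' With \code{epochs = 0} the untrained model scores at chance on balanced
#' data.
#'
#' @param width Hidden layer width (default 16).
#' @param n_filters Fixed convolution filters (default 4).
#' @param grid Pooling grid per filter (default 4).
#' @return A fitness backend (see \code{\link{fitness_backend}}).
#' @export
tiny_classifier_backend <- function(width = 16, n_filters = 4, grid = 4) {
  evaluate <- function(configuration, data, epochs = 5, seed = 1) {
    stopifnot(inherits(data, "split_dataset"))
    classes <- sort(unique(c(data$train$labels, data$test$labels)))
    if (length(classes) != 2L)
      stop("tiny classifier handles exactly two classes")
    local_seed(seed)
    feat_tr <- .conv_features(data$train$images, n_filters, grid)
    feat_te <- .conv_features(data$test$images, n_filters, grid)
    mu <- colMeans(feat_tr)
    sdv <- pmax(apply(feat_tr, 2, stats::sd), 1e-8)
    feat_tr <- sweep(sweep(feat_tr, 2, mu), 2, sdv, "/")
    feat_te <- sweep(sweep(feat_te, 2, mu), 2, sdv, "/")
    y_tr <- matrix(0, nrow(feat_tr), 2)
    y_tr[cbind(seq_len(nrow(feat_tr)), match(data$train$labels, classes))] <- 1
    nf <- ncol(feat_tr)
    W1 <- matrix(stats::rnorm(nf * width, sd = sqrt(2 / nf)), nf, width)
    b1 <- matrix(0, 1, width)
    W2 <- matrix(stats::rnorm(width * 2, sd = sqrt(2 / width)), width, 2)
    b2 <- matrix(0, 1, 2)
    n_trainable <- ceiling(configuration$tl_learn_ratio / 100 * width)
    trainable_cols <- seq_len(n_trainable)
    opt_name <- configuration$parameter_optimizer
    loss <- configuration$loss_function
    dropout <- configuration$dropout
    state <- new.env(parent = emptyenv())
    step_t <- 0L
    batch_sizes <- integer()
    forward <- function(X, drop = FALSE) {
      H <- pmax(sweep(X %*% W1, 2, -b1[1, ]), 0)
      if (drop && dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - dropout),
                       nrow(H)) / (1 - dropout)
        H <- H * mask
      }
      Z <- sweep(H %*% W2, 2, -b2[1, ])
      Zs <- Z - apply(Z, 1, max)
      P <- exp(Zs) / rowSums(exp(Zs))
      list(H = H, P = P)
    }
    n_tr <- nrow(feat_tr)
    frozen <- setdiff(seq_len(width), trainable_cols)
    epoch_losses <- numeric(0)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n_tr)
        batches <- split(ord, ceiling(seq_along(ord) /
                                        configuration$batch_size))
        ep_loss <- 0
        for (bt in batches) {
          batch_sizes <- c(batch_sizes, length(bt))
          X <- feat_tr[bt, , drop = FALSE]
          Y <- y_tr[bt, , drop = FALSE]
          fw <- forward(X, drop = TRUE)
          # gradient w.r.t. logits
          dZ <- if (loss %in% c("categorical cross-entropy", "kl divergence")) {
            (fw$P - Y) / length(bt)
          } else {
            t(vapply(seq_len(nrow(X)), function(i) {
              p <- fw$P[i, ]
              gp <- .loss_grad_p(loss, p, Y[i, ])
              p * (gp - sum(p * gp))  # softmax Jacobian
            }, numeric(2))) / length(bt)
          }
          ep_loss <- ep_loss -
            sum(Y * log(pmax(fw$P, 1e-12))) / length(bt)
          gW2 <- t(fw$H) %*% dZ
          gb2 <- matrix(colSums(dZ), 1, 2)
          dH <- dZ %*% t(W2)
          dH[fw$H <= 0] <- 0
          gW1 <- t(X) %*% dH
          gb1 <- matrix(colSums(dH), 1, width)
          gW1[, frozen] <- 0
          gb1[, frozen] <- 0
          step_t <- step_t + 1L
          W2 <- .optimizer_step(opt_name, W2, gW2, state, "W2", step_t)
          b2 <- .optimizer_step(opt_name, b2, gb2, state, "b2", step_t)
          if (length(trainable_cols) > 0) {
            W1 <- .optimizer_step(opt_name, W1, gW1, state, "W1", step_t)
            b1 <- .optimizer_step(opt_name, b1, gb1, state, "b1", step_t)
          }
        }
        epoch_losses <- c(epoch_losses, ep_loss / length(batches))
      }
    }
    probs <- forward(feat_te, drop = FALSE)$P
    colnames(probs) <- classes
    predicted <- classes[max.col(probs, ties.method = "first")]
    counts <- micro_confusion(data$test$labels, predicted, classes = classes)
    score <- 100 * sum(predicted == data$test$labels) /
      length(data$test$labels)
    list(counts = counts, truth = data$test$labels, probabilities = probs,
         score = score, batch_sizes = batch_sizes,
         epoch_losses = epoch_losses)
  }
  list(name = "tiny_classifier", needs_data = TRUE, evaluate = evaluate)
}

#' Evaluate a solution vector through a fitness backend
#'
#' Decodes the vector, applies the decoded scaling technique to every image
#' of the partitioned dataset, applies augmentation-based balancing to the
#' training part when the decoded augmentation gate is on, delegates to the
#' backend, and assembles the full twelve-metric report (count metrics from
#' the confusion counts; AUC and cosine similarity from the per-sample
#' probabilities). The fitness scalar is taken from the report.
#'
#' @param vector Normalized solution vector.
#' @param space A \code{search_space}.
#' @param backend A fitness backend.
#' @param data A \code{split_dataset} (ignored by data-free backends).
#' @param epochs Training epochs per evaluation (default 5).
#' @param seed Integer seed.
#' @param fitness_metric \code{"accuracy"} (default) or
#'   \code{"weighted_sum"}.
#' @return A list of class \code{evaluation_result} with \code{counts},
#'   \code{report}, \code{fitness}, \code{configuration} and
#'   \code{backend_detail}.
#' @export
evaluate_solution <- function(vector, space, backend, data = NULL,
                              epochs = 5, seed = 1,
                              fitness_metric = c("accuracy", "weighted_sum")) {
  fitness_metric <- match.arg(fitness_metric)
  configuration <- decode_solution(vector, space)
  eval_data <- data
  if (isTRUE(backend$needs_data)) {
    if (is.null(eval_data)) stop("backend '", backend$name, "' needs data")
    scale_part <- function(ds) {
      ds$images <- lapply(ds$images, scale_image,
                          method = configuration$scaling_technique)
      ds
    }
    if (configuration$apply_augmentation)
      eval_data$train <- balance_by_augmentation(
        eval_data$train, configuration$augmentation, seed = seed)
    eval_data$train <- scale_part(eval_data$train)
    eval_data$validation <- scale_part(eval_data$validation)
    eval_data$test <- scale_part(eval_data$test)
  }
  res <- tryCatch(
    backend$evaluate(configuration, eval_data, epochs, seed),
    error = function(e) stop("evaluation failed for configuration [loss=",
                             configuration$loss_function, ", batch=",
                             configuration$batch_size, "]: ",
                             conditionMessage(e), call. = FALSE))
  report <- compute_metrics(res$counts)
  if (!is.null(res$probabilities) && !is.null(res$truth)) {
    classes <- colnames(res$probabilities)
    positive <- classes[1]
    report$auc <- auc_rank(res$truth, res$probabilities[, positive],
                           positive = positive)
    onehot <- matrix(0, length(res$truth), length(classes))
    onehot[cbind(seq_along(res$truth), match(res$truth, classes))] <- 1
    colnames(onehot) <- classes
    report$cosine_similarity <- cosine_similarity(onehot, res$probabilities)
  }
  fitness <- if (fitness_metric == "accuracy") report$accuracy
             else weighted_sum(report)
  structure(list(counts = res$counts, report = report, fitness = fitness,
                 configuration = configuration, backend_detail = res),
            class = "evaluation_result")
}

#' Objective closure over a backend for the optimizer loop
#'
#' Wraps \code{\link{evaluate_solution}} into the decoded-configuration
#' objective shape \code{\link{run_optimizer}} expects. Note
#' \code{run_optimizer} decodes vectors itself, so this helper re-encodes
#' nothing: it accepts the decoded configuration and evaluates through the
#' backend by reusing the evaluation pathway.
#'
#' @inheritParams evaluate_solution
#' @return A function mapping a \code{decoded_configuration} to a fitness.
#' @export
backend_objective <- function(backend, data = NULL, epochs = 5, seed = 1,
                              fitness_metric = c("accuracy", "weighted_sum")) {
  fitness_metric <- match.arg(fitness_metric)
  function(configuration) {
    res <- backend$evaluate(configuration,
                            if (isTRUE(backend$needs_data))
                              .preprocess_for(configuration, data, seed)
                            else data,
                            epochs, seed)
    if (fitness_metric == "accuracy") return(res$score)
    report <- compute_metrics(res$counts)
    classes <- colnames(res$probabilities)
    report$auc <- auc_rank(res$truth, res$probabilities[, classes[1]],
                           positive = classes[1])
    onehot <- matrix(0, length(res$truth), length(classes))
    onehot[cbind(seq_along(res$truth), match(res$truth, classes))] <- 1
    report$cosine_similarity <- cosine_similarity(onehot, res$probabilities)
    weighted_sum(report)
  }
}

# Scaling + conditional balancing applied before a data-using backend call.
.preprocess_for <- function(configuration, data, seed) {
  scale_part <- function(ds) {
    ds$images <- lapply(ds$images, scale_image,
                        method = configuration$scaling_technique)
    ds
  }
  if (configuration$apply_augmentation)
    data$train <- balance_by_augmentation(data$train,
                                          configuration$augmentation,
                                          seed = seed)
  data$train <- scale_part(data$train)
  data$validation <- scale_part(data$validation)
  data$test <- scale_part(data$test)
  data
}
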