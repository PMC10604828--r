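#' Image dataset container
#'
#' A lightweight in-memory collection of RGB images: a list of H x W x 3
#' numeric arrays (8-bit intensities 0-255 on ingest, real-valued after
#' scaling), a class label per image, and a provenance string (source path
#' or synthetic tag).
#'
#' @param images List of H x W x 3 arrays.
#' @param labels Character vector of class labels, one per image.
#' @param provenance Optional character vector, recycled if length 1.
#' @return An object of class \code{image_dataset}.
#' @export
image_dataset <- function(images, labels, provenance = "memory") {
  stopifnot(length(images) == length(labels))
  if (length(provenance) == 1L) provenance <- rep(provenance, length(images))
  structure(list(images = images, labels = as.character(labels),
                 provenance = provenance), class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images; classes: %s\n", length(x$images),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.image_dataset <- function(x) length(x$images)

# Subset a dataset by index.
subset_dataset <- function(dataset, idx) {
  image_dataset(dataset$images[idx], dataset$labels[idx],
                dataset$provenance[idx])
}

# Concatenate two datasets.
bind_datasets <- function(a, b) {
  image_dataset(c(a$images, b$images), c(a$labels, b$labels),
                c(a$provenance, b$provenance))
}

# --- bicubic resize -------------------------------------------------------

# Catmull-Rom cubic kernel (a = -0.5), the standard bicubic interpolant.
.cubic_kernel <- function(d, a = -0.5) {
  d <- abs(d)
  ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
         ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
}

# Dense n_out x n_in interpolation weight matrix for one axis. Source
# coordinates use center alignment; out-of-range taps are clamped to the
# edge (nearest-edge extension) and rows are renormalized to sum to one so
# constants are preserved exactly.
.resize_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    k <- .cubic_kernel(src - taps)
    taps <- pmin(pmax(taps, 1L), n_in)
    for (j in seq_along(taps)) w[i, taps[j]] <- w[i, taps[j]] + k[j]
  }
  sweep(w, 1, rowSums(w), "/")
}

#' Resize an RGB image with bicubic interpolation
#'
#' Separable bicubic (Catmull-Rom) resampling in RGB space; the default
#' target is the pipeline's working shape 128 x 128 x 3. Resizing to the
#' input shape reproduces the input exactly, and constant images stay
#' constant.
#'
#' @param image H x W x 3 numeric array.
#' @param target Integer vector \code{c(height, width)} (a third element, if
#'   given, must be 3).
#' @return The resized array, \code{target[1] x target[2] x 3}.
#' @export
resize_image <- function(image, target = c(128L, 128L)) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("format error: resize_image expects an H x W x 3 RGB array")
  if (length(target) >= 3L && target[3] != 3L)
    stop("format error: target must keep 3 channels")
  h_out <- as.integer(target[1]); w_out <- as.integer(target[2])
  wr <- .resize_weights(d[1], h_out)
  wc <- .resize_weights(d[2], w_out)
  out <- array(0, dim = c(h_out, w_out, 3L))
  for (ch in 1:3) out[, , ch] <- wr %*% image[, , ch] %*% t(wc)
  out
}

#' Scale image intensities
#'
#' The four per-image scaling transforms, each computed from the image's own
#' pixel statistics over all channels:
#' \itemize{
#'   \item \code{normalize}: \code{X / max(X)}
#'   \item \code{standard}: \code{(X - mean(X)) / sd(X)}
#'   \item \code{minmax}: \code{(X - min(X)) / (max(X) - min(X))}
#'   \item \code{maxabs}: \code{X / max(|X|)}
#' }
#' Degenerate inputs (constant image under \code{standard}/\code{minmax},
#' all-zero under \code{normalize}/\code{maxabs}) return an all-zero image
#' with a warning rather than failing mid-pipeline.
#'
#' @param image H x W x 3 numeric array.
#' @param method One of \code{"normalize"}, \code{"standard"},
#'   \code{"minmax"}, \code{"maxabs"}.
#' @return The scaled array, same shape.
#' @export
scale_image <- function(image,
                        method = c("normalize", "standard", "minmax", "maxabs")) {
  method <- match.arg(method)
  if (length(image) == 0L) stop("degenerate input: empty image")
  degenerate <- function() {
    warning("degenerate image for scaling method '", method,
            "'; returning zeros")
    array(0, dim = dim(image))
  }
  switch(method,
    normalize = {
      m <- max(image)
      if (m == 0) degenerate() else image / m
    },
    standard = {
      s <- stats::sd(image)
      if (s == 0) degenerate() else (image - mean(image)) / s
    },
    minmax = {
      lo <- min(image); hi <- max(image)
      if (hi == lo) degenerate() else (image - lo) / (hi - lo)
    },
    maxabs = {
      m <- max(abs(image))
      if (m == 0) degenerate() else image / m
    })
}

#' Augmentation configuration
#'
#' Magnitudes of the label-preserving image transforms used both for class
#' balancing and as searched hyperparameters. Shift/shear/zoom magnitudes
#' are fractions in \code{[0, 0.25]}; rotation is in degrees up to 45;
#' brightness is a multiplier interval inside \code{[0.5, 2]}.
#'
#' @param rotation_deg Maximum rotation angle, degrees.
#' @param width_shift,height_shift Maximum shift, fraction of the image size.
#' @param shear Maximum shear, fraction.
#' @param zoom Maximum zoom deviation, fraction.
#' @param brightness Length-2 numeric \code{c(low, high)} multiplier range.
#' @param horizontal_flip,vertical_flip Enable random flips?
#' @return A list of class \code{augmentation_config}.
#' @export
augmentation_config <- function(rotation_deg = 30, width_shift = 0.2,
                                height_shift = 0.2, shear = 0.2, zoom = 0.2,
                                brightness = c(0.8, 1.2),
                                horizontal_flip = TRUE, vertical_flip = TRUE) {
  stopifnot(rotation_deg >= 0, rotation_deg <= 45,
            width_shift >= 0, width_shift <= 0.25,
            height_shift >= 0, height_shift <= 0.25,
            shear >= 0, shear <= 0.25, zoom >= 0, zoom <= 0.25,
            length(brightness) == 2L, brightness[1] >= 0.5,
            brightness[2] <= 2, brightness[1] <= brightness[2])
  structure(list(rotation_deg = rotation_deg, width_shift = width_shift,
                 height_shift = height_shift, shear = shear, zoom = zoom,
                 brightness = brightness, horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip),
            class = "augmentation_config")
}

# The study's balancing configuration: rotation 30 degrees, 20% shifts,
# shear and zoom, brightness [0.8, 1.2], both flips enabled.
#' @rdname augmentation_config
#' @export
default_balancing_config <- function() augmentation_config()

#' Flip an image
#'
#' Exact mirror about the vertical (horizontal flip) or horizontal
#' (vertical flip) axis; an involution.
#'
#' @param image H x W x 3 array.
#' @param direction \code{"horizontal"} (left-right) or \code{"vertical"}
#'   (top-bottom).
#' @return Flipped array.
#' @export
flip_image <- function(image, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (direction == "horizontal") image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
}

# Inverse-mapped affine resampling with bilinear interpolation and
# nearest-edge fill. `m` is the 2x2 output->input linear map about the image
# center, `off` an additional (row, col) translation in pixels.
.affine_sample <- function(image, m, off = c(0, 0)) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  grid_y <- rep(seq_len(h), times = w) - cy
  grid_x <- rep(seq_len(w), each = h) - cx
  src_y <- m[1, 1] * grid_y + m[1, 2] * grid_x + cy - off[1]
  src_x <- m[2, 1] * grid_y + m[2, 2] * grid_x + cx - off[2]
  y0 <- floor(src_y); x0 <- floor(src_x)
  fy <- src_y - y0; fx <- src_x - x0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  y0c <- cl(y0, h); y1c <- cl(y0 + 1, h)
  x0c <- cl(x0, w); x1c <- cl(x0 + 1, w)
  out <- array(0, dim = d)
  for (ch in 1:3) {
    plane <- image[, , ch]
    i00 <- plane[cbind(y0c, x0c)]; i01 <- plane[cbind(y0c, x1c)]
    i10 <- plane[cbind(y1c, x0c)]; i11 <- plane[cbind(y1c, x1c)]
    vals <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
      fy * ((1 - fx) * i10 + fx * i11)
    out[, , ch] <- vals
  }
  out
}

#' Apply a random augmentation to one image
#'
#' Draws transform parameters uniformly within the configured magnitudes:
#' rotation in \code{[-r, r]} degrees, width/height shifts in
#' \code{[-s, s]} of the image size, shear in \code{[-sh, sh]}, zoom factor
#' in \code{[1 - z, 1 + z]}, each enabled flip applied with probability 1/2,
#' and a brightness multiplier in \code{[low, high]} with the result clipped
#' to \code{[0, 255]}. Geometric resampling is bilinear with nearest-edge
#' fill; the identity configuration (all magnitudes 0, flips off,
#' brightness \code{c(1, 1)}) reproduces the input exactly.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param config An \code{\link{augmentation_config}}.
#' @return The augmented array, same shape.
#' @export
augment_image <- function(image, config) {
  d <- dim(image)
  theta <- if (config$rotation_deg > 0)
    stats::runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180 else 0
  shear <- if (config$shear > 0)
    stats::runif(1, -config$shear, config$shear) else 0
  zoom <- if (config$zoom > 0)
    stats::runif(1, 1 - config$zoom, 1 + config$zoom) else 1
  dy <- if (config$height_shift > 0)
    stats::runif(1, -config$height_shift, config$height_shift) * d[1] else 0
  dx <- if (config$width_shift > 0)
    stats::runif(1, -config$width_shift, config$width_shift) * d[2] else 0
  out <- image
  if (theta != 0 || shear != 0 || zoom != 1 || dy != 0 || dx != 0) {
    rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    shr <- matrix(c(1, shear, 0, 1), 2, 2)
    fwd <- (rot %*% shr) * zoom          # input -> output map
    m <- solve(fwd)                      # output -> input
    out <- .affine_sample(out, m, off = c(dy, dx))
  }
  if (isTRUE(config$horizontal_flip) && stats::runif(1) < 0.5)
    out <- flip_image(out, "horizontal")
  if (isTRUE(config$vertical_flip) && stats::runif(1) < 0.5)
    out <- flip_image(out, "vertical")
  b <- config$brightness
  if (!(b[1] == 1 && b[2] == 1)) {
    mult <- stats::runif(1, b[1], b[2])
    out <- pmin(pmax(out * mult, 0), 255)
  }
  out
}

#' Balance classes by augmentation
#'
#' Brings every class up to the size of the largest class by appending
#' augmented copies of uniformly resampled originals of that class. No
#' record is ever removed. With the study's class sizes (normal 2494,
#' OSCC 2698) the balanced set holds 2698 per class, 5396 in total.
#'
#' @param dataset An \code{image_dataset}.
#' @param config An \code{\link{augmentation_config}} used to synthesize the
#'   added copies (default \code{\link{default_balancing_config}}).
#' @param seed Integer seed for the resampling and transform draws.
#' @return The balanced \code{image_dataset}.
#' @export
balance_by_augmentation <- function(dataset, config = default_balancing_config(),
                                    seed = 1) {
  counts <- table(dataset$labels)
  if (any(counts == 0) || length(counts) == 0)
    stop("balance error: every class needs at least one image")
  target <- max(counts)
  local_seed(seed)
  out <- dataset
  for (cls in names(counts)) {
    deficit <- target - counts[[cls]]
    if (deficit == 0) next
    pool <- which(dataset$labels == cls)
    picks <- pool[sample.int(length(pool), deficit, replace = TRUE)]
    new_images <- lapply(dataset$images[picks], augment_image, config = config)
    out <- bind_datasets(out, image_dataset(
      new_images, rep(cls, deficit),
      paste0(dataset$provenance[picks], "#aug")))
  }
  out
}

#' Nested train/validation/test partition
#'
#' First splits the shuffled records \code{ratio} : \code{1 - ratio} into a
#' training pool and the test part, then splits the pool with the same
#' ratio into training and validation. With the default ratio 0.85 the
#' proportions are 72.25\% / 12.75\% / 15\%. Assignment is class-agnostic
#' (plain ratio split of the shuffled records); set
#' \code{stratify = TRUE} to split each class separately.
#'
#' @param dataset An \code{image_dataset}.
#' @param ratio Split ratio in (0, 1), default 0.85.
#' @param seed Integer seed for the shuffle.
#' @param stratify Apply the split per class? Default \code{FALSE}.
#' @return A list of class \code{split_dataset} with \code{train},
#'   \code{validation} and \code{test} datasets.
#' @export
partition_dataset <- function(dataset, ratio = 0.85, seed = 1,
                              stratify = FALSE) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(dataset)
  if (n < 3L) stop("partition error: need at least 3 records")
  local_seed(seed)
  assign_split <- function(idx) {
    idx <- idx[sample.int(length(idx))]
    n_test <- round(length(idx) * (1 - ratio))
    test <- idx[seq_len(n_test)]
    pool <- idx[-seq_len(n_test)]
    n_val <- round(length(pool) * (1 - ratio))
    validation <- pool[seq_len(n_val)]
    train <- pool[-seq_len(n_val)]
    list(train = train, validation = validation, test = test)
  }
  parts <- if (stratify) {
    per_class <- lapply(split(seq_len(n), dataset$labels), assign_split)
    list(train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
         validation = unlist(lapply(per_class, `[[`, "validation"),
                             use.names = FALSE),
         test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE))
  } else assign_split(seq_len(n))
  if (length(parts$train) == 0 || length(parts$validation) == 0 ||
      length(parts$test) == 0)
    stop("partition error: dataset too small to populate all three parts")
  structure(list(train = subset_dataset(dataset, parts$train),
                 validation = subset_dataset(dataset, parts$validation),
                 test = subset_dataset(dataset, parts$test)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

# --- directory-per-class I/O ---------------------------------------------

#' Read / write a directory-per-class PNG image collection
#'
#' \code{read_imageset} ingests a directory whose immediate subdirectories
#' are class names holding PNG files; intensities are returned on the 8-bit
#' 0-255 scale. \code{write_imageset} writes a dataset back in the same
#' layout. \code{write_split_manifest} records a partition as a CSV of
#' (path, class, split).
#'
#' @param dir Root directory.
#' @param dataset An \code{image_dataset}.
#' @param split A \code{split_dataset}.
#' @param path Manifest CSV path.
#' @return \code{read_imageset}: an \code{image_dataset}; the writers return
#'   their output path invisibly.
#' @export
read_imageset <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE)
  if (length(classes) == 0) stop("no class subdirectories under ", dir)
  images <- list(); labels <- character(); prov <- character()
  for (cd in classes) {
    files <- list.files(cd, pattern = "\\.png$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in files) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
      if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
      images[[length(images) + 1L]] <- px * 255
      labels <- c(labels, basename(cd))
      prov <- c(prov, f)
    }
  }
  image_dataset(images, labels, prov)
}

#' @rdname read_imageset
#' @export
write_imageset <- function(dataset, dir) {
  for (cls in unique(dataset$labels)) {
    cd <- file.path(dir, cls)
    dir.create(cd, recursive = TRUE, showWarnings = FALSE)
    idx <- which(dataset$labels == cls)
    for (k in seq_along(idx)) {
      img <- dataset$images[[idx[k]]]
      png::writePNG(pmin(pmax(img / 255, 0), 1),
                    file.path(cd, sprintf("img_%05d.png", k)))
    }
  }
  invisible(dir)
}

#' @rdname read_imageset
#' @export
write_split_manifest <- function(split, path) {
  rows <- do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
    ds <- split[[p]]
    if (length(ds) == 0) return(NULL)
    data.frame(path = ds$provenance, class = ds$labels, split = p)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
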