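# Dataset manifests, SMOTE balance planning/generation, stratified
# splitting, and the synthetic fixture generators (lesion-like images and
# feature tables with planted informative columns) that make the whole
# pipeline testable without external downloads.

#' Plan SMOTE class balancing
#'
#' For each class, the number of synthetic samples needed to reach the
#' target count: `synthetic = max(0, target - original)`.  Exempt classes
#' (typically the majority class) are never oversampled and keep their
#' original counts as their targets.
#'
#' @param counts named integer vector of per-class original counts.
#' @param target target count per non-exempt class.
#' @param exempt character vector of class names excluded from
#'   oversampling.
#' @return object of class `balance_plan`: data frame with columns `class`,
#'   `original`, `target`, `synthetic`, plus attributes `total_synthetic`
#'   and `grand_total`.
#' @export
plan_balance <- function(counts, target, exempt = character(0)) {
  stopifnot(target >= 1)
  if (any(counts < 0)) stop("negative class counts")
  if (is.null(names(counts))) names(counts) <- paste0("class", seq_along(counts))
  is_ex <- names(counts) %in% exempt
  tgt <- ifelse(is_ex, counts, pmax(counts, 0))
  tgt[!is_ex] <- target
  synth <- ifelse(is_ex, 0, pmax(0, target - counts))
  plan <- data.frame(class = names(counts),
                     original = as.numeric(counts),
                     target = pmax(as.numeric(tgt), as.numeric(counts)),
                     synthetic = as.numeric(synth),
                     exempt = is_ex,
                     row.names = NULL)
  structure(plan,
            total_synthetic = sum(plan$synthetic),
            grand_total = sum(plan$original + plan$synthetic),
            class = c("balance_plan", "data.frame"))
}

#' Generate synthetic minority samples (SMOTE)
#'
#' Each synthetic row is `x + delta * (x_nn - x)` where `x` is a uniformly
#' drawn class sample, `x_nn` one of its `k` nearest same-class neighbors
#' (Euclidean distance on the raw vectors, no standardization) and
#' `delta ~ U(0, 1)`.  With `clip` set (image mode), values are clipped to
#' that range.
#'
#' @param samples n x d numeric matrix of one class's samples (n >= 2).
#' @param n_new number of synthetic rows to generate.
#' @param k neighbor count (default 5, capped below n).
#' @param seed RNG seed.
#' @param clip optional length-2 range to clip synthetic values into
#'   (e.g. `c(0, 255)` for 8-bit pixels).
#' @return n_new x d numeric matrix.
#' @export
smote_generate <- function(samples, n_new, k = 5L, seed = 1L, clip = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop("SMOTE needs at least 2 samples")
  if (k > n - 1) stop("k must be at most n - 1")
  set.seed(seed)
  d2 <- as.matrix(stats::dist(samples))
  diag(d2) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(d2[i, ])[seq_len(k)]
  base <- sample.int(n, n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  delta <- stats::runif(n_new)
  neighbor <- nn[cbind(base, pick)]
  out <- samples[base, , drop = FALSE] +
    delta * (samples[neighbor, , drop = FALSE] -
             samples[base, , drop = FALSE])
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  out
}

#' Dataset manifest
#'
#' @param classes named list: class name to character vector of image paths
#'   (or to an in-memory list of image arrays).
#' @param image_size length-2 integer (H, W).
#' @param bit_depth bits per pixel (default 24).
#' @return object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(classes, image_size, bit_depth = 24L) {
  structure(list(classes = classes,
                 image_size = as.integer(image_size),
                 bit_depth = as.integer(bit_depth),
                 counts = vapply(classes, length, integer(1))),
            class = "dataset_manifest")
}

#' Stratified train/test split of a manifest
#'
#' Per class, `floor(fraction * n)` members go to the training manifest and
#' the remainder to the test manifest; the split is a shuffled exact
#' partition, reproducible per seed.
#'
#' @param manifest a [dataset_manifest()].
#' @param fraction train fraction in (0, 1) (default 0.70).
#' @param seed RNG seed.
#' @return list of two manifests, `train` and `test`.
#' @export
split_dataset <- function(manifest, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  tr <- list(); te <- list()
  for (cl in names(manifest$classes)) {
    items <- manifest$classes[[cl]]
    n <- length(items)
    if (n < 2) stop("class ", cl, " has fewer than 2 members")
    idx <- sample.int(n)
    n_tr <- floor(fraction * n)
    tr[[cl]] <- items[idx[seq_len(n_tr)]]
    te[[cl]] <- items[idx[-seq_len(n_tr)]]
  }
  list(train = dataset_manifest(tr, manifest$image_size, manifest$bit_depth),
       test = dataset_manifest(te, manifest$image_size, manifest$bit_depth))
}

#' Synthetic data configuration
#'
#' @param n_classes number of classes.
#' @param mode `"features"` or `"images"`.
#' @param n_per_class images per class (image mode).
#' @param image_size square image side (image mode, default 32).
#' @param n total sample count (feature mode).
#' @param n_features feature-table width D (feature mode).
#' @param n_informative number of informative columns (feature mode); each
#'   informative column shifts the mean of one class (assigned cyclically)
#'   by `effect_size` noise SDs.
#' @param effect_size class-mean shift in SD units (default 3).
#' @param noise_sd within-class SD of every column (default 1).
#' @param seed RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 3L, mode = c("features", "images"),
                         n_per_class = 50L, image_size = 32L,
                         n = 200L, n_features = 12L, n_informative = 3L,
                         effect_size = 3, noise_sd = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_informative <= n_features, n_classes >= 2)
  structure(list(n_classes = as.integer(n_classes), mode = mode,
                 n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 n = as.integer(n), n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic feature table with planted informative columns
#'
#' Informative column j has a class-dependent mean: class
#' `((j - 1) mod C) + 1` is shifted by `effect_size * noise_sd`, so each
#' informative column separates one class from the rest and (for
#' `n_informative <= C`) every informative column is needed for full
#' separation.  Remaining columns are pure noise.  The planted index set is
#' attached as attribute `informative`.
#'
#' @param config a [synth_config()] in feature mode.
#' @return a [feature_matrix()] with attribute `informative`.
#' @export
generate_synthetic_features <- function(config) {
  set.seed(config$seed)
  C <- config$n_classes
  labels <- rep_len(seq_len(C), config$n)
  vals <- matrix(stats::rnorm(config$n * config$n_features,
                              sd = config$noise_sd),
                 config$n, config$n_features)
  info <- seq_len(config$n_informative)
  for (j in info) {
    cl <- ((j - 1) %% C) + 1
    vals[labels == cl, j] <- vals[labels == cl, j] +
      config$effect_size * config$noise_sd
  }
  fm <- feature_matrix(vals, labels, C)
  attr(fm, "informative") <- info
  fm
}

# One lesion-like image: skin-toned background, a colored elliptical blob
# with class-dependent hue/radius, class-dependent sinusoidal texture.
render_lesion_image <- function(size, class_id, n_classes) {
  base <- c(0.85, 0.70, 0.60)                       # skin tone, [0,1] RGB
  hue <- (class_id - 1) / n_classes
  blob_col <- c(0.45 + 0.3 * hue, 0.25 + 0.2 * (1 - hue), 0.20 + 0.1 * hue)
  cx <- stats::runif(1, 0.35, 0.65) * size
  cy <- stats::runif(1, 0.35, 0.65) * size
  rx <- stats::runif(1, 0.18, 0.22 + 0.04 * class_id) * size
  ry <- stats::runif(1, 0.15, 0.20 + 0.03 * class_id) * size
  freq <- 2 + 2 * class_id                           # texture frequency
  xi <- matrix(seq_len(size), size, size)
  yi <- t(xi)
  inside <- ((xi - cx) / rx)^2 + ((yi - cy) / ry)^2 <= 1
  tex <- 0.08 * sin(2 * pi * freq * xi / size) *
    cos(2 * pi * freq * yi / size)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    plane <- base[ch] + tex + stats::rnorm(size^2, sd = 0.02)
    plane[inside] <- blob_col[ch] + tex[inside] +
      stats::rnorm(sum(inside), sd = 0.03)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  img
}

#' Generate a synthetic lesion-like image dataset
#'
#' Per-class sets of images: skin-toned background plus a colored elliptical
#' blob and a sinusoidal texture whose color, radius distribution and
#' frequency depend on the class.  With `dir` set the images are written as
#' PNG files and the manifest lists paths; otherwise the manifest holds the
#' image arrays in memory.
#'
#' @param config a [synth_config()] in image mode.
#' @param dir optional output directory for PNG files.
#' @return a [dataset_manifest()].
#' @export
generate_synthetic_images <- function(config, dir = NULL) {
  set.seed(config$seed)
  classes <- list()
  for (cl in seq_len(config$n_classes)) {
    name <- paste0("class", cl)
    imgs <- lapply(seq_len(config$n_per_class), function(i)
      render_lesion_image(config$image_size, cl, config$n_classes))
    if (!is.null(dir)) {
      cdir <- file.path(dir, name)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      paths <- vapply(seq_along(imgs), function(i) {
        p <- file.path(cdir, sprintf("img%03d.png", i))
        png::writePNG(imgs[[i]], p)
        p
      }, character(1))
      classes[[name]] <- paths
    } else {
      classes[[name]] <- imgs
    }
  }
  dataset_manifest(classes, rep(config$image_size, 2))
}

#' Generate a synthetic dataset per configuration
#'
#' Dispatches on the config mode: feature tables with planted informative
#' columns, or directories of lesion-like images.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory (image mode).
#' @return a [feature_matrix()] or a [dataset_manifest()].
#' @export
generate_synthetic_dataset <- function(config, dir = NULL) {
  if (config$mode == "features") generate_synthetic_features(config)
  else generate_synthetic_images(config, dir)
}

manifest_images <- function(manifest) {
  lapply(manifest$classes, function(items) {
    if (is.character(items)) lapply(items, png::readPNG) else items
  })
}

#' Write / read a dataset manifest as JSON
#'
#' Path-based manifests only (in-memory manifests must be materialized
#' first).
#'
#' @param manifest a [dataset_manifest()] whose classes hold file paths.
#' @param path JSON file.
#' @export
write_manifest_json <- function(manifest, path) {
  stopifnot(all(vapply(manifest$classes, is.character, logical(1))))
  jsonlite::write_json(list(classes = manifest$classes,
                            image_size = manifest$image_size,
                            bit_depth = manifest$bit_depth),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dataset_manifest(as.list(x$classes), x$image_size, x$bit_depth)
}
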