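#' Construct a labelled feature matrix
#'
#' @param values n x D numeric matrix (feature columns may be named).
#' @param labels integer class labels in 1..C.
#' @param n_classes class count C (default: `max(labels)`).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, n_classes = max(labels)) {
  values <- as.matrix(values)
  labels <- as.integer(labels)
  stopifnot(nrow(values) == length(labels),
            all(is.finite(values)),
            all(labels >= 1), all(labels <= n_classes))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, labels = labels,
                 n_classes = as.integer(n_classes)),
            class = "feature_matrix")
}

#' Specification of the feature-selection fitness
#'
#' A candidate subset S is scored by training the inner label-smoothed
#' softmax classifier on the masked columns of an internal stratified train
#' split and returning `-(validation loss + lambda * |S| / D)`, which the
#' swarm maximizes.  Normalizing the cardinality by D makes `lambda`
#' independent of the feature-table width.
#'
#' @param lambda sparsity penalty weight (default 0.01).
#' @param epsilon label-smoothing parameter in \[0, 1) (default 0.1).
#' @param learning_rate,epochs inner gradient-descent settings.
#' @param train_fraction inner stratified train fraction (default 0.7).
#' @param seed seed controlling the internal split (drawn once per selection
#'   run so the fitness is a fixed deterministic function during a search).
#' @return object of class `fitness_spec`.
#' @export
fitness_spec <- function(lambda = 0.01, epsilon = 0.1,
                         learning_rate = 0.5, epochs = 150L,
                         train_fraction = 0.7, seed = 1L) {
  stopifnot(lambda >= 0, epsilon >= 0, epsilon < 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(lambda = lambda, epsilon = epsilon,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "fitness_spec")
}

#' Map a continuous particle position to a binary selection mask
#'
#' Deterministic sigmoid thresholding: bit d is 1 iff `sigmoid(x_d) >= 0.5`,
#' equivalently `x_d >= 0` (ties map to 1).  `rule = "stochastic"` instead
#' draws bit d as Bernoulli(sigmoid(x_d)), the transfer rule of stochastic
#' binary PSO.
#'
#' @param x finite numeric vector.
#' @param rule `"deterministic"` (default) or `"stochastic"`.
#' @return integer 0/1 vector with attribute-free semantics (`sum` is the
#'   cardinality).
#' @export
continuous_to_binary <- function(x, rule = c("deterministic", "stochastic")) {
  rule <- match.arg(rule)
  stopifnot(all(is.finite(x)))
  if (rule == "deterministic") as.integer(x >= 0)
  else as.integer(stats::runif(length(x)) < 1 / (1 + exp(-x)))
}

# Stratified sample of indices: floor(fraction * n) per class into the first
# partition, remainder into the second.
stratified_split_idx <- function(labels, fraction, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 2)
      stop("class ", cl, " has fewer than 2 members; cannot stratify")
    n_tr <- floor(fraction * length(idx))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Internal fitness context: the inner split is frozen once so that fitness
# is a pure function of the mask during a search.
make_fitness_context <- function(data, spec, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(data$labels) else subset
  labels <- data$labels[idx]
  if (length(unique(labels)) < data$n_classes)
    stop("every class must be present for fitness evaluation")
  sp <- stratified_split_idx(labels, spec$train_fraction, spec$seed)
  list(x_train = data$values[idx[sp$train], , drop = FALSE],
       y_train = labels[sp$train],
       x_val = data$values[idx[sp$test], , drop = FALSE],
       y_val = labels[sp$test],
       n_classes = data$n_classes)
}

fitness_from_context <- function(ctx, mask, spec) {
  mask <- as.integer(mask)
  card <- sum(mask)
  if (card == 0) return(-Inf)
  cols <- which(mask == 1)
  model <- fit_softmax(ctx$x_train[, cols, drop = FALSE], ctx$y_train,
                       ctx$n_classes, spec$epsilon,
                       spec$learning_rate, spec$epochs)
  loss <- softmax_loss(model, ctx$x_val[, cols, drop = FALSE], ctx$y_val)
  -(loss + spec$lambda * card / length(mask))
}

#' Fitness of a feature subset
#'
#' Trains the inner classifier on the masked columns of an internal
#' stratified 70/30 split of `data`, evaluates the label-smoothed
#' cross-entropy L on the internal validation part and returns
#' `-(L + lambda * |S|/D)`.  The all-zero mask gets the worst-possible
#' sentinel (`-Inf`): empty subsets are never repaired.
#'
#' @param data a [feature_matrix()].
#' @param mask 0/1 vector of length D.
#' @param spec a [fitness_spec()].
#' @return scalar score (larger is better).
#' @export
selection_fitness <- function(data, mask, spec = fitness_spec()) {
  stopifnot(inherits(data, "feature_matrix"),
            length(mask) == ncol(data$values))
  ctx <- make_fitness_context(data, spec)
  fitness_from_context(ctx, mask, spec)
}

#' QBPSO wrapper feature selection
#'
#' Maximizes [selection_fitness()] over binary masks by running the
#' quantum-behaved swarm on continuous positions in `[-1, 1]^D` mapped
#' through [continuous_to_binary()].  The outer data are first split into a
#' stratified train/test partition; the fitness sees only the training
#' partition (through its own internal split), and the returned held-out
#' metrics come from retraining on the full outer training partition and
#' scoring the untouched outer test partition.
#'
#' @param data a [feature_matrix()].
#' @param spec a [fitness_spec()].
#' @param qconfig a [qbpso_config()] with `dimension = ncol(data$values)`;
#'   defaults to the feature-selection preset (M = 100, 350 iterations).
#' @param outer_split optional list with integer `train` and `test` indices;
#'   by default a stratified 70/30 split seeded by `spec$seed`.
#' @param outer_fraction outer train fraction when `outer_split` is `NULL`.
#' @param binary_rule transfer rule for [continuous_to_binary()].
#' @return object of class `selection_result`: `mask`, `score`,
#'   `per_iteration_scores`, `selected_indices`, `final_metrics` (held-out
#'   [per_class_metrics()] bundle) and `result` (the raw `qbpso_result`).
#' @export
run_selection <- function(data, spec = fitness_spec(), qconfig = NULL,
                          outer_split = NULL, outer_fraction = 0.7,
                          binary_rule = "deterministic") {
  stopifnot(inherits(data, "feature_matrix"))
  D <- ncol(data$values)
  if (D == 0) stop("feature matrix has zero columns")
  if (is.null(qconfig))
    qconfig <- qbpso_config(dimension = D, num_particles = 100L,
                            max_iter = 350L, maximize = TRUE,
                            seed = spec$seed)
  stopifnot(qconfig$dimension == D, qconfig$maximize)
  if (is.null(outer_split))
    outer_split <- stratified_split_idx(data$labels, outer_fraction,
                                        spec$seed)
  ctx <- make_fitness_context(data, spec, subset = outer_split$train)
  objective <- function(x)
    fitness_from_context(ctx, continuous_to_binary(x, binary_rule), spec)
  opt <- qbpso_optimize(objective, qconfig)
  mask <- continuous_to_binary(opt$best_position, binary_rule)
  final <- final_train_test_eval(data, mask, spec, outer_split)
  structure(list(mask = mask,
                 score = opt$best_score,
                 per_iteration_scores = opt$score_trace,
                 selected_indices = which(mask == 1),
                 final_metrics = final,
                 result = opt),
            class = "selection_result")
}

#' Held-out evaluation of a feature subset
#'
#' Retrains the inner classifier on the outer stratified 70/30 training
#' partition restricted to the selected columns and scores the outer test
#' partition, returning the confusion matrix and the full per-class metric
#' suite.
#'
#' @param data a [feature_matrix()].
#' @param mask non-empty 0/1 vector of length D.
#' @param spec a [fitness_spec()].
#' @param outer_split optional precomputed split (list of `train`/`test`
#'   indices); defaults to a stratified split at `outer_fraction` seeded by
#'   `spec$seed`.
#' @param outer_fraction outer train fraction.
#' @return list with `confusion` ([build_confusion()]) and `metrics`
#'   ([per_class_metrics()]).
#' @export
final_train_test_eval <- function(data, mask, spec = fitness_spec(),
                                  outer_split = NULL, outer_fraction = 0.7) {
  stopifnot(inherits(data, "feature_matrix"),
            length(mask) == ncol(data$values))
  if (sum(mask) == 0) stop("empty mask: nothing to evaluate")
  if (is.null(outer_split))
    outer_split <- stratified_split_idx(data$labels, outer_fraction,
                                        spec$seed)
  cols <- which(as.integer(mask) == 1)
  model <- fit_softmax(data$values[outer_split$train, cols, drop = FALSE],
                       data$labels[outer_split$train], data$n_classes,
                       spec$epsilon, spec$learning_rate, spec$epochs)
  pred <- predict(model, data$values[outer_split$test, cols, drop = FALSE])
  cm <- build_confusion(data$labels[outer_split$test], pred, data$n_classes)
  list(confusion = cm, metrics = per_class_metrics(cm))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("QBPSO feature selection\n")
  cat("  selected:", length(x$selected_indices), "of", length(x$mask),
      "features\n")
  cat("  score:", format(x$score), "\n")
  cat("  held-out accuracy:",
      format(x$final_metrics$metrics$overall$accuracy), "\n")
  invisible(x)
}

#' Read / write delimited feature tables
#'
#' Tab-delimited text with a header row of feature names and the final
#' column `label` holding the integer class.
#'
#' @param data a [feature_matrix()].
#' @param path file path.
#' @return `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(data, path) {
  df <- as.data.frame(data$values)
  df$label <- data$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  feature_matrix(as.matrix(df[, -ncol(df), drop = FALSE]), df[[ncol(df)]])
}

#' Serialize a selection mask as JSON
#'
#' @param result a `selection_result` (or compatible list).
#' @param path output file.
#' @param lambda,seed values recorded alongside the mask.
#' @export
write_mask_json <- function(result, path, lambda = NA, seed = NA) {
  jsonlite::write_json(
    list(selected = result$selected_indices,
         D = length(result$mask),
         score = result$score, lambda = lambda, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
}

#' Exhaustively score every mask of a small feature matrix
#'
#' Brute-force oracle for wrapper selection on D <= ~14: evaluates the
#' fitness of all 2^D masks (the empty mask is skipped: it carries the
#' sentinel score).  Returns the best mask and score plus the per-mask loss
#' so different `lambda` values can be rescored without refitting.
#'
#' @param data a [feature_matrix()].
#' @param spec a [fitness_spec()].
#' @param subset optional row subset defining the fitness context (as in a
#'   selection run's outer training partition).
#' @return list with `best_mask`, `best_score`, `masks` (2^D - 1 x D) and
#'   `losses` (validation loss per mask, penalty excluded).
#' @export
exhaustive_selection <- function(data, spec = fitness_spec(), subset = NULL) {
  D <- ncol(data$values)
  stopifnot(D <= 20)
  ctx <- make_fitness_context(data, spec, subset)
  n_masks <- 2^D - 1
  masks <- matrix(0L, n_masks, D)
  losses <- numeric(n_masks)
  for (m in seq_len(n_masks)) {
    bits <- as.integer(intToBits(m))[seq_len(D)]
    masks[m, ] <- bits
    sc <- fitness_from_context(ctx, bits, spec)
    losses[m] <- -sc - spec$lambda * sum(bits) / D
  }
  scores <- -(losses + spec$lambda * rowSums(masks) / D)
  best <- which.max(scores)
  list(best_mask = masks[best, ], best_score = scores[best],
       masks = masks, losses = losses)
}
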