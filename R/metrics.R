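# Confusion-matrix construction and the evaluation suite: per-class
# precision/recall/FNR/F1/specificity/FPR, Matthews correlation (binary and
# macro one-vs-rest), bias-corrected excess kurtosis, and Monte-Carlo run
# aggregation with ANOVA-F and two-sample-t comparisons.

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes:
#' `counts[a, b] = #\{i : true_i = a, pred_i = b\}`.
#'
#' @param true,pred integer label vectors in 1..K, equal length.
#' @param n_classes class count K.
#' @param labels optional class names.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
build_confusion <- function(true, pred, n_classes,
                            labels = paste0("class", seq_len(n_classes))) {
  stopifnot(length(true) == length(pred))
  if (any(c(true, pred) < 1) || any(c(true, pred) > n_classes))
    stop("labels must lie in 1..K")
  cm <- matrix(0L, n_classes, n_classes, dimnames = list(labels, labels))
  for (i in seq_along(true))
    cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Construct a confusion matrix from a count table
#'
#' @param counts K x K nonnegative integer matrix (rows = true class).
#' @param labels optional class names.
#' @return a `confusion_matrix`.
#' @export
as_confusion <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (!is.null(labels)) dimnames(counts) <- list(labels, labels)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

# Per-class one-vs-rest TP/FP/FN/TN tallies.
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class and aggregate classification metrics
#'
#' One-vs-rest precision, recall, FNR, F1, specificity and FPR per class,
#' plus overall accuracy (`trace/total`), misclassification rate, weighted
#' (support-weighted) F1 and the macro one-vs-rest Matthews correlation.
#' Metrics with a zero denominator are reported as `NA` (undefined), never
#' silently as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return list with `per_class` (data frame, Table-style column order:
#'   precision, recall, fnr, f1, specificity, fpr) and `overall` (list with
#'   `accuracy`, `misclassification`, `weighted_f1`, `macc`).
#' @export
per_class_metrics <- function(cm) {
  oc <- ovr_counts(cm)
  precision <- safe_ratio(oc$tp, oc$tp + oc$fp)
  recall <- safe_ratio(oc$tp, oc$tp + oc$fn)
  specificity <- safe_ratio(oc$tn, oc$tn + oc$fp)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(cm)))
  per_class <- data.frame(class = cls,
                          precision = precision,
                          recall = recall,
                          fnr = 1 - recall,
                          f1 = f1,
                          specificity = specificity,
                          fpr = 1 - specificity,
                          row.names = NULL)
  support <- rowSums(cm)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  wf1 <- sum(f1 * support, na.rm = TRUE) / sum(support[!is.na(f1)])
  list(per_class = per_class,
       overall = list(accuracy = acc,
                      misclassification = 1 - acc,
                      weighted_f1 = wf1,
                      macc = matthews_cc(cm)))
}

binary_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' For K = 2 the standard binary formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; any
#' zero-denominator binary term is defined as 0 (the constant-predictor
#' convention).  For K > 2 the default is the macro average of the K
#' one-vs-rest binary coefficients; `method = "multiclass"` computes the
#' generalized multiclass correlation statistic instead.
#'
#' @param cm a `confusion_matrix` (K >= 2).
#' @param method `"macro_ovr"` (default) or `"multiclass"`.
#' @return value in \[-1, 1\].
#' @export
matthews_cc <- function(cm, method = c("macro_ovr", "multiclass")) {
  method <- match.arg(method)
  K <- nrow(cm)
  stopifnot(K >= 2)
  if (method == "multiclass") {
    n <- sum(cm)
    correct <- sum(diag(cm))
    rs <- rowSums(cm); cs <- colSums(cm)
    num <- correct * n - sum(rs * cs)
    den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
    return(if (den == 0) 0 else num / den)
  }
  oc <- ovr_counts(cm)
  if (K == 2) return(binary_mcc(oc$tp[1], oc$tn[1], oc$fp[1], oc$fn[1]))
  mean(vapply(seq_len(K), function(c)
    binary_mcc(oc$tp[c], oc$tn[c], oc$fp[c], oc$fn[c]), numeric(1)))
}

#' Bias-corrected sample excess kurtosis
#'
#' `[n(n+1)/((n-1)(n-2)(n-3))] * sum(((x - mean)/sd)^4)
#'  - 3(n-1)^2/((n-2)(n-3))` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector of length >= 4 with positive variance.
#' @return scalar excess kurtosis (0 for a normal population,
#'   asymptotically).
#' @export
kurtosis_excess <- function(x) {
  n <- length(x)
  if (n < 4) stop("kurtosis needs at least 4 observations")
  s <- stats::sd(x)
  if (s == 0) stop("kurtosis undefined for a constant series")
  z <- (x - mean(x)) / s
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Aggregate Monte-Carlo run records
#'
#' MIN/MAX/mean/Std (sample SD) over the per-run objective values, excess
#' kurtosis when at least 4 non-constant runs are available, and the same
#' statistics for elapsed time when recorded.
#'
#' @param records data frame with columns `fval` and optionally `seconds`,
#'   `accuracy`, `n_selected` (one row per independent run).
#' @return object of class `run_stats`: list of named statistic vectors.
#' @export
summarize_runs <- function(records) {
  if (NROW(records) < 1) stop("no run records")
  stat_block <- function(x) {
    kur <- if (length(x) >= 4 && stats::sd(x) > 0) kurtosis_excess(x)
           else NA_real_
    c(min = min(x), max = max(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0, kur = kur)
  }
  out <- list(fval = stat_block(records$fval), n_runs = NROW(records))
  if (!is.null(records$seconds)) out$seconds <- stat_block(records$seconds)
  if (!is.null(records$accuracy)) out$accuracy <- stat_block(records$accuracy)
  structure(out, class = "run_stats")
}

#' One-way ANOVA F test across run groups
#'
#' Standard between/within mean-square ratio with its F-distribution
#' p-value (via [stats::oneway.test()] with equal variances).  Identical
#' groups (zero between-group variance) return F = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors (each length >= 2).
#' @return list with `statistic` and `p.value`.
#' @export
anova_f <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  means <- vapply(groups, mean, numeric(1))
  if (max(means) == min(means))
    return(list(statistic = 0, p.value = 1))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value))
}

#' Two-sample t test between optimizer run sets
#'
#' Student's pooled-variance two-sample t by default (paired optional), via
#' [stats::t.test()].  Zero pooled variance with equal means returns t = 0.
#'
#' @param a,b numeric vectors (length >= 2; equal lengths when paired).
#' @param paired logical.
#' @return list with `statistic` and `p.value`.
#' @export
two_sample_t <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired test requires equal lengths")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(statistic = 0, p.value = 1))
  tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p.value = unname(tt$p.value))
}

#' Write / read a confusion matrix as delimited text
#'
#' Integer grid with a header row of class names.
#'
#' @param cm a `confusion_matrix`.
#' @param path file path.
#' @export
write_confusion <- function(cm, path) {
  utils::write.table(as.data.frame(unclass(cm)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  as_confusion(as.matrix(df), labels = colnames(df))
}

#' Write a per-class metric report as delimited text
#'
#' Columns mirror the standard report order: Precision, Recall, FNR, F1,
#' Specificity, FPR.
#'
#' @param metrics output of [per_class_metrics()].
#' @param path file path.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.table(metrics$per_class, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @export
print.run_stats <- function(x, ...) {
  cat("Monte-Carlo run statistics (", x$n_runs, " runs)\n", sep = "")
  print(round(x$fval, 6))
  invisible(x)
}
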