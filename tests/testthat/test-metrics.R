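test_that("confusion matrices tally true-by-predicted counts", {
  cm <- build_confusion(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  perfect <- build_confusion(c(1, 2, 3, 3), c(1, 2, 3, 3), 3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(diag(perfect), c(1, 1, 2), ignore_attr = TRUE)
  expect_error(build_confusion(c(1, 4), c(1, 1), 3), "1..K")
})

test_that("per-class metrics reproduce printed benchmark arithmetic", {
  # 7-class matrix with the published diagonal counts: AKIC 1989/2000,
  # MV 6692/6705; off-diagonal spill placed in the next column
  rows <- c(2000, 2000, 2000, 2000, 2000, 6705, 2000)
  diags <- c(1989, 1991, 1990, 1989, 1992, 6692, 1990)
  cm <- matrix(0, 7, 7)
  for (i in 1:7) {
    cm[i, i] <- diags[i]
    cm[i, (i %% 7) + 1] <- cm[i, (i %% 7) + 1] + rows[i] - diags[i]
  }
  m <- per_class_metrics(as_confusion(cm, labels = c(
    "AKIC", "BCC", "BKL", "DF", "MEL", "MV", "VL")))
  expect_equal(m$per_class$recall[1], 0.9945)
  expect_equal(round(m$per_class$recall[6], 4), 0.9981)
  expect_equal(round(m$per_class$fnr[6], 4), 0.0019)
  expect_equal(m$per_class$recall + m$per_class$fnr, rep(1, 7))
  expect_equal(m$per_class$specificity + m$per_class$fpr, rep(1, 7))
  expect_equal(m$overall$accuracy, sum(diags) / sum(rows))
  expect_equal(m$overall$accuracy + m$overall$misclassification, 1)
})

test_that("degenerate metric denominators are reported as missing, not zero", {
  # class 2 never predicted, class 3 has no members
  cm <- as_confusion(rbind(c(5, 0, 0), c(2, 0, 0), c(0, 0, 0)))
  m <- per_class_metrics(cm)
  expect_true(is.na(m$per_class$precision[2]))
  expect_true(is.na(m$per_class$recall[3]))
  # perfect single-class prediction
  p <- per_class_metrics(as_confusion(rbind(c(4, 0), c(0, 3))))
  expect_equal(p$per_class$precision, c(1, 1))
  expect_equal(p$per_class$fnr, c(0, 0))
  expect_equal(p$per_class$fpr, c(0, 0))
})

test_that("per-class metrics are equivariant under class relabeling", {
  set.seed(2)
  cm <- matrix(rpois(16, 20), 4, 4)
  perm <- c(3, 1, 4, 2)
  m1 <- per_class_metrics(as_confusion(cm))$per_class
  m2 <- per_class_metrics(as_confusion(cm[perm, perm]))$per_class
  for (col in c("precision", "recall", "f1", "specificity"))
    expect_equal(sort(m2[[col]]), sort(m1[[col]]))
})

test_that("Matthews correlation matches its binary closed forms", {
  expect_equal(matthews_cc(as_confusion(rbind(c(10, 0), c(0, 7)))), 1)
  # constant predictor: zero-denominator convention gives 0
  expect_equal(matthews_cc(as_confusion(rbind(c(6, 0), c(3, 0)))), 0)
  # TP=6, TN=3, FP=1, FN=2 (class 1 positive)
  cm <- as_confusion(rbind(c(6, 2), c(1, 3)))
  expect_equal(matthews_cc(cm), 16 / sqrt(7 * 8 * 4 * 5))
  expect_equal(matthews_cc(cm), 0.4780914, tolerance = 1e-6)
  expect_gte(matthews_cc(cm), -1)
  expect_lte(matthews_cc(cm), 1)
  # macro one-vs-rest and generalized multiclass agree on perfection
  p3 <- as_confusion(diag(c(4, 5, 6)))
  expect_equal(matthews_cc(p3), 1)
  expect_equal(matthews_cc(p3, method = "multiclass"), 1)
})

test_that("excess kurtosis matches the bias-corrected formula and its oracles", {
  expect_equal(kurtosis_excess(1:10), -1.2)
  set.seed(0)
  for (i in 1:100) {
    x <- rnorm(sample(10:60, 1), sd = runif(1, 0.5, 3))
    expect_equal(kurtosis_excess(x), brute_kurtosis(x), tolerance = 1e-10)
  }
  # cross-check against the independent e1071 implementation
  set.seed(1)
  y <- rexp(50)
  expect_equal(kurtosis_excess(y), e1071::kurtosis(y, type = 2),
               tolerance = 1e-12)
  set.seed(0)
  big <- rnorm(1e5)
  expect_lt(abs(kurtosis_excess(big)), 0.05)
  expect_error(kurtosis_excess(rep(2, 10)), "constant")
  expect_error(kurtosis_excess(c(1, 2, 3)), "at least 4")
})

test_that("run summaries aggregate MIN/MAX/mean/Std/Kur correctly", {
  one <- summarize_runs(data.frame(fval = 0.25))
  expect_equal(unname(one$fval[c("min", "max", "mean", "sd")]),
               c(0.25, 0.25, 0.25, 0))
  s <- summarize_runs(data.frame(fval = c(1, 2, 3),
                                 seconds = c(10, 12, 11)))
  expect_equal(unname(s$fval["mean"]), 2)
  expect_equal(unname(s$fval["sd"]), 1)
  expect_equal(unname(s$seconds["max"]), 12)
  set.seed(5)
  r <- data.frame(fval = rexp(30))
  st <- summarize_runs(r)
  expect_lte(st$fval["min"], st$fval["mean"])
  expect_lte(st$fval["mean"], st$fval["max"])
  expect_equal(unname(st$fval["kur"]), brute_kurtosis(r$fval))
  expect_error(summarize_runs(data.frame()), "no run")
})

test_that("ANOVA F and two-sample t match hand computation", {
  expect_equal(anova_f(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  g <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(anova_f(g)$statistic, brute_f(g))
  expect_equal(anova_f(g)$statistic, 13.5)
  set.seed(6)
  for (i in 1:10) {
    gs <- list(rnorm(5), rnorm(7, 1), rnorm(6, -1))
    expect_gte(anova_f(gs)$statistic, 0)
    expect_equal(anova_f(gs)$statistic, brute_f(gs), tolerance = 1e-10)
  }
  a <- c(1, 2, 3); b <- c(3, 4, 5)
  expect_equal(two_sample_t(a, a)$statistic, 0)
  expect_equal(two_sample_t(a, b)$statistic, -two_sample_t(b, a)$statistic)
  expect_equal(two_sample_t(a, b)$statistic, brute_t(a, b))
  expect_equal(two_sample_t(a, b)$statistic, -sqrt(6), tolerance = 1e-10)
  expect_error(two_sample_t(a, c(1, 2), paired = TRUE), "equal lengths")
})

test_that("confusion matrices and metric tables round-trip as delimited text", {
  cm <- as_confusion(rbind(c(6, 2), c(1, 3)), labels = c("pos", "neg"))
  tf <- tempfile(fileext = ".tsv")
  write_confusion(cm, tf)
  back <- read_confusion(tf)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
  mt <- tempfile(fileext = ".tsv")
  write_metrics_table(per_class_metrics(cm), mt)
  tab <- read.delim(mt)
  expect_identical(names(tab)[2:7], c("precision", "recall", "fnr", "f1",
                                      "specificity", "fpr"))
})
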