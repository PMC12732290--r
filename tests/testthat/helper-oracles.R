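# Independent oracles used across the suite. These deliberately re-derive
# quantities with different arithmetic than the package code paths.

# Excess kurtosis, brute force: explicit moment sums, no shared helpers.
brute_kurtosis <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  s2 <- sum((x - mu)^2) / (n - 1)
  m4 <- sum((x - mu)^4)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * m4 / s2^2 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# Pooled-variance two-sample t statistic by hand.
brute_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# One-way ANOVA F statistic by hand.
brute_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Minimum distance from point p to segment [a, b].
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  den <- sum(ab^2)
  t <- if (den == 0) 0 else max(0, min(1, sum((p - a) * ab) / den))
  sqrt(sum((p - (a + t * ab))^2))
}

# Small planted feature table shared by selection tests.
planted_features <- function(n = 200, D = 12, informative = 3, seed = 1,
                             effect = 3) {
  generate_synthetic_features(
    synth_config(n_classes = 3, n = n, n_features = D,
                 n_informative = informative, effect_size = effect,
                 seed = seed))
}

# Minimal initialized single-block spec with controllable weights.
tiny_mbconv <- function(c_in = 2, c_out = 2, expansion = 1, kernel = 1,
                        stride = 1, seed = 7) {
  set.seed(seed)
  init_mbconv_weights(mbconv_spec(c_in, c_out, expansion, kernel, stride))
}
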