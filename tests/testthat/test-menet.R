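test_that("swish matches its closed forms", {
  expect_identical(swish(0), 0)
  expect_lt(abs(swish(20) - 20), 1e-6)
  expect_equal(swish(1), 1 / (1 + exp(-1)))
  expect_equal(swish(c(-1, 0, 2)), c(-1, 0, 2) / (1 + exp(-c(-1, 0, 2))))
})

test_that("1x1 expansion grows channels and respects identity weights", {
  spec <- tiny_mbconv(c_in = 2, expansion = 6)
  spec$weights$w_exp <- matrix(rnorm(2 * 12), 2, 12)
  x <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  z <- expand_channels(x, spec)
  expect_equal(dim(z), c(3, 3, 12))
  # t = 1 with identity weights reduces to swish(X)
  id <- tiny_mbconv(c_in = 2, expansion = 1)
  id$weights$w_exp <- diag(2)
  expect_equal(expand_channels(x, id), swish(x))
  expect_equal(expand_channels(array(0, c(3, 3, 2)), spec),
               array(0, c(3, 3, 12)))
  expect_error(expand_channels(array(0, c(3, 3, 5)), spec), "channels")
})

test_that("depthwise convolution matches hand arithmetic", {
  # k = 1 with unit filters is the identity before activation
  spec <- tiny_mbconv(c_in = 3, expansion = 1, kernel = 1)
  spec$weights$w_dw <- array(1, c(1, 1, 3))
  z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(depthwise_conv(z, spec), swish(z))
  # constant field, filter summing to 1: interior stays at swish(constant)
  s3 <- tiny_mbconv(c_in = 1, expansion = 1, kernel = 3)
  s3$weights$w_dw <- array(1 / 9, c(3, 3, 1))
  zc <- array(5, c(5, 5, 1))
  out <- depthwise_conv(zc, s3)
  expect_equal(out[3, 3, 1], swish(5))
  # hand-specified 3x3 filter and patch at the center position
  filt <- matrix(c(1, 0, -1, 2, 0.5, -2, 1, 0, -1), 3, 3)
  s3$weights$w_dw <- array(filt, c(3, 3, 1))
  patch <- matrix(seq(0.1, 0.9, by = 0.1), 3, 3)
  zp <- array(patch, c(3, 3, 1))
  pre <- sum(patch * filt)
  expect_equal(depthwise_conv(zp, s3)[2, 2, 1], swish(pre))
  spec_even <- tiny_mbconv(c_in = 1, expansion = 1, kernel = 1)
  spec_even$kernel <- 2L
  expect_error(depthwise_conv(zc, spec_even), "odd")
})

test_that("squeeze-excitation pools, gates in (0,1) and can be an exact identity", {
  spec <- tiny_mbconv(c_in = 2, expansion = 1)
  z <- array(abs(rnorm(4 * 4 * 2)) + 0.5, c(4, 4, 2))
  # saturated second layer: sigmoid gate is exactly 1 in double precision
  spec$weights$w1 <- diag(2)
  spec$weights$w2 <- matrix(100, 2, 2)
  expect_identical(squeeze_excite(z, spec), z)
  # pooled descriptor of a constant channel is that constant
  zc <- array(5, c(3, 3, 1))
  expect_equal(apply(zc, 3, mean), 5)
  # hand evaluation on a 1x1x2 map
  h <- tiny_mbconv(c_in = 2, expansion = 1)
  h$weights$w1 <- matrix(c(0.5, -0.3, 0.2, 0.4), 2, 2)
  h$weights$w2 <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  zm <- array(c(2, -1), c(1, 1, 2))
  pool <- c(2, -1)
  a <- pmax(h$weights$w1 %*% pool, 0)
  gate <- 1 / (1 + exp(-(h$weights$w2 %*% a)))
  expect_equal(as.numeric(squeeze_excite(zm, h)),
               as.numeric(gate) * c(2, -1))
  expect_true(all(gate > 0 & gate < 1))
  # printed-form (ReLU-outer) alternative stays available
  lit <- squeeze_excite(zm, h, literal_gate = TRUE)
  expect_true(all(is.finite(lit)))
})

test_that("projection is linear with a guarded residual", {
  spec <- tiny_mbconv(c_in = 2, c_out = 2, expansion = 1, stride = 2)
  spec$weights$w_proj <- diag(2)
  z <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_equal(project_channels(z, spec), z)
  # zero projection with residual returns the block input
  r <- tiny_mbconv(c_in = 2, c_out = 2, expansion = 1, stride = 1)
  r$weights$w_proj <- matrix(0, 2, 2)
  x_in <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_equal(project_channels(z, r, x_in), x_in)
  # hand dot product on a 1x1x2 map projected to one channel
  p <- tiny_mbconv(c_in = 2, c_out = 1, expansion = 1)
  p$weights$w_proj <- matrix(c(0.3, -0.7), 2, 1)
  zm <- array(c(2, 4), c(1, 1, 2))
  expect_equal(as.numeric(project_channels(zm, p)), 2 * 0.3 + 4 * (-0.7))
  bad <- tiny_mbconv(c_in = 2, c_out = 1, expansion = 1)
  expect_error(project_channels(z, bad, x_in), "residual")
})

test_that("self-attention is row-stochastic, mean-collapsing and permutation-equivariant", {
  set.seed(21)
  attn <- dermselect:::init_attention_weights(attention_spec(3))
  # zero queries give uniform attention; identity values collapse to the mean
  attn$weights$w_q <- matrix(0, 3, 3)
  attn$weights$w_v <- diag(3)
  x <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  out <- self_attention_refine(x, attn)
  mean_tok <- colMeans(matrix(x, 4, 3))
  for (i in 1:2) for (j in 1:2)
    expect_equal(as.numeric(out[i, j, ]), mean_tok)
  # a single spatial token returns its value projection
  attn2 <- dermselect:::init_attention_weights(attention_spec(3))
  x1 <- array(rnorm(3), c(1, 1, 3))
  expect_equal(as.numeric(self_attention_refine(x1, attn2)),
               as.numeric(matrix(x1, 1, 3) %*% attn2$weights$w_v))
  # permuting spatial positions permutes outputs identically
  attn3 <- dermselect:::init_attention_weights(attention_spec(3))
  tok <- matrix(x, 4, 3)
  perm <- c(3, 1, 4, 2)
  xp <- array(tok[perm, ], c(2, 2, 3))
  op <- matrix(self_attention_refine(xp, attn3), 4, 3)
  o <- matrix(self_attention_refine(x, attn3), 4, 3)
  expect_equal(op, o[perm, ])
})

test_that("compound scaling obeys its closed forms and balance constraint", {
  expect_equal(unname(compound_scale(1.2, 1.1, 1.15, 0)), c(1, 1, 1))
  expect_equal(unname(compound_scale(1.2, 1.1, 1.15, 2)["dept"]), 1.44)
  expect_equal(1.2 * 1.1^2 * 1.15^2, 1.92027, tolerance = 1e-5)
  expect_silent(compound_scale(1.2, 1.1, 1.15, 1))
  expect_warning(compound_scale(1.5, 1.3, 1.3, 1), "outside")
  expect_error(compound_scale(1.5, 1.3, 1.3, 1, check = "error"), "outside")
})

test_that("MAC counting matches hand formulas and an independent recount", {
  empty <- list(stem = NULL, blocks = list(), attention = FALSE,
                num_classes = 0L, feature_dim = 0L, in_channels = 0L)
  expect_identical(count_flops(empty, 4), 0)
  one_conv <- list(stem = list(filters = 3L, kernel = 1L, stride = 1L),
                   blocks = list(), attention = FALSE, num_classes = 0L,
                   feature_dim = 3L, in_channels = 2L)
  expect_identical(count_flops(one_conv, 4), 4 * 4 * 2 * 3)
  # independent per-layer recount on random specs
  set.seed(31)
  for (rep in 1:5) {
    widths <- sample(4:12, 3)
    cin <- sample(4:8, 1)
    ks <- sample(c(3L, 5L), 3, replace = TRUE)
    ss <- sample(c(1L, 2L), 3, replace = TRUE)
    blocks <- list(); c_prev <- cin
    for (i in 1:3) {
      blocks[[i]] <- mbconv_spec(c_prev, widths[i], expansion = 6,
                                 kernel = ks[i], stride = ss[i])
      c_prev <- widths[i]
    }
    net <- network_spec(list(filters = cin, kernel = 3L, stride = 1L),
                        blocks, attention = FALSE, num_classes = 2L,
                        in_channels = 3L)
    hin <- 16
    expected <- ceiling(hin / 1)^2 * 9 * 3 * cin
    h <- hin; cp <- cin
    for (i in 1:3) {
      tc <- 6 * cp
      expected <- expected + h^2 * cp * tc
      h <- ceiling(h / ss[i])
      expected <- expected + h^2 * ks[i]^2 * tc +
        2 * tc * ceiling(0.25 * cp) + h^2 * tc * widths[i]
      cp <- widths[i]
    }
    expected <- expected + widths[3] * 2
    expect_identical(count_flops(net, hin), expected)
  }
})

test_that("compound-scaled networks roughly double their MACs per increment", {
  base <- network_spec(
    list(filters = 48L, kernel = 3L, stride = 1L),
    list(mbconv_spec(48, 64, 6, 3, 1), mbconv_spec(64, 64, 6, 5, 2),
         mbconv_spec(64, 96, 6, 3, 1), mbconv_spec(96, 96, 6, 5, 2)),
    attention = FALSE, num_classes = 3L, in_channels = 3L)
  c0 <- compound_scale(1.2, 1.1, 1.15, 0)
  c1 <- compound_scale(1.2, 1.1, 1.15, 1)
  s0 <- scale_network_spec(base, c0, 64, base_repeats = c(5, 5, 5, 5))
  s1 <- scale_network_spec(base, c1, 64, base_repeats = c(5, 5, 5, 5))
  ratio <- count_flops(s1$net, s1$input_size) /
    count_flops(s0$net, s0$input_size)
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("label-smoothed cross-entropy matches closed forms", {
  # extreme logits on the true class, no smoothing: zero loss
  logits <- rbind(c(1e4, 0, 0, 0), c(0, 1e4, 0, 0))
  expect_equal(label_smoothed_cross_entropy(logits, c(1, 2), 0), 0)
  # uniform logits, C = 4: log 4
  expect_equal(label_smoothed_cross_entropy(matrix(0, 3, 4), c(1, 2, 3), 0),
               log(4))
  # hand case: eps = 0.1, C = 2, probabilities (0.9, 0.1), true class 1
  lg <- matrix(c(log(0.9), log(0.1)), 1, 2)
  expect_equal(label_smoothed_cross_entropy(lg, 1, 0.1),
               -(0.95 * log(0.9) + 0.05 * log(0.1)))
  expect_equal(label_smoothed_cross_entropy(lg, 1, 0.1), 0.2152217,
               tolerance = 1e-6)
  expect_error(label_smoothed_cross_entropy(lg, 3, 0.1), "label")
})

test_that("analytic softmax-head gradients match central finite differences", {
  set.seed(13)
  for (rep in 1:3) {
    x <- matrix(rnorm(5 * 3), 5, 3)
    y <- sample(1:3, 5, replace = TRUE)
    W <- matrix(rnorm(4 * 3, sd = 0.5), 4, 3)
    an <- dermselect:::softmax_head_loss_grad(W, x, y, 3, 0.1)
    h <- 1e-6
    num <- W * 0
    for (i in seq_along(W)) {
      Wp <- W; Wm <- W
      Wp[i] <- Wp[i] + h; Wm[i] <- Wm[i] - h
      num[i] <- (dermselect:::softmax_head_loss_grad(Wp, x, y, 3, 0.1)$loss -
                 dermselect:::softmax_head_loss_grad(Wm, x, y, 3, 0.1)$loss) /
        (2 * h)
    }
    expect_lt(max(abs(num - an$grad)) / max(abs(an$grad)), 1e-5)
  }
})

test_that("extracted features are finite, deterministic and batch-equivariant", {
  net <- menet_init(default_menet_spec(num_classes = 2, seed = 17,
                                       widths = c(8, 12, 12, 16, 16, 24, 24)))
  imgs <- c(list(array(0, c(16, 16, 3))),
            lapply(1:3, function(i) {
              set.seed(40 + i); array(runif(16 * 16 * 3), c(16, 16, 3))
            }))
  imgs[[5]] <- imgs[[2]]
  f <- extract_features(imgs, net)
  expect_true(all(is.finite(f)))
  expect_equal(f[2, ], f[5, ])
  expect_equal(extract_features(imgs, net), f)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(extract_features(imgs[perm], net), f[perm, ],
               ignore_attr = TRUE)
  expect_error(extract_features(list(array(0, c(16, 16, 2))), net),
               "channels")
})

test_that("features of texturally distinct classes support above-chance classification", {
  cfg <- synth_config(mode = "images", n_classes = 2, n_per_class = 30,
                      image_size = 16, seed = 19)
  man <- generate_synthetic_images(cfg)
  flat <- dermselect:::flatten_manifest(man)
  net <- menet_init(default_menet_spec(num_classes = 2, seed = 19,
                                       widths = c(8, 12, 12, 16, 16, 24, 24)))
  fm <- feature_matrix(extract_features(flat$images, net), flat$labels, 2)
  ev <- final_train_test_eval(fm, rep(1, ncol(fm$values)),
                              fitness_spec(seed = 19))
  n_test <- sum(ev$confusion)
  expect_gt(ev$metrics$overall$accuracy, 0.5 + 3 * sqrt(0.25 / n_test))
})
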