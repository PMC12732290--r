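# Compact EfficientNet-style feature extractor: mobile inverted bottleneck
# (MBConv) blocks with squeeze-and-excitation, swish activations, a
# self-attention refinement over spatial tokens, compound scaling and FLOP
# accounting. Feature maps are H x W x C arrays (channels-last); convolutions
# use "same" padding and 0-based spatial offset conventions.

#' Swish activation
#'
#' Elementwise `t * sigmoid(t)`.
#'
#' @param t numeric scalar or array.
#' @return same shape as `t`.
#' @export
swish <- function(t) t / (1 + exp(-t))

relu <- function(t) pmax(t, 0)

sigmoid <- function(t) 1 / (1 + exp(-t))

# "Same" padding for a k x k kernel at a given stride (TF convention:
# out = ceiling(in / stride), extra padding goes to the bottom/right).
pad_same <- function(x, k, stride) {
  d <- dim(x)
  ho <- ceiling(d[1] / stride); wo <- ceiling(d[2] / stride)
  ph <- max(0, (ho - 1) * stride + k - d[1])
  pw <- max(0, (wo - 1) * stride + k - d[2])
  xp <- array(0, c(d[1] + ph, d[2] + pw, d[3]))
  xp[(ph %/% 2) + seq_len(d[1]), (pw %/% 2) + seq_len(d[2]), ] <- x
  xp
}

# Full convolution via im2col; W is a k x k x Cin x Cout array.
conv2d <- function(x, W, stride = 1) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  stopifnot(dim(x)[3] == cin)
  ho <- ceiling(dim(x)[1] / stride); wo <- ceiling(dim(x)[2] / stride)
  xp <- pad_same(x, k, stride)
  ri <- (seq_len(ho) - 1) * stride + 1
  ci <- (seq_len(wo) - 1) * stride + 1
  patches <- matrix(0, ho * wo, k * k * cin)
  col <- 1L
  for (c in seq_len(cin)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    patches[, col] <- xp[ri + di, ci + dj, c]
    col <- col + 1L
  }
  array(patches %*% matrix(W, k * k * cin, cout), c(ho, wo, cout))
}

# Depthwise convolution: one k x k filter per channel; W is k x k x C.
depthwise2d <- function(x, W, stride = 1) {
  k <- dim(W)[1]; ch <- dim(W)[3]
  stopifnot(dim(x)[3] == ch)
  ho <- ceiling(dim(x)[1] / stride); wo <- ceiling(dim(x)[2] / stride)
  xp <- pad_same(x, k, stride)
  ri <- (seq_len(ho) - 1) * stride + 1
  ci <- (seq_len(wo) - 1) * stride + 1
  out <- array(0, c(ho, wo, ch))
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    out <- out + sweep(xp[ri + di, ci + dj, , drop = FALSE], 3,
                       W[di + 1, dj + 1, ], "*")
  }
  out
}

#' Mobile inverted bottleneck block specification
#'
#' Hyperparameters and (optionally) weights of one MBConv block: 1x1
#' channel expansion by factor `expansion`, depthwise `kernel` x `kernel`
#' convolution at `stride`, squeeze-and-excitation gating squeezed to
#' `ceiling(se_ratio * c_in)` units, linear 1x1 projection, and a residual
#' connection when `stride == 1` and `c_in == c_out`.
#'
#' @param c_in,c_out input/output channel counts.
#' @param expansion positive integer expansion ratio t (default 6, the
#'   MBConv6 setting).
#' @param kernel odd depthwise kernel size (3 or 5).
#' @param stride 1 or 2.
#' @param se_ratio squeeze ratio in (0, 1] (default 0.25).
#' @param weights optional weight list (see [init_mbconv_weights()]).
#' @return object of class `mbconv_spec`.
#' @export
mbconv_spec <- function(c_in, c_out, expansion = 6L, kernel = 3L,
                        stride = 1L, se_ratio = 0.25, weights = NULL) {
  stopifnot(c_in >= 1, c_out >= 1, expansion >= 1,
            kernel %% 2 == 1, stride %in% c(1L, 2L),
            se_ratio > 0, se_ratio <= 1)
  structure(list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 expansion = as.integer(expansion),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 se_ratio = se_ratio, weights = weights),
            class = "mbconv_spec")
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialize MBConv weights (He-uniform, current RNG state)
#'
#' @param spec an [mbconv_spec()].
#' @return the spec with a populated `weights` list: `w_exp`
#'   (c_in x t*c_in), `w_dw` (k x k x t*c_in), `w1`
#'   (se_dim x t*c_in), `w2` (t*c_in x se_dim), `w_proj`
#'   (t*c_in x c_out).
#' @export
init_mbconv_weights <- function(spec) {
  tc <- spec$expansion * spec$c_in
  se_dim <- ceiling(spec$se_ratio * spec$c_in)
  spec$weights <- list(
    w_exp = he_uniform(c(spec$c_in, tc), spec$c_in),
    w_dw = he_uniform(c(spec$kernel, spec$kernel, tc), spec$kernel^2),
    w1 = he_uniform(c(se_dim, tc), tc),
    w2 = he_uniform(c(tc, se_dim), se_dim),
    w_proj = he_uniform(c(tc, spec$c_out), tc))
  spec
}

as_channels_matrix <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

#' 1x1 channel expansion
#'
#' `Z = swish(X * W_exp)`: pointwise convolution from `c_in` to
#' `expansion * c_in` channels; spatial size unchanged.
#'
#' @param x H x W x c_in array.
#' @param spec an initialized [mbconv_spec()].
#' @return H x W x (expansion * c_in) array.
#' @export
expand_channels <- function(x, spec) {
  d <- dim(x)
  if (d[3] != spec$c_in)
    stop("input has ", d[3], " channels, spec expects ", spec$c_in)
  z <- as_channels_matrix(x) %*% spec$weights$w_exp
  array(swish(z), c(d[1], d[2], ncol(z)))
}

#' Depthwise convolution stage
#'
#' `Z_dw = swish(Z (.) W_dw)`: one k x k filter per channel at the block
#' stride with "same" padding; channel count preserved.
#'
#' @param z H x W x (expansion * c_in) array.
#' @param spec an initialized [mbconv_spec()].
#' @return array with spatial size `ceiling(H/stride)` etc.
#' @export
depthwise_conv <- function(z, spec) {
  if (spec$kernel %% 2 == 0) stop("depthwise kernel must be odd")
  tc <- spec$expansion * spec$c_in
  if (dim(z)[3] != tc)
    stop("input has ", dim(z)[3], " channels, expected ", tc)
  swish(depthwise2d(z, spec$weights$w_dw, spec$stride))
}

#' Squeeze-and-excitation recalibration
#'
#' Global average pooling per channel, a bottleneck MLP, and a sigmoid gate
#' multiplying each channel: `gate = sigmoid(W2 relu(W1 pool))`, entries in
#' (0, 1).  `literal_gate = TRUE` instead applies the reversed operator
#' order `relu(W2 sigmoid(W1 pool))` (unbounded gate; kept as a documented
#' alternative, not the default).
#'
#' @param z_dw H x W x (expansion * c_in) array.
#' @param spec an initialized [mbconv_spec()].
#' @param literal_gate use the reversed (ReLU-outer) operator order.
#' @return array of the same shape as `z_dw`.
#' @export
squeeze_excite <- function(z_dw, spec, literal_gate = FALSE) {
  pool <- apply(z_dw, 3, mean)
  gate <- if (literal_gate)
    relu(spec$weights$w2 %*% sigmoid(spec$weights$w1 %*% pool))
  else
    sigmoid(spec$weights$w2 %*% relu(spec$weights$w1 %*% pool))
  sweep(z_dw, 3, as.numeric(gate), "*")
}

#' Linear 1x1 projection with optional residual
#'
#' Projects `expansion * c_in` channels down to `c_out` with no activation;
#' adds `x_input` elementwise when supplied, which requires `stride == 1`
#' and `c_in == c_out`.
#'
#' @param z_se H x W x (expansion * c_in) array.
#' @param spec an initialized [mbconv_spec()].
#' @param x_input optional block input for the residual connection.
#' @return H x W x c_out array.
#' @export
project_channels <- function(z_se, spec, x_input = NULL) {
  tc <- spec$expansion * spec$c_in
  if (dim(z_se)[3] != tc)
    stop("input has ", dim(z_se)[3], " channels, expected ", tc)
  d <- dim(z_se)
  out <- array(as_channels_matrix(z_se) %*% spec$weights$w_proj,
               c(d[1], d[2], spec$c_out))
  if (!is.null(x_input)) {
    if (spec$stride != 1 || spec$c_in != spec$c_out ||
        !all(dim(x_input) == dim(out)))
      stop("residual connection requires stride 1 and c_in == c_out")
    out <- out + x_input
  }
  out
}

#' Full MBConv block forward pass
#'
#' Expansion, depthwise convolution, squeeze-excitation, projection, with
#' the residual applied automatically when `stride == 1` and
#' `c_in == c_out`.
#'
#' @param x H x W x c_in array.
#' @param spec an initialized [mbconv_spec()].
#' @return H x W x c_out array (spatially strided).
#' @export
mbconv_forward <- function(x, spec) {
  z <- expand_channels(x, spec)
  z <- depthwise_conv(z, spec)
  z <- squeeze_excite(z, spec)
  resid <- if (spec$stride == 1 && spec$c_in == spec$c_out) x else NULL
  project_channels(z, spec, resid)
}

#' Self-attention head specification
#'
#' @param channels token dimension C.
#' @param d_k key/query dimension (default `channels`).
#' @param weights optional list with `w_q`, `w_k` (C x d_k) and `w_v`
#'   (C x C).
#' @return object of class `attention_spec`.
#' @export
attention_spec <- function(channels, d_k = channels, weights = NULL) {
  structure(list(channels = as.integer(channels), d_k = as.integer(d_k),
                 weights = weights),
            class = "attention_spec")
}

init_attention_weights <- function(attn) {
  attn$weights <- list(w_q = he_uniform(c(attn$channels, attn$d_k),
                                        attn$channels),
                       w_k = he_uniform(c(attn$channels, attn$d_k),
                                        attn$channels),
                       w_v = he_uniform(c(attn$channels, attn$channels),
                                        attn$channels))
  attn
}

row_softmax_r <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Self-attention refinement of a feature map
#'
#' Single-head scaled dot-product attention over the H*W spatial positions,
#' each position a C-vector token: `softmax(Q K' / sqrt(d_k)) V` with the
#' attention rows summing to one.  Output shape equals the input shape.
#'
#' @param feature_map H x W x C array.
#' @param attn an initialized [attention_spec()].
#' @return H x W x C array.
#' @export
self_attention_refine <- function(feature_map, attn) {
  d <- dim(feature_map)
  stopifnot(d[3] == attn$channels)
  tok <- as_channels_matrix(feature_map)
  q <- tok %*% attn$weights$w_q
  k <- tok %*% attn$weights$w_k
  v <- tok %*% attn$weights$w_v
  a <- row_softmax_r(q %*% t(k) / sqrt(attn$d_k))
  array(a %*% v, d)
}

#' Compound scaling coefficients
#'
#' Depth, width and resolution multipliers `(alpha^theta, beta^theta,
#' gamma^theta)` under the balance constraint `alpha * beta^2 * gamma^2 ~ 2`
#' (checked against \[1.8, 2.2\]), so FLOPs roughly double per increment of
#' `theta`.
#'
#' @param alpha,beta,gamma per-dimension base multipliers (>= 1).
#' @param theta nonnegative integer scaling exponent.
#' @param check `"warn"` (default), `"error"` or `"none"` when the product
#'   constraint is violated.
#' @return named numeric vector `c(dept, wid, reso)`.
#' @export
compound_scale <- function(alpha, beta, gamma, theta,
                           check = c("warn", "error", "none")) {
  check <- match.arg(check)
  stopifnot(alpha >= 1, beta >= 1, gamma >= 1, theta >= 0)
  prod <- alpha * beta^2 * gamma^2
  if (check != "none" && (prod < 1.8 || prod > 2.2)) {
    msg <- sprintf("alpha * beta^2 * gamma^2 = %.4f outside [1.8, 2.2]",
                   prod)
    if (check == "error") stop(msg) else warning(msg)
  }
  c(dept = alpha^theta, wid = beta^theta, reso = gamma^theta)
}

#' Network specification for the feature extractor
#'
#' @param stem list with `filters`, `kernel`, `stride` of the initial
#'   convolution.
#' @param blocks ordered list of [mbconv_spec()]s; consecutive channel
#'   counts must chain.
#' @param attention logical or an [attention_spec()]; `TRUE` builds a head
#'   over the final channel count.
#' @param num_classes classifier head width (>= 2).
#' @param in_channels image channel count (default 3).
#' @param dropout head dropout rate (recorded; inference-time forward pass
#'   does not drop).
#' @param seed weight-initialization seed.
#' @return object of class `network_spec` (weights unset until
#'   [menet_init()]).
#' @export
network_spec <- function(stem, blocks, attention = TRUE, num_classes = 2L,
                         in_channels = 3L, dropout = 0.2, seed = 1L) {
  stopifnot(num_classes >= 2)
  cin <- stem$filters
  for (b in blocks) {
    if (b$c_in != cin) stop("block channel counts do not chain")
    cin <- b$c_out
  }
  structure(list(stem = stem, blocks = blocks, attention = attention,
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 dropout = dropout, seed = as.integer(seed),
                 feature_dim = cin, initialized = FALSE),
            class = "network_spec")
}

#' Compact default extractor specification
#'
#' Seven MBConv stages alternating 3x3 and 5x5 kernels with interleaved
#' stride-2 stages, mirroring the EfficientNet-B0 stage structure at a
#' desk-scale width; the final channel count (default 64) is the extracted
#' feature dimension.
#'
#' @param num_classes classifier head width.
#' @param in_channels image channels.
#' @param widths per-stage output channels (length 7).
#' @param expansion MBConv expansion ratio (default 6).
#' @param seed weight seed.
#' @return a [network_spec()].
#' @export
default_menet_spec <- function(num_classes = 3L, in_channels = 3L,
                               widths = c(8, 16, 16, 24, 32, 48, 64),
                               expansion = 6L, seed = 1L) {
  kernels <- rep(c(3L, 5L), length.out = length(widths))
  strides <- rep(c(1L, 2L), length.out = length(widths))
  cin <- 8L
  blocks <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    blocks[[i]] <- mbconv_spec(cin, widths[i], expansion = expansion,
                               kernel = kernels[i], stride = strides[i])
    cin <- as.integer(widths[i])
  }
  network_spec(stem = list(filters = 8L, kernel = 3L, stride = 1L),
               blocks = blocks, attention = TRUE,
               num_classes = num_classes, in_channels = in_channels,
               seed = seed)
}

#' Initialize all network weights (seeded He-uniform)
#'
#' @param net a [network_spec()].
#' @return the spec with weights populated and `initialized = TRUE`.
#' @export
menet_init <- function(net) {
  set.seed(net$seed)
  net$stem$weights <- he_uniform(
    c(net$stem$kernel, net$stem$kernel, net$in_channels, net$stem$filters),
    net$stem$kernel^2 * net$in_channels)
  net$blocks <- lapply(net$blocks, init_mbconv_weights)
  if (isTRUE(net$attention))
    net$attention <- attention_spec(net$feature_dim)
  if (inherits(net$attention, "attention_spec") &&
      is.null(net$attention$weights))
    net$attention <- init_attention_weights(net$attention)
  net$head_weights <- he_uniform(c(net$feature_dim, net$num_classes),
                                 net$feature_dim)
  net$initialized <- TRUE
  net
}

#' Extract deep features from a batch of images
#'
#' Stem convolution, MBConv stages, self-attention refinement over spatial
#' tokens, global average pooling, flatten.  Deterministic given the
#' network's seed.
#'
#' @param images list of H x W x C arrays (or a single such array).
#' @param net an initialized [network_spec()] (see [menet_init()]).
#' @return n x D numeric matrix, D the final channel count.
#' @export
extract_features <- function(images, net) {
  if (!isTRUE(net$initialized)) net <- menet_init(net)
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  feats <- matrix(0, length(images), net$feature_dim)
  for (i in seq_along(images)) {
    x <- images[[i]]
    if (dim(x)[3] != net$in_channels)
      stop("image has ", dim(x)[3], " channels, network expects ",
           net$in_channels)
    x <- swish(conv2d(x, net$stem$weights, net$stem$stride))
    for (b in net$blocks) x <- mbconv_forward(x, b)
    if (inherits(net$attention, "attention_spec"))
      x <- self_attention_refine(x, net$attention)
    feats[i, ] <- apply(x, 3, mean)
  }
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  feats
}

#' Label-smoothed cross-entropy loss
#'
#' Row-softmax of the logits against one-hot targets smoothed to
#' `1 - epsilon + epsilon/C` on the true class and `epsilon/C` elsewhere;
#' mean over samples.
#'
#' @param logits N x C numeric matrix.
#' @param labels integer labels in 1..C.
#' @param epsilon smoothing parameter in \[0, 1).
#' @return nonnegative scalar.
#' @export
label_smoothed_cross_entropy <- function(logits, labels, epsilon = 0.1) {
  logits <- as.matrix(logits)
  n <- nrow(logits); C <- ncol(logits)
  stopifnot(C >= 2, length(labels) == n, epsilon >= 0, epsilon < 1)
  if (any(labels < 1 | labels > C)) stop("label outside 1..C")
  p <- row_softmax_r(logits)
  targets <- matrix(epsilon / C, n, C)
  targets[cbind(seq_len(n), labels)] <- 1 - epsilon + epsilon / C
  -sum(targets * log(pmax(p, 1e-300))) / n
}

#' Apply compound scaling to a network specification
#'
#' Each base block is treated as a stage: depth multiplies (and rounds up)
#' its repeat count, with repeats beyond the first running at stride 1 on
#' the stage's output channels; width multiplies and rounds channel counts;
#' resolution multiplies the nominal input size used by [count_flops()].
#'
#' @param net a [network_spec()].
#' @param coefs output of [compound_scale()].
#' @param input_size nominal square input resolution of the base network.
#' @param base_repeats per-stage repeat counts of the base network (default
#'   1 per stage).
#' @return list with the scaled `net` and scaled `input_size`.
#' @export
scale_network_spec <- function(net, coefs, input_size,
                               base_repeats = rep(1L, length(net$blocks))) {
  stopifnot(length(base_repeats) == length(net$blocks))
  w <- function(c) max(1L, as.integer(round(c * coefs["wid"])))
  scaled <- list()
  cin <- w(net$stem$filters)
  for (i in seq_along(net$blocks)) {
    b <- net$blocks[[i]]
    cout <- w(b$c_out)
    reps <- ceiling(base_repeats[i] * coefs["dept"])
    for (r in seq_len(reps)) {
      scaled[[length(scaled) + 1]] <- mbconv_spec(
        if (r == 1) cin else cout, cout, b$expansion, b$kernel,
        if (r == 1) b$stride else 1L, b$se_ratio)
    }
    cin <- cout
  }
  stem <- net$stem
  stem$filters <- w(net$stem$filters)
  list(net = network_spec(stem, scaled, attention = net$attention,
                          num_classes = net$num_classes,
                          in_channels = net$in_channels,
                          dropout = net$dropout, seed = net$seed),
       input_size = max(1L, as.integer(round(input_size * coefs["reso"]))))
}

#' Multiply-accumulate count of the extractor forward pass
#'
#' Sums standard per-layer MAC formulas over the stem, expansions, depthwise
#' convolutions, squeeze-excitation MLPs, projections, the attention head
#' and the dense classifier head.
#'
#' @param net a [network_spec()] (weights not required).
#' @param input_size square input resolution H = W.
#' @return nonnegative numeric MAC count.
#' @export
count_flops <- function(net, input_size) {
  total <- 0
  h <- input_size
  if (!is.null(net$stem)) {
    h <- ceiling(h / net$stem$stride)
    total <- total + h^2 * net$stem$kernel^2 * net$in_channels *
      net$stem$filters
  }
  for (b in net$blocks) {
    tc <- b$expansion * b$c_in
    se_dim <- ceiling(b$se_ratio * b$c_in)
    total <- total + h^2 * b$c_in * tc            # 1x1 expansion
    h <- ceiling(h / b$stride)
    total <- total + h^2 * b$kernel^2 * tc        # depthwise
    total <- total + 2 * tc * se_dim              # SE bottleneck MLP
    total <- total + h^2 * tc * b$c_out           # 1x1 projection
  }
  if (!isFALSE(net$attention) && !is.null(net$attention)) {
    C <- net$feature_dim
    dk <- if (inherits(net$attention, "attention_spec")) net$attention$d_k
          else C
    n_tok <- h^2
    total <- total + 2 * n_tok * C * dk + n_tok * C * C +
      n_tok^2 * dk + n_tok^2 * C
  }
  if (net$num_classes >= 2)
    total <- total + net$feature_dim * net$num_classes
  total
}
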