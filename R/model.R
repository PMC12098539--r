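# Boundary-aware enhanced U-Net: a standard lightweight 2D U-Net backbone
# (seg-net + 1x1 seg-head) plus a Sobel boundary branch and a channel-attention
# fusion module (BSFM) feeding the seg-head.

#' Model configuration
#'
#' @param in_channels number of image channels (RGB tiles: 3)
#' @param n_classes number of output classes (binary tumor/background: 2)
#' @param base_width channel width of the first U-Net level; doubles per level
#' @param n_levels number of resolution levels (encoder depth)
#' @param dropout_p dropout rate, active in the bottleneck and before the
#'   seg-head; also drives Monte-Carlo sampling at inference
#' @param boundary_channels channel width `C_B` of the boundary branch; must
#'   equal `base_width` (the fusion module requires `C_S = C_B`)
#' @param projection_channels output channels `C_out` of the per-scale
#'   contrastive projection heads
#' @param n_scales number of decoder scales `D` used for multi-scale
#'   contrastive learning (finest first)
#' @param sobel_alpha_init initial value of the learnable Sobel scale
#' @param fusion_alpha_init initial value of the learnable fusion scale
#' @return a `model_config` list
#' @export
model_config <- function(in_channels = 3L, n_classes = 2L, base_width = 16L,
                         n_levels = 5L, dropout_p = 0.5,
                         boundary_channels = base_width,
                         projection_channels = 64L,
                         n_scales = min(3L, n_levels - 1L),
                         sobel_alpha_init = 1.0, fusion_alpha_init = 1.0) {
  if (n_levels < 2L || base_width < 1L)
    stop("n_levels must be >= 2 and base_width >= 1")
  if (boundary_channels != base_width)
    stop("boundary_channels must equal base_width (C_S = C_B)")
  if (n_scales < 1L || n_scales > n_levels - 1L)
    stop("n_scales must be between 1 and n_levels - 1")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width),
                 n_levels = as.integer(n_levels),
                 dropout_p = dropout_p,
                 boundary_channels = as.integer(boundary_channels),
                 projection_channels = as.integer(projection_channels),
                 n_scales = as.integer(n_scales),
                 sobel_alpha_init = sobel_alpha_init,
                 fusion_alpha_init = fusion_alpha_init),
            class = "model_config")
}

# run code with a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# He-normal conv weights in im2col matrix layout
init_conv <- function(k, cin, cout) {
  list(w = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

unet_widths <- function(config) config$base_width * 2L^(0:(config$n_levels - 1L))

# parameter values (plain arrays) for the plain U-Net backbone
init_backbone_values <- function(config) {
  W <- unet_widths(config)
  L <- config$n_levels
  v <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    cv1 <- init_conv(3L, cin, W[l]); cv2 <- init_conv(3L, W[l], W[l])
    bn1 <- init_bn(W[l]); bn2 <- init_bn(W[l])
    v[[sprintf("enc%d.conv1.w", l)]] <- cv1$w
    v[[sprintf("enc%d.conv1.b", l)]] <- cv1$b
    v[[sprintf("enc%d.bn1.gamma", l)]] <- bn1$gamma
    v[[sprintf("enc%d.bn1.beta", l)]] <- bn1$beta
    v[[sprintf("enc%d.conv2.w", l)]] <- cv2$w
    v[[sprintf("enc%d.conv2.b", l)]] <- cv2$b
    v[[sprintf("enc%d.bn2.gamma", l)]] <- bn2$gamma
    v[[sprintf("enc%d.bn2.beta", l)]] <- bn2$beta
    cin <- W[l]
  }
  for (l in seq(L - 1L, 1L)) {
    red <- init_conv(1L, W[l + 1L], W[l])
    cv1 <- init_conv(3L, 2L * W[l], W[l]); cv2 <- init_conv(3L, W[l], W[l])
    bn1 <- init_bn(W[l]); bn2 <- init_bn(W[l])
    v[[sprintf("dec%d.reduce.w", l)]] <- red$w
    v[[sprintf("dec%d.reduce.b", l)]] <- red$b
    v[[sprintf("dec%d.conv1.w", l)]] <- cv1$w
    v[[sprintf("dec%d.conv1.b", l)]] <- cv1$b
    v[[sprintf("dec%d.bn1.gamma", l)]] <- bn1$gamma
    v[[sprintf("dec%d.bn1.beta", l)]] <- bn1$beta
    v[[sprintf("dec%d.conv2.w", l)]] <- cv2$w
    v[[sprintf("dec%d.conv2.b", l)]] <- cv2$b
    v[[sprintf("dec%d.bn2.gamma", l)]] <- bn2$gamma
    v[[sprintf("dec%d.bn2.beta", l)]] <- bn2$beta
  }
  head <- init_conv(1L, W[1L], config$n_classes)
  v[["head.w"]] <- head$w
  v[["head.b"]] <- head$b
  v
}

# boundary branch + fusion + per-scale contrastive heads
init_branch_values <- function(config) {
  cb <- config$boundary_channels
  v <- list()
  v[["sobel.alpha"]] <- config$sobel_alpha_init
  kk <- c(5L, 5L, 3L, 3L, 1L)
  cin <- config$in_channels
  for (i in seq_along(kk)) {
    cv <- init_conv(kk[i], cin, cb); bn <- init_bn(cb)
    v[[sprintf("be%d.conv.w", i)]] <- cv$w
    v[[sprintf("be%d.conv.b", i)]] <- cv$b
    v[[sprintf("be%d.bn.gamma", i)]] <- bn$gamma
    v[[sprintf("be%d.bn.beta", i)]] <- bn$beta
    cin <- cb
  }
  v <- c(v, init_bsfm_values(cb, config$fusion_alpha_init))
  W <- unet_widths(config)
  for (d in seq_len(config$n_scales)) {
    pr <- init_conv(1L, W[d], config$projection_channels)
    v[[sprintf("proj%d.w", d)]] <- pr$w
    v[[sprintf("proj%d.b", d)]] <- pr$b
  }
  v
}

init_bsfm_values <- function(c_s, fusion_alpha_init = 1.0) {
  list("bsfm.alpha" = fusion_alpha_init,
       "bsfm.cc.w" = 1.0, "bsfm.cc.b" = 0.0,
       "bsfm.mlp1.w" = matrix(stats::rnorm(4L * c_s * 2L * c_s, 0,
                                           sqrt(2 / (4 * c_s))), 4L * c_s, 2L * c_s),
       "bsfm.mlp1.b" = numeric(2L * c_s),
       "bsfm.mlp2.w" = matrix(stats::rnorm(2L * c_s * 2L * c_s, 0,
                                           sqrt(2 / (2 * c_s))), 2L * c_s, 2L * c_s),
       "bsfm.mlp2.b" = numeric(2L * c_s))
}

wrap_params <- function(values) {
  p <- lapply(values, ag_param)
  names(p) <- names(values)
  p
}

#' Build the plain U-Net backbone (seg-net + seg-head)
#'
#' Standard 2D U-Net: two 3x3 conv + normalization + ReLU blocks per level,
#' channel widths `base_width * 2^level`, 2x2 max-pool downsampling, decoder
#' with 1x1-conv channel reduction, bilinear x2 upsampling and skip
#' concatenation, and a 1x1 seg-head. No boundary branch.
#'
#' @param config a [model_config()]
#' @param seed integer seed for weight initialization
#' @return a `semiseg_model` object
#' @export
build_backbone <- function(config = model_config(), seed = 1L) {
  values <- with_seed(seed, init_backbone_values(config))
  structure(list(config = config, params = wrap_params(values),
                 boundary = FALSE),
            class = c("unet_backbone", "semiseg_model"))
}

#' Build the full boundary-aware enhanced U-Net
#'
#' The backbone of [build_backbone()] plus the Sobel boundary-aware module,
#' the five-layer boundary-enhancement stack (kernels 5, 5, 3, 3, 1), the
#' channel-attention fusion module feeding the seg-head, and the per-scale
#' projection / classifier heads used by multi-scale contrastive learning.
#'
#' @inheritParams build_backbone
#' @return a `semiseg_model` object
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  values <- with_seed(seed, c(init_backbone_values(config),
                              init_branch_values(config)))
  structure(list(config = config, params = wrap_params(values),
                 boundary = TRUE),
            class = c("bae_unet", "semiseg_model"))
}

#' Count trainable parameters
#'
#' @param model a `semiseg_model` (or a named list of parameters)
#' @return integer total number of trainable scalars
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "semiseg_model")) model$params else model
  sum(vapply(p, function(x) length(ag_value(x)), numeric(1)))
}

#' @export
print.semiseg_model <- function(x, ...) {
  cat(sprintf("<%s: base_width=%d, n_levels=%d, %s parameters>\n",
              class(x)[1], x$config$base_width, x$config$n_levels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# canonical 3x3 Sobel pair; Kx responds to horizontal intensity change
# (vertical edges), Ky = t(Kx) to vertical change.
sobel_kx <- function() matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

#' Per-channel Sobel gradient responses
#'
#' Cross-correlation with the canonical 3x3 Sobel pair under reflective
#' padding, computed independently for each channel.
#'
#' @param image H x W x C array
#' @return list with `h` (horizontal-change response) and `v` arrays, H x W x C
#' @export
sobel_gradients <- function(image) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  kx <- sobel_kx(); ky <- t(kx)
  h <- array(0, d); v <- array(0, d)
  for (c in seq_len(d[3])) {
    cols <- im2col(image[, , c, drop = FALSE], 3L, "reflect")
    wx <- kernel_to_matrix(array(kx, c(3, 3, 1, 1)))
    wy <- kernel_to_matrix(array(ky, c(3, 3, 1, 1)))
    h[, , c] <- matrix(cols %*% wx, d[1], d[2])
    v[, , c] <- matrix(cols %*% wy, d[1], d[2])
  }
  list(h = h, v = v)
}

#' Sobel boundary-aware response map
#'
#' Gradient magnitude of the two Sobel responses per channel, scaled by the
#' learnable scalar `alpha`.
#'
#' @param image H x W x C array in `[0, 1]`
#' @param alpha scale factor (the module's learnable parameter)
#' @return H x W x C array
#' @export
sobel_boundary_aware <- function(image, alpha = 1.0) {
  g <- sobel_gradients(image)
  sqrt(g$h^2 + g$v^2) * alpha
}

# conv + norm + relu block (internal, autodiff path)
conv_block <- function(x, P, prefix, k = 3L) {
  x <- ag_conv2d(x, P(paste0(prefix, ".conv.w")), P(paste0(prefix, ".conv.b")), k)
  x <- ag_norm_channels(x, P(paste0(prefix, ".bn.gamma")), P(paste0(prefix, ".bn.beta")))
  ag_relu(x)
}

double_block <- function(x, P, prefix) {
  x <- ag_conv2d(x, P(paste0(prefix, ".conv1.w")), P(paste0(prefix, ".conv1.b")), 3L)
  x <- ag_norm_channels(x, P(paste0(prefix, ".bn1.gamma")), P(paste0(prefix, ".bn1.beta")))
  x <- ag_relu(x)
  x <- ag_conv2d(x, P(paste0(prefix, ".conv2.w")), P(paste0(prefix, ".conv2.b")), 3L)
  x <- ag_norm_channels(x, P(paste0(prefix, ".bn2.gamma")), P(paste0(prefix, ".bn2.beta")))
  ag_relu(x)
}

# channel-attention fusion (autodiff path); params accessed through P
bsfm_core <- function(f_s, f_be, P) {
  cs <- dim(ag_value(f_s))[3]
  cb <- dim(ag_value(f_be))[3]
  if (cs != cb) stop("BSFM requires C_S == C_B")
  ss <- ag_sigmoid(f_s); sb <- ag_sigmoid(f_be)
  cc <- function(v) ag_add(ag_mul(v, P("bsfm.cc.w")), P("bsfm.cc.b"))
  pooled <- ag_cat(list(cc(ag_chan_mean(ss)), cc(ag_chan_max(ss)),
                        cc(ag_chan_mean(sb)), cc(ag_chan_max(sb))))
  h <- ag_relu(ag_dense(pooled, P("bsfm.mlp1.w"), P("bsfm.mlp1.b")))
  wbes <- ag_dense(h, P("bsfm.mlp2.w"), P("bsfm.mlp2.b"))
  w_s <- ag_subset(wbes, seq_len(cs))
  w_be <- ag_subset(wbes, cs + seq_len(cb))
  mixed <- ag_add(ag_channel_scale(f_s, w_s), ag_channel_scale(f_be, w_be))
  ag_add(f_s, ag_mul(mixed, P("bsfm.alpha")))
}

#' Boundary-spatial fusion of feature maps
#'
#' Channel-attention fusion of spatial features `F_S` and boundary features
#' `F_BE`: sigmoid activation, per-channel average and max pooling, a shared
#' 1-D convolution on each pooled vector, concatenation and a two-layer MLP
#' yield channel weights split into `W_S` and `W_BE`; the output is
#' `F_S + alpha * (F_S * W_S + F_BE * W_BE)` with per-channel scaling.
#'
#' @param f_s spatial features, H x W x C
#' @param f_be boundary features, H x W x C (same C)
#' @param params named list with elements `bsfm.alpha`, `bsfm.cc.w`,
#'   `bsfm.cc.b`, `bsfm.mlp1.w/b`, `bsfm.mlp2.w/b` (see `init_bsfm_values`)
#' @return fused H x W x C array
#' @export
bsfm_fuse <- function(f_s, f_be, params) {
  P <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing BSFM parameter: ", nm)
    v
  }
  ag_no_grad(ag_value(bsfm_core(as_ag(f_s), as_ag(f_be), P)))
}

#' Five-layer boundary-enhancement stack
#'
#' Convolution + normalization + ReLU layers with kernel sizes 5, 5, 3, 3, 1
#' and `same` padding; spatial size is preserved throughout.
#'
#' @param boundary_response H x W x C array (Sobel output)
#' @param params named list holding `be1..be5` conv/bn parameters
#' @return H x W x C_B array
#' @export
boundary_enhance <- function(boundary_response, params) {
  P <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing boundary parameter: ", nm)
    v
  }
  ag_no_grad(ag_value(boundary_enhance_core(as_ag(boundary_response), P)))
}

boundary_enhance_core <- function(x, P) {
  kk <- c(5L, 5L, 3L, 3L, 1L)
  for (i in seq_along(kk)) x <- conv_block(x, P, sprintf("be%d", i), kk[i])
  x
}

#' Forward pass through the model
#'
#' Returns the feature pyramid used by the training losses: seg-head logits,
#' the last `n_scales` decoder feature maps (finest first), the spatial
#' features `F_S`, boundary features `F_BE` and fused features `F_BSF`.
#' With `dropout = FALSE` the pass is fully deterministic; repeated calls with
#' `dropout = TRUE` give Monte-Carlo samples.
#'
#' @param model a `semiseg_model`
#' @param image H x W x in_channels array
#' @param dropout logical; activate the dropout layers (bottleneck and
#'   pre-seg-head)
#' @param params optional parameter override (e.g. the teacher's EMA values)
#' @return a `feature_pyramid` list of `ag_tensor` nodes
#' @export
model_forward <- function(model, image, dropout = FALSE, params = model$params) {
  cfg <- model$config
  d <- dim(image)
  if (length(d) != 3L || d[3] != cfg$in_channels)
    stop("image must be H x W x ", cfg$in_channels)
  div <- 2L^(cfg$n_levels - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("tile size must be divisible by 2^(n_levels-1) = ", div)
  P <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) stop("missing parameter: ", nm)
    v
  }
  L <- cfg$n_levels
  enc <- vector("list", L)
  x <- as_ag(image)
  for (l in seq_len(L)) {
    if (l > 1L) x <- ag_maxpool2(x)
    x <- double_block(x, P, sprintf("enc%d", l))
    enc[[l]] <- x
  }
  x <- ag_dropout(x, cfg$dropout_p, dropout)
  dec <- vector("list", L - 1L)
  for (l in seq(L - 1L, 1L)) {
    r <- ag_conv2d(x, P(sprintf("dec%d.reduce.w", l)), P(sprintf("dec%d.reduce.b", l)), 1L)
    r <- ag_upsample2(r)
    x <- ag_concat_c(r, enc[[l]])
    x <- double_block(x, P, sprintf("dec%d", l))
    dec[[l]] <- x
  }
  f_s <- dec[[1L]]
  f_be <- NULL
  f_bsf <- f_s
  if (isTRUE(model$boundary)) {
    mag <- sobel_boundary_aware(image, alpha = 1.0)
    b <- ag_mul(ag_const(mag), P("sobel.alpha"))
    f_be <- boundary_enhance_core(b, P)
    f_bsf <- bsfm_core(f_s, f_be, P)
  }
  h <- ag_dropout(f_bsf, cfg$dropout_p, dropout)
  logits <- ag_conv2d(h, P("head.w"), P("head.b"), 1L)
  structure(list(logits = logits,
                 decoder_feats = dec[seq_len(cfg$n_scales)],
                 F_S = f_s, F_BE = f_be, F_BSF = f_bsf),
            class = "feature_pyramid")
}

#' Per-pixel class probabilities for one tile
#'
#' Deterministic softmax prediction (no graph is retained).
#'
#' @inheritParams model_forward
#' @return H x W x n_classes array of probabilities
#' @export
predict_probs <- function(model, image, dropout = FALSE, params = model$params) {
  ag_no_grad({
    fp <- model_forward(model, image, dropout = dropout, params = params)
    ag_value(ag_softmax_c(fp$logits))
  })
}

# teacher-side snapshot of parameter values
param_values <- function(params) lapply(params, ag_value)
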