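test_that("backbone parameter count matches the independent enumeration", {
  # layer-by-layer closed-form count for the 16/5-level configuration:
  # conv k*k*Cin*Cout + Cout, normalization 2*C per conv
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  W <- c(16, 32, 64, 128, 256)
  expected <- 0
  cin <- 3
  for (w in W) {
    expected <- expected + conv_n(3, cin, w) + 2 * w + conv_n(3, w, w) + 2 * w
    cin <- w
  }
  for (i in 4:1) {
    expected <- expected + conv_n(1, W[i + 1], W[i]) +
      conv_n(3, 2 * W[i], W[i]) + 2 * W[i] + conv_n(3, W[i], W[i]) + 2 * W[i]
  }
  expected <- expected + conv_n(1, 16, 2)
  expect_equal(expected, 1813506)
  bb <- build_backbone(model_config())
  expect_equal(count_parameters(bb), expected)
  expect_equal(round(count_parameters(bb) / 1e6, 2), 1.81)
  # conv parameters scale quadratically in width
  small <- count_parameters(build_backbone(model_config(base_width = 8L,
                                                        n_levels = 3L)))
  big <- count_parameters(build_backbone(model_config(base_width = 16L,
                                                      n_levels = 3L)))
  expect_gt(big / small, 3.4)
  expect_lt(big / small, 4.0)
})

test_that("Sobel module: zero on constants, 4 at a unit step edge, flip-covariant", {
  const <- array(0.7, c(6, 6, 3))
  expect_equal(max(abs(sobel_boundary_aware(const, alpha = 1))), 0)
  expect_equal(max(abs(sobel_boundary_aware(const + 0.1, alpha = 0))), 0)
  # vertical step edge of height 1: horizontal-kernel response 4 at the edge
  step <- array(0, c(8, 8, 1)); step[, 5:8, ] <- 1
  g <- sobel_gradients(step)
  expect_equal(g$h[4, 4, 1], 4)
  expect_equal(g$h[4, 5, 1], 4)
  expect_equal(g$v[4, 4, 1], 0)
  # magnitude commutes with horizontal flip
  set.seed(6)
  img <- array(stats::runif(12 * 12 * 3), c(12, 12, 3))
  flip <- img[, 12:1, , drop = FALSE]
  m1 <- sobel_boundary_aware(img)
  m2 <- sobel_boundary_aware(flip)
  expect_equal(m2, m1[, 12:1, , drop = FALSE], tolerance = 1e-12)
})

test_that("boundary-enhancement stack preserves spatial size with kernels 5,5,3,3,1", {
  cfg <- model_config(base_width = 4L, n_levels = 3L, projection_channels = 8L,
                      n_scales = 2L)
  m <- build_model(cfg, seed = 2L)
  # introspect the stored kernels
  ks <- vapply(1:5, function(i) {
    w <- semiseg:::ag_value(m$params[[sprintf("be%d.conv.w", i)]])
    cin <- if (i == 1) 3L else 4L
    as.integer(sqrt(nrow(w) / cin))
  }, integer(1))
  expect_identical(ks, c(5L, 5L, 3L, 3L, 1L))
  vals <- semiseg:::param_values(m$params)
  x <- array(stats::runif(20 * 12 * 3), c(20, 12, 3))
  out <- boundary_enhance(x, vals)
  expect_equal(dim(out)[1:2], c(20L, 12L))
  expect_equal(dim(out)[3], 4L)
  # zero input with zero biases gives zero pre-activation output
  vals0 <- vals
  for (i in 1:5) vals0[[sprintf("be%d.bn.beta", i)]] <-
    vals0[[sprintf("be%d.bn.beta", i)]] * 0
  out0 <- boundary_enhance(array(0, c(8, 8, 3)), vals0)
  expect_equal(max(abs(out0)), 0)
})

test_that("BSFM fusion follows the channel-attention formula", {
  set.seed(8)
  c_s <- 2L
  f_s <- array(stats::rnorm(2 * 2 * c_s), c(2, 2, c_s))
  f_be <- array(stats::rnorm(2 * 2 * c_s), c(2, 2, c_s))
  params <- semiseg:::with_seed(4L, semiseg:::init_bsfm_values(c_s))
  # independent by-hand evaluation of the attention weights and fusion
  sig <- function(x) 1 / (1 + exp(-x))
  pool_ap <- function(x) apply(sig(x), 3, mean)
  pool_mp <- function(x) apply(sig(x), 3, max)
  cc <- function(v) v * params[["bsfm.cc.w"]] + params[["bsfm.cc.b"]]
  pooled <- c(cc(pool_ap(f_s)), cc(pool_mp(f_s)), cc(pool_ap(f_be)), cc(pool_mp(f_be)))
  h <- pmax(drop(crossprod(params[["bsfm.mlp1.w"]], pooled)) + params[["bsfm.mlp1.b"]], 0)
  wbes <- drop(crossprod(params[["bsfm.mlp2.w"]], h)) + params[["bsfm.mlp2.b"]]
  w_s <- wbes[1:c_s]; w_be <- wbes[c_s + 1:c_s]
  expected <- f_s
  for (c in 1:c_s)
    expected[, , c] <- f_s[, , c] +
      params[["bsfm.alpha"]] * (f_s[, , c] * w_s[c] + f_be[, , c] * w_be[c])
  expect_equal(bsfm_fuse(f_s, f_be, params), expected, tolerance = 1e-12)
  # alpha frozen at zero leaves the spatial features untouched
  params0 <- params; params0[["bsfm.alpha"]] <- 0
  expect_equal(bsfm_fuse(f_s, f_be, params0), f_s, tolerance = 1e-12)
  # C_S must equal C_B
  expect_error(bsfm_fuse(f_s, array(0, c(2, 2, 3)), params), "C_S == C_B")
})

test_that("forward pass: shapes, determinism, scale count, MC variation", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 2L)
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  fp <- model_forward(m, img)
  expect_s3_class(fp, "feature_pyramid")
  expect_equal(dim(semiseg:::ag_value(fp$logits)), c(16L, 16L, 2L))
  expect_length(fp$decoder_feats, 2L)
  expect_equal(dim(semiseg:::ag_value(fp$decoder_feats[[2]]))[1:2], c(8L, 8L))
  # deterministic without dropout
  expect_identical(predict_probs(m, img), predict_probs(m, img))
  # stochastic with dropout
  set.seed(1)
  p1 <- predict_probs(m, img, dropout = TRUE)
  p2 <- predict_probs(m, img, dropout = TRUE)
  expect_false(identical(p1, p2))
  # indivisible tile size rejected
  expect_error(model_forward(m, array(0, c(18, 18, 3))), "divisible")
  # default configuration exposes D = 3 scales
  expect_equal(model_config()$n_scales, 3L)
})

test_that("ablating the boundary branch recovers the plain U-Net output", {
  cfg <- tiny_model_config()
  full <- build_model(cfg, seed = 3L)
  full$params[["bsfm.alpha"]]$value <- 0
  plain <- build_backbone(cfg, seed = 99L)
  for (nm in names(plain$params))
    plain$params[[nm]]$value <- semiseg:::ag_value(full$params[[nm]])
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(predict_probs(full, img), predict_probs(plain, img),
               tolerance = 1e-12)
})
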