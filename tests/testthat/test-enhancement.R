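# multi-branch extraction, dual attention, depthwise-separable convolution

test_that("multi-branch extraction has the contract shapes and limits", {
  set.seed(2)
  N <- 20
  feats <- matrix(rnorm(N * 5), N, 5)
  coords <- unit_sphere_coords(N)
  cfg <- enhancement_config(branch_ks = c(1, 4, 8), branch_width = 16)
  w <- init_enhancement_weights(cfg, 5, seed = 1)
  out <- multi_branch_extract(feats, coords, cfg, w)
  expect_equal(dim(out), c(N, 48))

  # single k=1 branch with identity maps: rectified input
  cfg1 <- enhancement_config(branch_ks = 1, branch_width = 5,
                             integration_width = 5,
                             attention_reduction = 1)
  w1 <- list(branches = list(list(W = diag(5), b = numeric(5))),
             integration = list(W = diag(5), b = numeric(5)))
  expect_equal(multi_branch_extract(feats, coords, cfg1, w1), pmax(feats, 0))

  # all points identical: every branch emits the same vector everywhere
  same <- matrix(1, N, 5)
  outs <- multi_branch_extract(same, matrix(0.5, N, 3), cfg, w)
  expect_equal(outs, outs[rep(1, N), ], tolerance = 1e-12)
})

test_that("channel attention matches its closed forms", {
  N <- 7
  feats <- matrix(rnorm(N * 4, sd = 2), N, 4)
  wz <- list(W1 = matrix(0, 4, 4), b1 = numeric(4),
             W2 = matrix(0, 4, 4), b2 = numeric(4))
  ca <- channel_attention(feats, wz)
  expect_equal(ca$channel_gates, rep(0.5, 4))
  expect_equal(ca$gated, feats / 2)

  # identity bottleneck (r = 1) on constant features (1, -1): both squeeze
  # paths give (1, -1), their sum (2, -2), gates (sigmoid(2), sigmoid(-2))
  const <- matrix(rep(c(1, -1), each = 5), 5, 2)
  wid <- list(W1 = diag(2), b1 = numeric(2), W2 = diag(2), b2 = numeric(2))
  ca2 <- channel_attention(const, wid)
  expect_equal(ca2$channel_gates, c(plogis(2), plogis(-2)), tolerance = 1e-6)

  # duplicating every point leaves mean and max squeezes unchanged
  set.seed(4)
  w <- list(W1 = matrix(rnorm(8), 4, 2), b1 = rnorm(2),
            W2 = matrix(rnorm(8), 2, 4), b2 = rnorm(4))
  expect_equal(channel_attention(feats[rep(1:N, 2), ], w)$channel_gates,
               channel_attention(feats, w)$channel_gates, tolerance = 1e-12)
})

test_that("spatial attention gates per point as specified", {
  feats <- matrix(rnorm(12), 4, 3)
  wz <- list(W = matrix(0, 2, 1), b = 0)
  sa <- spatial_attention(feats, wz)
  expect_equal(sa$point_gates, rep(0.5, 4))

  # weights (1, 0), bias 0, a point with channel-mean 1 -> gate sigmoid(1)
  row1 <- matrix(c(1, 1, 1), 1, 3)
  w10 <- list(W = matrix(c(1, 0), 2, 1), b = 0)
  expect_equal(spatial_attention(row1, w10)$point_gates, plogis(1),
               tolerance = 1e-6)
  # duplication invariance of the per-point gates
  set.seed(1)
  w <- list(W = matrix(rnorm(2), 2, 1), b = 0.2)
  expect_equal(spatial_attention(feats[rep(1:4, 2), ], w)$point_gates,
               rep(spatial_attention(feats, w)$point_gates, 2),
               tolerance = 1e-12)
})

test_that("depthwise-separable conv: identity limit and parameter savings", {
  feats <- matrix(rnorm(15), 5, 3)
  wid <- list(depthwise = matrix(1, 1, 3), depthwise_b = numeric(3),
              pointwise = diag(3), pointwise_b = numeric(3))
  expect_equal(depthwise_separable_conv(feats, wid, 1, 3), pmax(feats, 0))

  sv <- ds_conv_param_savings(128, 128, 3)
  expect_equal(sv$ds_params, 17024)
  expect_equal(sv$standard_params, 49280)
  expect_equal(sv$reduction_pct, 100 * (1 - 17024 / 49280), tolerance = 1e-9)
  expect_gt(sv$reduction_pct, 50)

  # the saving exceeds 50% across a grid of practical widths (at C = 8
  # the depthwise pair costs 52% of the standard conv, so the bound starts
  # holding from C = 16 up)
  for (C in c(16, 32, 64, 128, 256))
    for (k in c(3, 5, 7))
      expect_gt(ds_conv_param_savings(C, C, k)$reduction_pct, 50)
})

test_that("the full enhancement chain composes with valid attention maps", {
  set.seed(9)
  N <- 24
  feats <- matrix(rnorm(N * 6), N, 6)
  coords <- unit_sphere_coords(N)
  cfg <- enhancement_config(branch_ks = c(1, 5), branch_width = 6,
                            integration_width = 12, attention_reduction = 2,
                            ds_kernel = 3, out_width = 10)
  w <- init_enhancement_weights(cfg, 6, seed = 2)
  out <- enhance_features(feats, coords, cfg, w)
  expect_equal(dim(out$features), c(N, 10))
  expect_true(all(out$attention$channel_gates > 0 &
                    out$attention$channel_gates < 1))
  expect_true(all(out$attention$point_gates > 0 &
                    out$attention$point_gates < 1))
  # deterministic
  expect_identical(out, enhance_features(feats, coords, cfg, w))

  # zero attention weights: output is the DS-conv of branch features / 4
  wz <- w
  wz$channel <- list(W1 = 0 * w$channel$W1, b1 = 0 * w$channel$b1,
                     W2 = 0 * w$channel$W2, b2 = 0 * w$channel$b2)
  wz$spatial <- list(W = matrix(0, 2, 1), b = 0)
  mb <- multi_branch_extract(feats, coords, cfg, wz)
  expect_equal(enhance_features(feats, coords, cfg, wz)$features,
               depthwise_separable_conv(mb * 0.25, wz$ds, 3, 10),
               tolerance = 1e-12)
})

test_that("enhancement config validates its invariants", {
  expect_error(enhancement_config(branch_ks = c(1, 8), branch_width = 5,
                                  attention_reduction = 4),
               "divide")
  expect_error(enhancement_config(ds_kernel = 2), "odd")
})
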