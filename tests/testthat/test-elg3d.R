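# the three neighborhood operators and the fusion logic

test_that("edge_conv matches the hand oracle and handles degenerate offsets", {
  # C = 1: center feature 1, neighbor features {1, 3}; h sums [f_i, f_j-f_i]
  g <- manual_group(1, matrix(c(1, 3), 2, 1))
  w <- list(W = matrix(c(1, 1), 2, 1), b = 0)
  expect_equal(edge_conv(g, w), matrix(3, 1, 1))

  # all neighbors identical to the center: output = relu(h([f_i, 0]))
  g0 <- manual_group(2, matrix(2, 3, 1))
  expect_equal(edge_conv(g0, w), matrix(2, 1, 1))
  w_neg <- list(W = matrix(c(-1, 1), 2, 1), b = 0)
  expect_equal(edge_conv(g0, w_neg), matrix(0, 1, 1))  # rectifier clips
})

test_that("local_attention reproduces the hand softmax oracle", {
  # values {2, 4} from identity map; scores {0, log 3}
  g <- manual_group(0, matrix(c(2, 4), 2, 1))
  w <- list(W = matrix(1, 1, 1), b = 0,
            score_W = matrix(log(3) / 2, 1, 1), score_b = -log(3))
  out <- local_attention(g, w)
  expect_equal(as.numeric(out), 3.5)
  expect_equal(attr(out, "alpha")[1, ], c(0.25, 0.75))

  # K = 1: alpha = 1, output = the sole value
  g1 <- manual_group(0, matrix(5, 1, 1))
  expect_equal(as.numeric(local_attention(g1, w)), 5)

  # equal scores: unweighted mean of values
  weq <- list(W = matrix(1, 1, 1), b = 0,
              score_W = matrix(0, 1, 1), score_b = 2)
  expect_equal(as.numeric(local_attention(g, weq)), 3)
})

test_that("attention weights are a proper distribution per center", {
  set.seed(5)
  xyz <- unit_sphere_coords(25)
  ci <- farthest_point_sample(xyz, 6)
  g <- group_neighborhoods(xyz, NULL, ci, ball_query(xyz, xyz[ci, ], 0.8, 5))
  w <- list(W = matrix(rnorm(3 * 4), 3, 4), b = rnorm(4),
            score_W = matrix(rnorm(3), 3, 1), score_b = 0.3)
  a <- attr(local_attention(g, w), "alpha")
  expect_true(all(a >= 0))
  expect_equal(rowSums(a), rep(1, 6), tolerance = 1e-6)
})

test_that("gcn_aggregate matches a dense normalized-propagation oracle", {
  # hand case: star with one neighbor, scalar features 1 and 3, W = 1
  g <- manual_group(1, matrix(3, 1, 1))
  w <- list(W = matrix(1, 1, 1), b = 0)
  expect_equal(gcn_aggregate(g, w), matrix(2, 1, 1))

  # padding collapsed onto the center: isolated self-loop
  gc <- manual_group(4, matrix(9, 3, 1),
                     center_index = 1L, neighbor_indices = matrix(1L, 1, 3))
  expect_equal(gcn_aggregate(gc, w), matrix(4, 1, 1))

  # dense-matrix oracle on random star graphs with <= 8 nodes
  for (seed in 1:5) {
    set.seed(seed)
    K <- sample(1:7, 1)
    C <- sample(1:4, 1)
    W <- matrix(rnorm(C * 2), C, 2)
    xc <- rnorm(C)
    Xn <- matrix(rnorm(K * C), K, C)
    g <- manual_group(xc, Xn)
    # dense D^{-1/2} (A+I) D^{-1/2} X W, center = node 1
    A <- matrix(0, K + 1, K + 1)
    A[1, 1 + seq_len(K)] <- 1; A[1 + seq_len(K), 1] <- 1
    Ahat <- A + diag(K + 1)
    Dm <- diag(1 / sqrt(rowSums(Ahat)))
    prop <- (Dm %*% Ahat %*% Dm %*% rbind(xc, Xn)) %*% W
    expect_equal(gcn_aggregate(g, list(W = W, b = numeric(2))),
                 pmax(prop, 0)[1, , drop = FALSE], tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("all three operators are invariant to neighbor ordering", {
  set.seed(8)
  K <- 5; C <- 4
  Xn <- matrix(rnorm(K * C), K, C)
  xc <- rnorm(C)
  perm <- sample(K)
  g1 <- manual_group(xc, Xn)
  g2 <- manual_group(xc, Xn[perm, ],
                     neighbor_indices = matrix(perm + 1L, 1, K))
  we <- list(W = matrix(rnorm(2 * C * 3), 2 * C, 3), b = rnorm(3))
  wa <- list(W = matrix(rnorm(C * 3), C, 3), b = rnorm(3),
             score_W = matrix(rnorm(C), C, 1), score_b = 0.1)
  wg <- list(W = matrix(rnorm(C * 3), C, 3), b = rnorm(3))
  expect_equal(edge_conv(g1, we), edge_conv(g2, we), tolerance = 1e-12)
  expect_equal(as.matrix(local_attention(g1, wa)),
               as.matrix(local_attention(g2, wa)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(gcn_aggregate(g1, wg), gcn_aggregate(g2, wg),
               tolerance = 1e-12)
})

test_that("same-scale fusion is an unattenuated residual sum", {
  base <- matrix(c(1, 2, 0.5, 3), 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(fuse_same_scale(z, z, z, base), base)
  x <- matrix(c(1, -1, 2, 0.5), 2, 2)
  expect_equal(fuse_same_scale(x, x, x, z), pmax(3 * x, 0))
  expect_error(fuse_same_scale(z, z, z, matrix(0, 3, 2)), "shape")
})

test_that("cross-scale fusion concatenates then projects", {
  s1 <- matrix(1:4, 2, 2); s2 <- matrix(5:8, 2, 2)
  wid <- list(W = diag(4), b = numeric(4))
  expect_equal(fuse_cross_scale(list(s1, s2), wid), cbind(s1, s2))
  wz <- list(W = matrix(0, 4, 3), b = numeric(3))
  expect_equal(fuse_cross_scale(list(s1, s2), wz), matrix(0, 2, 3))
  expect_error(fuse_cross_scale(list(s1, matrix(0, 3, 2)), wid), "share")
})

test_that("elg3d_forward has the right shapes and translation invariance", {
  xyz <- unit_sphere_coords(40)
  cfg <- elg3d_config(10, list(scale_spec(0.4, 5, 6), scale_spec(0.8, 8, 7)),
                      12)
  w <- init_elg3d_weights(cfg, in_channels = 0, seed = 21)
  out <- elg3d_forward(xyz, NULL, cfg, w)
  expect_equal(dim(out$centers), c(10, 3))
  expect_equal(dim(out$features), c(10, 12))

  shifted <- sweep(xyz, 2, c(3, -2, 7), "+")
  out2 <- elg3d_forward(shifted, NULL, cfg, w)
  expect_equal(out2$features, out$features, tolerance = 1e-9)
  expect_equal(out2$centers, out$centers + rep(c(3, -2, 7), each = 10),
               tolerance = 1e-9)
  expect_error(elg3d_forward(xyz[1:5, ], NULL, cfg, w), "n_centers")
})

test_that("permuting input points permutes elg3d output consistently", {
  xyz <- unit_sphere_coords(30, seed = 4)
  # K must exceed every ball's population: with fewer candidates than slots
  # the ascending-index gather picks the same physical subset under any
  # input ordering
  kmax <- max(vapply(1:30, function(i)
    sum(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) <= 0.5), 0L))
  cfg <- elg3d_config(8, list(scale_spec(0.5, kmax + 1L, 5)), 9)
  w <- init_elg3d_weights(cfg, 0, seed = 3)
  out1 <- elg3d_forward(xyz, NULL, cfg, w, start_index = 1L)
  perm <- sample(30)
  out2 <- elg3d_forward(xyz[perm, ], NULL, cfg, w,
                        start_index = which(perm == 1L))
  # same physical center set, same features after matching centers
  o1 <- order(out1$centers[, 1], out1$centers[, 2], out1$centers[, 3])
  o2 <- order(out2$centers[, 1], out2$centers[, 2], out2$centers[, 3])
  expect_equal(out1$centers[o1, ], out2$centers[o2, ], tolerance = 1e-12)
  expect_equal(out1$features[o1, ], out2$features[o2, ], tolerance = 1e-9)
})

test_that("with operator branches silenced the stage reduces to plain SA", {
  # zeroing edge/attention/gcn weights leaves relu(0+0+0+base) = base, so
  # the pre-unification concatenation equals a set-abstraction stage whose
  # per-scale mini-PointNet is the shared base map
  xyz <- unit_sphere_coords(36, seed = 6)
  scales <- list(scale_spec(0.5, 5, 7), scale_spec(0.9, 7, 9))
  ecfg <- elg3d_config(9, scales, 11)
  m <- build_model(model_config(
    stages = list(ecfg, global_config(c(8L))),
    fp = list(6L, 6L), n_input_points = 36L, n_classes = 2L,
    head_hidden = 4L, head_dropout = 0), seed = 2)
  for (nm in names(m$params))
    if (grepl("enc1\\.s[0-9]+\\.(edge|attv|atts|gcn)\\.(W|b|gamma|beta)", nm))
      m$params[[nm]] <- m$params[[nm]] * 0
  ctx <- new.env(); ctx$params <- m$params
  ctx$buffers <- list2env(m$buffers); ctx$mode <- "eval"
  st <- elgcot3d:::elg3d_stage_fwd(xyz, NULL, ecfg, ctx, "enc1")
  cat_pre_unify <- st$cache$un$cache$X

  sa <- sa_config(9, list(list(radius = 0.5, K = 5L, mlp = 7L),
                          list(radius = 0.9, K = 7L, mlp = 9L)))
  params2 <- list()
  for (s in 1:2) for (f in c("W", "b", "gamma", "beta"))
    params2[[sprintf("enc1.s%d.l1.%s", s, f)]] <-
      m$params[[sprintf("enc1.s%d.base.%s", s, f)]]
  ctx2 <- new.env(); ctx2$params <- params2
  ctx2$buffers <- list2env(m$buffers); ctx2$mode <- "eval"
  st2 <- elgcot3d:::sa_stage_fwd(xyz, NULL, sa, ctx2, "enc1")
  expect_equal(cat_pre_unify, st2$feats, tolerance = 1e-10)
})
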