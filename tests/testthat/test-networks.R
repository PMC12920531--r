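# model assembly, feature propagation, forward/backward correctness

test_that("fp interpolation uses exact-hit and inverse-distance rules", {
  coarse <- rbind(c(0, 0, 0), c(4, 0, 0))
  cf <- matrix(c(0, 10), 2, 1)
  # distances 1 and 3: (1*0 + 1/3*10) / (4/3) = 2.5
  ip <- fp_interpolate(coarse, cf, matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.numeric(ip$feats), 2.5)
  expect_equal(rowSums(ip$weights), 1)
  expect_true(all(ip$weights >= 0))

  # coincident fine point takes the coarse feature verbatim
  ip0 <- fp_interpolate(coarse, cf, coarse[2, , drop = FALSE])
  expect_equal(as.numeric(ip0$feats), 10)

  # equidistant neighbors: unweighted mean
  tri <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  ipe <- fp_interpolate(tri, matrix(c(3, 6, 9), 3, 1), matrix(0, 1, 3))
  expect_equal(as.numeric(ipe$feats), 6)

  # single coarse point broadcasts
  ip1 <- fp_interpolate(matrix(0, 1, 3), matrix(7, 1, 1),
                        matrix(rnorm(9), 3, 3))
  expect_equal(as.numeric(ip1$feats), rep(7, 3))

  fpw <- list(W = matrix(1, 1, 2), b = c(0, -10))
  out <- feature_propagation(coarse, cf, matrix(c(1, 0, 0), 1, 3), NULL, fpw)
  expect_equal(out, matrix(c(2.5, 0), 1, 2))
})

test_that("model builds are seeded, deterministic, and shape-correct", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))

  xyz <- unit_sphere_coords(40)
  fw <- elgcot3d:::net_fwd(m1, xyz)
  expect_equal(dim(fw$probs), c(40, 3))
  expect_equal(rowSums(fw$probs), rep(1, 40), tolerance = 1e-5)

  expect_error(model_config(stages = list(global_config(4L)), fp = list()),
               "mirror|global")
  expect_error(model_config(
    stages = list(elg3d_config(4, list(scale_spec(1, 2, 3)), 4),
                  elg3d_config(8, list(scale_spec(1, 2, 3)), 4),
                  global_config(4L)),
    fp = list(4L, 4L, 4L)), "decrease")
})

test_that("backpropagation matches finite differences through every module", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 7)
  xyz <- unit_sphere_coords(40, seed = 42)
  set.seed(43)
  lab <- sample(0:2, 40, TRUE)
  onehot <- matrix(0, 40, 3); onehot[cbind(1:40, lab + 1)] <- 1
  fw <- elgcot3d:::net_fwd(m, xyz, mode = "train", keep_cache = TRUE)
  gr <- elgcot3d:::net_bwd(m, fw, (fw$probs - onehot) / 40)
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    cross_entropy_loss(elgcot3d:::net_fwd(m2, xyz, mode = "train")$probs, lab)
  }
  set.seed(44)
  # one random entry from a parameter in every module family
  picks <- c(sample(grep("^enc1", names(m$params), value = TRUE), 4),
             sample(grep("^enc2", names(m$params), value = TRUE), 3),
             sample(grep("^enc3", names(m$params), value = TRUE), 2),
             sample(grep("^fp", names(m$params), value = TRUE), 3),
             sample(grep("^enh", names(m$params), value = TRUE), 4),
             sample(grep("^head", names(m$params), value = TRUE), 2))
  for (nm in picks) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    ana <- if (is.null(gr[[nm]])) 0 else gr[[nm]][i]
    expect_equal(ana, num, tolerance = 1e-3,
                 label = sprintf("grad[%s][%d]", nm, i))
  }
})

test_that("reference and ablation configurations order as published", {
  pe <- count_parameters(build_elgcot3d(seed = 1))
  pa <- count_parameters(build_pointnet2_baseline(seed = 1))
  expect_lt(pe, pa)                                  # lightweight direction
  pc <- count_parameters(build_model(ablation_config("C"), seed = 1))
  expect_lt(pc, pa)                                  # enhancement slims
  expect_identical(ablation_config("A")$stages,
                   reference_baseline_config()$stages)
  expect_identical(count_parameters(build_model(ablation_config("D"), 1)), pa)
  expect_identical(ablation_config("E")$enhancement,
                   reference_elgcot3d_config()$enhancement)
  pb <- count_parameters(build_model(ablation_config("B"), seed = 1))
  expect_false(pb == pa)                             # stages actually swapped
})

test_that("segmentation is deterministic, complete and order-equivariant", {
  cfg <- tiny_model_config(ds_kernel = 1L)
  m <- build_model(cfg, seed = 9)
  cloud <- tiny_cloud(55, seed = 10)                 # more points than input
  s1 <- segment_points(m, cloud)
  s2 <- segment_points(m, cloud)
  expect_identical(s1$class_probabilities, s2$class_probabilities)
  expect_equal(nrow(s1$class_probabilities), 55)
  expect_equal(rowSums(s1$class_probabilities), rep(1, 55),
               tolerance = 1e-5)
  expect_true(all(s1$predicted_labels %in% 0:2))
  expect_equal(s1$predicted_labels,
               max.col(s1$class_probabilities, ties.method = "first") - 1L)

  # permuting the input points permutes the outputs identically
  # (depthwise stage neutralized via ds_kernel = 1)
  set.seed(11)
  perm <- sample(55)
  s3 <- segment_points(m, cloud[perm, ])
  expect_equal(s3$predicted_labels, s1$predicted_labels[perm])
  expect_equal(s3$class_probabilities, s1$class_probabilities[perm, ],
               tolerance = 1e-8)

  # fewer points than the input size: cycling resample still covers all
  small <- tiny_cloud(25, seed = 12)
  s4 <- segment_points(m, small)
  expect_equal(length(s4$predicted_labels), 25)
})

test_that("checkpoints restore a model bit-exactly", {
  m <- build_model(tiny_model_config(), seed = 13)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, f, optimizer_state = list(t = 3L))
  back <- load_checkpoint(f)
  expect_identical(back$model$params, m$params)
  expect_identical(back$optimizer_state$t, 3L)
  xyz <- unit_sphere_coords(40)
  expect_identical(elgcot3d:::net_fwd(back$model, xyz)$probs,
                   elgcot3d:::net_fwd(m, xyz)$probs)
})
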