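# MuSGD, schedule, augmentations, loss, metrics, and the training loop

test_that("a MuSGD step reproduces the hand-evaluated update", {
  # scalar p = 1, grad = 1, lambda = 0, beta = .9, mu = .99, eta = .1:
  # m1 = 1, v1 = 1, d1 = 1 + 1e-8, p1 ~ 0.9
  cfg <- musgd_config(eta = 0.1, beta = 0.9, mu = 0.99, lam = 0)
  st <- musgd_init(list(p = 1))
  up <- musgd_step(list(p = 1), list(p = 1), st, cfg)
  expect_equal(up$state$m$p, 1)
  expect_equal(up$state$v$p, 1)
  expect_equal(up$params$p, 1 - 0.1 / (1 + 1e-8), tolerance = 1e-12)
  expect_equal(up$state$t, 1L)

  # zero gradients, zero buffers, lambda = 0: a fixed point
  up0 <- musgd_step(list(p = 2), list(p = 0), musgd_init(list(p = 2)),
                    musgd_config(lam = 0))
  expect_equal(up0$params$p, 2)
  expect_equal(up0$state$m$p, 0)

  # weight decay alone shrinks |p| monotonically
  p <- 1; st <- musgd_init(list(p = 1))
  cfgl <- musgd_config(eta = 0.01, lam = 0.1)
  for (i in 1:20) {
    up <- musgd_step(list(p = p), list(p = 0), st, cfgl)
    expect_lt(abs(up$params$p), abs(p))
    p <- up$params$p; st <- up$state
  }

  expect_error(musgd_step(list(p = 1), list(p = NaN), musgd_init(list(p = 1)),
                          musgd_config()), "p")
})

test_that("constant-gradient momentum follows the geometric closed form", {
  cfg <- musgd_config(beta = 0.9, mu = 0.99, lam = 0)
  g <- 0.37
  st <- musgd_init(list(p = 0))
  p <- list(p = 0)
  for (t in 1:20) {
    up <- musgd_step(p, list(p = g), st, cfg)
    st <- up$state
    expect_equal(st$m$p, g * (1 - 0.9^t) / (1 - 0.9), tolerance = 1e-10)
    # p itself moves, but the gradient we feed stays constant
  }
})

test_that("with mu = 0, lam = 0 and huge eps MuSGD tends to momentum/eps", {
  cfg <- musgd_config(eta = 1, beta = 0.8, mu = 0, lam = 0, eps = 1e6)
  p <- list(p = 0); st <- musgd_init(p)
  m_ref <- 0; p_ref <- 0
  for (t in 1:10) {
    g <- sin(t)
    up <- musgd_step(p, list(p = g), st, cfg)
    m_ref <- 0.8 * m_ref + g
    p_ref <- p_ref - m_ref / (abs(g) + 1e6)   # d = sqrt(g^2) + eps
    expect_equal(up$params$p, p_ref, tolerance = 1e-6)
    p <- up$params; st <- up$state
  }
})

test_that("MuSGD converges on the 1-D quadratic within 500 steps", {
  # unit-scale problem, step size 0.01; the adaptive ratio m/sqrt(v) is
  # scale-invariant so each step moves ~eta, reaching the origin well
  # inside the budget and then collapsing by momentum cancellation
  cfg <- musgd_config(eta = 0.01)
  p <- list(p = 1); st <- musgd_init(p)
  for (i in 1:500) {
    up <- musgd_step(p, list(p = p$p), st, cfg)   # dL/dp of L = p^2/2
    p <- up$params; st <- up$state
  }
  expect_lt(abs(p$p), 0.01)
})

test_that("cosine annealing hits its endpoints and midpoint monotonically", {
  cfg <- schedule_config(eta_max = 0.1, eta_min = 0.001, T = 100)
  expect_equal(cosine_lr(0, cfg), 0.1)
  expect_equal(cosine_lr(100, cfg), 0.001)
  expect_equal(cosine_lr(50, cfg), (0.1 + 0.001) / 2)
  lrs <- vapply(0:100, cosine_lr, 0, cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-12))
  expect_error(cosine_lr(101, cfg), "outside")
})

test_that("rotation preserves z, norms and pairwise distances", {
  pc <- tiny_cloud(20, seed = 3)
  expect_equal(pc_coords(rotate_z(pc, 0)), pc_coords(pc))
  expect_equal(pc_coords(rotate_z(point_cloud(matrix(c(1, 0, 0), 1, 3)),
                                  pi / 2)),
               matrix(c(0, 1, 0), 1, 3), tolerance = 1e-12)
  rot <- random_z_rotation(pc, seed = 5)
  expect_equal(rot$z, pc$z)
  expect_equal(rowSums(pc_coords(rot)^2), rowSums(pc_coords(pc)^2),
               tolerance = 1e-9)
  expect_equal(as.matrix(dist(pc_coords(rot))),
               as.matrix(dist(pc_coords(pc))), tolerance = 1e-9)
  expect_identical(pc_labels(rot), pc_labels(pc))
})

test_that("point dropout is shape-stable and bounded by the max ratio", {
  pc <- tiny_cloud(50, seed = 6)
  expect_identical(random_point_dropout(pc, max_ratio = 0, seed = 1), pc)
  for (s in 1:20) {
    out <- random_point_dropout(pc, max_ratio = 0.1, seed = s)
    expect_equal(nrow(out), 50)
    changed <- rowSums(pc_coords(out) != pc_coords(pc)) > 0
    expect_lte(sum(changed), floor(0.1 * 50))
    # replaced points are copies of the first point
    if (any(changed))
      expect_true(all(pc_coords(out)[changed, 1] == pc$x[1]))
  }
})

test_that("mirror flip is an involution with calibrated frequency", {
  pc <- tiny_cloud(15, seed = 7)
  expect_equal(pc_coords(mirror_flip(mirror_flip(pc, "x"), "x")),
               pc_coords(pc))
  expect_equal(pc_coords(mirror_flip(mirror_flip(pc, "y"), "y")),
               pc_coords(pc))
  out <- random_mirror_flip(pc, p = 0.5, seed = 8)
  expect_equal(nrow(out), 15)
  expect_identical(pc_labels(out), pc_labels(pc))
  # distances are preserved whether or not the flip fired
  expect_equal(as.matrix(dist(pc_coords(out))),
               as.matrix(dist(pc_coords(pc))), tolerance = 1e-12)

  set.seed(9)
  one <- point_cloud(matrix(c(1, 2, 3), 1, 3))
  flips <- vapply(1:10000, function(i) {
    f <- random_mirror_flip(one, p = 0.5)
    f$x != one$x || f$y != one$y
  }, TRUE)
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})

test_that("cross-entropy matches closed forms and validates labels", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(perfect, 0:2), 0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(cross_entropy_loss(unif, rep(2L, 5)), log(4))
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy_loss(two, c(0L, 0L)), (log(2) + log(4)) / 2)
  expect_error(cross_entropy_loss(two, c(0L, 2L)), "range")
})

test_that("confusion accumulation and metrics match the hand oracle", {
  cm <- confusion_matrix(2)
  cm <- update_confusion(cm, predicted = c(0, 1), true = c(1, 1))
  expect_equal(unname(unclass(cm)), rbind(c(0, 0), c(1, 1)))
  expect_equal(sum(update_confusion(cm, 0:1, 0:1)), 4)

  hand <- matrix(c(3, 2, 1, 4), 2, 2)      # rows true: [[3,1],[2,4]]
  mr <- compute_metrics(hand)
  expect_equal(mr$per_class$iou, c(0.5, 4 / 7), tolerance = 1e-9)
  expect_equal(mr$miou, mean(c(0.5, 4 / 7)), tolerance = 1e-4)
  expect_equal(mr$oa, 0.7)

  diag3 <- diag(c(5, 2, 9))
  mrd <- compute_metrics(diag3)
  expect_equal(mrd$miou, 1)
  expect_equal(mrd$oa, 1)
  expect_equal(mrd$per_class$f1, rep(1, 3))

  # class absent from truth and prediction is excluded from the mean
  absent <- matrix(0, 3, 3); absent[1, 1] <- 4; absent[2, 2] <- 2
  expect_equal(compute_metrics(absent)$miou, 1)

  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")

  for (seed in 1:5) {
    set.seed(seed)
    M <- sample(2:5, 1); n <- sample(50:1000, 1)
    true <- sample(0:(M - 1), n, TRUE)
    pred <- sample(0:(M - 1), n, TRUE)
    mr <- compute_metrics(update_confusion(confusion_matrix(M), pred, true))
    or <- metrics_oracle(pred, true, M)
    expect_equal(mr$miou, or$miou, tolerance = 1e-12)
    expect_equal(mr$oa, or$oa, tolerance = 1e-12)
  }
})

test_that("evaluate aggregates a single global confusion matrix", {
  m <- build_model(tiny_model_config(), seed = 3)
  clouds <- list(tiny_cloud(40, 1), tiny_cloud(40, 2))
  r_all <- evaluate(m, clouds)
  cm <- confusion_matrix(3)
  for (cl in clouds)
    cm <- update_confusion(cm, segment_points(m, cl)$predicted_labels,
                           pc_labels(cl))
  expect_equal(r_all$confusion, cm, ignore_attr = TRUE)
  # order invariance
  expect_equal(evaluate(m, rev(clouds))$miou, r_all$miou)
})

test_that("short training runs are reproducible and shrink the loss", {
  plants <- generate_dataset(synthetic_plant_config(n_points = 128),
                             n_samples = 4, seed = 21)
  cfg <- tiny_model_config(n_points = 128L, dropout = 0.2)
  m <- build_model(cfg, seed = 2)
  args <- list(musgd_cfg = musgd_config(eta = 0.01),
               schedule_cfg = schedule_config(eta_max = 0.01, T = 8),
               epochs = 8L, batch_size = 2L, seed = 31)
  f1 <- do.call(train, c(list(m, plants, plants), args))
  f2 <- do.call(train, c(list(m, plants, plants), args))
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_equal(nrow(f1$history), 8)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$epochs, 8)
})

test_that("pausing at a checkpoint and resuming reproduces the straight run", {
  plants <- generate_dataset(synthetic_plant_config(n_points = 96),
                             n_samples = 3, seed = 41)
  cfg <- tiny_model_config(n_points = 96L)
  args <- list(musgd_cfg = musgd_config(eta = 0.01),
               schedule_cfg = schedule_config(eta_max = 0.01, T = 6),
               epochs = 6L, batch_size = 3L, seed = 17)
  straight <- do.call(train, c(list(build_model(cfg, 1), plants, plants),
                               args))
  ckdir <- withr::local_tempdir()
  do.call(train, c(list(build_model(cfg, 1), plants, plants), args,
                   list(checkpoint_every = 3L, checkpoint_dir = ckdir)))
  resumed <- do.call(train, c(
    list(build_model(cfg, 1), plants, plants), args,
    list(resume = load_checkpoint(file.path(ckdir, "epoch_0003.ckpt")))))
  # the resumed fit's history holds epochs 4..6 only
  expect_identical(resumed$history$epoch, 4:6)
  expect_identical(resumed$history$train_loss,
                   straight$history$train_loss[4:6])
  expect_identical(resumed$history$val_oa, straight$history$val_oa[4:6])
})
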