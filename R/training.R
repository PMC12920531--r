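# Training strategy: the MuSGD hybrid optimizer (momentum buffer plus an
# RMSProp-style squared-gradient accumulator with weight decay), cosine
# annealing, the three point-cloud augmentations, the per-point
# cross-entropy loss, and the segmentation metrics.

#' MuSGD optimizer configuration
#'
#' MuSGD combines momentum accumulation with an adaptive denominator built
#' from an exponential moving average of squared gradients, plus decoupled
#' L2 weight decay folded into the gradient:
#' \deqn{g_t = \nabla_p L_t + \lambda p_t,\quad
#'       m_t = \beta m_{t-1} + g_t,\quad
#'       v_t = \mu v_{t-1} + g_t^2,\quad
#'       d_t = \sqrt{v_t} + \epsilon,\quad
#'       p_{t+1} = p_t - \eta\, m_t / d_t.}
#'
#' @param eta learning rate (> 0), default 1e-3.
#' @param beta momentum coefficient in \[0, 1).
#' @param mu squared-gradient decay factor in \[0, 1).
#' @param lam L2 weight-decay coefficient (>= 0).
#' @param eps numerical stability term added to the denominator.
#' @param sqrt_inside if TRUE uses the variant denominator
#'   `sqrt(v_t + eps)`.
#' @return a `musgd_config` list.
#' @export
musgd_config <- function(eta = 1e-3, beta = 0.9, mu = 0.99, lam = 1e-4,
                         eps = 1e-8, sqrt_inside = FALSE) {
  stopifnot(eta > 0, beta >= 0, beta < 1, mu >= 0, mu < 1, lam >= 0,
            eps > 0)
  list(eta = eta, beta = beta, mu = mu, lam = lam, eps = eps,
       sqrt_inside = sqrt_inside)
}

#' Initialize MuSGD state
#'
#' @param params named list of parameter arrays.
#' @return a `musgd_state`: zero momentum buffer `m`, zero squared-gradient
#'   accumulator `v`, step counter `t = 0`.
#' @export
musgd_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' One MuSGD update
#'
#' @param params named list of parameter arrays.
#' @param grads named list of gradients (missing entries are treated as
#'   zero gradient; weight decay still applies).
#' @param state a `musgd_state` from [musgd_init()].
#' @param cfg a [musgd_config()].
#' @param eta optional learning-rate override (used by the cosine schedule).
#' @return list with updated `params` and `state`.
#' @export
musgd_step <- function(params, grads, state, cfg, eta = NULL) {
  if (is.null(eta)) eta <- cfg$eta
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- grads[[nm]]
    if (is.null(g)) g <- 0
    if (any(!is.finite(g)))
      abort(sprintf("non-finite gradient for parameter '%s'", nm))
    g <- g + cfg$lam * p
    m <- cfg$beta * state$m[[nm]] + g
    v <- cfg$mu * state$v[[nm]] + g^2
    d <- if (cfg$sqrt_inside) sqrt(v + cfg$eps) else sqrt(v) + cfg$eps
    params[[nm]] <- p - eta * m / d
    state$m[[nm]] <- m
    state$v[[nm]] <- v
  }
  state$t <- state$t + 1L
  list(params = params, state = state)
}

#' Cosine-annealing schedule configuration
#'
#' @param eta_max initial learning rate.
#' @param eta_min final learning rate (default 0).
#' @param T total epochs.
#' @return a `schedule_config` list.
#' @export
schedule_config <- function(eta_max = 1e-3, eta_min = 0, T = 300L) {
  stopifnot(eta_max >= eta_min, eta_min >= 0, T >= 1)
  list(eta_max = eta_max, eta_min = eta_min, T = as.integer(T))
}

#' Cosine-annealed learning rate at epoch t
#'
#' `eta_t = eta_min + (eta_max - eta_min) (1 + cos(pi t / T)) / 2`,
#' monotone non-increasing from `eta_max` at `t = 0` to `eta_min` at
#' `t = T`.
#'
#' @param t epoch index in `[0, T]`.
#' @param cfg a [schedule_config()].
#' @return the learning rate.
#' @export
cosine_lr <- function(t, cfg) {
  if (t < 0 || t > cfg$T) abort("epoch t outside [0, T]")
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) * (1 + cos(pi * t / cfg$T))
}

#' Augmentation configuration
#'
#' @param rotate_z apply a random rotation about the vertical axis.
#' @param max_dropout_ratio maximum fraction of points replaced by the
#'   dropout augmentation (default 0.10).
#' @param flip_prob probability of a mirror flip (default 0.5).
#' @return an `aug_config` list.
#' @export
aug_config <- function(rotate_z = TRUE, max_dropout_ratio = 0.10,
                       flip_prob = 0.5) {
  stopifnot(max_dropout_ratio >= 0, max_dropout_ratio <= 1,
            flip_prob >= 0, flip_prob <= 1)
  list(rotate_z = rotate_z, max_dropout_ratio = max_dropout_ratio,
       flip_prob = flip_prob)
}

#' Rotate a cloud about the Z axis
#'
#' @param cloud a [point_cloud()].
#' @param theta rotation angle in radians.
#' @return the rotated cloud; z coordinates, labels and pairwise distances
#'   are preserved.
#' @export
rotate_z <- function(cloud, theta) {
  ct <- cos(theta); st <- sin(theta)
  x <- cloud$x * ct - cloud$y * st
  y <- cloud$x * st + cloud$y * ct
  cloud$x <- x; cloud$y <- y
  cloud
}

#' Random Z-axis rotation augmentation
#'
#' Draws `theta ~ Uniform[0, 2*pi)` from the current RNG stream and applies
#' [rotate_z()]; emulates arbitrary plant posture in the horizontal plane.
#'
#' @param cloud a [point_cloud()].
#' @param seed optional seed (otherwise the current RNG stream is used,
#'   which is how the training loop chains its reproducible randomness).
#' @return the rotated cloud.
#' @export
random_z_rotation <- function(cloud, seed = NULL) {
  theta <- if (is.null(seed)) runif(1, 0, 2 * pi)
           else withr_seed(seed, runif(1, 0, 2 * pi))
  rotate_z(cloud, theta)
}

#' Random point-dropout augmentation
#'
#' Draws a ratio `r ~ Uniform[0, max_ratio]` and replaces `floor(r * N)`
#' randomly chosen points — coordinates, colors and labels — with copies of
#' the first point, keeping N fixed (the shape-stable convention, so
#' fixed-size batching works).  Emulates missing regions in real scans.
#'
#' @param cloud a [point_cloud()].
#' @param max_ratio maximum dropout fraction (default 0.10).
#' @param seed optional seed.
#' @return the augmented cloud, still with exactly N points.
#' @export
random_point_dropout <- function(cloud, max_ratio = 0.10, seed = NULL) {
  run <- function() {
    N <- nrow(cloud)
    r <- runif(1, 0, max_ratio)
    nd <- floor(r * N)
    if (nd >= 1) {
      idx <- sample.int(N, nd)
      cloud[idx, ] <- cloud[rep(1L, nd), ]
    }
    cloud
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Random mirror-flip augmentation
#'
#' With probability `p`, negates the x or the y coordinate (axis chosen
#' uniformly).  Applying the same flip twice is the identity.
#'
#' @param cloud a [point_cloud()].
#' @param p flip probability (default 0.5).
#' @param seed optional seed.
#' @return the (possibly) flipped cloud.
#' @export
random_mirror_flip <- function(cloud, p = 0.5, seed = NULL) {
  run <- function() {
    if (runif(1) < p) {
      axis <- if (runif(1) < 0.5) "x" else "y"
      cloud <- mirror_flip(cloud, axis)
    }
    cloud
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Deterministic mirror flip
#' @param cloud a [point_cloud()].
#' @param axis `"x"` or `"y"`.
#' @return the flipped cloud.
#' @export
mirror_flip <- function(cloud, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cloud[[axis]] <- -cloud[[axis]]
  cloud
}

#' Mean per-point cross-entropy loss
#'
#' @param probabilities N x M matrix of row-normalized class probabilities.
#' @param labels integer vector of true class ids in `[0, M)`.
#' @return scalar mean of `-log p(true class)`, probabilities floored at
#'   1e-12.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  M <- ncol(probabilities)
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= M)) abort("label out of range [0, M)")
  p <- probabilities[cbind(seq_len(nrow(probabilities)), labels + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Create an empty confusion matrix
#' @param n_classes number of classes M.
#' @param class_names optional names.
#' @return M x M zero matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(n_classes, class_names = NULL) {
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes) - 1)
  matrix(0L, n_classes, n_classes,
         dimnames = list(true = class_names, predicted = class_names))
}

#' Accumulate predictions into a confusion matrix
#'
#' @param cm matrix from [confusion_matrix()].
#' @param predicted integer predictions in `[0, M)`.
#' @param true integer ground truth in `[0, M)`.
#' @return the updated matrix.
#' @export
update_confusion <- function(cm, predicted, true) {
  M <- nrow(cm)
  predicted <- as.integer(predicted); true <- as.integer(true)
  if (any(predicted < 0 | predicted >= M | true < 0 | true >= M))
    abort("labels out of range [0, M)")
  t <- table(factor(true, levels = 0:(M - 1)),
             factor(predicted, levels = 0:(M - 1)))
  cm + unclass(t)
}

#' Segmentation metrics from a confusion matrix
#'
#' Per class i with `TP_i = cm[i, i]`, `FP_i = colsum - TP_i`,
#' `FN_i = rowsum - TP_i`: `IoU_i = TP_i / (TP_i + FP_i + FN_i)`; mIoU is
#' the mean over classes with a defined denominator (classes absent from
#' both truth and prediction are excluded); `OA = trace / total`;
#' precision, recall and F1 are reported per class (0 when undefined).
#'
#' @param cm confusion matrix (rows = truth, columns = prediction).
#' @return a `metrics_report`: list with `per_class` tibble
#'   (class, iou, precision, recall, f1), `miou`, `oa`, `confusion`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) abort("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- tp + fp + fn
  iou <- ifelse(denom > 0, tp / denom, NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    per_class = tibble(class = seq_along(tp) - 1L,
                       name = rownames(cm) %||% paste0("class",
                                                       seq_along(tp) - 1L),
                       iou = as.numeric(iou),
                       precision = as.numeric(precision),
                       recall = as.numeric(recall),
                       f1 = as.numeric(f1)),
    miou = mean(iou, na.rm = TRUE),
    oa = sum(tp) / total,
    confusion = cm),
    class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("segmentation metrics: mIoU %.4f, OA %.4f\n", x$miou, x$oa))
  print(x$per_class)
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(miou = x$miou, oa = x$oa, n_points = sum(x$confusion))
}

#' Evaluate a model over a dataset
#'
#' Runs [segment_points()] on every cloud, accumulates one global confusion
#' matrix over all points of all samples, and computes the metrics.
#'
#' @param model an `elgcot3d_model`.
#' @param dataset list of labeled [point_cloud()]s.
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, dataset) {
  if (length(dataset) == 0) abort("empty dataset")
  M <- model$config$n_classes
  cm <- confusion_matrix(M, attr(dataset[[1]], "class_names"))
  for (cloud in dataset) {
    truth <- pc_labels(cloud)
    if (is.null(truth)) abort("evaluation requires labeled clouds")
    seg <- segment_points(model, cloud)
    cm <- update_confusion(cm, seg$predicted_labels, truth)
  }
  compute_metrics(cm)
}

# prepare a cloud for the network: normalize + deterministic resample
prep_sample <- function(cloud, n_points) {
  norm <- normalize_unit_sphere(cloud)
  xyz <- pc_coords(norm)
  N <- nrow(xyz)
  sel <- if (N >= n_points)
    cpp_fps(xyz, as.integer(n_points), canonical_start(xyz))
  else rep_len(seq_len(N), n_points)
  new_point_cloud(tibble(x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
                         label = pc_labels(norm)[sel]),
                  sample_id = attr(cloud, "sample_id"),
                  class_names = attr(cloud, "class_names"))
}

#' Train a segmentation model
#'
#' Per epoch: seeded shuffle of the training clouds, per-sample augmentation
#' (rotation, then dropout, then mirror flip), forward pass in training
#' mode, per-point cross-entropy, hand-written backpropagation, and one
#' MuSGD step per mini-batch at the cosine-annealed learning rate.
#' Everything — shuffling, augmentation, head dropout — draws from one RNG
#' stream seeded once, so the loss history is exactly reproducible on a
#' single thread.
#'
#' @param model an `elgcot3d_model`.
#' @param train_set,val_set lists of labeled [point_cloud()]s (validation is
#'   never augmented).
#' @param musgd_cfg a [musgd_config()].
#' @param schedule_cfg a [schedule_config()] (its `T` should be >= `epochs`).
#' @param aug_cfg an [aug_config()].
#' @param epochs training epochs (total; a resumed run counts from the
#'   checkpointed epoch).
#' @param batch_size samples per MuSGD step.
#' @param seed master seed; each epoch reseeds deterministically from
#'   `(seed, epoch)`, so a run paused at a checkpoint and resumed
#'   reproduces the remaining epochs of the straight run exactly.
#' @param verbose print one line per epoch.
#' @param checkpoint_every if `checkpoint_dir` is given, save a resumable
#'   checkpoint every this many epochs.
#' @param checkpoint_dir directory for periodic checkpoints, or NULL.
#' @param resume a checkpoint list from [load_checkpoint()] of a periodic
#'   checkpoint; continues that run (its model, optimizer state and epoch
#'   counter replace the fresh ones).
#' @return list with the trained `model`, the `history` tibble
#'   (epoch, lr, train_loss, val_miou, val_oa) and the final optimizer
#'   `state`; class `elgcot3d_fit`.
#' @export
train <- function(model, train_set, val_set = train_set,
                  musgd_cfg = musgd_config(),
                  schedule_cfg = schedule_config(eta_max = musgd_cfg$eta),
                  aug_cfg = aug_config(),
                  epochs = 10L, batch_size = 8L, seed = 0L,
                  verbose = FALSE, checkpoint_every = NULL,
                  checkpoint_dir = NULL, resume = NULL) {
  if (length(train_set) == 0) abort("empty training set")
  start_epoch <- 1L
  state <- musgd_init(model$params)
  if (!is.null(resume)) {
    model <- resume$model
    state <- resume$optimizer_state$state
    start_epoch <- resume$optimizer_state$epoch + 1L
  }
  n_in <- model$config$n_input_points
  prepped <- lapply(train_set, prep_sample, n_points = n_in)
  history <- vector("list", epochs)
  for (epoch in seq(start_epoch, epochs)) {
    set.seed((seed + 7919L * epoch) %% .Machine$integer.max)
    eta <- cosine_lr(epoch - 1, schedule_cfg)
    ord <- sample(length(prepped))
    losses <- c()
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (batch in batches) {
      gsum <- NULL
      for (i in batch) {
        cloud <- prepped[[i]]
        if (aug_cfg$rotate_z) cloud <- random_z_rotation(cloud)
        cloud <- random_point_dropout(cloud, aug_cfg$max_dropout_ratio)
        cloud <- random_mirror_flip(cloud, aug_cfg$flip_prob)
        xyz <- pc_coords(cloud)
        lab <- pc_labels(cloud)
        fw <- net_fwd(model, xyz, mode = "train", keep_cache = TRUE)
        model$buffers <- fw$buffers
        losses <- c(losses, cross_entropy_loss(fw$probs, lab))
        onehot <- matrix(0, n_in, model$config$n_classes)
        onehot[cbind(seq_len(n_in), lab + 1L)] <- 1
        dlogits <- (fw$probs - onehot) / n_in
        g <- net_bwd(model, fw, dlogits)
        gsum <- if (is.null(gsum)) g else {
          for (nm in names(g))
            gsum[[nm]] <- (gsum[[nm]] %||% 0) + g[[nm]]
          gsum
        }
      }
      gavg <- lapply(gsum, function(x) x / length(batch))
      upd <- musgd_step(model$params, gavg, state, musgd_cfg, eta = eta)
      model$params <- upd$params
      state <- upd$state
    }
    vm <- evaluate(model, val_set)
    history[[epoch]] <- tibble(epoch = epoch, lr = eta,
                               train_loss = mean(losses),
                               val_miou = vm$miou, val_oa = vm$oa)
    if (!is.null(checkpoint_dir) && !is.null(checkpoint_every) &&
        epoch %% checkpoint_every == 0) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(model,
                      file.path(checkpoint_dir,
                                sprintf("epoch_%04d.ckpt", epoch)),
                      optimizer_state = list(state = state, epoch = epoch))
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val mIoU %.3f  OA %.3f",
                      epoch, eta, mean(losses), vm$miou, vm$oa))
  }
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 state = state),
            class = "elgcot3d_fit")
}

#' @export
print.elgcot3d_fit <- function(x, ...) {
  last <- tail(x$history, 1)
  cat(sprintf("trained %s: %d epochs, final loss %.4f, val mIoU %.3f, OA %.3f\n",
              x$model$config$name, nrow(x$history), last$train_loss,
              last$val_miou, last$val_oa))
  invisible(x)
}

#' @method tidy elgcot3d_fit
#' @export
tidy.elgcot3d_fit <- function(x, ...) x$history

#' @method glance elgcot3d_fit
#' @export
glance.elgcot3d_fit <- function(x, ...) {
  last <- tail(x$history, 1)
  tibble(epochs = nrow(x$history), final_loss = last$train_loss,
         val_miou = last$val_miou, val_oa = last$val_oa,
         params = count_parameters(x$model))
}
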