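# shared fixtures: tiny configurations and independent oracles

tiny_cloud <- function(n = 30, seed = 1, labels = TRUE) {
  set.seed(seed)
  xyz <- matrix(rnorm(n * 3), n, 3)
  point_cloud(xyz, labels = if (labels) sample(0:2, n, TRUE),
              sample_id = "tiny")
}

unit_sphere_coords <- function(n = 40, seed = 2) {
  set.seed(seed)
  xyz <- matrix(rnorm(n * 3), n, 3)
  xyz / max(sqrt(rowSums(xyz^2)))
}

tiny_model_config <- function(n_points = 40L, n_classes = 3L,
                              enhancement = TRUE, ds_kernel = 3L,
                              dropout = 0) {
  model_config(
    stages = list(
      elg3d_config(16L, list(scale_spec(0.3, 4, 6), scale_spec(0.6, 6, 8)),
                   10L),
      elg3d_config(6L, list(scale_spec(0.6, 4, 12)), 12L),
      global_config(c(12L, 16L))),
    fp = list(12L, 10L, 8L),
    enhancement = if (enhancement)
      enhancement_config(branch_ks = c(1L, 4L), branch_width = 4L,
                         integration_width = 8L, attention_reduction = 2L,
                         ds_kernel = ds_kernel, out_width = 8L),
    n_input_points = n_points, n_classes = n_classes,
    head_hidden = 8L, head_dropout = dropout)
}

# brute-force farthest point sampling: recompute all pairwise distances at
# every pick (no incremental min-distance array)
fps_oracle <- function(coords, S, start = 1L) {
  N <- nrow(coords)
  picked <- start
  for (s in seq_len(S - 1)) {
    dmin <- rep(Inf, N)
    for (p in picked) {
      d <- rowSums((coords - matrix(coords[p, ], N, 3, byrow = TRUE))^2)
      dmin <- pmin(dmin, d)
    }
    picked <- c(picked, which.max(dmin))
  }
  picked
}

# naive per-point metrics oracle (loops, no confusion matrix)
metrics_oracle <- function(pred, true, M) {
  iou <- numeric(0)
  for (i in 0:(M - 1)) {
    tp <- sum(pred == i & true == i)
    fp <- sum(pred == i & true != i)
    fn <- sum(pred != i & true == i)
    if (tp + fp + fn > 0) iou <- c(iou, tp / (tp + fp + fn))
  }
  list(miou = mean(iou), oa = mean(pred == true))
}

# hand-made single-center neighborhood group with explicit features
manual_group <- function(center_feat, neighbor_feats, center_index = 1L,
                         neighbor_indices = NULL) {
  K <- nrow(neighbor_feats)
  C <- ncol(neighbor_feats)
  if (is.null(neighbor_indices))
    neighbor_indices <- matrix(seq_len(K) + 1L, 1, K)
  structure(list(
    center_indices = center_index,
    centers = matrix(0, 1, 3),
    neighbor_indices = neighbor_indices,
    rel_coords = array(0, c(1, K, 3)),
    neighbor_feats = array(t(neighbor_feats), dim = c(C, K, 1)) |>
      aperm(c(3, 2, 1)),
    center_feats = matrix(center_feat, 1, C),
    S = 1L, K = K, C = C),
    class = "neighborhood_group")
}
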