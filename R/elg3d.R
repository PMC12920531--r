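# The ELG3D encoder stage: three parallel neighborhood operators (EdgeConv,
# local attention, graph convolution) plus a mini-PointNet base path, fused
# per scale by an elementwise residual sum and across scales by a 1x1
# unification map.  The exported functions below are the plain (inference)
# operator contracts; the *_stage_* functions are the batch-normalized
# trainable versions used inside the assembled networks, with hand-written
# backward passes.

#' Scale specification for multi-scale grouping
#'
#' @param radius ball-query radius in normalized (unit-sphere) units.
#' @param K neighbors per center.
#' @param out_width operator output width at this scale (all four branches
#'   share it).
#' @return a `scale_spec` list.
#' @export
scale_spec <- function(radius, K, out_width) {
  stopifnot(radius > 0, K >= 1, out_width >= 1)
  list(radius = radius, K = as.integer(K), out_width = as.integer(out_width))
}

#' ELG3D stage configuration
#'
#' @param n_centers number of farthest-point-sampled centers.
#' @param scales list of [scale_spec()]s.
#' @param fused_width output width after the cross-scale 1x1 unification.
#' @return an `elg3d_config` list.
#' @export
elg3d_config <- function(n_centers, scales, fused_width) {
  stopifnot(n_centers >= 1, length(scales) >= 1, fused_width >= 1)
  list(type = "elg3d", n_centers = as.integer(n_centers), scales = scales,
       fused_width = as.integer(fused_width))
}

#' EdgeConv over a neighborhood group
#'
#' For each neighbor j of center i the edge feature `[f_i, f_j - f_i]` is
#' passed through a shared linear map with bias and rectifier, and the K
#' edge responses are reduced by an elementwise maximum — capturing local
#' geometric detail (leaf serrations, boll contours) independently of
#' neighbor ordering.
#'
#' @param group a `neighborhood_group` from [group_neighborhoods()].
#' @param weights list with `W` (2C x W) and `b` (length W).
#' @return S x W feature matrix.
#' @export
edge_conv <- function(group, weights) {
  gf <- group_flat(group)
  Fc_rep <- gf$Fc[rep(seq_len(gf$S), each = gf$K), , drop = FALSE]
  E <- cbind(Fc_rep, gf$G - Fc_rep)
  H <- relu(add_bias(E %*% weights$W, weights$b))
  cpp_group_max(H, gf$S, gf$K)$max
}

#' Local attention over a neighborhood group
#'
#' Per-neighbor values are a rectified shared linear map of the neighbor
#' feature; a second scalar-scoring map of the same input yields softmax
#' attention weights over the K neighbors; the output is the
#' attention-weighted sum of values.  The weights are exposed as the
#' `"alpha"` attribute (an S x K matrix, rows summing to 1).
#'
#' @param group a `neighborhood_group`.
#' @param weights list with `W` (C x W), `b`, `score_W` (C x 1), `score_b`.
#' @return S x W feature matrix with attribute `"alpha"`.
#' @export
local_attention <- function(group, weights) {
  gf <- group_flat(group)
  V <- relu(add_bias(gf$G %*% weights$W, weights$b))
  e <- as.vector(gf$G %*% weights$score_W) + weights$score_b
  alpha <- group_softmax(e, gf$S, gf$K)
  out <- rowsum(V * alpha, rep(seq_len(gf$S), each = gf$K))
  dimnames(out) <- NULL
  attr(out, "alpha") <- matrix(alpha, gf$S, gf$K, byrow = TRUE)
  out
}

#' One-layer graph convolution on per-center star graphs
#'
#' Each center and its (deduplicated, non-self) neighbors form a star graph
#' with self-loops; one propagation layer with symmetric normalization
#' `D^{-1/2} (A + I) D^{-1/2} X W` followed by a rectifier is applied and
#' the center node's row emitted.  Padding entries that collapse onto the
#' center reduce the graph to an isolated self-loop.
#'
#' @param group a `neighborhood_group`.
#' @param weights list with `W` (C x W) and `b`.
#' @return S x W feature matrix.
#' @export
gcn_aggregate <- function(group, weights) {
  gf <- group_flat(group)
  agg <- gcn_agg_matrix(gf, group$neighbor_indices, group$center_indices)
  relu(add_bias(agg$agg %*% weights$W, weights$b))
}

# the normalized-propagation center rows (linear in the node features)
gcn_agg_matrix <- function(gf, neighbor_indices, center_indices) {
  mask <- cpp_dedup_mask(neighbor_indices, as.integer(center_indices))
  degc <- 1 + rowSums(mask)                  # center degree with self-loop
  wc <- 1 / degc                             # 1/sqrt(degc)^2: self term
  wn <- mask / sqrt(2 * degc)                # leaf degree is always 2
  wn_flat <- as.vector(t(wn))
  grp <- rep(seq_len(gf$S), each = gf$K)
  agg <- gf$Fc * wc + rowsum(gf$G * wn_flat, grp)
  dimnames(agg) <- NULL
  list(agg = agg, wc = wc, wn_flat = wn_flat)
}

#' Same-scale residual fusion
#'
#' Elementwise sum of the three operator outputs and the base (mini-PointNet)
#' path, then a rectifier: the residual base passes through unattenuated when
#' the operator branches are silent.
#'
#' @param e,a,g S x W outputs of [edge_conv()], [local_attention()],
#'   [gcn_aggregate()].
#' @param base S x W max-pooled shared-linear feature of the raw
#'   neighborhood.
#' @return S x W fused features.
#' @export
fuse_same_scale <- function(e, a, g, base) {
  if (!all(dim(e) == dim(a)) || !all(dim(e) == dim(g)) ||
      !all(dim(e) == dim(base)))
    abort("all fusion inputs must share the same S x W shape")
  relu(e + a + g + base)
}

#' Cross-scale fusion by 1x1 convolution
#'
#' Concatenates the per-scale fused features along the feature axis and
#' applies a shared per-point linear map (+ rectifier) to the unified width.
#'
#' @param per_scale list of S x W_s matrices sharing S.
#' @param weights list with `W` (sum(W_s) x fused_width) and `b`.
#' @return S x fused_width matrix.
#' @export
fuse_cross_scale <- function(per_scale, weights) {
  S <- vapply(per_scale, nrow, 0L)
  if (length(unique(S)) != 1) abort("scales must share the center count S")
  relu(add_bias(do.call(cbind, per_scale) %*% weights$W, weights$b))
}

#' Initialize plain (inference-form) ELG3D operator weights
#'
#' @param config an [elg3d_config()].
#' @param in_channels feature width of the parent cloud (0 when the stage
#'   consumes raw coordinates only).
#' @param seed integer seed for reproducible initialization.
#' @return nested weights list usable by [elg3d_forward()].
#' @export
init_elg3d_weights <- function(config, in_channels = 0, seed = 0L) {
  C <- in_channels + 3
  withr_seed(seed, {
    mk <- function(ci, co) list(W = matrix(rnorm(ci * co, sd = sqrt(2 / ci)),
                                           ci, co),
                                b = numeric(co))
    scales <- lapply(config$scales, function(sc) {
      w <- sc$out_width
      att <- mk(C, w)
      sco <- mk(C, 1)
      list(edge = mk(2 * C, w),
           attention = c(att, list(score_W = sco$W, score_b = sco$b[1])),
           gcn = mk(C, w), base = mk(C, w))
    })
    tot <- sum(vapply(config$scales, function(sc) sc$out_width, 0L))
    list(scales = scales, unify = mk(tot, config$fused_width))
  })
}

#' Run one ELG3D stage
#'
#' Farthest-point-samples `n_centers` centers, and for every scale performs a
#' ball query, grouping, the three operators plus the base path,
#' [fuse_same_scale()], then [fuse_cross_scale()] across scales.
#' Deterministic given `(coords, feats, weights, start_index)`; translation
#' of `coords` leaves the features unchanged since every operator consumes
#' relative offsets and input features only.
#'
#' @param coords N x 3 coordinate matrix (normalized units).
#' @param feats N x C feature matrix or NULL.
#' @param config an [elg3d_config()].
#' @param weights from [init_elg3d_weights()].
#' @param start_index first farthest-point-sampling index.
#' @return list with `centers` (S x 3), `features` (S x fused_width),
#'   `center_indices`.
#' @export
elg3d_forward <- function(coords, feats, config, weights, start_index = 1L) {
  coords <- as.matrix(coords)
  if (config$n_centers > nrow(coords)) abort("n_centers > N")
  ci <- farthest_point_sample(coords, config$n_centers, start_index)
  centers <- coords[ci, , drop = FALSE]
  per_scale <- lapply(seq_along(config$scales), function(s) {
    sc <- config$scales[[s]]
    w <- weights$scales[[s]]
    ni <- ball_query(coords, centers, sc$radius, sc$K)
    group <- group_neighborhoods(coords, feats, ci, ni)
    base <- {
      gf <- group_flat(group)
      H <- relu(add_bias(gf$G %*% w$base$W, w$base$b))
      cpp_group_max(H, gf$S, gf$K)$max
    }
    fuse_same_scale(edge_conv(group, w$edge),
                    local_attention(group, w$attention),
                    gcn_aggregate(group, w$gcn),
                    base)
  })
  list(centers = centers,
       features = fuse_cross_scale(per_scale, weights$unify),
       center_indices = ci)
}

# ---------------------------------------------------------------------------
# trainable stage (batch-normalized units, cached forward, backward)

init_elg3d_stage <- function(params, buffers, cfg, c_feats, prefix) {
  C <- c_feats + 3
  for (s in seq_along(cfg$scales)) {
    w <- cfg$scales[[s]]$out_width
    nm <- function(op) paste0(prefix, ".s", s, ".", op)
    for (shape in list(c("edge", 2 * C, w), c("attv", C, w),
                       c("gcn", C, w), c("base", C, w))) {
      r <- init_unit(params, buffers, nm(shape[1]), as.integer(shape[2]),
                     as.integer(shape[3]))
      params <- r$params; buffers <- r$buffers
    }
    r <- init_unit(params, buffers, nm("atts"), C, 1L, bn = FALSE)
    params <- r$params; buffers <- r$buffers
  }
  tot <- sum(vapply(cfg$scales, function(sc) sc$out_width, 0L))
  r <- init_unit(params, buffers, paste0(prefix, ".unify"), tot,
                 cfg$fused_width)
  list(params = r$params, buffers = r$buffers)
}

elg3d_stage_fwd <- function(coords, feats, cfg, ctx, prefix,
                            start_index = 1L) {
  N <- nrow(coords)
  ci <- cpp_fps(coords, cfg$n_centers, as.integer(start_index))
  centers <- coords[ci, , drop = FALSE]
  S <- cfg$n_centers
  sc_caches <- vector("list", length(cfg$scales))
  per_scale <- vector("list", length(cfg$scales))
  for (s in seq_along(cfg$scales)) {
    sc <- cfg$scales[[s]]
    K <- sc$K
    nm <- function(op) paste0(prefix, ".s", s, ".", op)
    ni <- cpp_ball_query(coords, centers, sc$radius, K)
    flat <- as.vector(t(ni))
    grp <- rep(seq_len(S), each = K)
    rel <- coords[flat, , drop = FALSE] -
      centers[grp, , drop = FALSE]
    if (is.null(feats)) {
      G <- rel; Fc <- matrix(0, S, 3)
    } else {
      G <- cbind(feats[flat, , drop = FALSE], rel)
      Fc <- cbind(feats[ci, , drop = FALSE], matrix(0, S, 3))
    }
    C <- ncol(G)
    gf <- list(G = G, Fc = Fc, S = S, K = K)
    # EdgeConv branch
    Fc_rep <- Fc[grp, , drop = FALSE]
    E <- cbind(Fc_rep, G - Fc_rep)
    eu <- unit_fwd(E, ctx, nm("edge"))
    ep <- group_max_fwd(eu$out, S, K)
    # local-attention branch
    vu <- unit_fwd(G, ctx, nm("attv"))
    su <- unit_fwd(G, ctx, nm("atts"), act = FALSE)
    alpha <- group_softmax(as.vector(su$out), S, K)
    att <- rowsum(vu$out * alpha, grp)
    dimnames(att) <- NULL
    # graph-convolution branch
    ga <- gcn_agg_matrix(gf, ni, ci)
    gu <- unit_fwd(ga$agg, ctx, nm("gcn"))
    # base (mini-PointNet) branch
    bu <- unit_fwd(G, ctx, nm("base"))
    bp <- group_max_fwd(bu$out, S, K)
    pre <- ep$out + att + gu$out + bp$out
    fused <- relu(pre)
    per_scale[[s]] <- fused
    sc_caches[[s]] <- list(flat = flat, grp = grp, C = C,
                           c_feats = if (is.null(feats)) 0L else ncol(feats),
                           eu = eu, ep = ep, vu = vu, su = su, alpha = alpha,
                           gu = gu, ga = ga, bu = bu, bp = bp,
                           mask = pre > 0, K = K)
  }
  cat_feats <- do.call(cbind, per_scale)
  un <- unit_fwd(cat_feats, ctx, paste0(prefix, ".unify"))
  list(center_indices = ci, centers = centers, feats = un$out,
       cache = list(un = un, scales = sc_caches, widths =
                      vapply(per_scale, ncol, 0L), S = S, N = N, ci = ci,
                    has_feats = !is.null(feats)))
}

elg3d_stage_bwd <- function(dout, cache, ctx, gr) {
  dcat <- unit_bwd(dout, cache$un$cache, ctx, gr)
  S <- cache$S
  N <- cache$N
  offs <- cumsum(c(0L, cache$widths))
  dfeats <- NULL
  for (s in seq_along(cache$scales)) {
    sc <- cache$scales[[s]]
    dsum <- dcat[, offs[s] + seq_len(cache$widths[s]), drop = FALSE] * sc$mask
    C <- sc$C
    grp <- sc$grp
    dG <- matrix(0, length(sc$flat), C)
    dFc <- matrix(0, S, C)
    # EdgeConv
    dE <- unit_bwd(group_max_bwd(dsum, sc$ep), sc$eu$cache, ctx, gr)
    dG <- dG + dE[, C + seq_len(C), drop = FALSE]
    dFc <- dFc + rowsum(dE[, seq_len(C), drop = FALSE] -
                          dE[, C + seq_len(C), drop = FALSE], grp)
    # attention
    dsum_rep <- dsum[grp, , drop = FALSE]
    dv <- dsum_rep * sc$alpha
    dalpha <- rowSums(sc$vu$out * dsum_rep)
    de <- group_softmax_bwd(dalpha, sc$alpha, S, sc$K)
    dG <- dG + unit_bwd(dv, sc$vu$cache, ctx, gr)
    dG <- dG + unit_bwd(matrix(de, ncol = 1), sc$su$cache, ctx, gr)
    # graph convolution
    dagg <- unit_bwd(dsum, sc$gu$cache, ctx, gr)
    dFc <- dFc + dagg * sc$ga$wc
    dG <- dG + dagg[grp, , drop = FALSE] * sc$ga$wn_flat
    # base
    dG <- dG + unit_bwd(group_max_bwd(dsum, sc$bp), sc$bu$cache, ctx, gr)
    # route to the parent features (coords carry no trainable upstream)
    if (cache$has_feats) {
      cf <- sc$c_feats
      inc <- index_add(N, sc$flat, dG[, seq_len(cf), drop = FALSE])
      inc[cache$ci, ] <- inc[cache$ci, , drop = FALSE] +
        dFc[, seq_len(cf), drop = FALSE]
      dfeats <- if (is.null(dfeats)) inc else dfeats + inc
    }
  }
  dfeats
}
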