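# Model assembly: hierarchical encoder (ELG3D or plain multi-scale set
# abstraction), group-all global stage, feature-propagation decoder,
# optional enhancement module, per-point segmentation head.  One flat named
# parameter list per model; forward passes cache everything the hand-written
# backward passes need.

#' Plain set-abstraction stage configuration (baseline encoder)
#'
#' @param n_centers number of farthest-point-sampled centers.
#' @param scales list of `list(radius, K, mlp)` where `mlp` is the width
#'   chain of the shared mini-PointNet maps.
#' @return an `sa_config` list.
#' @export
sa_config <- function(n_centers, scales) {
  list(type = "sa", n_centers = as.integer(n_centers), scales = scales)
}

#' Group-all global stage configuration
#' @param widths shared-map width chain applied before global max pooling.
#' @return a `global_config` list.
#' @export
global_config <- function(widths) {
  list(type = "global", widths = as.integer(widths))
}

#' Full model configuration
#'
#' @param stages encoder stage list: [elg3d_config()] / [sa_config()] stages
#'   followed by one [global_config()]; center counts strictly decreasing.
#' @param fp decoder width chains, one integer vector per encoder stage
#'   (mirrored order: first entry decodes the global stage).
#' @param enhancement an [enhancement_config()] or NULL.
#' @param n_input_points points fed to the network per cloud.
#' @param n_classes number of organ classes M.
#' @param head_hidden hidden width of the segmentation head.
#' @param head_dropout dropout rate between the two head layers.
#' @param variant ablation tag ("A".."E") recorded on the model.
#' @param name human-readable model name.
#' @return a `model_config` list.
#' @export
model_config <- function(stages, fp, enhancement = NULL,
                         n_input_points = 2048L, n_classes = 3L,
                         head_hidden = 64L, head_dropout = 0.4,
                         variant = "E", name = "model") {
  L <- length(stages)
  if (stages[[L]]$type != "global")
    abort("the last encoder stage must be a global (group-all) stage")
  if (length(fp) != L)
    abort("decoder must mirror the encoder: one fp chain per stage")
  ctr <- vapply(stages[seq_len(L - 1)], function(s) s$n_centers, 0L)
  if (any(diff(ctr) >= 0)) abort("stage center counts must strictly decrease")
  structure(list(stages = stages, fp = lapply(fp, as.integer),
                 enhancement = enhancement,
                 n_input_points = as.integer(n_input_points),
                 n_classes = as.integer(n_classes),
                 head_hidden = as.integer(head_hidden),
                 head_dropout = head_dropout, variant = variant,
                 name = name),
            class = "model_config")
}

# feature width bookkeeping shared by parameter init and the FLOP profiler
config_widths <- function(config) {
  L <- length(config$stages)
  sw <- integer(L)
  prev <- 0L
  for (i in seq_len(L)) {
    st <- config$stages[[i]]
    sw[i] <- switch(st$type,
      elg3d = st$fused_width,
      sa = sum(vapply(st$scales, function(sc) tail(sc$mlp, 1), 0L)),
      global = tail(st$widths, 1))
    prev <- sw[i]
  }
  fp_in <- integer(L)
  fp_out <- integer(L)
  cw <- sw[L]
  for (j in seq_len(L)) {
    skip <- if (L - j >= 1) sw[L - j] else 0L
    fp_in[j] <- cw + skip
    fp_out[j] <- tail(config$fp[[j]], 1)
    cw <- fp_out[j]
  }
  head_in <- if (is.null(config$enhancement)) fp_out[L]
             else config$enhancement$out_width
  list(stage_out = sw, fp_in = fp_in, fp_out = fp_out, head_in = head_in)
}

init_sa_stage <- function(params, buffers, cfg, c_feats, prefix) {
  C <- c_feats + 3L
  for (s in seq_along(cfg$scales)) {
    widths <- cfg$scales[[s]]$mlp
    ci <- C
    for (j in seq_along(widths)) {
      r <- init_unit(params, buffers, paste0(prefix, ".s", s, ".l", j),
                     ci, widths[j])
      params <- r$params; buffers <- r$buffers
      ci <- widths[j]
    }
  }
  list(params = params, buffers = buffers)
}

init_global_stage <- function(params, buffers, cfg, c_feats, prefix) {
  ci <- c_feats + 3L
  for (j in seq_along(cfg$widths)) {
    r <- init_unit(params, buffers, paste0(prefix, ".l", j), ci,
                   cfg$widths[j])
    params <- r$params; buffers <- r$buffers
    ci <- cfg$widths[j]
  }
  list(params = params, buffers = buffers)
}

#' Build a model from a configuration
#'
#' Walks the configured stages in order, creating every weight array with a
#' seeded generator, so two builds from the same `(config, seed)` are
#' bit-identical.
#'
#' @param config a [model_config()].
#' @param seed integer initialization seed.
#' @return an `elgcot3d_model` list with `config`, `params`, `buffers`,
#'   `seed`.
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  widths <- config_widths(config)
  withr_seed(seed, {
    params <- list(); buffers <- list()
    prev <- 0L
    for (i in seq_along(config$stages)) {
      st <- config$stages[[i]]
      prefix <- paste0("enc", i)
      r <- switch(st$type,
        elg3d = init_elg3d_stage(params, buffers, st, prev, prefix),
        sa = init_sa_stage(params, buffers, st, prev, prefix),
        global = init_global_stage(params, buffers, st, prev, prefix))
      params <- r$params; buffers <- r$buffers
      prev <- widths$stage_out[i]
    }
    for (j in seq_along(config$fp)) {
      ci <- widths$fp_in[j]
      for (l in seq_along(config$fp[[j]])) {
        r <- init_unit(params, buffers, paste0("fp", j, ".l", l), ci,
                       config$fp[[j]][l])
        params <- r$params; buffers <- r$buffers
        ci <- config$fp[[j]][l]
      }
    }
    if (!is.null(config$enhancement)) {
      r <- init_enh_params(params, buffers, config$enhancement,
                           widths$fp_out[length(config$fp)])
      params <- r$params; buffers <- r$buffers
    }
    r <- init_unit(params, buffers, "head.l1", widths$head_in,
                   config$head_hidden)
    params <- r$params; buffers <- r$buffers
    r <- init_unit(params, buffers, "head.out", config$head_hidden,
                   config$n_classes, bn = FALSE)
    params <- r$params; buffers <- r$buffers
    structure(list(config = config, params = params, buffers = buffers,
                   seed = as.integer(seed)),
              class = "elgcot3d_model")
  })
}

#' @export
print.elgcot3d_model <- function(x, ...) {
  cat(sprintf("<%s> variant %s: %d classes, %d input points, %s parameters\n",
              x$config$name, x$config$variant, x$config$n_classes,
              x$config$n_input_points,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# stage forward/backward (baseline SA + group-all global)

sa_stage_fwd <- function(coords, feats, cfg, ctx, prefix, start_index = 1L) {
  N <- nrow(coords)
  ci <- cpp_fps(coords, cfg$n_centers, as.integer(start_index))
  centers <- coords[ci, , drop = FALSE]
  S <- cfg$n_centers
  sc_caches <- vector("list", length(cfg$scales))
  per_scale <- vector("list", length(cfg$scales))
  for (s in seq_along(cfg$scales)) {
    sc <- cfg$scales[[s]]
    ni <- cpp_ball_query(coords, centers, sc$radius, sc$K)
    flat <- as.vector(t(ni))
    rel <- coords[flat, , drop = FALSE] -
      centers[rep(seq_len(S), each = sc$K), , drop = FALSE]
    G <- if (is.null(feats)) rel
         else cbind(feats[flat, , drop = FALSE], rel)
    units <- vector("list", length(sc$mlp))
    H <- G
    for (j in seq_along(sc$mlp)) {
      units[[j]] <- unit_fwd(H, ctx, paste0(prefix, ".s", s, ".l", j))
      H <- units[[j]]$out
    }
    pool <- group_max_fwd(H, S, sc$K)
    per_scale[[s]] <- pool$out
    sc_caches[[s]] <- list(flat = flat, units = units, pool = pool,
                           c_feats = if (is.null(feats)) 0L else ncol(feats))
  }
  list(center_indices = ci, centers = centers,
       feats = do.call(cbind, per_scale),
       cache = list(scales = sc_caches, widths =
                      vapply(per_scale, ncol, 0L), N = N, ci = ci,
                    has_feats = !is.null(feats)))
}

sa_stage_bwd <- function(dout, cache, ctx, gr) {
  offs <- cumsum(c(0L, cache$widths))
  dfeats <- NULL
  for (s in seq_along(cache$scales)) {
    sc <- cache$scales[[s]]
    dH <- group_max_bwd(dout[, offs[s] + seq_len(cache$widths[s]),
                             drop = FALSE], sc$pool)
    for (j in rev(seq_along(sc$units)))
      dH <- unit_bwd(dH, sc$units[[j]]$cache, ctx, gr)
    if (cache$has_feats) {
      inc <- index_add(cache$N, sc$flat,
                       dH[, seq_len(sc$c_feats), drop = FALSE])
      dfeats <- if (is.null(dfeats)) inc else dfeats + inc
    }
  }
  dfeats
}

global_stage_fwd <- function(coords, feats, cfg, ctx, prefix) {
  ctr <- colMeans(coords)
  rel <- sweep(coords, 2, ctr)
  H <- if (is.null(feats)) rel else cbind(feats, rel)
  units <- vector("list", length(cfg$widths))
  for (j in seq_along(cfg$widths)) {
    units[[j]] <- unit_fwd(H, ctx, paste0(prefix, ".l", j))
    H <- units[[j]]$out
  }
  pool <- group_max_fwd(H, 1L, nrow(H))
  list(center_indices = NA_integer_, centers = matrix(ctr, 1, 3),
       feats = pool$out,
       cache = list(units = units, pool = pool,
                    c_feats = if (is.null(feats)) 0L else ncol(feats)))
}

global_stage_bwd <- function(dout, cache, ctx, gr) {
  dH <- group_max_bwd(dout, cache$pool)
  for (j in rev(seq_along(cache$units)))
    dH <- unit_bwd(dH, cache$units[[j]]$cache, ctx, gr)
  dH[, seq_len(cache$c_feats), drop = FALSE]
}

# ---------------------------------------------------------------------------
# feature propagation

#' Inverse-distance interpolation of coarse features onto fine points
#'
#' Each fine point receives the inverse-distance-weighted average of its 3
#' nearest coarse points' features, `w_i = (1/d_i) / sum_j (1/d_j)`; a fine
#' point coinciding with a coarse point takes that feature verbatim (zero
#' distances share the weight equally).  With a single coarse point the
#' feature is broadcast.
#'
#' @param coarse_coords Sc x 3 matrix.
#' @param coarse_feats Sc x C matrix.
#' @param fine_coords Nf x 3 matrix.
#' @return list with `feats` (Nf x C), `indices` (Nf x k), `weights`
#'   (Nf x k, rows nonnegative and summing to 1).
#' @export
fp_interpolate <- function(coarse_coords, coarse_feats, fine_coords) {
  Sc <- nrow(coarse_coords)
  if (Sc == 1) {
    Nf <- nrow(fine_coords)
    return(list(feats = coarse_feats[rep(1L, Nf), , drop = FALSE],
                indices = matrix(1L, Nf, 1),
                weights = matrix(1, Nf, 1)))
  }
  k <- min(3L, Sc)
  ni <- cpp_knn(coarse_coords, fine_coords, k)
  d2 <- vapply(seq_len(k), function(j)
    rowSums((fine_coords - coarse_coords[ni[, j], , drop = FALSE])^2),
    numeric(nrow(fine_coords)))
  d <- sqrt(matrix(d2, ncol = k))
  zero <- d < 1e-10
  w <- 1 / pmax(d, 1e-10)
  has0 <- rowSums(zero) > 0
  w[has0, ] <- zero[has0, , drop = FALSE] * 1
  w <- w / rowSums(w)
  feats <- matrix(0, nrow(fine_coords), ncol(coarse_feats))
  for (j in seq_len(k))
    feats <- feats + coarse_feats[ni[, j], , drop = FALSE] * w[, j]
  list(feats = feats, indices = ni, weights = w)
}

#' Feature-propagation decoder step
#'
#' [fp_interpolate()] then concatenation with the skip features and a shared
#' per-point linear map with rectifier.
#'
#' @inheritParams fp_interpolate
#' @param skip_feats Nf x Cs matrix or NULL.
#' @param weights list with `W` ((C + Cs) x W_out) and `b`.
#' @return Nf x W_out matrix.
#' @export
feature_propagation <- function(coarse_coords, coarse_feats, fine_coords,
                                skip_feats, weights) {
  ip <- fp_interpolate(as.matrix(coarse_coords), as.matrix(coarse_feats),
                       as.matrix(fine_coords))
  X <- if (is.null(skip_feats)) ip$feats else cbind(ip$feats, skip_feats)
  relu(add_bias(X %*% weights$W, weights$b))
}

fp_stage_fwd <- function(coarse_coords, coarse_feats, fine_coords,
                         skip_feats, widths, ctx, prefix) {
  ip <- fp_interpolate(coarse_coords, coarse_feats, fine_coords)
  H <- if (is.null(skip_feats)) ip$feats else cbind(ip$feats, skip_feats)
  units <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    units[[l]] <- unit_fwd(H, ctx, paste0(prefix, ".l", l))
    H <- units[[l]]$out
  }
  list(feats = H,
       cache = list(ip = ip, units = units, Sc = nrow(coarse_coords),
                    c_interp = ncol(coarse_feats),
                    has_skip = !is.null(skip_feats)))
}

fp_stage_bwd <- function(dout, cache, ctx, gr) {
  dH <- dout
  for (l in rev(seq_along(cache$units)))
    dH <- unit_bwd(dH, cache$units[[l]]$cache, ctx, gr)
  ci <- cache$c_interp
  dinterp <- dH[, seq_len(ci), drop = FALSE]
  dskip <- if (cache$has_skip) dH[, -seq_len(ci), drop = FALSE]
  ip <- cache$ip
  dcoarse <- matrix(0, cache$Sc, ci)
  for (j in seq_len(ncol(ip$indices))) {
    inc <- index_add(cache$Sc, ip$indices[, j], dinterp * ip$weights[, j])
    dcoarse <- dcoarse + inc
  }
  list(dcoarse = dcoarse, dskip = dskip)
}

# ---------------------------------------------------------------------------
# full forward / backward

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

net_fwd <- function(model, coords, mode = "eval", keep_cache = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- model$params
  ctx$buffers <- list2env(model$buffers, parent = emptyenv())
  ctx$mode <- mode
  cfg <- model$config
  L <- length(cfg$stages)
  lev_coords <- vector("list", L + 1)
  lev_feats <- vector("list", L + 1)
  enc_caches <- vector("list", L)
  lev_coords[[1]] <- coords
  lev_feats[[1]] <- NULL
  for (i in seq_len(L)) {
    st <- cfg$stages[[i]]
    prefix <- paste0("enc", i)
    r <- switch(st$type,
      elg3d = elg3d_stage_fwd(lev_coords[[i]], lev_feats[[i]], st, ctx,
                              prefix, canonical_start(lev_coords[[i]])),
      sa = sa_stage_fwd(lev_coords[[i]], lev_feats[[i]], st, ctx, prefix,
                        canonical_start(lev_coords[[i]])),
      global = global_stage_fwd(lev_coords[[i]], lev_feats[[i]], st, ctx,
                                prefix))
    lev_coords[[i + 1]] <- r$centers
    lev_feats[[i + 1]] <- r$feats
    enc_caches[[i]] <- r$cache
  }
  dec_feats <- lev_feats[[L + 1]]
  dec_coords <- lev_coords[[L + 1]]
  fp_caches <- vector("list", L)
  for (j in seq_len(L)) {
    fine_level <- L - j + 1                       # index into lev_* lists
    skip <- lev_feats[[fine_level]]
    r <- fp_stage_fwd(dec_coords, dec_feats, lev_coords[[fine_level]],
                      skip, cfg$fp[[j]], ctx, paste0("fp", j))
    dec_feats <- r$feats
    dec_coords <- lev_coords[[fine_level]]
    fp_caches[[j]] <- r$cache
  }
  attention <- NULL
  enh_cache <- NULL
  if (!is.null(cfg$enhancement)) {
    r <- enh_fwd(dec_feats, coords, cfg$enhancement, ctx)
    dec_feats <- r$out
    attention <- r$attention
    enh_cache <- r$cache
  }
  h1 <- unit_fwd(dec_feats, ctx, "head.l1")
  dp <- dropout_fwd(h1$out, cfg$head_dropout, mode)
  ho <- unit_fwd(dp$out, ctx, "head.out", act = FALSE)
  probs <- row_softmax(ho$out)
  out <- list(probs = probs, logits = ho$out, attention = attention,
              buffers = as.list(ctx$buffers))
  if (keep_cache)
    out$cache <- list(ctx = ctx, enc = enc_caches, fp = fp_caches,
                      enh = enh_cache, h1 = h1, dp = dp, ho = ho, L = L)
  out
}

net_bwd <- function(model, fw, dlogits) {
  cache <- fw$cache
  ctx <- cache$ctx
  gr <- new.env(parent = emptyenv())
  d <- unit_bwd(dlogits, cache$ho$cache, ctx, gr)
  d <- dropout_bwd(d, cache$dp$mask)
  d <- unit_bwd(d, cache$h1$cache, ctx, gr)
  if (!is.null(cache$enh))
    d <- enh_bwd(d, cache$enh, ctx, gr)
  L <- cache$L
  skip_grads <- vector("list", L + 1)             # grads on encoder levels
  for (j in rev(seq_len(L))) {
    r <- fp_stage_bwd(d, cache$fp[[j]], ctx, gr)
    fine_level <- L - j + 1
    if (!is.null(r$dskip))
      skip_grads[[fine_level]] <- add_or_set(skip_grads[[fine_level]],
                                             r$dskip)
    d <- r$dcoarse                                 # grad on the next-coarser
  }
  skip_grads[[L + 1]] <- add_or_set(skip_grads[[L + 1]], d)
  denc <- skip_grads[[L + 1]]
  for (i in rev(seq_len(L))) {
    st <- model$config$stages[[i]]
    dprev <- switch(st$type,
      elg3d = elg3d_stage_bwd(denc, cache$enc[[i]], ctx, gr),
      sa = sa_stage_bwd(denc, cache$enc[[i]], ctx, gr),
      global = global_stage_bwd(denc, cache$enc[[i]], ctx, gr))
    if (i > 1) {
      denc <- add_or_set(skip_grads[[i]], dprev)
    }
  }
  as.list(gr)
}

add_or_set <- function(a, b) if (is.null(a)) b else a + b

#' Build the reference lightweight segmentation network
#'
#' Two ELG3D encoder stages, one group-all global stage, three
#' feature-propagation decoder steps, the enhancement module on the final
#' per-point features, and a two-layer head with dropout and
#' exponential-normalized class probabilities.
#'
#' @param config a [model_config()]; default [reference_elgcot3d_config()].
#' @param seed integer weight-initialization seed.
#' @return an `elgcot3d_model`.
#' @export
build_elgcot3d <- function(config = reference_elgcot3d_config(),
                           seed = 0L) {
  build_model(config, seed)
}

#' Build the multi-scale-grouping hierarchical baseline
#'
#' The comparison anchor: plain set-abstraction stages (multi-scale grouping
#' with shared mini-PointNet maps and max pooling), no enhancement module.
#' Serves as ablation variant A and as the denominator of the
#' parameter/FLOP reduction percentages.
#'
#' @param config a [model_config()]; default [reference_baseline_config()].
#' @param seed integer weight-initialization seed.
#' @return an `elgcot3d_model`.
#' @export
build_pointnet2_baseline <- function(config = reference_baseline_config(),
                                     seed = 0L) {
  build_model(config, seed)
}

#' Reference configuration of the lightweight network
#'
#' Widths chosen so the assembled model stays within the published budget of
#' 0.86 M trainable parameters and 2.41 GFLOPs at 2048 input points.
#'
#' @param n_classes number of organ classes.
#' @param n_points input points per cloud.
#' @return a [model_config()].
#' @export
reference_elgcot3d_config <- function(n_classes = 3L, n_points = 2048L) {
  model_config(
    stages = list(
      elg3d_config(512L, list(scale_spec(0.1, 16, 48),
                              scale_spec(0.2, 32, 64),
                              scale_spec(0.4, 64, 96)), 128L),
      elg3d_config(128L, list(scale_spec(0.4, 32, 128),
                              scale_spec(0.8, 64, 128)), 256L),
      global_config(c(256L, 512L))),
    fp = list(256L, 128L, 128L),
    enhancement = enhancement_config(branch_ks = c(1L, 8L, 16L),
                                     branch_width = 43L,
                                     integration_width = 128L,
                                     attention_reduction = 4L,
                                     ds_kernel = 3L, out_width = 128L),
    n_input_points = n_points, n_classes = n_classes,
    head_hidden = 64L, head_dropout = 0.4, variant = "E",
    name = "ELGCot3D")
}

#' Reference configuration of the baseline
#'
#' The standard multi-scale-grouping part-segmentation layout of the
#' hierarchical point network family, XYZ-only input.
#'
#' @inheritParams reference_elgcot3d_config
#' @return a [model_config()].
#' @export
reference_baseline_config <- function(n_classes = 3L, n_points = 2048L) {
  model_config(
    stages = list(
      sa_config(512L, list(
        list(radius = 0.1, K = 32L, mlp = c(32L, 32L, 64L)),
        list(radius = 0.2, K = 64L, mlp = c(64L, 64L, 128L)),
        list(radius = 0.4, K = 128L, mlp = c(64L, 96L, 128L)))),
      sa_config(128L, list(
        list(radius = 0.4, K = 64L, mlp = c(128L, 128L, 256L)),
        list(radius = 0.8, K = 128L, mlp = c(128L, 196L, 256L)))),
      global_config(c(256L, 512L, 1024L))),
    fp = list(c(256L, 256L), c(256L, 128L), c(128L, 128L, 128L)),
    enhancement = NULL,
    n_input_points = n_points, n_classes = n_classes,
    head_hidden = 128L, head_dropout = 0.5, variant = "A",
    name = "PointNet++ MSG baseline")
}

#' Ablation variant configurations
#'
#' \describe{
#'   \item{A}{the baseline exactly.}
#'   \item{B}{baseline with the two set-abstraction stages replaced by
#'     ELG3D stages.}
#'   \item{C}{baseline encoder with the streamlined single-layer decoder,
#'     the enhancement module and the slim head (the lightweight path).}
#'   \item{D}{the baseline architecture (the training-strategy variant is
#'     architecturally identical to A).}
#'   \item{E}{the full lightweight model.}
#' }
#'
#' @param variant one of "A".."E".
#' @inheritParams reference_elgcot3d_config
#' @return a [model_config()].
#' @export
ablation_config <- function(variant = c("A", "B", "C", "D", "E"),
                            n_classes = 3L, n_points = 2048L) {
  variant <- match.arg(variant)
  base <- reference_baseline_config(n_classes, n_points)
  full <- reference_elgcot3d_config(n_classes, n_points)
  cfg <- switch(variant,
    A = base,
    B = {
      b <- base
      b$stages[1:2] <- full$stages[1:2]
      b$name <- "baseline + ELG3D"
      b
    },
    C = {
      b <- base
      b$fp <- full$fp
      b$enhancement <- full$enhancement
      b$head_hidden <- full$head_hidden
      b$head_dropout <- full$head_dropout
      b$name <- "baseline + enhancement"
      b
    },
    D = {
      b <- base
      b$name <- "baseline + training strategy"
      b
    },
    E = full)
  cfg$variant <- variant
  cfg
}

#' Desk-scale reduced-width configuration
#'
#' A narrow version of the full model for CPU-only experiments and the
#' self-contained overfitting demonstrations: same architecture, reduced
#' widths and center counts, sized for 512-point clouds.  The first stage
#' keeps a small-radius (0.1) grouping scale because boll surfaces span
#' only a few percent of the normalized radius.
#'
#' @param n_classes number of organ classes.
#' @param n_points input points per cloud (default 512).
#' @return a [model_config()].
#' @export
reduced_elgcot3d_config <- function(n_classes = 3L, n_points = 512L) {
  model_config(
    stages = list(
      elg3d_config(160L, list(scale_spec(0.1, 8, 24),
                              scale_spec(0.2, 12, 24),
                              scale_spec(0.4, 16, 32)), 64L),
      elg3d_config(40L, list(scale_spec(0.4, 12, 48),
                             scale_spec(0.8, 16, 48)), 96L),
      global_config(c(96L, 128L))),
    fp = list(96L, 64L, 64L),
    enhancement = enhancement_config(branch_ks = c(1L, 8L), branch_width = 32L,
                                     integration_width = 64L,
                                     attention_reduction = 4L,
                                     ds_kernel = 3L, out_width = 64L),
    n_input_points = n_points, n_classes = n_classes,
    head_hidden = 48L, head_dropout = 0.2, variant = "E",
    name = "ELGCot3D (reduced)")
}

#' Segment a point cloud with a trained model
#'
#' Normalizes the cloud into the unit sphere, samples it to the model's
#' input size (farthest-point subsampling when larger, index cycling when
#' smaller), runs a deterministic evaluation-mode forward pass, and maps the
#' per-point predictions back to every original point through its nearest
#' sampled point.
#'
#' @param model an `elgcot3d_model`.
#' @param cloud a [point_cloud()].
#' @return list with `class_probabilities` (N x M), `predicted_labels`
#'   (N, ids from 0; argmax ties resolved to the lowest class id),
#'   `attention` (per-original-point gates, when the model has the
#'   enhancement module) and `cloud` (the input cloud with a `label` column
#'   of predictions).
#' @export
segment_points <- function(model, cloud) {
  if (nrow(cloud) < 1) abort("empty cloud")
  norm <- normalize_unit_sphere(cloud)
  xyz <- pc_coords(norm)
  n <- model$config$n_input_points
  N <- nrow(xyz)
  sel <- if (N >= n) cpp_fps(xyz, as.integer(n), canonical_start(xyz))
         else rep_len(seq_len(N), n)
  sub <- xyz[sel, , drop = FALSE]
  fw <- net_fwd(model, sub, mode = "eval")
  back <- as.vector(cpp_knn(sub, xyz, 1L))
  probs <- fw$probs[back, , drop = FALSE]
  labels <- max.col(probs, ties.method = "first") - 1L
  out_cloud <- cloud
  out_cloud$label <- labels
  list(class_probabilities = probs,
       predicted_labels = labels,
       attention = if (!is.null(fw$attention))
         list(point_gates = fw$attention$point_gates[back],
              channel_gates = fw$attention$channel_gates),
       cloud = out_cloud)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized container holding the configuration,
#' the initialization seed, all weight arrays and normalization buffers
#' (and, when given, the optimizer state), reloadable bit-exactly.
#'
#' @param model an `elgcot3d_model`.
#' @param path file path.
#' @param optimizer_state optional optimizer state to store alongside.
#' @return `path` invisibly (`save_checkpoint`); the restored list with
#'   `model` and `optimizer_state` (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path, optimizer_state = NULL) {
  saveRDS(list(model = model, optimizer_state = optimizer_state,
               version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
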