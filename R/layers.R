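# Low-level differentiable units.
#
# All network parameters live in one flat named list (`model$params`); a
# "unit" named `nm` owns `nm.W` (C_in x C_out), `nm.b`, and - when it is a
# per-point map followed by normalization - `nm.gamma`, `nm.beta` plus
# non-trainable running statistics `nm.rm`, `nm.rv` in `model$buffers`.
# Forward functions return the output plus a cache; backward functions take
# the output gradient and the cache, accumulate parameter gradients into an
# environment, and return the input gradient.  Gradients are checked against
# finite differences in the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

relu <- function(x) {
  x[x < 0] <- 0
  x
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# accumulate `val` into gr[[name]]
gacc <- function(gr, name, val) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

init_unit <- function(params, buffers, name, c_in, c_out, bn = TRUE) {
  # He-style fan-in scaling, suited to rectifier units
  params[[paste0(name, ".W")]] <-
    matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)
  params[[paste0(name, ".b")]] <- numeric(c_out)
  if (bn) {
    params[[paste0(name, ".gamma")]] <- rep(1, c_out)
    params[[paste0(name, ".beta")]] <- numeric(c_out)
    buffers[[paste0(name, ".rm")]] <- numeric(c_out)
    buffers[[paste0(name, ".rv")]] <- rep(1, c_out)
  }
  list(params = params, buffers = buffers)
}

# shared per-point linear map (+ optional batch-style normalization over the
# point axis, + optional rectifier)
unit_fwd <- function(X, ctx, name, act = TRUE) {
  p <- ctx$params
  W <- p[[paste0(name, ".W")]]
  Z <- add_bias(X %*% W, p[[paste0(name, ".b")]])
  gamma <- p[[paste0(name, ".gamma")]]
  cache <- list(X = X, name = name, act = act, bn = !is.null(gamma))
  if (!is.null(gamma)) {
    # point-axis normalization: statistics of the current cloud in BOTH
    # modes (train and eval see identical semantics; evaluation stays
    # deterministic because the statistics are functions of the input)
    beta <- p[[paste0(name, ".beta")]]
    mu <- colMeans(Z)
    Zc <- Z - rep(mu, each = nrow(Z))
    va <- colMeans(Zc^2)
    istd <- 1 / sqrt(va + BN_EPS)
    Zh <- Zc * rep(istd, each = nrow(Z))
    if (ctx$mode == "train") {
      bm <- BN_MOMENTUM   # running stats kept for diagnostics/checkpoints
      ctx$buffers[[paste0(name, ".rm")]] <-
        (1 - bm) * ctx$buffers[[paste0(name, ".rm")]] + bm * mu
      ctx$buffers[[paste0(name, ".rv")]] <-
        (1 - bm) * ctx$buffers[[paste0(name, ".rv")]] + bm * va
    }
    cache$Zh <- Zh; cache$istd <- istd
    A <- add_bias(Zh * rep(gamma, each = nrow(Z)), beta)
  } else {
    A <- Z
  }
  if (act) {
    mask <- A > 0
    A <- A * mask
    cache$mask <- mask
  }
  list(out = A, cache = cache)
}

unit_bwd <- function(dY, cache, ctx, gr) {
  name <- cache$name
  p <- ctx$params
  W <- p[[paste0(name, ".W")]]
  if (cache$act) dY <- dY * cache$mask
  if (cache$bn) {
    gamma <- p[[paste0(name, ".gamma")]]
    n <- nrow(dY)
    gacc(gr, paste0(name, ".beta"), colSums(dY))
    gacc(gr, paste0(name, ".gamma"), colSums(dY * cache$Zh))
    dZh <- dY * rep(gamma, each = n)
    # full normalization backward (statistics are functions of Z)
    s1 <- colSums(dZh)
    s2 <- colSums(dZh * cache$Zh)
    dZ <- (dZh - rep(s1 / n, each = n) -
             cache$Zh * rep(s2 / n, each = n)) *
      rep(cache$istd, each = n)
  } else {
    dZ <- dY
  }
  gacc(gr, paste0(name, ".W"), crossprod(cache$X, dZ))
  gacc(gr, paste0(name, ".b"), colSums(dZ))
  dZ %*% t(W)
}

# max over K consecutive rows per group; returns S x C maxima + scatter info
group_max_fwd <- function(X, S, K) {
  gm <- cpp_group_max(X, as.integer(S), as.integer(K))
  list(out = gm$max, argmax = gm$argmax, n_in = nrow(X), C = ncol(X))
}

group_max_bwd <- function(dY, cache) {
  dX <- matrix(0, cache$n_in, cache$C)
  idx <- cbind(as.vector(cache$argmax), rep(seq_len(cache$C),
                                            each = nrow(dY)))
  dX[idx] <- as.vector(dY)
  dX
}

# numerically stable softmax over each group of K consecutive entries
group_softmax <- function(score, S, K) {
  m <- matrix(score, nrow = K)                    # columns = groups
  mx <- apply(m, 2, max)
  e <- exp(m - rep(mx, each = K))
  sums <- colSums(e)
  as.vector(e / rep(sums, each = K))
}

# d(score) given d(alpha) for a grouped softmax
group_softmax_bwd <- function(dalpha, alpha, S, K) {
  grp <- rep(seq_len(S), each = K)
  inner <- rowsum(alpha * dalpha, grp)            # S x 1 sums
  alpha * (dalpha - inner[grp, ])
}

# scatter-add rows of `dG` (indexed by `flat`, values 1..N) into an N x C matrix
index_add <- function(N, flat, dG) {
  rs <- rowsum(dG, flat)
  out <- matrix(0, N, ncol(dG))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# inverted dropout; draws from the current RNG stream
dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0)
    return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}
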