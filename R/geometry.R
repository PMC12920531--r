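#' Farthest point sampling
#'
#' Greedy subset selection: starting from `start_index`, each subsequent pick
#' maximizes the minimum Euclidean distance to all points already selected;
#' ties are broken by the lowest index.  This is the center-selection step of
#' every set-abstraction / ELG3D encoder stage.
#'
#' @param coords N x 3 coordinate matrix.
#' @param S number of samples, `1 <= S <= N`.
#' @param start_index 1-based index of the first selected point (default 1;
#'   deterministic).
#' @return integer vector of `S` 1-based indices, first equal to
#'   `start_index`.
#' @examples
#' pts <- cbind(c(0, 1, 2, 3, 10), 0, 0)
#' farthest_point_sample(pts, 3)  # 1, 5, 4
#' @export
farthest_point_sample <- function(coords, S, start_index = 1L) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  if (S < 1 || S > N) abort(sprintf("S must be in [1, N = %d], got %d", N, S))
  if (start_index < 1 || start_index > N) abort("start_index out of range")
  cpp_fps(coords, as.integer(S), as.integer(start_index))
}

#' Fixed-radius neighborhood query
#'
#' For each center, returns up to `K` point indices within `radius`
#' (Euclidean), in ascending index order.  If fewer than `K` qualify, the
#' nearest qualifying index is repeated to fill the row (a geometric choice,
#' so padded groups do not depend on point storage order); if the ball is
#' empty, the nearest point's index fills all `K` slots — so every row is
#' always usable for fixed-size grouping.
#'
#' @param coords N x 3 coordinate matrix.
#' @param centers S x 3 center matrix.
#' @param radius ball radius (> 0), in the same (normalized) units as
#'   `coords`.
#' @param K neighbors per center (>= 1).
#' @return S x K matrix of 1-based indices.
#' @export
ball_query <- function(coords, centers, radius, K) {
  coords <- as.matrix(coords)
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (radius <= 0) abort("radius must be > 0")
  if (K < 1) abort("K must be >= 1")
  cpp_ball_query(coords, centers, radius, as.integer(K))
}

#' K nearest neighbors
#'
#' @param coords N x 3 data matrix.
#' @param queries Q x 3 query matrix.
#' @param K neighbors per query, `K <= N`; returned in ascending distance,
#'   ties broken by lowest index.
#' @return Q x K matrix of 1-based indices.
#' @export
knn <- function(coords, queries, K) {
  coords <- as.matrix(coords)
  queries <- matrix(as.numeric(queries), ncol = 3)
  if (K > nrow(coords)) abort("K must be <= number of data points")
  if (K < 1) abort("K must be >= 1")
  cpp_knn(coords, queries, as.integer(K))
}

#' Gather neighborhood groups
#'
#' Builds the grouped tensors every neighborhood operator consumes: relative
#' offsets `x_j - x_i` and per-neighbor features.  Gathered neighbor features
#' are the parent features concatenated with the relative offsets (width
#' `C + 3`); when `feats` is NULL the neighbor features are the offsets alone
#' (width 3).  The group also carries each center's own feature (parent
#' feature with a zero offset) which the EdgeConv and graph operators need.
#'
#' @param coords N x 3 coordinate matrix of the parent cloud.
#' @param feats N x C feature matrix or NULL.
#' @param center_indices S-vector of 1-based center indices.
#' @param neighbor_indices S x K matrix of 1-based neighbor indices
#'   (e.g. from [ball_query()]).
#' @return a `neighborhood_group`: list with `center_indices`, `centers`
#'   (S x 3), `neighbor_indices` (S x K), `rel_coords` (S x K x 3 array),
#'   `neighbor_feats` (S x K x C array) and `center_feats` (S x C).
#' @export
group_neighborhoods <- function(coords, feats, center_indices,
                                neighbor_indices) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  ni <- as.matrix(neighbor_indices)
  ci <- as.integer(center_indices)
  if (any(ci < 1 | ci > N) || any(ni < 1 | ni > N))
    abort("index out of range")
  S <- length(ci); K <- ncol(ni)
  flat <- as.vector(t(ni))                       # center-major
  centers <- coords[ci, , drop = FALSE]
  rel <- coords[flat, , drop = FALSE] -
    centers[rep(seq_len(S), each = K), , drop = FALSE]
  if (is.null(feats)) {
    nf <- rel
    cf <- matrix(0, S, 3)
  } else {
    feats <- as.matrix(feats)
    nf <- cbind(feats[flat, , drop = FALSE], rel)
    cf <- cbind(feats[ci, , drop = FALSE], matrix(0, S, 3))
  }
  C <- ncol(nf)
  structure(list(
    center_indices = ci,
    centers = centers,
    neighbor_indices = ni,
    rel_coords = flat_to_array(rel, S, K),
    neighbor_feats = flat_to_array(nf, S, K),
    center_feats = cf,
    S = S, K = K, C = C),
    class = "neighborhood_group")
}

# (S*K) x C center-major matrix  ->  S x K x C array, and back
flat_to_array <- function(m, S, K) {
  aperm(array(t(m), dim = c(ncol(m), K, S)), c(3, 2, 1))
}

array_to_flat <- function(a) {
  d <- dim(a)
  t(matrix(aperm(a, c(3, 2, 1)), nrow = d[3]))
}

group_flat <- function(group) {
  list(G = array_to_flat(group$neighbor_feats),
       Fc = group$center_feats, S = group$S, K = group$K)
}

#' Canonical farthest-point-sampling start index
#'
#' The point farthest from the centroid (ties to the lowest index): a
#' geometric choice, so resampling and encoder center selection do not
#' depend on the storage order of the points.
#'
#' @param coords N x 3 matrix.
#' @return 1-based index.
#' @export
canonical_start <- function(coords) {
  d <- rowSums(sweep(as.matrix(coords), 2, colMeans(coords))^2)
  which.max(d)
}
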