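#' Construct a point cloud
#'
#' A point cloud is a tibble with one row per point: columns `x`, `y`, `z`
#' (scene units), optional colors `r`, `g`, `b` in \[0, 1\], and an optional
#' integer `label` giving the organ class id in `[0, n_classes)`.  The sample
#' identifier travels as an attribute so clouds can be split into named
#' train/validation/test sets.
#'
#' @param coords numeric N x 3 matrix (or data frame) of XYZ coordinates.
#' @param colors optional N x 3 matrix of RGB values in \[0, 1\].
#' @param labels optional integer vector of length N, class ids from 0.
#' @param sample_id character scalar naming the sample.
#' @param class_names optional character vector mapping label id `i` to
#'   `class_names[i + 1]`; carried as an attribute.
#' @return A `point_cloud` tibble.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3), labels = rep(0:1, 5))
#' pc
#' @export
point_cloud <- function(coords, colors = NULL, labels = NULL,
                        sample_id = "sample", class_names = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("`coords` must have exactly 3 columns")
  if (nrow(coords) < 1) abort("a point cloud needs at least one point (N >= 1)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) abort("`coords` must be finite")
  out <- tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != nrow(coords) || ncol(colors) != 3)
      abort("`colors` must be an N x 3 matrix")
    out$r <- colors[, 1]; out$g <- colors[, 2]; out$b <- colors[, 3]
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(coords))
      abort("`labels` must have exactly N entries")
    labels <- as.integer(labels)
    if (anyNA(labels) || any(labels < 0))
      abort("labels must be nonnegative integers")
    out$label <- labels
  }
  new_point_cloud(out, sample_id = sample_id, class_names = class_names)
}

new_point_cloud <- function(df, sample_id = "sample", class_names = NULL) {
  structure(df,
            class = c("point_cloud", class(tibble())),
            sample_id = sample_id,
            class_names = class_names)
}

#' Coerce a data frame to a point cloud
#'
#' @param x data frame with columns `x`, `y`, `z` and optionally
#'   `r`, `g`, `b`, `label`.
#' @inheritParams point_cloud
#' @return A `point_cloud` tibble.
#' @export
as_point_cloud <- function(x, sample_id = "sample", class_names = NULL) {
  if (inherits(x, "point_cloud")) return(x)
  if (!all(c("x", "y", "z") %in% names(x)))
    abort("need columns x, y, z")
  point_cloud(cbind(x$x, x$y, x$z),
              colors = if (all(c("r", "g", "b") %in% names(x)))
                cbind(x$r, x$g, x$b),
              labels = x$label,
              sample_id = sample_id, class_names = class_names)
}

#' @export
print.point_cloud <- function(x, ...) {
  id <- attr(x, "sample_id")
  cat(sprintf("# point cloud '%s': %d points%s%s\n", id, nrow(x),
              if ("label" %in% names(x))
                sprintf(", %d classes", length(unique(x$label))) else "",
              if ("r" %in% names(x)) ", with colors" else ""))
  NextMethod()
}

#' Extract the coordinate matrix of a point cloud
#' @param cloud a `point_cloud`.
#' @return N x 3 numeric matrix.
#' @export
pc_coords <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

#' Extract the label vector of a point cloud (or NULL)
#' @param cloud a `point_cloud`.
#' @return integer vector or NULL.
#' @export
pc_labels <- function(cloud) {
  if ("label" %in% names(cloud)) as.integer(cloud$label) else NULL
}

pc_replace_coords <- function(cloud, coords) {
  cloud$x <- coords[, 1]; cloud$y <- coords[, 2]; cloud$z <- coords[, 3]
  cloud
}

#' Center a cloud and scale it into the unit sphere
#'
#' Subtracts the centroid and divides by the maximum point norm so the
#' furthest point sits on the unit sphere.  All grouping radii used by the
#' encoders are expressed in these normalized units, so every cloud is
#' normalized before it reaches a network.  A degenerate cloud whose points
#' all coincide maps to the origin.  Labels and colors are untouched.
#'
#' @param cloud a `point_cloud`.
#' @return the normalized `point_cloud`.
#' @export
normalize_unit_sphere <- function(cloud) {
  xyz <- pc_coords(cloud)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  rmax <- sqrt(max(rowSums(xyz^2)))
  if (rmax > 0) xyz <- xyz / rmax
  pc_replace_coords(cloud, xyz)
}

#' Reproducible train/validation/test split
#'
#' Shuffles the ids with the given seed, then allocates `floor(n * ratio)`
#' ids to train and validation in order and the remainder to test.  On id
#' counts that are multiples of 10 the default ratios reproduce a 7:2:1
#' split exactly.
#'
#' @param ids character vector of sample ids.
#' @param ratios three nonnegative reals summing to 1
#'   (default `c(0.7, 0.2, 0.1)`).
#' @param seed integer seed; the same `(ids, ratios, seed)` always yields the
#'   identical split.
#' @return list with `train_ids`, `val_ids`, `test_ids`, `ratios`, `seed`.
#' @examples
#' split_dataset(sprintf("p%02d", 1:10), seed = 1)
#' @export
split_dataset <- function(ids, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (length(ids) == 0) abort("`ids` must be nonempty")
  if (length(ratios) != 3 || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    abort("`ratios` must be three nonnegative reals summing to 1")
  if (anyDuplicated(ids)) abort("`ids` must be unique")
  n <- length(ids)
  shuffled <- withr_seed(seed, sample(ids))
  n_train <- floor(n * ratios[1])
  n_val <- floor(n * ratios[2])
  list(train_ids = shuffled[seq_len(n_train)],
       val_ids = shuffled[n_train + seq_len(n_val)],
       test_ids = shuffled[setdiff(seq_len(n), seq_len(n_train + n_val))],
       ratios = ratios, seed = as.integer(seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
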