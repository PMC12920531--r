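# Procedural cotton-like plants: a tapered, gently curved stem tube,
# serrated elliptical leaf discs attached at drawn heights/azimuths, and
# spherical bolls at short branch tips.  Geometry is deliberately simple
# parametric surfaces — the aim is the statistical structure of real scans
# (dense foliage, class imbalance, organ scale heterogeneity, sensor jitter,
# one-sided self-occlusion), not botanical realism.

#' Synthetic plant configuration
#'
#' Scene units are meters; a plant stands roughly 1 m tall.  Surface-area
#' proportional sampling reproduces the class imbalance of cotton scans
#' (foliage >> boll > stem points).
#'
#' @param n_points points per plant after occlusion and resampling.
#' @param class_mode `"three_class"` (stem / leaf / boll) or `"two_class"`
#'   (foliage / boll, stems counted as foliage).
#' @param n_leaves integer range `c(lo, hi)` of leaf count.
#' @param n_bolls integer range of boll count.
#' @param stem_height range of stem height (m).
#' @param stem_radius range of stem base radius (m); the tube tapers to 40%
#'   at the top.
#' @param leaf_length range of leaf length (m); width is
#'   `leaf_aspect * length`.
#' @param leaf_aspect leaf width/length ratio.
#' @param serration_amp relative amplitude of the sinusoidal leaf-edge
#'   serration.
#' @param boll_radius range of boll radius (m).
#' @param jitter_sigma Gaussian sensor-noise s.d. as a fraction of plant
#'   height.
#' @param occlusion_fraction fraction of points removed as self-occluded
#'   from a random view direction, in \[0, 0.3\].
#' @param seed default generation seed.
#' @return a `synthetic_plant_config` list.
#' @export
synthetic_plant_config <- function(n_points = 2048L,
                                   class_mode = c("three_class", "two_class"),
                                   n_leaves = c(6L, 12L),
                                   n_bolls = c(3L, 8L),
                                   stem_height = c(0.9, 1.3),
                                   stem_radius = c(0.003, 0.005),
                                   leaf_length = c(0.12, 0.20),
                                   leaf_aspect = 0.6,
                                   serration_amp = 0.08,
                                   boll_radius = c(0.015, 0.025),
                                   jitter_sigma = 0.003,
                                   occlusion_fraction = 0.15,
                                   seed = 0L) {
  class_mode <- match.arg(class_mode)
  stopifnot(n_points >= 3, occlusion_fraction >= 0, occlusion_fraction < 1,
            jitter_sigma >= 0)
  list(n_points = as.integer(n_points), class_mode = class_mode,
       n_leaves = as.integer(n_leaves), n_bolls = as.integer(n_bolls),
       stem_height = stem_height, stem_radius = stem_radius,
       leaf_length = leaf_length, leaf_aspect = leaf_aspect,
       serration_amp = serration_amp, boll_radius = boll_radius,
       jitter_sigma = jitter_sigma,
       occlusion_fraction = occlusion_fraction, seed = as.integer(seed))
}

# exact point on an organ's parametric surface at parameters (u, v)
#' Evaluate an organ surface at stored parameters
#'
#' Re-evaluates the parametric form of a generated organ: stem tube
#' (`u` = height, `v` = angle), serrated leaf disc (`u` = radial fraction,
#' `v` = angle) or boll sphere (`u` = cos of polar angle, `v` = azimuth).
#' With zero jitter and zero occlusion every generated point equals
#' `plant_surface_point(organ, u, v)` exactly.
#'
#' @param organ one element of the cloud's `organs` attribute.
#' @param u,v surface parameters (vectors).
#' @return length(u) x 3 coordinate matrix.
#' @export
plant_surface_point <- function(organ, u, v) {
  switch(organ$type,
    stem = {
      h <- u
      f <- h / organ$height
      ax <- organ$bend_amp[1] * (sin(pi * f + organ$bend_phase[1]) -
                                   sin(organ$bend_phase[1]))
      ay <- organ$bend_amp[2] * (sin(pi * f + organ$bend_phase[2]) -
                                   sin(organ$bend_phase[2]))
      r <- organ$r0 * (1 - 0.6 * f)
      cbind(ax + r * cos(v), ay + r * sin(v), h)
    },
    leaf = {
      q <- u * (1 + organ$serr_amp * sin(organ$n_serr * v))
      px <- organ$a * q * cos(v) + organ$a
      py <- organ$b * q * sin(v)
      ct <- cos(organ$tilt); st <- sin(organ$tilt)
      ca <- cos(organ$azimuth); sa <- sin(organ$azimuth)
      # tilt about the local y axis, then rotate to the azimuth
      lx <- ct * px
      lz <- st * px
      cbind(organ$attach[1] + ca * lx - sa * py,
            organ$attach[2] + sa * lx + ca * py,
            organ$attach[3] + lz)
    },
    boll = {
      s <- sqrt(pmax(0, 1 - u^2))
      cbind(organ$center[1] + organ$radius * s * cos(v),
            organ$center[2] + organ$radius * s * sin(v),
            organ$center[3] + organ$radius * u)
    })
}

draw_range <- function(r) if (length(r) == 1) r else runif(1, r[1], r[2])
draw_int_range <- function(r) {
  if (r[2] < r[1]) abort("empty integer range")
  if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
}

organ_area <- function(organ) {
  switch(organ$type,
    stem = 2 * pi * organ$r0 * 0.7 * organ$height,
    leaf = pi * organ$a * organ$b,
    boll = 4 * pi * organ$radius^2)
}

sample_organ_points <- function(organ, n) {
  u <- switch(organ$type,
    stem = runif(n, 0, organ$height),
    leaf = sqrt(runif(n)),
    boll = runif(n, -1, 1))
  v <- runif(n, 0, 2 * pi)
  list(coords = plant_surface_point(organ, u, v), u = u, v = v)
}

#' Generate one labeled synthetic plant
#'
#' Builds the organ set, samples points proportionally to organ surface
#' area, applies Gaussian jitter, removes the most view-hidden fraction of
#' points (depth ordering within projected grid cells approximates
#' single-side scan self-occlusion), and resamples from the surviving
#' organs to restore `n_points`.  Deterministic given `(cfg, seed)`.
#' The returned cloud carries attributes `organs` (the parametric organ
#' descriptors), `point_params` (per-point organ index and surface
#' parameters, pre-occlusion semantics preserved for surviving points) and
#' `height`.
#'
#' @param cfg a [synthetic_plant_config()].
#' @param seed generation seed (default: the config's).
#' @return a labeled [point_cloud()].
#' @export
generate_plant <- function(cfg = synthetic_plant_config(), seed = cfg$seed) {
  withr_seed(seed, {
    H <- draw_range(cfg$stem_height)
    r0 <- draw_range(cfg$stem_radius)
    stem <- list(type = "stem", height = H, r0 = r0,
                 bend_amp = runif(2, 0.005, 0.015) * H,
                 bend_phase = runif(2, 0, 2 * pi))
    n_leaves <- draw_int_range(cfg$n_leaves)
    n_bolls <- draw_int_range(cfg$n_bolls)
    if (n_leaves + n_bolls + 1 > cfg$n_points)
      abort("n_points smaller than the number of organs")
    if (n_leaves == 0 && n_bolls == 0 && cfg$class_mode == "three_class")
      abort("infeasible config: no foliage or boll organs")
    organs <- list(stem)
    for (i in seq_len(n_leaves)) {
      len <- draw_range(cfg$leaf_length)
      ha <- runif(1, 0.15 * H, 0.95 * H)
      organs[[length(organs) + 1]] <- list(
        type = "leaf",
        attach = as.vector(plant_surface_point(stem, ha, runif(1, 0, 2 * pi))),
        azimuth = runif(1, 0, 2 * pi),
        tilt = runif(1, pi / 10, pi / 3),
        a = len / 2, b = cfg$leaf_aspect * len / 2,
        serr_amp = cfg$serration_amp, n_serr = 9)
    }
    for (i in seq_len(n_bolls)) {
      ha <- runif(1, 0.3 * H, 0.95 * H)
      az <- runif(1, 0, 2 * pi)
      off <- runif(1, 0.03, 0.08)
      base <- as.vector(plant_surface_point(stem, ha, az))
      organs[[length(organs) + 1]] <- list(
        type = "boll",
        center = base + c(off * cos(az), off * sin(az),
                          runif(1, -0.01, 0.02)),
        radius = draw_range(cfg$boll_radius))
    }
    areas <- vapply(organs, organ_area, 0)
    n_org <- pmax(1L, round(cfg$n_points * areas / sum(areas)))
    # settle rounding on the largest organ
    n_org[which.max(n_org)] <- n_org[which.max(n_org)] +
      cfg$n_points - sum(n_org)
    pieces <- lapply(seq_along(organs), function(i) {
      sp <- sample_organ_points(organs[[i]], n_org[i])
      list(coords = sp$coords,
           params = tibble(organ = i, u = sp$u, v = sp$v))
    })
    coords <- do.call(rbind, lapply(pieces, `[[`, "coords"))
    params <- dplyr::bind_rows(lapply(pieces, `[[`, "params"))
    # one-sided self-occlusion: drop the most hidden points seen from a
    # random view direction (depth rank within projected grid cells)
    if (cfg$occlusion_fraction > 0) {
      view <- rnorm(3); view <- view / sqrt(sum(view^2))
      b1 <- c(-view[2], view[1], 0)
      if (sum(b1^2) < 1e-12) b1 <- c(1, 0, 0)
      b1 <- b1 / sqrt(sum(b1^2))
      b2 <- c(view[2] * b1[3] - view[3] * b1[2],
              view[3] * b1[1] - view[1] * b1[3],
              view[1] * b1[2] - view[2] * b1[1])
      depth <- coords %*% view
      cell <- paste(round(coords %*% b1 / (H / 25)),
                    round(coords %*% b2 / (H / 25)))
      in_front <- stats::ave(as.vector(depth), cell,
                             FUN = function(d) rank(d, ties.method = "first") - 1)
      n_rm <- floor(cfg$occlusion_fraction * nrow(coords))
      rm_idx <- order(in_front, depth, decreasing = TRUE)[seq_len(n_rm)]
      if (n_rm > 0) {
        coords <- coords[-rm_idx, , drop = FALSE]
        params <- params[-rm_idx, , drop = FALSE]
      }
      # restore n_points from organs that survived the occlusion
      alive <- sort(unique(params$organ))
      counts <- table(factor(params$organ, levels = alive))
      add <- cfg$n_points - nrow(coords)
      if (add > 0) {
        org_draw <- sample(alive, add, replace = TRUE,
                           prob = as.numeric(counts))
        for (i in alive) {
          ni <- sum(org_draw == i)
          if (ni == 0) next
          sp <- sample_organ_points(organs[[i]], ni)
          coords <- rbind(coords, sp$coords)
          params <- dplyr::bind_rows(params,
                                     tibble(organ = i, u = sp$u, v = sp$v))
        }
      }
    }
    if (cfg$jitter_sigma > 0)
      coords <- coords + matrix(rnorm(length(coords),
                                      sd = cfg$jitter_sigma * H),
                                nrow(coords))
    types <- vapply(organs, `[[`, "", "type")[params$organ]
    if (cfg$class_mode == "three_class") {
      labels <- c(stem = 0L, leaf = 1L, boll = 2L)[types]
      class_names <- c("stem", "leaf", "boll")
    } else {
      labels <- c(stem = 0L, leaf = 0L, boll = 1L)[types]
      class_names <- c("foliage", "boll")
    }
    pc <- point_cloud(coords, labels = unname(labels),
                      sample_id = sprintf("plant_%06d", seed %% 1000000L),
                      class_names = class_names)
    attr(pc, "organs") <- organs
    attr(pc, "point_params") <- params
    attr(pc, "height") <- H
    pc
  })
}

#' Generate a synthetic dataset
#'
#' Draws one derived seed per sample, generates the plants, and (optionally)
#' writes them as a fixture directory plus PLY files with a manifest listing
#' sample ids, per-class point counts and class names.
#'
#' @param cfg a [synthetic_plant_config()].
#' @param n_samples number of plants.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param out_dir optional output directory.
#' @return named list of [point_cloud()]s (invisibly returns the same when
#'   writing).
#' @export
generate_dataset <- function(cfg = synthetic_plant_config(), n_samples = 10L,
                             seed = 0L, out_dir = NULL) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  sub_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           n_samples))
  clouds <- lapply(seq_len(n_samples), function(i) {
    pc <- generate_plant(cfg, sub_seeds[i])
    attr(pc, "sample_id") <- sprintf("plant_%03d", i)
    pc
  })
  names(clouds) <- vapply(clouds, attr, "", "sample_id")
  if (!is.null(out_dir)) {
    write_fixture_dir(clouds, out_dir)
    for (pc in clouds)
      write_point_cloud(pc, file.path(out_dir,
                                      paste0(attr(pc, "sample_id"), ".ply")))
  }
  invisible(clouds)
}
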