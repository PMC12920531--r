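# Analytic efficiency profiling: trainable-parameter counts and
# forward-pass FLOP estimates, counted layer by layer from the
# configuration.  Convention: one multiply-accumulate of a linear / 1x1 map
# is ONE floating-point operation (the convention prevailing in point-cloud
# profiling); elementwise operations, normalization, rectifiers, softmax
# terms, pooling comparisons and neighbor-search distance evaluations count
# one operation per output element.  The convention string is embedded in
# every report; reduction percentages are independent of it as long as the
# same rules are applied to both models.

FLOP_CONVENTION <- "1 MAC = 1 FLOP; elementwise/pool/distance ops = 1 per output element"

#' Count trainable parameters
#'
#' Sums the element counts of all trainable arrays (weights, biases,
#' normalization scales and shifts); running statistics buffers are
#' excluded.
#'
#' @param model an `elgcot3d_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# per-unit accounting helpers ------------------------------------------------

unit_row <- function(module, name, P, c_in, c_out, bn = TRUE, act = TRUE) {
  flops <- P * c_in * c_out + P * c_out +          # MACs + bias
    (if (bn) 2 * P * c_out else 0) +               # scale + shift
    (if (act) P * c_out else 0)                    # rectifier
  tibble(module = module, name = name,
         params = c_in * c_out + c_out + (if (bn) 2 * c_out else 0),
         flops = flops)
}

misc_row <- function(module, name, flops) {
  tibble(module = module, name = name, params = 0, flops = flops)
}

#' Per-layer parameter/FLOP layout of a configuration
#'
#' Walks the configured stages exactly as [build_model()] does and applies
#' the documented counting rules at the given input size.  The per-unit
#' `params` column matches [count_parameters()] of the built model.
#'
#' @param config a [model_config()].
#' @param n_points input cloud size (default: the configured size).
#' @param include_search include farthest-point-sampling and neighbor-search
#'   distance computations (real forward-pass work that some profilers
#'   omit; disable for cross-profiler comparison).
#' @return tibble with columns module, name, params, flops.
#' @export
model_layout <- function(config, n_points = config$n_input_points,
                         include_search = TRUE) {
  w <- config_widths(config)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r
  N <- n_points
  prev <- 0L
  lev_n <- integer(length(config$stages) + 1)
  lev_n[1] <- N
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    mod <- paste0("enc", i)
    Np <- lev_n[i]
    C <- prev + 3L
    if (st$type == "elg3d") {
      S <- st$n_centers
      if (include_search)
        add(misc_row(mod, paste0(mod, ".fps"), Np * S))
      for (s in seq_along(st$scales)) {
        sc <- st$scales[[s]]
        K <- sc$K; wd <- sc$out_width
        nm <- function(op) paste0(mod, ".s", s, ".", op)
        if (include_search)
          add(misc_row(mod, nm("ball"), Np * S))
        add(misc_row(mod, nm("edge_feat"), S * K * C))     # f_j - f_i
        add(unit_row(mod, nm("edge"), S * K, 2L * C, wd))
        add(misc_row(mod, nm("edge_pool"), S * K * wd))
        add(unit_row(mod, nm("attv"), S * K, C, wd))
        add(unit_row(mod, nm("atts"), S * K, C, 1L, bn = FALSE, act = FALSE))
        add(misc_row(mod, nm("att_softmax"), 3 * S * K + S * K * wd))
        add(misc_row(mod, nm("gcn_agg"), S * K * C))
        add(unit_row(mod, nm("gcn"), S, C, wd))
        add(unit_row(mod, nm("base"), S * K, C, wd))
        add(misc_row(mod, nm("base_pool"), S * K * wd))
        add(misc_row(mod, nm("fuse"), 4 * S * wd))
      }
      tot <- sum(vapply(st$scales, function(sc) sc$out_width, 0L))
      add(unit_row(mod, paste0(mod, ".unify"), S, tot, st$fused_width))
      lev_n[i + 1] <- S
    } else if (st$type == "sa") {
      S <- st$n_centers
      if (include_search)
        add(misc_row(mod, paste0(mod, ".fps"), Np * S))
      for (s in seq_along(st$scales)) {
        sc <- st$scales[[s]]
        if (include_search)
          add(misc_row(mod, paste0(mod, ".s", s, ".ball"), Np * S))
        ci <- C
        for (j in seq_along(sc$mlp)) {
          add(unit_row(mod, paste0(mod, ".s", s, ".l", j), S * sc$K, ci,
                       sc$mlp[j]))
          ci <- sc$mlp[j]
        }
        add(misc_row(mod, paste0(mod, ".s", s, ".pool"),
                     S * sc$K * tail(sc$mlp, 1)))
      }
      lev_n[i + 1] <- S
    } else {                                       # global, group-all
      ci <- C
      for (j in seq_along(st$widths)) {
        add(unit_row(mod, paste0(mod, ".l", j), Np, ci, st$widths[j]))
        ci <- st$widths[j]
      }
      add(misc_row(mod, paste0(mod, ".pool"), Np * tail(st$widths, 1)))
      lev_n[i + 1] <- 1L
    }
    prev <- w$stage_out[i]
  }
  L <- length(config$stages)
  cw <- w$stage_out[L]
  for (j in seq_len(L)) {
    mod <- paste0("fp", j)
    Nf <- lev_n[L - j + 1]
    Sc <- lev_n[L - j + 2]
    if (include_search && Sc > 1)
      add(misc_row(mod, paste0(mod, ".knn"), Nf * Sc))
    add(misc_row(mod, paste0(mod, ".interp"), Nf * 3 * cw))
    ci <- w$fp_in[j]
    for (l in seq_along(config$fp[[j]])) {
      add(unit_row(mod, paste0(mod, ".l", l), Nf, ci, config$fp[[j]][l]))
      ci <- config$fp[[j]][l]
    }
    cw <- w$fp_out[j]
  }
  if (!is.null(config$enhancement)) {
    e <- config$enhancement
    Ce <- w$fp_out[L]
    for (b in seq_along(e$branch_ks)) {
      k <- e$branch_ks[b]
      nm <- paste0("enh.br", b)
      if (k == 1) {
        add(unit_row("enh", nm, N, Ce, e$branch_width))
      } else {
        if (include_search)
          add(misc_row("enh", paste0(nm, ".knn"), N * N))
        add(unit_row("enh", nm, N * k, Ce, e$branch_width))
        add(misc_row("enh", paste0(nm, ".pool"), N * k * e$branch_width))
      }
    }
    Cw <- e$integration_width
    add(unit_row("enh", "enh.int", N, length(e$branch_ks) * e$branch_width,
                 Cw))
    r <- e$attention_reduction
    add(misc_row("enh", "enh.ca_squeeze", 2 * N * Cw))
    add(unit_row("enh", "enh.ca1", 2L, Cw, Cw %/% r, bn = FALSE,
                 act = FALSE))
    add(unit_row("enh", "enh.ca2", 2L, Cw %/% r, Cw, bn = FALSE,
                 act = FALSE))
    add(misc_row("enh", "enh.ca_gate", N * Cw + 2 * Cw))
    add(misc_row("enh", "enh.sa_squeeze", 2 * N * Cw))
    add(unit_row("enh", "enh.sa", N, 2L, 1L, bn = FALSE, act = FALSE))
    add(misc_row("enh", "enh.sa_gate", N * Cw + N))
    add(tibble(module = "enh", name = "enh.dw",
               params = e$ds_kernel * Cw + Cw,
               flops = N * Cw * e$ds_kernel + N * Cw))
    add(unit_row("enh", "enh.pw", N, Cw, e$out_width))
  }
  add(unit_row("head", "head.l1", N, w$head_in, config$head_hidden))
  add(unit_row("head", "head.out", N, config$head_hidden,
               config$n_classes, bn = FALSE, act = FALSE))
  add(misc_row("head", "head.softmax", 3 * N * config$n_classes))
  dplyr::bind_rows(rows)
}

#' Estimate forward-pass GFLOPs
#'
#' Analytic per-layer count for one cloud at batch 1 under the documented
#' convention (one multiply-accumulate = one FLOP).
#'
#' @param model an `elgcot3d_model` (or a [model_config()]).
#' @param n_points input points (default 2048).
#' @param include_search include neighbor-search distance work.
#' @return GFLOPs (total / 1e9).
#' @export
estimate_flops <- function(model, n_points = 2048L, include_search = TRUE) {
  config <- if (inherits(model, "model_config")) model else model$config
  sum(model_layout(config, n_points, include_search)$flops) / 1e9
}

#' Efficiency report for one model
#'
#' @param model an `elgcot3d_model`.
#' @param n_points input points for the FLOP estimate.
#' @param include_search include neighbor-search distance work.
#' @return an `efficiency_report`: param_count, params_M, gflops, the
#'   per-module breakdown tibble, and the counting-convention string.
#' @export
efficiency_report <- function(model, n_points = 2048L,
                              include_search = TRUE) {
  layout <- model_layout(model$config, n_points, include_search)
  per_module <- dplyr::summarise(dplyr::group_by(layout, .data$module),
                                 params = sum(.data$params),
                                 flops = sum(.data$flops), .groups = "drop")
  pc <- count_parameters(model)
  structure(list(model = model$config$name,
                 param_count = pc, params_M = pc / 1e6,
                 gflops = sum(layout$flops) / 1e9,
                 per_module = per_module,
                 n_points = n_points,
                 convention = FLOP_CONVENTION),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("%s @ %d points: %.3f M params, %.3f GFLOPs\n",
              x$model, x$n_points, x$params_M, x$gflops))
  cat(sprintf("convention: %s\n", x$convention))
  print(x$per_module)
  if (!is.null(x$reduction_params_pct))
    cat(sprintf("vs %s: params -%.1f%%, FLOPs -%.1f%%\n",
                x$baseline, x$reduction_params_pct, x$reduction_flops_pct))
  invisible(x)
}

#' @method tidy efficiency_report
#' @export
tidy.efficiency_report <- function(x, ...) x$per_module

#' @method glance efficiency_report
#' @export
glance.efficiency_report <- function(x, ...) {
  tibble(params_M = x$params_M, gflops = x$gflops,
         reduction_params_pct = x$reduction_params_pct %||% NA_real_,
         reduction_flops_pct = x$reduction_flops_pct %||% NA_real_)
}

#' Compare a model against a baseline
#'
#' Computes both models' parameter counts and FLOP estimates with identical
#' counting rules and reports the baseline-relative reductions
#' `100 * (1 - model / baseline)`.
#'
#' @param model,baseline `elgcot3d_model`s.
#' @param n_points input points.
#' @param include_search include neighbor-search distance work.
#' @return an `efficiency_report` for `model` with the extra fields
#'   `baseline`, `baseline_params_M`, `baseline_gflops`,
#'   `reduction_params_pct`, `reduction_flops_pct`.
#' @export
compare_models <- function(model, baseline, n_points = 2048L,
                           include_search = TRUE) {
  rm_ <- efficiency_report(model, n_points, include_search)
  rb <- efficiency_report(baseline, n_points, include_search)
  if (rb$param_count == 0 || rb$gflops == 0)
    abort("baseline has zero totals")
  rm_$baseline <- baseline$config$name
  rm_$baseline_params_M <- rb$params_M
  rm_$baseline_gflops <- rb$gflops
  rm_$reduction_params_pct <- 100 * (1 - rm_$param_count / rb$param_count)
  rm_$reduction_flops_pct <- 100 * (1 - rm_$gflops / rb$gflops)
  rm_
}
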