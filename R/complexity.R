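# Analytic complexity accounting. One MAC = one multiply + one accumulate;
# convs count H'*W'*C_out*k^2*C_in, linear layers C_in*C_out, attention the
# QK' and attention*V matrix products. Bias adds, ReLU, pooling, softmax and
# normalisation are excluded (standard convention). MACs are per image.

fire_param_count <- function(f) {
  f$c_in * f$c_s + f$c_s +
    f$c_s * f$n_e1 + f$n_e1 +
    f$c_s * 9L * f$n_e3 + f$n_e3
}

fire_mac_count <- function(f, h, w) {
  as.numeric(h) * w * (f$c_s * f$c_in + f$n_e1 * f$c_s + f$n_e3 * 9 * f$c_s)
}

encoder_layer_params <- function(spec) {
  d <- spec$token_dim; f <- spec$ffn_width
  2L * d +                       # ln1
    4L * (d * d + d) +           # q, k, v, o projections
    2L * d +                     # ln2
    (d * f + f) + (f * d + d)    # feed-forward
}

encoder_layer_macs <- function(spec, grid) {
  d <- spec$token_dim; f <- spec$ffn_width
  M <- as.numeric(grid$N) * grid$P        # tokens per image
  proj <- 4 * M * d * d
  scores <- as.numeric(grid$P) * spec$heads * grid$N^2 * (spec$d_k + spec$d_v)
  ffn <- M * d * f * 2
  proj + scores + ffn
}

#' Per-layer shape, parameter and MAC walk of a configuration
#'
#' @param cfg a `squeezevit_config`
#' @param input_size spatial input side
#' @return tibble: layer, kind, output `c/h/w`, params, macs (per image)
#' @export
layer_walk <- function(cfg, input_size = cfg$input_size) {
  rows <- list()
  add <- function(layer, kind, c_out, h, w, params, macs) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      layer = layer, kind = kind, c_out = as.integer(c_out),
      h_out = as.integer(h), w_out = as.integer(w),
      params = as.numeric(params), macs = as.numeric(macs))
  }
  h <- conv_out_dim(input_size, cfg$stem$k, cfg$stem$s, cfg$stem$p)
  add("stem.conv", "conv3x3", cfg$stem$c_out, h, h,
      cfg$stem$c_in * cfg$stem$c_out * cfg$stem$k^2 + cfg$stem$c_out,
      as.numeric(h) * h * cfg$stem$c_out * cfg$stem$k^2 * cfg$stem$c_in)
  h <- conv_out_dim(h, cfg$stem_pool$k, cfg$stem_pool$s, cfg$stem_pool$p)
  add("stem.pool", "maxpool3x3", cfg$stem$c_out, h, h, 0, 0)
  for (i in seq_len(cfg$stage1$n)) {
    f <- cfg$stage1$fires[[i]]
    add(paste0("stage1.fire", i), "fire", f$n_e1 + f$n_e3, h, h,
        fire_param_count(f), fire_mac_count(f, h, h))
  }
  h <- conv_out_dim(h, 3L, 2L, 1L)
  c1 <- cfg$stage1$channel_plan[length(cfg$stage1$channel_plan)]
  add("stage1.pool", "maxpool3x3", c1, h, h, 0, 0)
  if (!is.null(cfg$stage2)) {
    s2 <- cfg$stage2
    grid <- patch_grid(h, h, s2$patch_h, s2$patch_w)
    add("stage2.expand", "fire", 2L * s2$c_in, h, h,
        fire_param_count(s2$fire_expand), fire_mac_count(s2$fire_expand, h, h))
    add("stage2.reduce", "fire", s2$token_dim, h, h,
        fire_param_count(s2$fire_reduce), fire_mac_count(s2$fire_reduce, h, h))
    add("stage2.enc.norm_in", "layernorm", s2$token_dim, h, h,
        2L * s2$token_dim, 0)
    for (l in seq_len(s2$attention$depth)) {
      add(paste0("stage2.enc.layer", l), "encoder", s2$token_dim, h, h,
          encoder_layer_params(s2$attention),
          encoder_layer_macs(s2$attention, grid))
    }
    add("stage2.enc.norm_out", "layernorm", s2$token_dim, h, h,
        2L * s2$token_dim, 0)
    add("stage2.proj", "conv1x1", s2$c_in, h, h,
        s2$token_dim * s2$c_in + s2$c_in,
        as.numeric(h) * h * s2$c_in * s2$token_dim)
    add("stage2.concat", "concat", 2L * s2$c_in, h, h, 0, 0)
    add("stage2.fuse", "fire", s2$c_in, h, h,
        fire_param_count(s2$fire_fuse), fire_mac_count(s2$fire_fuse, h, h))
  }
  f3 <- cfg$stage3_fire
  add("stage3.fire", "fire", f3$n_e1 + f3$n_e3, h, h,
      fire_param_count(f3), fire_mac_count(f3, h, h))
  h <- conv_out_dim(h, 3L, 2L, 1L)
  add("stage3.pool", "maxpool3x3", f3$n_e1 + f3$n_e3, h, h, 0, 0)
  add("head.conv", "conv1x1", cfg$head$c_out, h, h,
      cfg$head$c_in * cfg$head$c_out + cfg$head$c_out,
      as.numeric(h) * h * cfg$head$c_out * cfg$head$c_in)
  add("head.gap", "global_avg_pool", cfg$head$c_out, 1L, 1L, 0, 0)
  add("head.fc", "linear", cfg$num_labels, 1L, 1L,
      cfg$head$c_out * cfg$num_labels + cfg$num_labels,
      cfg$head$c_out * cfg$num_labels)
  do.call(rbind, rows)
}

#' Count trainable parameters of a model
#'
#' Exact enumeration of every learnable scalar in the model's parameter
#' arrays.
#'
#' @param model a `squeezevit_model`
#' @return integer scalar
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

#' Count multiply-accumulate operations for one forward pass
#'
#' @param model a `squeezevit_model`
#' @param input_size spatial input side (MACs depend on it; parameters do
#'   not)
#' @return numeric scalar, MACs per image
#' @export
count_macs <- function(model, input_size = model$config$input_size) {
  sum(layer_walk(model$config, input_size)$macs)
}

#' Complexity report for a model
#'
#' @param model a `squeezevit_model`
#' @param input_size spatial input side
#' @return an object of class `squeezevit_complexity`: total `params`,
#'   total `macs` (raw and in 1e9 units), the per-layer tibble and the
#'   input size used
#' @export
complexity_report <- function(model, input_size = model$config$input_size) {
  per_layer <- layer_walk(model$config, input_size)
  structure(list(params = count_parameters(model),
                 params_analytic = sum(per_layer$params),
                 macs = sum(per_layer$macs),
                 per_layer = per_layer,
                 input_size = as.integer(input_size)),
            class = "squeezevit_complexity")
}

#' @export
print.squeezevit_complexity <- function(x, ...) {
  cat("SqueezeViT complexity at input ", x$input_size, "x", x$input_size,
      ":\n", sep = "")
  cat("  trainable parameters: ", format(x$params, big.mark = ","),
      " (", format(round(x$params / 1e6, 2), nsmall = 2), " x 10^6)\n",
      sep = "")
  cat("  MACs per image: ", format(x$macs, big.mark = ","),
      " (", format(round(x$macs / 1e9, 2), nsmall = 2), " x 10^9)\n",
      sep = "")
  print(x$per_layer, n = nrow(x$per_layer))
  invisible(x)
}

#' Parameter-reduction percentage against a reference budget
#'
#' `100 * (p_reference - p_model) / p_reference`, reported to one decimal.
#'
#' @param p_model model parameter count (any consistent unit)
#' @param p_reference reference parameter count (same unit, > 0)
#' @param digits decimals to round to (default 1)
#' @return percentage reduction
#' @export
reduction_percent <- function(p_model, p_reference, digits = 1L) {
  if (!is.numeric(p_reference) || any(p_reference <= 0)) {
    stop("reference parameter count must be positive", call. = FALSE)
  }
  round(100 * (p_reference - p_model) / p_reference, digits)
}

#' Published reference budgets for baseline architectures
#'
#' Printed constants (parameters in 1e6, MACs in 1e9) for the baseline
#' models the architecture is compared against; shipped as a read-only data
#' file, never recomputed.
#'
#' @return tibble with columns `model`, `params_millions`, `macs_1e9`
#' @export
reference_budgets <- function() {
  path <- system.file("extdata", "baseline_budgets.csv",
                      package = "squeezevit", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE))
}

#' Token-count and attention-FLOPs trade-off between two patch grids
#'
#' Compares per-sequence token counts and total attention-score FLOPs
#' (`P * heads * N^2 * d_k` per layer, the `Q K'` score product) between two
#' patch grids on the same feature map. Halving the patch side from 4 to 2
#' quadruples both.
#'
#' @param grid_a,grid_b `patch_grid` objects on the same `H x W`
#' @param spec an `attention_spec`
#' @return list with `token_ratio` (`N_a / N_b`) and `flops_ratio`
#' @export
patch_tradeoff <- function(grid_a, grid_b, spec = attention_spec()) {
  if (!inherits(grid_a, "patch_grid") || !inherits(grid_b, "patch_grid")) {
    stop("grid_a and grid_b must be patch_grid objects", call. = FALSE)
  }
  if (grid_a$H != grid_b$H || grid_a$W != grid_b$W) {
    stop("grids must cover the same feature map", call. = FALSE)
  }
  list(token_ratio = grid_a$N / grid_b$N,
       flops_ratio = attention_score_flops(grid_a, spec) /
         attention_score_flops(grid_b, spec))
}

#' Attention-score FLOPs for a patch grid
#'
#' @param grid a `patch_grid`
#' @param spec an `attention_spec`
#' @return numeric: `depth * P * heads * N^2 * d_k` multiply-accumulates for
#'   the score product
#' @export
attention_score_flops <- function(grid, spec = attention_spec()) {
  as.numeric(spec$depth) * grid$P * spec$heads * grid$N^2 * spec$d_k
}
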