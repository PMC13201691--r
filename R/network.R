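#' SqueezeViT network configuration
#'
#' Single source of truth for model construction: stem (3x3 conv to 3
#' channels, stride 2, then 3x3 max pool, stride 2), Stage 1 (Fire Block,
#' default plan 3 -> 32 -> 64 -> 64 -> 128), Stage 2 (Translution Block on
#' 128 channels, or disabled), Stage 3 (Fire 128 -> 256, 3x3 max pool, 1x1
#' conv 256 -> 256, global average pooling, fully connected head).
#'
#' @param num_labels number of output classes (14 multi-label; 1 binary)
#' @param input_size spatial input side (images must be exactly this size)
#' @param input_channels input channel count (1 = grayscale)
#' @param stage1_plan Stage-1 Fire Block channel plan
#' @param stage2 a [translution_config()] or `NULL` to disable Stage 2
#'   (identity pass-through)
#' @param head_width channel width of the Stage-3 1x1 convolution
#' @param seed RNG seed used for weight initialisation
#' @return an object of class `squeezevit_config`
#' @export
squeezevit_config <- function(num_labels = 14L, input_size = 224L,
                              input_channels = 1L,
                              stage1_plan = c(3L, 32L, 64L, 64L, 128L),
                              stage2 = translution_config(128L),
                              head_width = 256L, seed = 42L) {
  stage1 <- fire_block_config(stage1_plan)
  c1 <- stage1$channel_plan[length(stage1$channel_plan)]
  if (!is.null(stage2) && stage2$c_in != c1) {
    stop("channel chain mismatch at Stage 1 -> Stage 2 junction: Stage 1 ",
         "emits ", c1, " channels but the Translution Block expects ",
         stage2$c_in, call. = FALSE)
  }
  structure(list(
    num_labels = as.integer(num_labels),
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    stem = conv_spec(3L, 2L, 1L, input_channels, 3L),
    stem_pool = conv_spec(3L, 2L, 1L),
    stage1 = stage1,
    stage2 = stage2,
    stage3_fire = derive_fire_channels(c1, 2L * c1),
    stage3_pool = conv_spec(3L, 2L, 1L),
    head = conv_spec(1L, 1L, 0L, 2L * c1, as.integer(head_width)),
    seed = as.integer(seed)
  ), class = "squeezevit_config")
}

#' Table-9-style ablation switches
#'
#' `"no_translution"` replaces Stage 2 with an identity pass-through;
#' `"fire_n1"`, `"fire_n4"`, `"fire_n8"`, `"fire_n16"` set the Stage-1 Fire
#' Block to N modules with a geometric channel interpolation from the input
#' width to 128 (rounded to even interior widths).
#'
#' @param cfg a `squeezevit_config`
#' @param ablation one of `"no_translution"`, `"fire_n1"`, `"fire_n4"`,
#'   `"fire_n8"`, `"fire_n16"`
#' @return a modified, buildable `squeezevit_config`
#' @export
apply_ablation <- function(cfg, ablation) {
  valid <- c("no_translution", "fire_n1", "fire_n4", "fire_n8", "fire_n16")
  if (!is.character(ablation) || length(ablation) != 1L ||
      !(ablation %in% valid)) {
    stop("unknown ablation '", paste(ablation, collapse = ","),
         "'; valid tags: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (ablation == "no_translution") {
    cfg$stage2 <- NULL
    return(cfg)
  }
  n <- as.integer(sub("fire_n", "", ablation))
  cfg$stage1 <- fire_block_config(interp_channel_plan(3L, 128L, n))
  cfg
}

# Geometric channel interpolation start -> end over n modules, interior
# widths rounded to the nearest even integer.
interp_channel_plan <- function(start, end, n) {
  if (n == 1L) return(c(start, end))
  r <- (end / start)^(1 / n)
  mid <- start * r^seq_len(n - 1L)
  mid <- pmax(2L, 2L * round(mid / 2))
  as.integer(c(start, mid, end))
}

#' Build a SqueezeViT model
#'
#' Initialises every learnable parameter (Kaiming fan-in for convolutions,
#' Xavier-style for linear projections, zero biases, unit LayerNorm gains)
#' under the configuration's seed, so the parameter layout and values are
#' reproducible.
#'
#' @param cfg a [squeezevit_config()]
#' @return an object of class `squeezevit_model`
#' @export
build_squeezevit <- function(cfg = squeezevit_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  params <- list(
    stem.conv.W = init_weight(cfg$stem$c_in * cfg$stem$k^2, cfg$stem$c_out,
                              "relu"),
    stem.conv.b = numeric(cfg$stem$c_out)
  )
  p1 <- fire_block_init(cfg$stage1)
  names(p1) <- paste0("stage1.", names(p1))
  params <- c(params, p1)
  if (!is.null(cfg$stage2)) {
    p2 <- translution_init(cfg$stage2)
    names(p2) <- paste0("stage2.", names(p2))
    params <- c(params, p2)
  }
  p3 <- fire_init(cfg$stage3_fire)
  names(p3) <- paste0("stage3.fire.", names(p3))
  params <- c(params, p3)
  params$head.conv.W <- init_weight(cfg$head$c_in, cfg$head$c_out, "relu")
  params$head.conv.b <- numeric(cfg$head$c_out)
  params$head.fc.W <- init_weight(cfg$head$c_out, cfg$num_labels, "linear")
  params$head.fc.b <- numeric(cfg$num_labels)
  structure(list(config = cfg, params = params),
            class = "squeezevit_model")
}

# Full forward pass. images: array (H, W, n) or (H, W, n, C), or a single
# matrix. Returns logits (B x L); with cache = TRUE also every intermediate.
squeezevit_fwd <- function(model, x, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  x <- as_input_batch(x, cfg)
  cc <- list()
  a <- conv_fwd(x, p$stem.conv.W, p$stem.conv.b,
                cfg$stem$k, cfg$stem$s, cfg$stem$p, relu = TRUE)
  if (cache) cc$stem_in <- x
  if (cache) cc$stem_act <- a
  sp <- maxpool_fwd(a, cfg$stem_pool$k, cfg$stem_pool$s, cfg$stem_pool$p)
  if (cache) cc$stem_pool <- sp
  r1 <- fire_block_forward(sp$out, slice_params(p, "stage1."), cfg$stage1,
                           cache = cache)
  a1 <- if (cache) r1$out else r1
  if (cache) cc$stage1 <- r1$cache
  if (!is.null(cfg$stage2)) {
    r2 <- translution_forward(a1, slice_params(p, "stage2."), cfg$stage2,
                              cache = cache)
    a2 <- if (cache) r2$out else r2
    if (cache) cc$stage2 <- r2$cache
  } else {
    a2 <- a1
  }
  r3 <- fire_forward(a2, slice_params(p, "stage3.fire."), cfg$stage3_fire,
                     cache = cache)
  a3 <- if (cache) r3$out else r3
  if (cache) cc$stage3_fire <- r3$cache
  p3 <- maxpool_fwd(a3, cfg$stage3_pool$k, cfg$stage3_pool$s,
                    cfg$stage3_pool$p)
  if (cache) cc$stage3_pool <- p3
  hc <- conv_fwd(p3$out, p$head.conv.W, p$head.conv.b, 1L, 1L, 0L,
                 relu = TRUE)
  if (cache) { cc$head_in <- p3$out; cc$head_act <- hc }
  gp <- global_avg_pool_fwd(hc)
  if (cache) cc$gap <- gp
  out <- linear_fwd(gp$out, p$head.fc.W, p$head.fc.b)   # (B, L)
  if (!cache) return(out)
  list(out = out, cache = c(cc, list(pooled = gp$out)))
}

squeezevit_bwd <- function(model, dlogits, cache) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  gf <- linear_bwd(dlogits, cache$pooled, p$head.fc.W)
  grads$head.fc.W <- gf$dW; grads$head.fc.b <- gf$db
  dg <- global_avg_pool_bwd(gf$dx, cache$gap)
  gh <- conv_bwd(dg, cache$head_act, cache$head_in, p$head.conv.W,
                 1L, 1L, 0L, relu = TRUE)
  grads$head.conv.W <- gh$dW; grads$head.conv.b <- gh$db
  dx <- maxpool_bwd(gh$dx, cache$stage3_pool)
  g3 <- fire_backward(dx, cache$stage3_fire, slice_params(p, "stage3.fire."),
                      cfg$stage3_fire)
  names(g3$grads) <- paste0("stage3.fire.", names(g3$grads))
  grads <- c(grads, g3$grads)
  dx <- g3$dx
  if (!is.null(cfg$stage2)) {
    g2 <- translution_backward(dx, cache$stage2, slice_params(p, "stage2."),
                               cfg$stage2)
    names(g2$grads) <- paste0("stage2.", names(g2$grads))
    grads <- c(grads, g2$grads)
    dx <- g2$dx
  }
  g1 <- fire_block_backward(dx, cache$stage1, slice_params(p, "stage1."),
                            cfg$stage1, need_dx = TRUE)
  names(g1$grads) <- paste0("stage1.", names(g1$grads))
  grads <- c(grads, g1$grads)
  dx <- maxpool_bwd(g1$dx, cache$stem_pool)
  gs <- conv_bwd(dx, cache$stem_act, cache$stem_in, p$stem.conv.W,
                 cfg$stem$k, cfg$stem$s, cfg$stem$p, relu = TRUE,
                 need_dx = FALSE)
  grads$stem.conv.W <- gs$dW; grads$stem.conv.b <- gs$db
  grads
}

as_input_batch <- function(x, cfg) {
  d <- dim(x)
  if (is.null(d)) stop("images must be an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L)          # single image
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)                             # (H, W, n) grayscale
    d <- dim(x)
  }
  if (length(d) != 4L) stop("images must be (H, W, n) or (H, W, n, C)",
                            call. = FALSE)
  if (d[4L] != cfg$input_channels || d[1L] != cfg$input_size ||
      d[2L] != cfg$input_size) {
    stop("model expects ", cfg$input_size, "x", cfg$input_size, "x",
         cfg$input_channels, " inputs, got ", d[1L], "x", d[2L], "x", d[4L],
         "; resize images in the data layer, the model never resizes",
         call. = FALSE)
  }
  x
}

#' Forward a batch of images through a SqueezeViT model
#'
#' @param object a `squeezevit_model`
#' @param images array `(H, W, n)` (grayscale) or `(H, W, n, C)`; spatial
#'   size must equal the configured input size exactly
#' @param type `"logit"` (default) or `"prob"` (sigmoid per class)
#' @param chunk images forwarded per slice (memory bound; result identical
#'   for any value)
#' @param ... unused
#' @return numeric matrix `n x num_labels`, rows in batch order
#' @export
predict.squeezevit_model <- function(object, images, type = c("logit", "prob"),
                                     chunk = 32L, ...) {
  type <- match.arg(type)
  x <- as_input_batch(images, object$config)
  n <- dim(x)[3L]
  out <- matrix(NA_real_, n, object$config$num_labels)
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(s + chunk - 1L, n)
    out[i, ] <- squeezevit_fwd(object, x[, , i, , drop = FALSE],
                               cache = FALSE)
  }
  colnames(out) <- model_label_names(object)
  if (type == "prob") out <- 1 / (1 + exp(-out))
  out
}

model_label_names <- function(model) {
  L <- model$config$num_labels
  if (L == 1L) "Abnormal" else {
    v <- cxr14_vocabulary()
    head_n <- setdiff(v, "No Finding")
    if (length(head_n) == L) head_n else paste0("class", seq_len(L))
  }
}

#' Per-layer summary of a model
#'
#' @param object a `squeezevit_model`
#' @param input_size spatial input side used for shape/MAC accounting
#' @param ... unused
#' @return a tibble with one row per layer: name, kind, output shape,
#'   parameter count, MAC count
#' @export
summary.squeezevit_model <- function(object, input_size = object$config$input_size,
                                     ...) {
  layer_walk(object$config, input_size)
}

#' @export
print.squeezevit_model <- function(x, ...) {
  tab <- layer_walk(x$config, x$config$input_size)
  cat("SqueezeViT model: ", x$config$num_labels, " labels, input ",
      x$config$input_channels, "x", x$config$input_size, "x",
      x$config$input_size, "\n", sep = "")
  cat("  trainable parameters: ", count_parameters(x), "\n", sep = "")
  cat("  MACs at configured input: ",
      format(sum(tab$macs), big.mark = ","), "\n", sep = "")
  cat("  layers: ", nrow(tab), " (see summary() for the per-layer table)\n",
      sep = "")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed a format version, the full configuration (including the
#' initialisation seed) and every parameter array.
#'
#' @param model a `squeezevit_model`
#' @param path file path (`.rds`)
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `squeezevit_model`
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "squeezevit-checkpoint", version = 1L,
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "squeezevit-checkpoint")) {
    stop("not a squeezevit checkpoint: ", path, call. = FALSE)
  }
  structure(list(config = x$config, params = x$params),
            class = "squeezevit_model")
}

#' Read / write a network configuration as YAML
#'
#' @param cfg a `squeezevit_config`
#' @param path YAML file path
#' @return `read_network_config` returns a `squeezevit_config`
#' @export
write_network_config <- function(cfg, path) {
  y <- list(num_labels = cfg$num_labels, input_size = cfg$input_size,
            input_channels = cfg$input_channels,
            stage1_plan = cfg$stage1$channel_plan,
            stage2 = if (is.null(cfg$stage2)) "disabled" else list(
              c_in = cfg$stage2$c_in, token_dim = cfg$stage2$token_dim,
              patch_h = cfg$stage2$patch_h, patch_w = cfg$stage2$patch_w,
              heads = cfg$stage2$attention$heads,
              depth = cfg$stage2$attention$depth,
              ffn_width = cfg$stage2$attention$ffn_width),
            head_width = cfg$head$c_out, seed = cfg$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  y <- yaml::read_yaml(path)
  stage2 <- if (identical(y$stage2, "disabled")) NULL else {
    translution_config(
      c_in = y$stage2$c_in, token_dim = y$stage2$token_dim,
      patch_h = y$stage2$patch_h, patch_w = y$stage2$patch_w,
      attention = attention_spec(token_dim = y$stage2$token_dim,
                                 heads = y$stage2$heads,
                                 depth = y$stage2$depth,
                                 ffn_width = y$stage2$ffn_width))
  }
  squeezevit_config(num_labels = y$num_labels, input_size = y$input_size,
                    input_channels = y$input_channels,
                    stage1_plan = unlist(y$stage1_plan),
                    stage2 = stage2, head_width = y$head_width,
                    seed = y$seed)
}
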