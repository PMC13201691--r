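#' Derive Fire-module channel widths from input and target output widths
#'
#' A Fire module squeezes its input through a 1x1 convolution to
#' `C_s = max(1, floor(C_in / 2))` channels, then excites through parallel
#' 1x1 and 3x3 convolutions that each produce half of the requested output
#' width, so the channel-concatenated output has exactly `c_out` channels.
#'
#' @param c_in input channel count (>= 1)
#' @param c_out target output channel count (even, >= 2)
#' @return an object of class `fire_config` with fields `c_in`, `c_s`,
#'   `n_e1`, `n_e3`
#' @examples
#' derive_fire_channels(128, 256)  # c_s = 64, n_e1 = n_e3 = 128
#' @export
derive_fire_channels <- function(c_in, c_out) {
  stopifnot(c_in >= 1, c_out >= 2)
  if (c_out %% 2L != 0L) {
    stop("Fire output width must be even so the excitation branches split ",
         "evenly; got c_out = ", c_out, call. = FALSE)
  }
  structure(list(c_in = as.integer(c_in),
                 c_s = max(1L, as.integer(c_in %/% 2L)),
                 n_e1 = as.integer(c_out %/% 2L),
                 n_e3 = as.integer(c_out %/% 2L)),
            class = "fire_config")
}

# Parameters of one Fire module: squeeze 1x1, excite 1x1, excite 3x3 (pad 1).
# The squeeze is the network's information bottleneck and its input is
# non-negative (post-ReLU): a one-channel squeeze whose random weights all
# land negative is silenced by its ReLU for every input, and no gradient can
# revive it. Degenerate (width-1) squeezes therefore initialise half-normal
# (a positive weighted channel average) and all squeeze biases start at 0.1.
fire_init <- function(cfg) {
  sq.W <- init_weight(cfg$c_in, cfg$c_s, "relu")
  if (cfg$c_s == 1L) sq.W <- abs(sq.W)
  list(
    sq.W = sq.W,
    sq.b = rep(0.1, cfg$c_s),
    e1.W = init_weight(cfg$c_s, cfg$n_e1, "relu"),
    e1.b = numeric(cfg$n_e1),
    e3.W = init_weight(cfg$c_s * 9L, cfg$n_e3, "relu"),
    e3.b = numeric(cfg$n_e3)
  )
}

# Channel concatenation: with channels-last (H, W, B, C) arrays this is a
# plain vector concatenation.
channel_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
}

channel_split <- function(x, c1) {
  d <- dim(x)
  n1 <- prod(d[1:3]) * c1
  a <- x[seq_len(n1)]
  b <- x[(n1 + 1L):length(x)]
  dim(a) <- c(d[1:3], c1)
  dim(b) <- c(d[1:3], d[4L] - c1)
  list(a, b)
}

#' Forward pass of a single Fire module
#'
#' Squeeze (1x1 conv + ReLU), parallel excitation (1x1 and 3x3 convs + ReLU),
#' channel concatenation. Spatial dimensions are preserved (the 3x3 branch
#' uses padding 1, stride 1); the output has `n_e1 + n_e3` channels.
#'
#' @param x feature map, array `(H, W, B, C)` with `C = cfg$c_in` (an
#'   `(H, W)` matrix or `(H, W, C)` array is promoted)
#' @param params parameter list from the internal initialiser (or a trained
#'   model's slice)
#' @param cfg a `fire_config`
#' @param cache logical; keep intermediates for backprop
#' @return the output feature map, or a list `(out, cache)` when
#'   `cache = TRUE`
#' @export
fire_forward <- function(x, params, cfg, cache = FALSE) {
  x <- as_feature_map(x)
  if (dim(x)[4L] != cfg$c_in) {
    stop("Fire module expected ", cfg$c_in, " input channels, got ",
         dim(x)[4L], call. = FALSE)
  }
  xs <- conv_fwd(x, params$sq.W, params$sq.b, 1L, 1L, 0L, relu = TRUE)
  a <- conv_fwd(xs, params$e1.W, params$e1.b, 1L, 1L, 0L, relu = TRUE)
  e3 <- conv_fwd(xs, params$e3.W, params$e3.b, 3L, 1L, 1L, relu = TRUE)
  out <- channel_concat(a, e3)
  if (!cache) return(out)
  list(out = out, cache = list(x = x, xs = xs, a = a, e3 = e3))
}

fire_backward <- function(dout, cache, params, cfg, need_dx = TRUE) {
  sp <- channel_split(dout, cfg$n_e1)
  g1 <- conv_bwd(sp[[1L]], cache$a, cache$xs, params$e1.W, 1L, 1L, 0L)
  g3 <- conv_bwd(sp[[2L]], cache$e3, cache$xs, params$e3.W, 3L, 1L, 1L)
  dxs <- g1$dx + g3$dx
  gs <- conv_bwd(dxs, cache$xs, cache$x, params$sq.W, 1L, 1L, 0L,
                 need_dx = need_dx)
  list(dx = gs$dx,
       grads = list(sq.W = gs$dW, sq.b = gs$db,
                    e1.W = g1$dW, e1.b = g1$db,
                    e3.W = g3$dW, e3.b = g3$db))
}

#' Fire Block configuration
#'
#' A Fire Block is `N` stacked Fire modules followed by a 3x3 max-pooling
#' layer (stride 2, padding 1) that halves the spatial dimensions. The
#' channel plan lists the `N + 1` widths through the block; every width after
#' the first must be even.
#'
#' @param channel_plan integer vector of length `N + 1`; the Stage-1 default
#'   is `c(3, 32, 64, 64, 128)`
#' @return an object of class `fire_block_config`
#' @export
fire_block_config <- function(channel_plan = c(3L, 32L, 64L, 64L, 128L)) {
  channel_plan <- as.integer(channel_plan)
  if (length(channel_plan) < 2L) {
    stop("channel_plan needs at least 2 entries (N >= 1 Fire modules)",
         call. = FALSE)
  }
  fires <- lapply(seq_len(length(channel_plan) - 1L), function(i) {
    derive_fire_channels(channel_plan[i], channel_plan[i + 1L])
  })
  structure(list(n = length(fires), channel_plan = channel_plan,
                 fires = fires, pool = conv_spec(3L, 2L, 1L)),
            class = "fire_block_config")
}

fire_block_init <- function(cfg) {
  params <- list()
  for (i in seq_len(cfg$n)) {
    p <- fire_init(cfg$fires[[i]])
    names(p) <- paste0("fire", i, ".", names(p))
    params <- c(params, p)
  }
  params
}

slice_params <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

#' Forward pass of a Fire Block
#'
#' @param x input feature map with `channel_plan[1]` channels
#' @param params flat parameter list (names `fire<i>.*`)
#' @param cfg a `fire_block_config`
#' @param cache keep intermediates for backprop
#' @return output feature map with `channel_plan[N + 1]` channels and halved
#'   spatial dimensions, or `(out, cache)` when `cache = TRUE`
#' @export
fire_block_forward <- function(x, params, cfg, cache = FALSE) {
  x <- as_feature_map(x)
  if (dim(x)[4L] != cfg$channel_plan[1L]) {
    stop("Fire Block expected ", cfg$channel_plan[1L], " input channels, got ",
         dim(x)[4L], call. = FALSE)
  }
  caches <- vector("list", cfg$n)
  for (i in seq_len(cfg$n)) {
    r <- fire_forward(x, slice_params(params, paste0("fire", i, ".")),
                      cfg$fires[[i]], cache = cache)
    if (cache) { caches[[i]] <- r$cache; x <- r$out } else x <- r
  }
  pr <- maxpool_fwd(x, cfg$pool$k, cfg$pool$s, cfg$pool$p)
  if (!cache) return(pr$out)
  list(out = pr$out, cache = list(fires = caches, pool = pr))
}

fire_block_backward <- function(dout, cache, params, cfg, need_dx = TRUE) {
  dx <- maxpool_bwd(dout, cache$pool)
  grads <- list()
  for (i in rev(seq_len(cfg$n))) {
    pref <- paste0("fire", i, ".")
    g <- fire_backward(dx, cache$fires[[i]], slice_params(params, pref),
                       cfg$fires[[i]],
                       need_dx = need_dx || i > 1L)
    names(g$grads) <- paste0(pref, names(g$grads))
    grads <- c(grads, g$grads)
    dx <- g$dx
  }
  list(dx = dx, grads = grads)
}
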