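#' Patch grid for tokenization
#'
#' Partitions an `H x W` feature map into patches of size `h x w`. Each patch
#' contributes `P = h * w` pixel positions and the map yields
#' `N = (H * W) / (h * w)` patches; tokens are grouped by intra-patch offset,
#' giving `P` sequences of `N` tokens (MobileViT-style, preserving local
#' pixel order, no positional embeddings).
#'
#' @param H,W feature-map spatial dimensions
#' @param h,w patch height and width
#' @return an object of class `patch_grid` with fields `H, W, h, w, P, N` and
#'   the padded dims `Hp, Wp` actually used
#' @export
patch_grid <- function(H, W, h = 4L, w = 4L) {
  stopifnot(H >= 1, W >= 1, h >= 1, w >= 1)
  if (h > H || w > W) {
    stop("patch size (", h, "x", w, ") exceeds feature map (", H, "x", W, ")",
         call. = FALSE)
  }
  Hp <- as.integer(ceiling(H / h) * h)
  Wp <- as.integer(ceiling(W / w) * w)
  structure(list(H = as.integer(H), W = as.integer(W),
                 h = as.integer(h), w = as.integer(w),
                 Hp = Hp, Wp = Wp,
                 P = as.integer(h * w), N = as.integer((Hp / h) * (Wp / w))),
            class = "patch_grid")
}

#' Rearrange a feature map into order-preserving patch tokens
#'
#' Bijective rearrangement of an `(H, W, B, C)` feature map into a token
#' array `(N, P, B, C)`: token `[n, p, b, ]` is the channel vector of patch
#' `n` at intra-patch pixel offset `p`. If `H` or `W` is not divisible by
#' the patch side the map is zero-padded on the bottom/right first.
#'
#' @param x feature map `(H, W, B, C)`
#' @param grid a `patch_grid` consistent with `x`
#' @return token array of dim `(N, P, B, C)`
#' @export
unfold_patches <- function(x, grid) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1L] != grid$H || d[2L] != grid$W) {
    stop("feature map is ", d[1L], "x", d[2L], " but grid expects ",
         grid$H, "x", grid$W, call. = FALSE)
  }
  if (grid$Hp != grid$H || grid$Wp != grid$W) {
    xp <- array(0, c(grid$Hp, grid$Wp, d[3L], d[4L]))
    xp[seq_len(grid$H), seq_len(grid$W), , ] <- x
    x <- xp
  }
  B <- d[3L]; C <- d[4L]
  nh <- grid$Hp %/% grid$h; nw <- grid$Wp %/% grid$w
  dim(x) <- c(grid$h, nh, grid$w, nw, B, C)
  x <- aperm(x, c(2L, 4L, 1L, 3L, 5L, 6L))
  dim(x) <- c(nh * nw, grid$h * grid$w, B, C)
  x
}

#' Inverse of [unfold_patches()]
#'
#' @param tokens token array `(N, P, B, C)`
#' @param grid the `patch_grid` used to unfold
#' @return feature map `(H, W, B, C)` (padding, if any, is cropped)
#' @export
fold_patches <- function(tokens, grid) {
  d <- dim(tokens)
  if (length(d) != 4L || d[1L] != grid$N || d[2L] != grid$P) {
    stop("token array dim (", paste(d, collapse = ","),
         ") inconsistent with grid N=", grid$N, " P=", grid$P, call. = FALSE)
  }
  B <- d[3L]; C <- d[4L]
  nh <- grid$Hp %/% grid$h; nw <- grid$Wp %/% grid$w
  dim(tokens) <- c(nh, nw, grid$h, grid$w, B, C)
  x <- aperm(tokens, c(3L, 1L, 4L, 2L, 5L, 6L))
  dim(x) <- c(grid$Hp, grid$Wp, B, C)
  if (grid$Hp != grid$H || grid$Wp != grid$W) {
    x <- x[seq_len(grid$H), seq_len(grid$W), , , drop = FALSE]
  }
  x
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`, rows of the score
#' matrix softmax-normalised, so every output row is a convex combination of
#' the rows of `V`.
#'
#' @param Q,K matrices `N x d_k` (queries, keys)
#' @param V matrix `N x d_v` (values)
#' @return matrix `N x d_v`
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) == 0L) stop("d_k must be positive", call. = FALSE)
  if (ncol(Q) != ncol(K) || nrow(Q) != nrow(K) || nrow(K) != nrow(V)) {
    stop("Q, K, V shapes are inconsistent", call. = FALSE)
  }
  s <- tcrossprod(Q, K) / sqrt(ncol(Q))
  s <- exp(s - apply(s, 1L, max))
  (s / rowSums(s)) %*% V
}

#' Attention / encoder specification
#'
#' @param token_dim token dimensionality `d`
#' @param heads number of attention heads (must divide `token_dim`)
#' @param depth number of encoder layers
#' @param ffn_width hidden width of the per-token feed-forward sublayer
#' @param dropout dropout rate (0 disables; default 0)
#' @return an object of class `attention_spec`; per-head `d_k = d_v =
#'   token_dim / heads`
#' @export
attention_spec <- function(token_dim = 64L, heads = 4L, depth = 2L,
                           ffn_width = 64L, dropout = 0) {
  stopifnot(token_dim >= 1, heads >= 1, depth >= 1, ffn_width >= 1,
            dropout >= 0, dropout < 1)
  if (token_dim %% heads != 0L) {
    stop("heads must divide token_dim", call. = FALSE)
  }
  structure(list(token_dim = as.integer(token_dim), heads = as.integer(heads),
                 d_k = as.integer(token_dim %/% heads),
                 d_v = as.integer(token_dim %/% heads),
                 depth = as.integer(depth), ffn_width = as.integer(ffn_width),
                 dropout = dropout),
            class = "attention_spec")
}

encoder_init <- function(spec) {
  d <- spec$token_dim; f <- spec$ffn_width
  params <- list(norm_in.gamma = rep(1, d), norm_in.beta = numeric(d))
  for (l in seq_len(spec$depth)) {
    p <- list(
      ln1.gamma = rep(1, d), ln1.beta = numeric(d),
      q.W = init_weight(d, d, "linear"), q.b = numeric(d),
      k.W = init_weight(d, d, "linear"), k.b = numeric(d),
      v.W = init_weight(d, d, "linear"), v.b = numeric(d),
      o.W = init_weight(d, d, "linear"), o.b = numeric(d),
      ln2.gamma = rep(1, d), ln2.beta = numeric(d),
      ffn1.W = init_weight(d, f, "relu"), ffn1.b = numeric(f),
      ffn2.W = init_weight(f, d, "linear"), ffn2.b = numeric(d)
    )
    names(p) <- paste0("layer", l, ".", names(p))
    params <- c(params, p)
  }
  c(params, list(norm_out.gamma = rep(1, d), norm_out.beta = numeric(d)))
}

# (M, d) row-token matrix -> (d, N, S) array for the attention kernels.
to_dns <- function(x, N, S, d) {
  dim(x) <- c(N, S, d)
  aperm(x, c(3L, 1L, 2L))
}

from_dns <- function(x, N, S, d) {
  dim(x) <- c(d, N, S)
  x <- aperm(x, c(2L, 3L, 1L))
  dim(x) <- c(N * S, d)
  x
}

# tokens: (N, P, B, d) -> same shape. Attention runs over the N dimension of
# each of the P*B sequences; pre-norm residual layers, entry/exit LayerNorm.
encoder_fwd <- function(tokens, params, spec, cache = FALSE) {
  d0 <- dim(tokens)
  if (d0[4L] != spec$token_dim) {
    stop("token dim ", d0[4L], " != spec token_dim ", spec$token_dim,
         call. = FALSE)
  }
  N <- d0[1L]; S <- d0[2L] * d0[3L]; d <- d0[4L]
  x <- tokens
  dim(x) <- c(N * S, d)
  caches <- list()
  ni <- layernorm_fwd(x, params$norm_in.gamma, params$norm_in.beta)
  if (cache) caches$norm_in <- c(ni["xhat"], ni["inv"])
  x <- ni$out
  for (l in seq_len(spec$depth)) {
    pl <- slice_params(params, paste0("layer", l, "."))
    lc <- list()
    n1 <- layernorm_fwd(x, pl$ln1.gamma, pl$ln1.beta)
    Q <- linear_fwd(n1$out, pl$q.W, pl$q.b)
    K <- linear_fwd(n1$out, pl$k.W, pl$k.b)
    V <- linear_fwd(n1$out, pl$v.W, pl$v.b)
    Qd <- to_dns(Q, N, S, d); Kd <- to_dns(K, N, S, d); Vd <- to_dns(V, N, S, d)
    at <- attn_fwd_cpp(Qd, Kd, Vd, d, N, S, spec$heads)
    ao <- from_dns(at$out, N, S, d)
    proj <- linear_fwd(ao, pl$o.W, pl$o.b)
    x1 <- x + proj
    n2 <- layernorm_fwd(x1, pl$ln2.gamma, pl$ln2.beta)
    h <- relu_fwd(linear_fwd(n2$out, pl$ffn1.W, pl$ffn1.b))
    f2 <- linear_fwd(h, pl$ffn2.W, pl$ffn2.b)
    xn <- x1 + f2
    if (cache) {
      lc$x_in <- x; lc$n1 <- n1; lc$Qd <- Qd; lc$Kd <- Kd; lc$Vd <- Vd
      lc$attn <- at$attn; lc$ao <- ao; lc$x1 <- x1; lc$n2 <- n2; lc$h <- h
      caches[[paste0("layer", l)]] <- lc
    }
    x <- xn
  }
  no <- layernorm_fwd(x, params$norm_out.gamma, params$norm_out.beta)
  out <- no$out
  dim(out) <- d0
  if (!cache) return(out)
  caches$norm_out <- c(no["xhat"], no["inv"])
  caches$dims <- list(d = d, N = N, S = S, d0 = d0)
  list(out = out, cache = caches)
}

encoder_bwd <- function(dout, cache, params, spec) {
  dm <- cache$dims
  d <- dm$d; N <- dm$N; S <- dm$S
  g <- dout
  dim(g) <- c(N * S, d)
  grads <- list()
  bo <- layernorm_bwd(g, cache$norm_out, params$norm_out.gamma)
  grads$norm_out.gamma <- bo$dgamma; grads$norm_out.beta <- bo$dbeta
  g <- bo$dx
  for (l in rev(seq_len(spec$depth))) {
    pl <- slice_params(params, paste0("layer", l, "."))
    lc <- cache[[paste0("layer", l)]]
    # feed-forward branch
    g2 <- linear_bwd(g, lc$h, pl$ffn2.W)
    dh <- relu_bwd(g2$dx, lc$h)
    g1 <- linear_bwd(dh, lc$n2$out, pl$ffn1.W)
    bn2 <- layernorm_bwd(g1$dx, lc$n2, pl$ln2.gamma)
    dx1 <- g + bn2$dx
    # attention branch
    go <- linear_bwd(dx1, lc$ao, pl$o.W)
    dao <- to_dns(go$dx, N, S, d)
    ab <- attn_bwd_cpp(dao, lc$Qd, lc$Kd, lc$Vd, lc$attn, d, N, S,
                       spec$heads)
    dQ <- from_dns(ab$dQ, N, S, d)
    dK <- from_dns(ab$dK, N, S, d)
    dV <- from_dns(ab$dV, N, S, d)
    gq <- linear_bwd(dQ, lc$n1$out, pl$q.W)
    gk <- linear_bwd(dK, lc$n1$out, pl$k.W)
    gv <- linear_bwd(dV, lc$n1$out, pl$v.W)
    bn1 <- layernorm_bwd(gq$dx + gk$dx + gv$dx, lc$n1, pl$ln1.gamma)
    g <- dx1 + bn1$dx
    lg <- list(ln1.gamma = bn1$dgamma, ln1.beta = bn1$dbeta,
               q.W = gq$dW, q.b = gq$db, k.W = gk$dW, k.b = gk$db,
               v.W = gv$dW, v.b = gv$db, o.W = go$dW, o.b = go$db,
               ln2.gamma = bn2$dgamma, ln2.beta = bn2$dbeta,
               ffn1.W = g1$dW, ffn1.b = g1$db,
               ffn2.W = g2$dW, ffn2.b = g2$db)
    names(lg) <- paste0("layer", l, ".", names(lg))
    grads <- c(grads, lg)
  }
  bi <- layernorm_bwd(g, cache$norm_in, params$norm_in.gamma)
  grads$norm_in.gamma <- bi$dgamma; grads$norm_in.beta <- bi$dbeta
  dx <- bi$dx
  dim(dx) <- dm$d0
  list(dx = dx, grads = grads)
}

#' Apply a transformer encoder to a token array
#'
#' Shape-preserving pre-norm residual encoder (attention + feed-forward
#' sublayers) over `(N, P, B, d)` token arrays; no positional embeddings.
#'
#' @param tokens token array `(N, P, B, d)` from [unfold_patches()]
#' @param params parameter list from the internal initialiser
#' @param spec an `attention_spec` with `token_dim = d`
#' @return encoded token array of identical shape
#' @export
transformer_encode <- function(tokens, params, spec) {
  encoder_fwd(tokens, params, spec, cache = FALSE)
}

#' Translution Block configuration
#'
#' Stage-2 block: Fire expansion `C -> 2C`, Fire squeeze `2C -> 64` tokens,
#' patch tokenization, transformer encoding, fold, 1x1-conv projection back
#' to `C`, channel concatenation with the block input (`C_output = 2C`), and
#' a fusing Fire module `2C -> C`.
#'
#' @param c_in block input/output channel count (default 128)
#' @param token_dim token dimensionality after the squeezing Fire (default 64)
#' @param patch_h,patch_w patch dims (default 4 x 4)
#' @param attention an `attention_spec` (defaults to the standard encoder)
#' @return an object of class `translution_config`
#' @export
translution_config <- function(c_in = 128L, token_dim = 64L,
                               patch_h = 4L, patch_w = 4L,
                               attention = attention_spec(token_dim = token_dim)) {
  stopifnot(attention$token_dim == token_dim)
  structure(list(
    c_in = as.integer(c_in),
    token_dim = as.integer(token_dim),
    patch_h = as.integer(patch_h), patch_w = as.integer(patch_w),
    fire_expand = derive_fire_channels(c_in, 2L * c_in),
    fire_reduce = derive_fire_channels(2L * c_in, token_dim),
    attention = attention,
    project = conv_spec(1L, 1L, 0L, token_dim, c_in),
    fire_fuse = derive_fire_channels(2L * c_in, c_in)
  ), class = "translution_config")
}

translution_init <- function(cfg) {
  p1 <- fire_init(cfg$fire_expand); names(p1) <- paste0("expand.", names(p1))
  p2 <- fire_init(cfg$fire_reduce); names(p2) <- paste0("reduce.", names(p2))
  pe <- encoder_init(cfg$attention); names(pe) <- paste0("enc.", names(pe))
  pp <- list(proj.W = init_weight(cfg$token_dim, cfg$c_in, "linear"),
             proj.b = numeric(cfg$c_in))
  pf <- fire_init(cfg$fire_fuse); names(pf) <- paste0("fuse.", names(pf))
  c(p1, p2, pe, pp, pf)
}

#' Forward pass of the Translution Block
#'
#' @param x input feature map `(H, W, B, C)` with `C = cfg$c_in`
#' @param params flat parameter list
#' @param cfg a `translution_config`
#' @param cache keep intermediates for backprop
#' @return output feature map with identical `(H, W, C)` shape, or
#'   `(out, cache)` when `cache = TRUE`
#' @export
translution_forward <- function(x, params, cfg, cache = FALSE) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[4L] != cfg$c_in) {
    stop("Translution Block expected ", cfg$c_in, " channels, got ", d[4L],
         call. = FALSE)
  }
  grid <- patch_grid(d[1L], d[2L], cfg$patch_h, cfg$patch_w)
  r1 <- fire_forward(x, slice_params(params, "expand."), cfg$fire_expand,
                     cache = cache)
  a1 <- if (cache) r1$out else r1
  r2 <- fire_forward(a1, slice_params(params, "reduce."), cfg$fire_reduce,
                     cache = cache)
  a2 <- if (cache) r2$out else r2
  tok <- unfold_patches(a2, grid)
  re <- encoder_fwd(tok, slice_params(params, "enc."), cfg$attention,
                    cache = cache)
  enc <- if (cache) re$out else re
  folded <- fold_patches(enc, grid)
  proj <- conv_fwd(folded, params$proj.W, params$proj.b, 1L, 1L, 0L,
                   relu = FALSE)
  cat2 <- channel_concat(x, proj)
  rf <- fire_forward(cat2, slice_params(params, "fuse."), cfg$fire_fuse,
                     cache = cache)
  out <- if (cache) rf$out else rf
  if (!cache) return(out)
  list(out = out,
       cache = list(grid = grid, x = x, f1 = r1$cache, f2 = r2$cache,
                    enc = re$cache, folded = folded, fuse = rf$cache))
}

translution_backward <- function(dout, cache, params, cfg, need_dx = TRUE) {
  gf <- fire_backward(dout, cache$fuse, slice_params(params, "fuse."),
                      cfg$fire_fuse)
  names(gf$grads) <- paste0("fuse.", names(gf$grads))
  sp <- channel_split(gf$dx, cfg$c_in)
  dx_skip <- sp[[1L]]
  dproj <- sp[[2L]]
  gp <- conv_bwd(dproj, NULL, cache$folded, params$proj.W, 1L, 1L, 0L,
                 relu = FALSE)
  dtok <- unfold_patches(gp$dx, cache$grid)
  ge <- encoder_bwd(dtok, cache$enc, slice_params(params, "enc."),
                    cfg$attention)
  names(ge$grads) <- paste0("enc.", names(ge$grads))
  da2 <- fold_patches(ge$dx, cache$grid)
  g2 <- fire_backward(da2, cache$f2, slice_params(params, "reduce."),
                      cfg$fire_reduce)
  names(g2$grads) <- paste0("reduce.", names(g2$grads))
  g1 <- fire_backward(g2$dx, cache$f1, slice_params(params, "expand."),
                      cfg$fire_expand, need_dx = need_dx)
  names(g1$grads) <- paste0("expand.", names(g1$grads))
  dx <- if (need_dx) dx_skip + g1$dx else NULL
  list(dx = dx,
       grads = c(gf$grads, list(proj.W = gp$dW, proj.b = gp$db),
                 ge$grads, g2$grads, g1$grads))
}
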