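#' @useDynLib squeezevit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom plogis qlogis cor sd quantile
#' @importFrom utils read.csv write.csv
NULL

#' Convolution layer specification
#'
#' Describes a 2-D convolution (or pooling window) by kernel size, stride,
#' padding and channel widths. Output spatial dimensions follow
#' \eqn{H' = \lfloor (H + 2p - k)/s \rfloor + 1} (same for width).
#'
#' @param k kernel size (positive integer, square kernels only)
#' @param s stride (positive integer)
#' @param p zero padding (non-negative integer)
#' @param c_in,c_out input / output channel counts
#' @return an object of class `conv_spec`
#' @export
conv_spec <- function(k, s = 1L, p = 0L, c_in = 1L, c_out = 1L) {
  stopifnot(k >= 1, s >= 1, p >= 0, c_in >= 1, c_out >= 1)
  structure(list(k = as.integer(k), s = as.integer(s), p = as.integer(p),
                 c_in = as.integer(c_in), c_out = as.integer(c_out)),
            class = "conv_spec")
}

#' Output spatial size of a convolution or pooling window
#'
#' @param n input spatial extent (height or width)
#' @param k,s,p kernel size, stride, padding
#' @return integer output extent, floor mode
#' @export
conv_out_dim <- function(n, k, s = 1L, p = 0L) {
  out <- (n + 2L * p - k) %/% s + 1L
  if (any(out < 1L)) {
    stop("convolution output dimension < 1 for input ", n,
         " with k=", k, " s=", s, " p=", p, call. = FALSE)
  }
  as.integer(out)
}

# ---- internal tensor primitives -------------------------------------------
# Feature maps are numeric arrays dim (H, W, B, C) — channels last, so a
# channel plane is contiguous and concatenation along channels is cheap.
# Convolution weights are (k*k*C_in) x C_out matrices, rows ordered
# (kh, kw, c_in); the heavy lifting happens in float32 im2col + sgemm in C++.

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d[1L], d[2L], 1L, 1L)       # (H, W)
  else if (length(d) == 3L) dim(x) <- c(d[1L], d[2L], 1L, d[3L]) # (H, W, C)
  x
}

conv_fwd <- function(x, W, b, k, s, p, relu = TRUE) {
  conv2d_f32_fwd(x, dim(x), W, b, as.integer(k), as.integer(s),
                 as.integer(p), relu)
}

# act: the layer's (post-ReLU) output, used as the ReLU mask; ignored when
# relu = FALSE.
conv_bwd <- function(dout, act, x, W, k, s, p, relu = TRUE,
                     need_dx = TRUE) {
  conv2d_f32_bwd(dout, if (relu) act else numeric(0), x, dim(x), W,
                 as.integer(k), as.integer(s), as.integer(p), relu, need_dx)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dout, out) {
  dout * (out > 0)
}

maxpool_fwd <- function(x, k = 3L, s = 2L, p = 1L) {
  d <- dim(x)
  r <- maxpool_fwd_cpp(x, d, as.integer(k), as.integer(s), as.integer(p))
  out <- r$out
  dim(out) <- c(r$Ho, r$Wo, d[3L], d[4L])
  list(out = out, argmax = r$argmax, in_dim = d)
}

maxpool_bwd <- function(dout, cache) {
  dx <- maxpool_bwd_cpp(dout, cache$argmax, prod(cache$in_dim))
  dim(dx) <- cache$in_dim
  dx
}

global_avg_pool_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  m <- x
  dim(m) <- c(hw, d[3L], d[4L])
  list(out = colMeans(m, dims = 1L), in_dim = d)   # (B, C)
}

global_avg_pool_bwd <- function(dout, cache) {
  d <- cache$in_dim
  hw <- d[1L] * d[2L]
  array(rep(as.vector(dout) / hw, each = hw), d)
}

# x: (M, in); W: (in, out); b: length out
linear_fwd <- function(x, W, b) {
  x %*% W + rep(b, each = nrow(x))
}

linear_bwd <- function(dout, x, W) {
  list(dx = tcrossprod(dout, W), dW = crossprod(x, dout),
       db = colSums(dout))
}

# Layer normalisation of each row of an (M, d) token matrix over its d
# channels.
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  m <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, gamma) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = m)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Kaiming / Xavier initialisation; returns a (fan_in, fan_out) matrix.
init_weight <- function(fan_in, fan_out, gain = c("relu", "linear")) {
  gain <- match.arg(gain)
  sdv <- if (gain == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  matrix(rnorm(fan_in * fan_out, sd = sdv), fan_in, fan_out)
}
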