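# Shared fixtures: all tiny, generated in code under fixed seeds.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# A seeded Fire module (params + config) on c_in -> c_out.
tiny_fire <- function(c_in, c_out, seed = 1) {
  cfg <- derive_fire_channels(c_in, c_out)
  params <- with_seed(seed, squeezevit:::fire_init(cfg))
  list(cfg = cfg, params = params)
}

# Direct elementwise convolution oracle, channels-last (H, W, B, C) layout,
# weight rows ordered (kh, kw, c_in) to match the package's convention.
conv_oracle <- function(x, W, b, k, s, p) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  Ho <- (H + 2 * p - k) %/% s + 1
  Wo <- (Wd + 2 * p - k) %/% s + 1
  Co <- ncol(W)
  out <- array(0, c(Ho, Wo, B, Co))
  for (co in seq_len(Co)) for (bb in seq_len(B)) {
    for (ow in seq_len(Wo)) for (oh in seq_len(Ho)) {
      acc <- b[co]
      for (cc in seq_len(C)) for (kw in 0:(k - 1)) for (kh in 0:(k - 1)) {
        hh <- (oh - 1) * s - p + kh
        ww <- (ow - 1) * s - p + kw
        if (hh >= 0 && hh < H && ww >= 0 && ww < Wd) {
          r <- kh + k * kw + k * k * (cc - 1) + 1
          acc <- acc + x[hh + 1, ww + 1, bb, cc] * W[r, co]
        }
      }
      out[oh, ow, bb, co] <- acc
    }
  }
  out
}

# Exhaustive pairwise AUROC: wins + half-ties over all pos/neg pairs.
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# Small synthetic image batch at full input size, for fast model smoke tests.
tiny_images <- function(n, side = 224L, seed = 5) {
  with_seed(seed, array(runif(side * side * n), c(side, side, n)))
}

random_labels <- function(n, L = 14L, seed = 6) {
  with_seed(seed, {
    m <- matrix(rbinom(n * L, 1L, 0.4), n, L)
    # guarantee both classes present per column
    m[1, ] <- 1L
    m[2, ] <- 0L
    m
  })
}
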