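test_that("patch grid counts patches and pixels per patch", {
  g <- patch_grid(28, 28, 4, 4)
  expect_equal(g$N, 49L)          # (28*28)/(4*4)
  expect_equal(g$P, 16L)
  expect_equal(g$N * g$P, 28L * 28L)   # token bijection, no pixel lost
  expect_equal(patch_grid(28, 28, 2, 2)$N, 4L * g$N)  # halving side quadruples N
  expect_error(patch_grid(3, 3, 4, 4), "exceeds")
})

test_that("fold is the exact inverse of unfold and is order-sensitive", {
  g <- patch_grid(28, 28, 4, 4)
  x <- with_seed(1, array(rnorm(28 * 28 * 2 * 64), c(28, 28, 2, 64)))
  tok <- unfold_patches(x, g)
  expect_equal(dim(tok), c(49L, 16L, 2L, 64L))
  expect_identical(fold_patches(tok, g), x)       # bit-exact round trip

  expect_true(all(fold_patches(array(0, dim(tok)), g) == 0))

  swapped <- tok
  swapped[1, , , ] <- tok[2, , , ]
  swapped[2, , , ] <- tok[1, , , ]
  expect_false(isTRUE(all.equal(fold_patches(swapped, g), x)))

  # non-divisible maps are padded on unfold and cropped back on fold
  g2 <- patch_grid(30, 30, 4, 4)
  x2 <- with_seed(2, array(rnorm(30 * 30 * 1 * 3), c(30, 30, 1, 3)))
  expect_identical(fold_patches(unfold_patches(x2, g2), g2), x2)
})

test_that("each token is one pixel position's channel vector", {
  g <- patch_grid(8, 8, 4, 4)
  x <- array(0, c(8, 8, 1, 3))
  x[5, 2, 1, ] <- c(7, 8, 9)   # patch (2,1) of the 2x2 grid, offset (1,2)
  tok <- unfold_patches(x, g)
  n <- 2L                      # patch index: nh=2, nw=1 -> n = 2
  p <- 1L + 4L * 1L            # offset index: dh=1, dw=2 -> p = 5
  expect_equal(tok[n, p, 1, ], c(7, 8, 9))
  expect_equal(sum(tok != 0), 3L)
})

test_that("attention obeys its closed-form special cases", {
  # single token: softmax of a scalar is 1, output is V
  V <- matrix(c(3.5, -2), 1, 2)
  expect_equal(attention(matrix(1, 1, 4), matrix(2, 1, 4), V), V)

  # identical keys: uniform weights, every output row is the mean of V
  Q <- with_seed(3, matrix(rnorm(12), 4, 3))
  K <- matrix(rep(c(1, 0, -1), each = 4), 4, 3)
  V2 <- with_seed(4, matrix(rnorm(8), 4, 2))
  out <- attention(Q, K, V2)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V2), tolerance = 1e-12)

  # N=2, d_k=d_v=1 hand-evaluated softmax arithmetic
  Q <- matrix(c(1, 0), 2, 1); K <- matrix(c(1, 0), 2, 1)
  V3 <- matrix(c(1, 2), 2, 1)
  s11 <- exp(1); s12 <- exp(0)   # row 1 scores exp(1*1/1), exp(1*0/1)
  w11 <- s11 / (s11 + s12)
  expected <- matrix(c(w11 * 1 + (1 - w11) * 2, 1.5), 2, 1)
  expect_equal(attention(Q, K, V3), expected, tolerance = 1e-12)

  expect_error(attention(matrix(0, 2, 0), matrix(0, 2, 0), V3), "d_k")
})

test_that("attention rows are convex weights over V", {
  spec <- attention_spec(token_dim = 8L, heads = 2L, depth = 1L)
  N <- 6L; S <- 3L
  Q <- with_seed(5, array(rnorm(8 * N * S), c(8, N, S)))
  K <- with_seed(6, array(rnorm(8 * N * S), c(8, N, S)))
  V <- with_seed(7, array(rnorm(8 * N * S), c(8, N, S)))
  r <- squeezevit:::attn_fwd_cpp(Q, K, V, 8L, N, S, 2L)
  A <- array(r$attn, c(N, N, 2L, S))
  expect_true(all(abs(apply(A, c(1, 3, 4), sum) - 1) < 1e-6))
  out <- array(r$out, c(8, N, S))
  for (s in seq_len(S)) for (h in 1:2) {
    rows <- ((h - 1) * 4 + 1):(h * 4)
    lo <- apply(V[rows, , s, drop = FALSE], 1, min)
    hi <- apply(V[rows, , s, drop = FALSE], 1, max)
    expect_true(all(out[rows, , s] >= lo - 1e-9))
    expect_true(all(out[rows, , s] <= hi + 1e-9))
  }
})

test_that("the multi-head kernel agrees with the plain attention operator", {
  spec <- attention_spec(token_dim = 8L, heads = 2L, depth = 1L)
  N <- 5L
  Q <- with_seed(8, array(rnorm(8 * N), c(8, N, 1)))
  K <- with_seed(9, array(rnorm(8 * N), c(8, N, 1)))
  V <- with_seed(10, array(rnorm(8 * N), c(8, N, 1)))
  r <- squeezevit:::attn_fwd_cpp(Q, K, V, 8L, N, 1L, 2L)
  out <- array(r$out, c(8, N, 1))
  for (h in 1:2) {
    rows <- ((h - 1) * 4 + 1):(h * 4)
    ref <- attention(t(Q[rows, , 1]), t(K[rows, , 1]), t(V[rows, , 1]))
    expect_equal(t(out[rows, , 1]), ref, tolerance = 1e-12)
  }
})

test_that("encoder preserves shape, is deterministic, and collapses to its norms when projections are zeroed", {
  for (depth in c(1L, 2L)) {
    spec <- attention_spec(token_dim = 16L, heads = 4L, depth = depth,
                           ffn_width = 16L)
    params <- with_seed(11, squeezevit:::encoder_init(spec))
    tok <- with_seed(12, array(rnorm(9 * 4 * 2 * 16), c(9, 4, 2, 16)))
    out1 <- transformer_encode(tok, params, spec)
    out2 <- transformer_encode(tok, params, spec)
    expect_equal(dim(out1), dim(tok))
    expect_identical(out1, out2)     # bit-identical reruns

    # zero the attention output projection and second FFN weight: residual
    # connections make every encoder layer the identity, so the whole stack
    # reduces to the entry and exit layer norms
    pz <- params
    for (l in seq_len(depth)) {
      pz[[paste0("layer", l, ".o.W")]][] <- 0
      pz[[paste0("layer", l, ".o.b")]][] <- 0
      pz[[paste0("layer", l, ".ffn2.W")]][] <- 0
      pz[[paste0("layer", l, ".ffn2.b")]][] <- 0
    }
    out_z <- transformer_encode(tok, pz, spec)
    m <- matrix(tok, 9 * 4 * 2, 16)
    ln_in <- squeezevit:::layernorm_fwd(m, pz$norm_in.gamma, pz$norm_in.beta)
    ln_out <- squeezevit:::layernorm_fwd(ln_in$out, pz$norm_out.gamma,
                                         pz$norm_out.beta)
    expect_equal(as.vector(out_z), as.vector(ln_out$out), tolerance = 1e-10)
  }
  expect_error(
    transformer_encode(array(0, c(4, 4, 1, 8)), list(),
                       attention_spec(token_dim = 16L)),
    "token dim")
})

test_that("translution block preserves (C, H, W), doubles channels at the concat, and backprops everywhere", {
  cfg <- translution_config(128L)
  params <- with_seed(13, squeezevit:::translution_init(cfg))
  x <- with_seed(14, array(runif(28 * 28 * 1 * 128), c(28, 28, 1, 128)))
  r <- translution_forward(x, params, cfg, cache = TRUE)
  expect_equal(dim(r$out), dim(x))                       # 28x28x128 in -> out
  expect_equal(dim(r$cache$fuse$x)[4], 256L)             # concat width = 2C
  expect_error(translution_forward(x[, , , 1:64, drop = FALSE], params, cfg),
               "expected 128 channels")

  g <- squeezevit:::translution_backward(array(1, dim(r$out)) / length(r$out),
                                         r$cache, params, cfg)
  expect_setequal(names(g$grads), names(params))
  groups <- c("expand.", "reduce.", "enc.", "proj.", "fuse.")
  for (gr in groups) {
    gs <- g$grads[startsWith(names(g$grads), gr)]
    expect_true(any(vapply(gs, function(z) any(z != 0), logical(1))),
                label = paste("gradient reaches group", gr))
  }
})
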