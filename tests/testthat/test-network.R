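test_that("the end-to-end spatial ledger holds at every stage", {
  m <- build_squeezevit()
  x <- tiny_images(2)
  fw <- squeezevit:::squeezevit_fwd(m, x, cache = TRUE)
  cc <- fw$cache
  expect_equal(dim(cc$stem_act)[1:2], c(112L, 112L))     # 224 -> 112
  expect_equal(dim(cc$stem_pool$out)[1:2], c(56L, 56L))  # -> 56
  expect_equal(dim(cc$stage2$x)[1:2], c(28L, 28L))       # Stage-1 pool -> 28
  expect_equal(dim(cc$stage3_fire$x)[1:2], c(28L, 28L))  # Stage 2 preserves 28
  expect_equal(dim(cc$head_in)[1:2], c(14L, 14L))        # Stage-3 pool -> 14
  expect_equal(dim(cc$pooled), c(2L, 256L))              # GAP -> (C, 1, 1)
  expect_equal(dim(fw$out), c(2L, 14L))
  # patch divisibility: 28 divisible by 4, no padding path triggered
  expect_equal(cc$stage2$grid$Hp, cc$stage2$grid$H)
})

test_that("forward emits finite logits with valid sigmoid probabilities, preserving batch order", {
  m <- build_squeezevit()
  x <- tiny_images(3)
  x[, , 3] <- x[, , 1]                      # duplicate image 1 as image 3
  lg <- predict(m, x)
  expect_true(all(is.finite(lg)))
  pr <- predict(m, x, type = "prob")
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(lg[3, ], lg[1, ], tolerance = 1e-12)  # identical inputs
  expect_false(isTRUE(all.equal(lg[2, ], lg[1, ])))
})

test_that("model construction is reproducible from the seed", {
  m1 <- build_squeezevit(squeezevit_config(seed = 99L))
  m2 <- build_squeezevit(squeezevit_config(seed = 99L))
  expect_identical(m1$params, m2$params)
  x <- tiny_images(1)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("binary mode yields a scalar logit per image", {
  m <- build_squeezevit(squeezevit_config(num_labels = 1L))
  expect_equal(dim(predict(m, tiny_images(2))), c(2L, 1L))
})

test_that("wrong input size is rejected, never silently resized", {
  m <- build_squeezevit()
  expect_error(predict(m, array(0, c(112, 112, 1))), "resize")
})

test_that("all five ablation configs build, forward and backprop", {
  x <- tiny_images(1)
  y <- matrix(c(rep(1L, 7), rep(0L, 7)), 1, 14)
  for (tag in c("no_translution", "fire_n1", "fire_n4", "fire_n8",
                "fire_n16")) {
    cfg <- apply_ablation(squeezevit_config(), tag)
    m <- build_squeezevit(cfg)
    fw <- squeezevit:::squeezevit_fwd(m, x, cache = TRUE)
    expect_equal(dim(fw$out), c(1L, 14L), label = tag)
    g <- squeezevit:::squeezevit_bwd(
      m, squeezevit:::bce_grad(fw$out, y, 14), fw$cache)
    expect_setequal(names(g), names(m$params))
    nonzero <- vapply(g, function(z) any(z != 0), logical(1))
    expect_true(all(nonzero), label = paste(tag, "all parameters reached"))
  }
  expect_error(apply_ablation(squeezevit_config(), "bogus"), "valid tags")
})

test_that("disabling the translution stage removes its parameters and passes 128 channels through", {
  cfg <- apply_ablation(squeezevit_config(), "no_translution")
  m <- build_squeezevit(cfg)
  expect_false(any(startsWith(names(m$params), "stage2.")))
  expect_lt(count_parameters(m), count_parameters(build_squeezevit()))
  expect_equal(dim(predict(m, tiny_images(1))), c(1L, 14L))
})

test_that("inconsistent channel chains are rejected at configuration time", {
  expect_error(
    squeezevit_config(stage1_plan = c(3L, 32L, 64L),
                      stage2 = translution_config(128L)),
    "junction")
})

test_that("checkpoints round-trip through disk", {
  m <- build_squeezevit(squeezevit_config(seed = 5L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_equal(m2$config$seed, 5L)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "not a squeezevit checkpoint")
})

test_that("network configs round-trip through YAML", {
  cfg <- squeezevit_config(num_labels = 5L, seed = 17L)
  path <- tempfile(fileext = ".yaml")
  write_network_config(cfg, path)
  cfg2 <- read_network_config(path)
  expect_equal(cfg2$num_labels, 5L)
  expect_equal(cfg2$stage1$channel_plan, cfg$stage1$channel_plan)
  expect_equal(cfg2$seed, 17L)
  m1 <- build_squeezevit(cfg); m2 <- build_squeezevit(cfg2)
  expect_identical(m1$params, m2$params)

  cfg3 <- apply_ablation(cfg, "no_translution")
  write_network_config(cfg3, path)
  expect_null(read_network_config(path)$stage2)
})
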