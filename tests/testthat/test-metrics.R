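test_that("auroc matches its closed-form examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)   # all ties
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "undefined")
  expect_error(auroc(1:4, c(0, 0, 0, 0)), "undefined")
  expect_error(auroc(1:3, c(1, 0)), "length")
})

test_that("midrank auroc equals exhaustive pairwise counting on random draws", {
  with_seed(20, {
    for (rep in 1:100) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- sample(round(rnorm(n), 1))        # coarse grid forces ties
      expect_identical(auroc(scores, labels), auroc_pairwise(scores, labels))
    }
  })
})

test_that("auroc is invariant under strictly increasing transforms", {
  with_seed(21, {
    scores <- rnorm(50)
    labels <- c(0, 1, rbinom(48, 1, 0.4))
    a <- auroc(scores, labels)
    expect_equal(auroc(exp(scores), labels), a)
    expect_equal(auroc(qlogis(plogis(scores)), labels), a)
    expect_equal(auroc(3 * scores + 7, labels), a)
  })
})

test_that("classwise_auroc averages defined classes and is permutation invariant", {
  with_seed(22, {
    n <- 40
    s <- matrix(rnorm(n * 3), n, 3)
    s[, 3] <- s[, 1]
    y <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), 0)
    y[1:2, ] <- rbind(c(1, 1, 0), c(0, 0, 0))
    y[, 3] <- y[, 1]                               # duplicate class
    ev <- classwise_auroc(s, y, class_names = c("a", "b", "dup_a"))
    expect_equal(ev$per_class$auroc[3], ev$per_class$auroc[1])
    expect_equal(ev$average, mean(ev$per_class$auroc))
    perm <- sample(n)
    ev2 <- classwise_auroc(s[perm, ], y[perm, ],
                           class_names = c("a", "b", "dup_a"))
    expect_equal(ev2$per_class$auroc, ev$per_class$auroc)
  })
})

test_that("undefined classes are skipped with a warning; all-undefined errors", {
  s <- matrix(rnorm(20), 10, 2)
  y <- cbind(c(1, 0, rbinom(8, 1, 0.5)), 1)       # class 2 has no negatives
  expect_warning(ev <- classwise_auroc(s, y), "skipped")
  expect_true(is.na(ev$per_class$auroc[2]))
  expect_error(suppressWarnings(classwise_auroc(s, cbind(1, 1)[rep(1, 10), ])),
               "no class")
})

test_that("macro F1 follows the confusion-matrix arithmetic", {
  y <- cbind(c(1, 1, 0, 0))
  expect_equal(f1_average(cbind(c(0.9, 0.8, 0.1, 0.2)), y), 1.0)
  expect_equal(f1_average(cbind(c(0.1, 0.2, 0.1, 0.2)), y), 0)  # no predictions
  # TP=1, FP=1, FN=1 -> F1 = 0.5
  expect_equal(f1_average(cbind(c(0.9, 0.1, 0.9, 0.1)), cbind(c(1, 1, 0, 0))),
               0.5)
  # class with zero true and zero predicted positives contributes 0
  expect_equal(f1_average(cbind(c(0.9, 0.1), c(0.1, 0.2)),
                          cbind(c(1, 0), c(0, 0))), 0.5)
})

test_that("bce_loss matches hand arithmetic and is numerically safe", {
  expect_equal(bce_loss(matrix(0), matrix(1)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(matrix(20), matrix(1)), 1e-8)
  lg <- matrix(c(0, -1, 1, 2), 2, 2)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  ref <- -mean(y * log(plogis(lg)) + (1 - y) * log(1 - plogis(lg)))
  expect_equal(bce_loss(lg, y), ref, tolerance = 1e-12)
  expect_true(is.finite(bce_loss(matrix(c(1e4, -1e4), 1, 2),
                                 matrix(c(0, 1), 1, 2))))
  expect_error(bce_loss(matrix(0, 2, 3), matrix(0, 2, 2)), "conformable")
})

test_that("bootstrap CI is seed-deterministic and degenerate cases concentrate", {
  with_seed(23, {
    scores <- c(rnorm(60, 3), rnorm(60, 0))
    labels <- rep(c(1, 0), each = 60)
  })
  ci1 <- bootstrap_ci(scores, labels, B = 400, seed = 9)
  ci2 <- bootstrap_ci(scores, labels, B = 400, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2] + 1e-12)
  expect_true(attr(ci1, "point") >= ci1[1] && attr(ci1, "point") <= ci1[2])

  sep <- c(rep(1, 100), rep(0, 100))
  ci <- bootstrap_ci(seq(2, 0.01, length.out = 200), sep, B = 300, seed = 1)
  expect_gte(ci[1], 0.99)
  expect_lte(ci[2], 1.0)
  expect_warning(bootstrap_ci(scores, labels, B = 50, seed = 1), "unstable")
})
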