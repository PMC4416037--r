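# random multi-class problems used by several property loops
random_problem <- function(seed, n = 20, p = 15, K = 3) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p),
       labels = rep(paste0("c", seq_len(K)), length.out = n))
}

test_that("with the sparsity constraint inactive the fit equals dense PLS2", {
  for (seed in c(42, 43, 44)) {
    prb <- random_problem(seed)
    y <- dummy_code(prb$labels)
    fit <- spls_da(prb$x, prb$labels, ncomp = 3, keepx = ncol(prb$x))
    ora <- oracle_pls2(prb$x, unclass(y)[, , drop = FALSE], 3)
    expect_lt(max(abs(fit$coefficients - ora$B)), 1e-8)
    expect_lt(max_signfree_diff(fit$W, ora$W), 1e-8)
    expect_lt(max_signfree_diff(fit$scores, ora$T), 1e-8)
  }
})

test_that("dense fits agree with the mixOmics PLS2 reference", {
  skip_if_not_installed("mixOmics")
  prb <- random_problem(7)
  y <- unclass(dummy_code(prb$labels))[, , drop = FALSE]
  fit <- spls_da(prb$x, prb$labels, ncomp = 3)
  mo <- mixOmics::pls(prb$x, y, ncomp = 3, mode = "regression", scale = FALSE)
  expect_lt(max_signfree_diff(fit$W, as.matrix(mo$loadings$X)), 1e-8)
  expect_lt(max_signfree_diff(fit$scores, as.matrix(mo$variates$X)), 1e-8)
})

test_that("the kept set is the maximal-covariance subset on planted signal", {
  set.seed(7)
  n <- 12; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b"), each = 6)
  x[labels == "b", 1:3] <- x[labels == "b", 1:3] + 5
  fit <- spls_da(x, labels, ncomp = 1, keepx = 3)
  expect_equal(unname(fit$kept[[1]]), 1:3)
  # brute force: the 3-subset maximising the restricted cross-covariance norm
  xc <- scale(x, scale = FALSE)
  yc <- scale(unclass(dummy_code(labels)), scale = FALSE)
  M <- crossprod(xc, yc)
  subs <- utils::combn(p, 3)
  vals <- apply(subs, 2, function(s) svd(M[s, , drop = FALSE])$d[1])
  expect_equal(sort(subs[, which.max(vals)]), 1:3)
})

test_that("degenerate fitting arguments are rejected", {
  prb <- random_problem(1)
  expect_error(spls_da(prb$x, prb$labels, ncomp = 0), "positive integer")
  expect_error(spls_da(prb$x, prb$labels, ncomp = 2, keepx = 0), "positive integer")
  expect_error(spls_da(prb$x[1:2, ], prb$labels[1:2], ncomp = 1), "3 samples")
  expect_error(spls_da(prb$x, prb$labels, ncomp = 18, strict = TRUE), "strict")
})

test_that("VIP satisfies the mean-square identity and the H=1 closed form", {
  for (seed in 1:4) {
    prb <- random_problem(seed, n = 15, p = 25, K = 3)
    for (keepx in c(5, 25)) {
      fit <- spls_da(prb$x, prb$labels, ncomp = 2, keepx = keepx)
      v <- vip(fit)
      expect_equal(mean(v^2), 1, tolerance = 1e-8)
      expect_true(all(v >= 0))
      v1 <- vip(fit, ncomp = 1)
      expect_equal(as.numeric(v1), sqrt(nrow(fit$W)) * abs(unname(fit$W[, 1])),
                   tolerance = 1e-10)
      # features outside every kept set have VIP exactly 0
      outside <- setdiff(seq_len(25), unique(unlist(fit$kept)))
      expect_true(all(v[outside] == 0))
    }
  }
})

test_that("the nonzero-VIP feature count is bounded by ncomp * keepx", {
  for (seed in 5:8) {
    prb <- random_problem(seed, n = 18, p = 40, K = 3)
    fit <- spls_da(prb$x, prb$labels, ncomp = 3, keepx = 4)
    expect_lte(sum(vip(fit) > 0), 3 * 4)
  }
})

test_that("permuting feature columns permutes weights, coefficients and VIP", {
  prb <- random_problem(9, n = 16, p = 20, K = 3)
  set.seed(1); perm <- sample(20)
  f1 <- spls_da(prb$x, prb$labels, ncomp = 2, keepx = 6)
  f2 <- spls_da(prb$x[, perm], prb$labels, ncomp = 2, keepx = 6)
  expect_equal(unname(f2$W), unname(f1$W[perm, ]), tolerance = 1e-10)
  expect_equal(unname(f2$coefficients), unname(f1$coefficients[perm, ]),
               tolerance = 1e-10)
  expect_equal(as.numeric(vip(f2)), as.numeric(vip(f1)[perm]), tolerance = 1e-10)
})

test_that("score vectors are mutually orthogonal", {
  for (seed in 11:13) {
    prb <- random_problem(seed, n = 20, p = 30, K = 4)
    fit <- spls_da(prb$x, prb$labels, ncomp = 4, keepx = 7)
    G <- crossprod(fit$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-6 * max(diag(G)))
  }
})

test_that("prediction reproduces training labels on separable data", {
  set.seed(3)
  n <- 15; p <- 12
  labels <- rep(c("a", "b", "c"), each = 5)
  x <- matrix(rnorm(n * p), n, p)
  x[labels == "b", 1:2] <- x[labels == "b", 1:2] + 8
  x[labels == "c", 3:4] <- x[labels == "c", 3:4] + 8
  fit <- spls_da(x, labels, ncomp = 3)
  expect_equal(as.character(predict(fit, x, type = "class")), labels)
  # duplicated query rows give identical prediction rows
  yr <- predict(fit, x[rep(1, 4), , drop = FALSE])
  expect_equal(unname(yr), unname(yr[rep(1, 4), ]))
  expect_error(predict(fit, x[, 1:5]), "columns")
})

test_that("predicted response columns follow the first-appearance class order", {
  labs <- rep(paste0("T", 5:1), each = 4)
  set.seed(2)
  x <- matrix(rnorm(20 * 10), 20, 10)
  fit <- spls_da(x, labs, ncomp = 2, keepx = 5)
  pr <- predict(fit, x)
  expect_equal(colnames(pr), paste0("T", 5:1))
  expect_equal(ncol(pr), 5)
})

test_that("explained response variance is monotone, bounded, and exact on
           perfectly predictable responses", {
  # X carries the dummy response itself: all Y variance is capturable
  labels <- rep(c("a", "b"), each = 5)
  x <- cbind(unclass(dummy_code(labels)), 0.01 * matrix(rnorm(20), 10, 2))
  fit <- spls_da(x, labels, ncomp = 2)
  ev <- explained_y_variance(fit)
  expect_equal(ev$cumulative[length(ev$cumulative)], 1, tolerance = 1e-8)
  for (seed in 14:16) {
    prb <- random_problem(seed)
    fit <- spls_da(prb$x, prb$labels, ncomp = 4, keepx = 6)
    ev <- explained_y_variance(fit)$cumulative
    expect_true(all(diff(ev) >= -1e-12))
    expect_true(all(ev >= 0 & ev <= 1 + 1e-12))
  }
})

test_that("model JSON serialization supports exact re-prediction", {
  prb <- random_problem(20)
  fit <- spls_da(prb$x, prb$labels, ncomp = 2, keepx = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_spls_model(fit, f)
  back <- read_spls_model(f)
  expect_equal(predict(back, prb$x), predict(fit, prb$x), tolerance = 1e-12)
  expect_equal(as.numeric(vip(back)), as.numeric(vip(fit)), tolerance = 1e-12)
})
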