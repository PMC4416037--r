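test_that("msep matches its closed forms and a brute-force recomputation", {
  y <- unclass(dummy_code(rep(paste0("c", 1:5), 2)))
  expect_equal(msep(y, y), 0)
  expect_equal(msep(matrix(0, 10, 5), y), 0.2)
  set.seed(31)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  brute <- 0
  for (i in 1:4) for (j in 1:3) brute <- brute + (a[i, j] - b[i, j])^2
  expect_equal(msep(a, b), brute / 12)
  expect_error(msep(a, b[1:3, ]), "mismatch")
})

test_that("outer VIP filtering yields masks of the expected size", {
  pl <- planted_table(seed = 4, classes = c(4, 4, 4), n_features = 30)
  filt <- outer_vip_filter(pl$table, nkeep = c(1, 30), ncomp = c(1, 2))
  expect_s3_class(filt, "spls_cv_filter")
  expect_length(filt$masks, 12)  # one per outer fold
  for (i in seq_along(filt$masks)) {
    # nkeep = 1, ncomp = 1: exactly one kept feature
    expect_length(filt$masks[[i]][[1]][[1]], 1)
    # nkeep = 1, ncomp = 2: at most two features
    expect_lte(length(filt$masks[[i]][[1]][[2]]), 2)
    # nkeep = p: mask equals the nonzero-VIP set, at most p features
    expect_lte(length(filt$masks[[i]][[2]][[2]]), 30)
    fit <- spls_da(pl$table$values[-i, ], pl$table$class_labels[-i],
                   ncomp = 2, keepx = 30)
    expect_equal(filt$masks[[i]][[2]][[2]], unname(which(vip(fit) > 0)))
  }
  expect_error(check_grid_error <- outer_vip_filter(pl$table, nkeep = c(3, 2), ncomp = 1),
               "increasing")
})

test_that("informative features dominate the outer masks on planted signal", {
  wins <- vapply(seq_len(50), function(s) {
    sim <- simulate_feature_table(synthetic_spec(
      n_classes = 5, samples_per_class = rep(5, 5), n_features = 200,
      n_informative = 10, effect_size = 2.5, seed = 400 + s))
    tab <- log_center_scale(sim$table)
    filt <- outer_vip_filter(tab, nkeep = 10, ncomp = c(1, 2))
    freq <- rowMeans(vapply(filt$masks, function(m)
      seq_len(200) %in% m[[1]][[2]], logical(200)))
    mean(freq[1:10]) > mean(freq[-(1:10)])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("inner tuning is deterministic and beats the intercept baseline on
           well-separated classes", {
  pl <- planted_table(seed = 12, classes = c(5, 5), n_features = 40,
                      n_informative = 6, effect = 4)
  y <- dummy_code(pl$table$class_labels)
  filt <- outer_vip_filter(pl$table, nkeep = c(2, 6), ncomp = c(1, 2))
  i <- 1
  tune <- inner_tune_ncomp(pl$table$values[-i, ], unclass(y)[-i, , drop = FALSE],
                           filt$masks[[i]], nkeep = c(2, 6), ncomp = c(1, 2))
  tune2 <- inner_tune_ncomp(pl$table$values[-i, ], unclass(y)[-i, , drop = FALSE],
                            filt$masks[[i]], nkeep = c(2, 6), ncomp = c(1, 2))
  expect_identical(tune, tune2)
  baseline <- oracle_baseline_msep(pl$table$class_labels[-i])
  expect_lt(min(tune$inner_msep), baseline)
  # a single candidate component count is trivially optimal
  tune1 <- inner_tune_ncomp(pl$table$values[-i, ], unclass(y)[-i, , drop = FALSE],
                            lapply(filt$masks[[i]], `[`, 1), nkeep = c(2, 6),
                            ncomp = 1)
  expect_equal(unname(tune1$optimal_ncomp), c(1L, 1L))
})

test_that("a 1x1 grid reduces the outer-test MSEP to a plain LOOCV error", {
  pl <- planted_table(seed = 5, classes = c(4, 4, 4), n_features = 25,
                      n_informative = 4)
  filt <- outer_vip_filter(pl$table, nkeep = 5, ncomp = 2)
  res <- outer_test_msep(pl$table, filt)
  expect_equal(dim(res$outer_msep), c(1L, 1L))
  # independent recomputation through the R-level fit/predict interface
  v <- pl$table$values
  y <- unclass(dummy_code(pl$table$class_labels))
  acc <- 0
  for (i in seq_len(nrow(v))) {
    mask <- filt$masks[[i]][[1]][[1]]
    fit <- spls_da(v[-i, mask, drop = FALSE], pl$table$class_labels[-i],
                   ncomp = 2, keepx = 5)
    acc <- acc + sum((predict(fit, v[i, mask, drop = FALSE]) - y[i, ])^2)
  }
  expect_equal(res$outer_msep[1, 1], acc / (nrow(v) * ncol(y)), tolerance = 1e-12)
})

test_that("on pure noise the outer-test MSEP tracks the class-proportion baseline", {
  ratios <- vapply(seq_len(50), function(s) {
    sim <- simulate_feature_table(synthetic_spec(
      n_classes = 3, samples_per_class = c(5, 5, 5), n_features = 30,
      n_informative = 0, seed = 600 + s))
    tab <- log_center_scale(sim$table)
    filt <- outer_vip_filter(tab, nkeep = 5, ncomp = 1)
    res <- outer_test_msep(tab, filt)
    res$outer_msep[1, 1] / oracle_baseline_msep(tab$class_labels)
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.2)
})

test_that("rank smoothing matches a direct double-loop convolution", {
  set.seed(55)
  m <- matrix(runif(20), 5, 4)
  rs <- rank_and_smooth(m)
  expect_equal(sort(as.numeric(rs$rank_matrix)), 1:20)  # tie-free permutation
  expect_equal(unname(rs$smoothed), oracle_smooth(rs$rank_matrix))
  # smoothing is bounded by the rank range
  expect_gte(min(rs$smoothed), min(rs$rank_matrix))
  expect_lte(max(rs$smoothed), max(rs$rank_matrix))
  # constant matrices are fixed points; 1x1 matrices are their own score
  cm <- matrix(3, 4, 3)
  rc <- rank_and_smooth(cm)
  expect_true(all(rc$smoothed == rc$rank_matrix[1, 1]))
  r1 <- rank_and_smooth(matrix(0.42))
  expect_equal(unname(r1$smoothed[1, 1]), unname(r1$rank_matrix[1, 1]))
})

test_that("non-finite grid cells are excluded from ranks and normalisation", {
  m <- matrix(c(0.3, 0.1, Inf, 0.2, 0.5, 0.4), 3, 2)
  rs <- rank_and_smooth(m)
  expect_equal(rs$rank_matrix[3, 1], 6)  # N + 1 with N = 5 finite cells
  expect_true(is.infinite(rs$smoothed[3, 1]))
  # neighbours of the infinite cell renormalise over finite support only
  expect_equal(rs$smoothed[2, 1],
               (1 * rs$rank_matrix[1, 1] + 2 * rs$rank_matrix[2, 1] +
                1 * rs$rank_matrix[2, 2]) / 4)
  expect_error(rank_and_smooth(matrix(Inf, 2, 2)), "non-finite")
})

test_that("the optimum is the smoothed argmin with a parsimony tie-break", {
  s <- matrix(10, 6, 4, dimnames = list(1:6, 1:4))
  s[3, 2] <- 1
  opt <- select_optimal(s)
  expect_equal(c(opt$nkeep, opt$ncomp), c(3L, 2L))
  # equal minima at (nkeep 5, ncomp 2) and (nkeep 3, ncomp 4): smaller ncomp wins
  s2 <- matrix(10, 6, 4, dimnames = list(1:6, 1:4))
  s2[5, 2] <- 1; s2[3, 4] <- 1
  opt2 <- select_optimal(s2)
  expect_equal(c(opt2$nkeep, opt2$ncomp), c(5L, 2L))
  expect_true(attr(opt2, "tied"))
})

test_that("relevance aggregation filters and sorts by mean VIP", {
  pl <- planted_table(seed = 6, classes = c(4, 4, 4), n_features = 40,
                      n_informative = 5, effect = 3)
  rel <- aggregate_relevance(pl$table, nkeep = 5, ncomp = 2)
  expect_true(all(rel$mean_vip >= 1))
  expect_true(all(diff(rel$mean_vip) <= 0))
  vips <- attr(rel, "vip_folds")
  expect_equal(dim(vips), c(12L, 40L))
  for (k in seq_len(nrow(rel))) {
    f <- rel$feature[k]
    expect_equal(rel$mean_vip[k], mean(vips[, f]))
    expect_equal(rel$occurrence[k], sum(vips[, f] >= 1))
  }
  # an unreachable threshold empties the table
  expect_equal(nrow(aggregate_relevance(pl$table, 5, 2, threshold = 1e6)), 0L)
  # strict comparison excludes boundary features
  rel_strict <- aggregate_relevance(pl$table, 5, 2, comparison = ">")
  expect_true(all(rel_strict$mean_vip > 1))
})

test_that("the full nested procedure is deterministic and structurally sound", {
  pl <- planted_table(seed = 9, classes = c(4, 4, 4), n_features = 30,
                      n_informative = 4, effect = 3)
  sel <- nested_select(pl$table, nkeep = c(2, 4, 6), ncomp = 1:2)
  sel2 <- nested_select(pl$table, nkeep = c(2, 4, 6), ncomp = 1:2)
  expect_identical(sel[names(sel) != "final_model"],
                   sel2[names(sel2) != "final_model"])
  # every sample is an outer test exactly once
  expect_equal(sel$filter$fold_ids, pl$table$sample_ids)
  expect_equal(sel$n_samples, 12)
  expect_equal(dim(sel$outer_msep), c(3L, 2L))
  expect_true(all(sel$outer_msep >= 0))
  expect_equal(dim(sel$inner_optimal_ncomp), c(12L, 3L))
  # the selected cell attains the smoothed minimum
  expect_equal(sel$smoothed[sel$optimal_nkeep == c(2, 4, 6),
                            sel$optimal_ncomp],
               min(sel$smoothed))
  # planted features are recovered as relevant
  expect_gte(sum(pl$truth$informative_features %in% sel$relevance$feature), 3)
})

test_that("label permutation abolishes the apparent predictive signal", {
  sim <- simulate_feature_table(synthetic_spec(
    n_classes = 3, samples_per_class = c(4, 4, 4), n_features = 25,
    n_informative = 0, seed = 5))
  tab <- log_center_scale(sim$table)
  baseline <- oracle_baseline_msep(tab$class_labels)
  set.seed(77)
  ratios <- vapply(seq_len(20), function(i) {
    t2 <- tab
    t2$class_labels <- sample(t2$class_labels)
    nested_select(t2, nkeep = c(2, 4, 6, 8), ncomp = 1:2)$msep_optimal / baseline
  }, numeric(1))
  # selection optimism at this problem size stays within Monte-Carlo slack
  expect_gte(mean(ratios), 0.75)
  expect_lt(mean(ratios), 1.3)
})
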