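# Independent oracles used to check the package's computations.
# These deliberately take different routes than the implementation:
# an iterative textbook NIPALS for dense PLS2, direct double-loop
# convolution, and exhaustive permutation enumeration for the rank tests.

# Dense PLS2, regression mode, classic alternating NIPALS iteration.
oracle_pls2 <- function(X, Y, ncomp, max_iter = 5000, tol = 1e-30) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  n <- nrow(Xc); p <- ncol(Xc); K <- ncol(Yc)
  W <- matrix(0, p, ncomp); T <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); C <- matrix(0, K, ncomp)
  for (h in seq_len(ncomp)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u <- drop(Yc %*% cc) / sum(cc^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pl <- drop(crossprod(Xc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, cc)
    W[, h] <- w; T[, h] <- tt; P[, h] <- pl; C[, h] <- cc
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  list(W = W, T = T, P = P, C = C, B = B)
}

# match matrix columns up to per-column sign
max_signfree_diff <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  max(vapply(seq_len(ncol(A)), function(j)
    min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j]))), numeric(1)))
}

# direct double-loop 3x3 rank smoothing (all-finite input)
oracle_smooth <- function(r) {
  kern <- rbind(c(0, 1, 0), c(1, 2, 1), c(0, 1, 0))
  nr <- nrow(r); nc <- ncol(r)
  s <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && kern[di + 2, dj + 2] > 0) {
        num <- num + kern[di + 2, dj + 2] * r[ii, jj]
        den <- den + kern[di + 2, dj + 2]
      }
    }
    s[i, j] <- num / den
  }
  s
}

# exhaustive two-sided rank-sum p-value (enumeration of group-1 positions)
oracle_wilcox_p <- function(x, y) {
  vals <- c(x, y)
  r <- rank(vals)
  nx <- length(x)
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(length(vals), nx)
  Ws <- apply(sets, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  p_le <- mean(Ws <= W_obs + 1e-12)
  p_ge <- mean(Ws >= W_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive Kruskal-Wallis permutation p-value; the statistic per
# arrangement comes from stats::kruskal.test, an independent route
oracle_kw_p <- function(values, labels) {
  labels <- as.character(labels)
  H_obs <- unname(stats::kruskal.test(values, factor(labels))$statistic)
  classes <- unique(labels)
  sizes <- as.integer(table(factor(labels, levels = classes)))
  n <- length(values)
  stats_all <- c()
  recurse <- function(avail, gi, assign_list) {
    if (gi == length(classes)) {
      g <- character(n)
      for (k in seq_along(assign_list)) g[assign_list[[k]]] <- classes[k]
      g[avail] <- classes[length(classes)]
      stats_all <<- c(stats_all,
                      unname(stats::kruskal.test(values, factor(g))$statistic))
      return(invisible())
    }
    for (cmb in utils::combn(avail, sizes[gi], simplify = FALSE))
      recurse(setdiff(avail, cmb), gi + 1L, c(assign_list, list(cmb)))
  }
  recurse(seq_len(n), 1L, list())
  mean(stats_all >= H_obs - 1e-12)
}

# leave-one-out MSEP of the intercept-only (class-proportion) predictor
oracle_baseline_msep <- function(labels) {
  y <- unclass(splsnest::dummy_code(labels))
  n <- nrow(y)
  acc <- 0
  for (i in seq_len(n)) {
    yhat <- colMeans(y[-i, , drop = FALSE])
    acc <- acc + sum((yhat - y[i, ])^2)
  }
  acc / (n * ncol(y))
}

# small planted-signal scaled table for reuse across tests
planted_table <- function(seed = 1, n_features = 60, n_informative = 5,
                          effect = 3, classes = c(4, 4, 4)) {
  sim <- splsnest::simulate_feature_table(splsnest::synthetic_spec(
    n_classes = length(classes), samples_per_class = classes,
    n_features = n_features, n_informative = n_informative,
    effect_size = effect, seed = seed))
  list(table = splsnest::log_center_scale(sim$table), truth = sim$truth)
}
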