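#' Mean squared error of prediction
#'
#' Mean over all m x K entries of the squared differences between a
#' predicted and a true dummy-response matrix.
#'
#' @param y_pred predicted response matrix.
#' @param y_true true dummy matrix of the same shape.
#' @return Nonnegative scalar.
#' @export
msep <- function(y_pred, y_true) {
  y_pred <- as.matrix(y_pred)
  y_true <- as.matrix(unclass(y_true))
  if (!all(dim(y_pred) == dim(y_true)))
    stop("shape mismatch: ", paste(dim(y_pred), collapse = "x"), " vs ",
         paste(dim(y_true), collapse = "x"))
  mean((y_pred - y_true)^2)
}

# validate and normalise a tuning grid
check_grid <- function(nkeep, ncomp) {
  nkeep <- as.integer(nkeep); ncomp <- as.integer(ncomp)
  if (!length(nkeep) || !length(ncomp))
    stop("empty tuning grid")
  if (any(diff(nkeep) <= 0) || any(diff(ncomp) <= 0))
    stop("grid values must be strictly increasing")
  if (any(nkeep < 1) || any(ncomp < 1))
    stop("grid values must be positive")
  list(nkeep = nkeep, ncomp = ncomp)
}

#' Outer-fold VIP filtering (step 1 of the nested cross-validation)
#'
#' For every outer leave-one-out fold and every cell of the
#' (nkeep x ncomp) grid, fits an sPLS-DA on the outer training set and
#' records which features carry a nonzero VIP coefficient.  Only those
#' features enter the inner cross-validation of that fold/cell.
#'
#' Within a fold, fits at a given `nkeep` are nested across component
#' counts, so a single fit at `max(ncomp)` provides the masks for every
#' `ncomp` value.  Cells whose component count is unreachable on the fold
#' (rank deficiency) reuse the deepest achievable model and are flagged.
#'
#' @param table a scaled [feature_table()].
#' @param nkeep,ncomp increasing integer vectors of grid values.
#' @param tol early-stop tolerance passed to [spls_da()].
#' @return An object of class `spls_cv_filter`: per-fold, per-cell masks of
#'   selected feature indices, achieved component counts, and the grid.
#' @export
outer_vip_filter <- function(table, nkeep = 1:20, ncomp = 1:4, tol = 1e-9) {
  stopifnot(inherits(table, "feature_table"))
  g <- check_grid(nkeep, ncomp)
  v <- table$values
  n <- nrow(v)
  if (n < 4) stop("at least 4 samples are required for the nested procedure")
  y <- dummy_code(table$class_labels)
  hmax <- max(g$ncomp)
  masks <- vector("list", n)
  achieved <- matrix(NA_integer_, n, length(g$nkeep))
  for (i in seq_len(n)) {
    xi <- v[-i, , drop = FALSE]
    yi <- unclass(y)[-i, , drop = FALSE]
    per_k <- vector("list", length(g$nkeep))
    for (ki in seq_along(g$nkeep)) {
      fit <- cpp_spls_fit(xi, yi, hmax, g$nkeep[ki], tol)
      ha <- fit$ncomp_used
      achieved[i, ki] <- ha
      per_h <- vector("list", length(g$ncomp))
      for (hi in seq_along(g$ncomp)) {
        he <- min(g$ncomp[hi], ha)
        per_h[[hi]] <- if (he > 0)
          which(rowSums(abs(fit$W[, seq_len(he), drop = FALSE])) > 0)
        else integer(0)
      }
      per_k[[ki]] <- per_h
    }
    masks[[i]] <- per_k
  }
  out <- list(fold_ids = table$sample_ids,
              masks = masks,
              achieved = achieved,
              nkeep = g$nkeep,
              ncomp = g$ncomp)
  class(out) <- "spls_cv_filter"
  out
}

#' Inner component tuning (step 2 of the nested cross-validation)
#'
#' Within one outer training set, runs a second leave-one-out
#' cross-validation for every grid cell, restricted to the features the
#' outer filter selected for that fold and cell, and records the mean
#' squared error of prediction.  For each `nkeep` the optimal component
#' count is the MSEP argmin (ties resolved toward fewer components).
#'
#' @param x,y outer-training data matrix and dummy response.
#' @param masks per-cell feature masks for this fold, as produced by
#'   [outer_vip_filter()] (`filter$masks[[fold]]`).
#' @param nkeep,ncomp the grid.
#' @param tol early-stop tolerance.
#' @return List with `inner_msep` (nkeep x ncomp matrix; `Inf` for empty
#'   masks) and `optimal_ncomp` (per nkeep).
#' @export
inner_tune_ncomp <- function(x, y, masks, nkeep, ncomp, tol = 1e-9) {
  g <- check_grid(nkeep, ncomp)
  y <- unclass(y)
  m <- matrix(Inf, length(g$nkeep), length(g$ncomp),
              dimnames = list(g$nkeep, g$ncomp))
  for (ki in seq_along(g$nkeep)) {
    for (hi in seq_along(g$ncomp)) {
      mask <- masks[[ki]][[hi]]
      if (!length(mask)) next
      m[ki, hi] <- cpp_loocv_msep(x[, mask, drop = FALSE], y,
                                  g$ncomp[hi], g$nkeep[ki], tol)
    }
  }
  opt <- apply(m, 1, which.min)  # which.min takes the first (smallest ncomp) tie
  list(inner_msep = m, optimal_ncomp = g$ncomp[opt])
}

#' Outer-test MSEP grid (step 3 of the nested cross-validation)
#'
#' For every grid cell, refits each outer fold on its own selected
#' variables and predicts the held-out sample; the cell's MSEP pools the
#' squared errors over all folds.  Cells are computed at the cell's own
#' component count; disagreement with the fold's inner-optimal `ncomp` is
#' recorded as a diagnostic, not collapsed, because the rank smoothing
#' operates on the full (nkeep x ncomp) matrix.
#'
#' @param table the scaled [feature_table()] used for the outer folds.
#' @param filter an `spls_cv_filter` from [outer_vip_filter()].
#' @param tol early-stop tolerance.
#' @return List with `outer_msep` (nkeep x ncomp matrix) and `flagged`
#'   (counts of folds per cell where the requested depth was unreachable).
#' @export
outer_test_msep <- function(table, filter, tol = 1e-9) {
  stopifnot(inherits(table, "feature_table"), inherits(filter, "spls_cv_filter"))
  v <- table$values
  n <- nrow(v)
  y <- unclass(dummy_code(table$class_labels))
  nk <- filter$nkeep; nc <- filter$ncomp
  sq <- matrix(0, length(nk), length(nc), dimnames = list(nk, nc))
  flagged <- matrix(0L, length(nk), length(nc), dimnames = list(nk, nc))
  for (i in seq_len(n)) {
    xi <- v[-i, , drop = FALSE]
    yi <- y[-i, , drop = FALSE]
    for (ki in seq_along(nk)) {
      for (hi in seq_along(nc)) {
        mask <- filter$masks[[i]][[ki]][[hi]]
        if (!length(mask)) {
          sq[ki, hi] <- Inf
          next
        }
        fit <- cpp_spls_fit(xi[, mask, drop = FALSE], yi, nc[hi], nk[ki], tol)
        if (fit$ncomp_used < nc[hi]) flagged[ki, hi] <- flagged[ki, hi] + 1L
        yhat <- if (fit$ncomp_used > 0)
          (v[i, mask, drop = FALSE] - fit$x_center) %*% fit$B + fit$y_center
        else fit$y_center
        sq[ki, hi] <- sq[ki, hi] + sum((yhat - y[i, ])^2)
      }
    }
  }
  list(outer_msep = sq / (n * ncol(y)), flagged = flagged)
}

#' Rank an MSEP grid and smooth it with a 3x3 convolution kernel
#'
#' MSEP values are ranked ascending (1 = best; ties receive the average
#' rank) over the (nkeep x ncomp) matrix, then convolved with the kernel
#' rows (0,1,0), (1,2,1), (0,1,0).  At each position the kernel is
#' normalised by the sum of its in-bounds weights, so border cells use
#' fewer neighbours and a constant matrix is a fixed point.  Non-finite
#' cells (unreachable grid points) are excluded from the ranking — they
#' receive rank N+1, where N is the number of finite cells — and from
#' their neighbours' normalisation; their own smoothed score is `Inf`.
#'
#' @param outer_msep numeric matrix, rows nkeep, columns ncomp.
#' @return List with `rank_matrix` and `smoothed`.
#' @export
rank_and_smooth <- function(outer_msep) {
  m <- as.matrix(outer_msep)
  fin <- is.finite(m)
  if (!any(fin)) stop("all grid cells are non-finite; nothing to rank")
  N <- sum(fin)
  r <- m
  r[fin] <- rank(m[fin], ties.method = "average")
  r[!fin] <- N + 1
  kern <- rbind(c(0, 1, 0), c(1, 2, 1), c(0, 1, 0))
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(Inf, nr, nc, dimnames = dimnames(m))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!fin[i, j]) next
      num <- 0; den <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          w <- kern[di + 2, dj + 2]
          if (w == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          if (!fin[ii, jj]) next
          num <- num + w * r[ii, jj]
          den <- den + w
        }
      }
      s[i, j] <- num / den
    }
  }
  list(rank_matrix = r, smoothed = s)
}

#' Select the optimal grid cell from the smoothed rank scores
#'
#' The (nkeep, ncomp) combination with the lowest smoothed rank score is
#' taken as the optimal, robust parameter pair.  Exact ties are broken
#' toward the smaller `ncomp`, then the smaller `nkeep` (parsimony); a tie
#' is recorded in the `"tied"` attribute.
#'
#' @param smoothed matrix from [rank_and_smooth()], rows nkeep, columns
#'   ncomp; dimnames carry the grid values.
#' @param nkeep,ncomp optional grid values (default: parsed from dimnames).
#' @return List with `nkeep`, `ncomp`, `row`, `col`.
#' @export
select_optimal <- function(smoothed, nkeep = NULL, ncomp = NULL) {
  s <- as.matrix(smoothed)
  if (!any(is.finite(s))) stop("no finite smoothed score to minimise")
  if (is.null(nkeep)) nkeep <- as.integer(rownames(s))
  if (is.null(ncomp)) ncomp <- as.integer(colnames(s))
  best <- min(s[is.finite(s)])
  hits <- which(s == best, arr.ind = TRUE)
  # parsimony tie-break: smallest ncomp (column), then smallest nkeep (row)
  hits <- hits[order(hits[, "col"], hits[, "row"]), , drop = FALSE]
  out <- list(nkeep = nkeep[hits[1, "row"]], ncomp = ncomp[hits[1, "col"]],
              row = unname(hits[1, "row"]), col = unname(hits[1, "col"]))
  attr(out, "tied") <- nrow(hits) > 1
  out
}

#' Aggregate feature relevance across outer folds
#'
#' At the selected (nkeep, ncomp), refits every outer fold on the full
#' feature set and computes per-fold VIP coefficients.  A feature's
#' relevance is its mean VIP across the outer folds; its occurrence is the
#' number of folds in which its own VIP reaches the threshold.  Features
#' whose mean VIP reaches the threshold are reported, sorted by descending
#' mean VIP.
#'
#' @param table the scaled [feature_table()].
#' @param nkeep,ncomp the selected parameter pair.
#' @param threshold relevance threshold on the VIP scale (default 1).
#' @param comparison `">="` (default) or `">"` for the mean-VIP inclusion
#'   rule.
#' @param tol early-stop tolerance.
#' @return Data frame with columns `feature`, `technique`, `mean_vip`,
#'   `occurrence`; the full fold-by-feature VIP matrix is attached as
#'   attribute `"vip_folds"`.
#' @export
aggregate_relevance <- function(table, nkeep, ncomp, threshold = 1,
                                comparison = c(">=", ">"), tol = 1e-9) {
  stopifnot(inherits(table, "feature_table"))
  comparison <- match.arg(comparison)
  v <- table$values
  n <- nrow(v)
  y <- unclass(dummy_code(table$class_labels))
  p <- ncol(v)
  vips <- matrix(0, n, p, dimnames = list(table$sample_ids, colnames(v)))
  for (i in seq_len(n)) {
    fit <- cpp_spls_fit(v[-i, , drop = FALSE], y[-i, , drop = FALSE],
                        as.integer(ncomp), as.integer(nkeep), tol)
    h <- fit$ncomp_used
    if (h == 0) next
    W <- fit$W
    ssy <- as.numeric(fit$ssy)
    vips[i, ] <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  }
  mean_vip <- colMeans(vips)
  occurrence <- colSums(vips >= threshold)
  keep <- if (comparison == ">=") mean_vip >= threshold else mean_vip > threshold
  ord <- order(-mean_vip[keep])
  rel <- data.frame(feature = colnames(v)[keep][ord],
                    technique = table$feature_meta$technique[keep][ord],
                    mean_vip = unname(mean_vip[keep][ord]),
                    occurrence = unname(occurrence[keep][ord]),
                    stringsAsFactors = FALSE)
  attr(rel, "vip_folds") <- vips
  attr(rel, "threshold") <- threshold
  attr(rel, "comparison") <- comparison
  rel
}

#' Nested double leave-one-out model selection for sparse PLS-DA
#'
#' Runs the full three-step selection procedure on a scaled feature table:
#'
#' 1. *Outer VIP filter* — for each leave-one-out fold and each
#'    (nkeep, ncomp) cell, fit an sPLS-DA on the outer training set and
#'    keep the features with nonzero VIP ([outer_vip_filter()]).
#' 2. *Inner tuning* — inside each outer training set, a second
#'    leave-one-out cross-validation measures the MSEP of every cell on
#'    the filtered features and identifies the optimal component count
#'    per nkeep ([inner_tune_ncomp()]).
#' 3. *Outer test* — each cell is refitted per fold on its selected
#'    variables and the held-out sample predicted; the pooled MSEP grid is
#'    rank-transformed, smoothed with the 3x3 kernel, and the cell with
#'    the lowest smoothed rank score is selected
#'    ([outer_test_msep()], [rank_and_smooth()], [select_optimal()]).
#'
#' Relevant features are then aggregated by mean VIP across the outer
#' folds at the selected cell ([aggregate_relevance()]) and a final model
#' is refitted on all samples.  The procedure is fully deterministic:
#' leave-one-out folds are exhaustive and nothing is randomised.
#'
#' @param table a scaled [feature_table()].
#' @param nkeep,ncomp increasing integer vectors defining the tuning grid
#'   (the full-scale default is `1:100` and `1:10`; desk-scale analyses
#'   use smaller grids).
#' @param vip_threshold relevance threshold on the VIP scale.
#' @param vip_comparison `">="` (default) or `">"`.
#' @param tol early-stop tolerance.
#' @param verbose print fold progress.
#' @return An object of class `spls_nested`; see the elements documented
#'   in the individual step functions, plus `optimal_nkeep`,
#'   `optimal_ncomp`, `msep_optimal`, `relevance`, `final_model`,
#'   `explained_y`.
#' @examples
#' sim <- simulate_feature_table(synthetic_spec(
#'   samples_per_class = c(4, 4, 4), n_features = 30, n_informative = 4,
#'   effect_size = 3, seed = 7))
#' tab <- log_center_scale(sim$table)
#' sel <- nested_select(tab, nkeep = c(2, 4, 6, 8), ncomp = 1:2)
#' sel
#' @export
nested_select <- function(table, nkeep = 1:20, ncomp = 1:4,
                          vip_threshold = 1, vip_comparison = c(">=", ">"),
                          tol = 1e-9, verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  vip_comparison <- match.arg(vip_comparison)
  g <- check_grid(nkeep, ncomp)
  v <- table$values
  n <- nrow(v)
  y <- dummy_code(table$class_labels)

  if (verbose) message("step 1/3: outer VIP filter (", n, " folds)")
  filter <- outer_vip_filter(table, g$nkeep, g$ncomp, tol = tol)

  if (verbose) message("step 2/3: inner component tuning")
  inner_msep <- array(NA_real_, c(n, length(g$nkeep), length(g$ncomp)),
                      dimnames = list(table$sample_ids, g$nkeep, g$ncomp))
  inner_opt <- matrix(NA_integer_, n, length(g$nkeep),
                      dimnames = list(table$sample_ids, g$nkeep))
  for (i in seq_len(n)) {
    tune <- inner_tune_ncomp(v[-i, , drop = FALSE],
                             unclass(y)[-i, , drop = FALSE],
                             filter$masks[[i]], g$nkeep, g$ncomp, tol = tol)
    inner_msep[i, , ] <- tune$inner_msep
    inner_opt[i, ] <- tune$optimal_ncomp
    if (verbose && i %% 5 == 0) message("  fold ", i, "/", n)
  }

  if (verbose) message("step 3/3: outer-test MSEP grid")
  outer <- outer_test_msep(table, filter, tol = tol)
  rs <- rank_and_smooth(outer$outer_msep)
  opt <- select_optimal(rs$smoothed, g$nkeep, g$ncomp)

  relevance <- aggregate_relevance(table, opt$nkeep, opt$ncomp,
                                   threshold = vip_threshold,
                                   comparison = vip_comparison, tol = tol)
  final <- spls_da(v, y, ncomp = opt$ncomp, keepx = opt$nkeep, tol = tol)

  # folds whose inner-optimal ncomp disagrees with the selected cell
  contradictions <- sum(inner_opt[, opt$row] != opt$ncomp)

  out <- list(grid = g,
              filter = filter,
              inner_msep = inner_msep,
              inner_optimal_ncomp = inner_opt,
              outer_msep = outer$outer_msep,
              flagged = outer$flagged,
              rank_matrix = rs$rank_matrix,
              smoothed = rs$smoothed,
              optimal_nkeep = opt$nkeep,
              optimal_ncomp = opt$ncomp,
              optimal_tied = isTRUE(attr(opt, "tied")),
              msep_optimal = outer$outer_msep[opt$row, opt$col],
              inner_contradictions = contradictions,
              relevance = relevance,
              final_model = final,
              explained_y = explained_y_variance(final),
              class_order = attr(y, "class_order"),
              n_samples = n)
  class(out) <- "spls_nested"
  out
}

#' @export
print.spls_nested <- function(x, ...) {
  cat("Nested leave-one-out sPLS-DA model selection\n")
  cat("  grid: nkeep ", min(x$grid$nkeep), "..", max(x$grid$nkeep),
      " x ncomp ", min(x$grid$ncomp), "..", max(x$grid$ncomp),
      "  (", x$n_samples, " outer folds)\n", sep = "")
  cat("  selected: nkeep =", x$optimal_nkeep, ", ncomp =", x$optimal_ncomp,
      if (x$optimal_tied) "(tie, parsimony rule applied)" else "", "\n")
  cat(sprintf("  outer-test MSEP at the selected cell: %.4f\n", x$msep_optimal))
  ev <- x$explained_y$cumulative
  cat(sprintf("  Y variance explained by the final refit: %.1f%%\n",
              100 * ev[length(ev)]))
  cat("  relevant features (mean VIP", attr(x$relevance, "comparison"),
      attr(x$relevance, "threshold"), "):", nrow(x$relevance), "\n")
  invisible(x)
}

#' @export
summary.spls_nested <- function(object, n_top = 10, ...) {
  print(object)
  cat("\nTop relevant features:\n")
  print(utils::head(object$relevance, n_top), row.names = FALSE)
  cat("\nInner-optimal ncomp vs selected cell: ",
      object$inner_contradictions, " of ", object$n_samples,
      " folds disagree\n", sep = "")
  invisible(object)
}

#' Plot the smoothed rank-score surface
#'
#' Image of the smoothed rank scores over the (nkeep, ncomp) grid with the
#' selected cell marked.
#'
#' @param x an `spls_nested` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.spls_nested <- function(x, ...) {
  s <- x$smoothed
  s[!is.finite(s)] <- NA
  graphics::image(x = x$grid$nkeep, y = x$grid$ncomp, z = s,
                  xlab = "nkeep (variables kept)", ylab = "ncomp (components)",
                  main = "Smoothed MSEP rank score", ...)
  graphics::points(x$optimal_nkeep, x$optimal_ncomp, pch = 4, cex = 2, lwd = 2)
  invisible(x)
}
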