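#' Kruskal-Wallis test with an exact small-sample mode
#'
#' Rank-based H statistic with tie correction.  For small samples
#' (total n <= 10 by default) the p-value is computed exactly by
#' enumerating every assignment of the observations to the observed group
#' sizes; otherwise the usual chi-square reference with k - 1 degrees of
#' freedom is used via [stats::kruskal.test()].
#'
#' @param values numeric vector of observations.
#' @param labels group labels, at least two groups, each non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact enumeration;
#'   default `NULL` enables it when `length(values) <= 10`.
#' @return List with `statistic` (H), `p_value`, `method`.
#' @export
kw_test <- function(values, labels, exact = NULL) {
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop("length mismatch")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("at least two groups are required")
  if (any(sizes == 0)) stop("every group needs at least one observation")
  n <- length(values)
  if (is.null(exact)) exact <- n <= 10
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1,
                method = if (exact) "exact" else "chi-square"))
  H <- kw_statistic(values, labels)
  if (!exact) {
    kt <- stats::kruskal.test(values, factor(labels))
    return(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                method = "chi-square"))
  }
  perms <- group_assignments(labels)
  Hs <- vapply(perms, function(g) kw_statistic(values, g), numeric(1))
  list(statistic = H, p_value = mean(Hs >= H - 1e-12), method = "exact")
}

# tie-corrected Kruskal-Wallis H
kw_statistic <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  agg <- tapply(r, labels, function(x) length(x) * (mean(x) - (n + 1) / 2)^2)
  H <- 12 / (n * (n + 1)) * sum(agg)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

# every distinct assignment of positions to the multiset of group labels
group_assignments <- function(labels) {
  n <- length(labels)
  classes <- unique(labels)
  sizes <- as.integer(table(factor(labels, levels = classes)))
  out <- list()
  recurse <- function(avail, gi, acc) {
    if (gi == length(classes)) {
      g <- character(n)
      for (k in seq_along(acc)) g[acc[[k]]] <- classes[k]
      g[avail] <- classes[length(classes)]
      out[[length(out) + 1L]] <<- g
      return(invisible())
    }
    for (cmb in utils::combn(avail, sizes[gi], simplify = FALSE)) {
      recurse(setdiff(avail, cmb), gi + 1L, c(acc, list(cmb)))
    }
  }
  recurse(seq_len(n), 1L, list())
  out
}

#' Per-feature Kruskal-Wallis tests
#'
#' @param table a [feature_table()].
#' @param features optional character vector of feature names to test
#'   (default: all).
#' @param exact see [kw_test()].
#' @return Data frame with columns `feature`, `H`, `p`.
#' @export
feature_kruskal <- function(table, features = NULL, exact = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(features)) features <- colnames(table$values)
  res <- lapply(features, function(f)
    kw_test(table$values[, f], table$class_labels, exact = exact))
  data.frame(feature = features,
             H = vapply(res, `[[`, numeric(1), "statistic"),
             p = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Pairwise Wilcoxon-Mann-Whitney tests
#'
#' Two-sided rank-sum test for every unordered pair of classes.  The exact
#' distribution is used when the combined sample size of the pair is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie correction is used.  p-values are nominal: no multiple-testing
#' correction is applied here (a Benjamini-Hochberg column is emitted by
#' [feature_stats()] alongside, for reference only).
#'
#' @param values numeric vector of observations.
#' @param labels class labels.
#' @param exact force/forbid the exact branch; default `NULL` applies the
#'   combined-n <= 12, no-ties rule.
#' @return Data frame with columns `class1`, `class2`, `p`, `method`;
#'   pairs with fewer than 2 observations in a class are skipped (`NA`,
#'   method `"skipped"`).
#' @export
pairwise_wilcoxon <- function(values, labels, exact = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("at least two classes are required")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- values[labels == pr[1]]
    y <- values[labels == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(class1 = pr[1], class2 = pr[2], p = NA_real_,
                        method = "skipped", stringsAsFactors = FALSE))
    ties <- anyDuplicated(c(x, y)) > 0
    ex <- if (is.null(exact)) (length(x) + length(y) <= 12) && !ties else exact
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = ex, correct = TRUE)$p.value)
    data.frame(class1 = pr[1], class2 = pr[2], p = p,
               method = if (ex) "exact" else "normal+ties",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confirmatory univariate statistics for a set of features
#'
#' Kruskal-Wallis across all classes plus pairwise Wilcoxon-Mann-Whitney
#' tests per feature, with a Benjamini-Hochberg adjusted column computed
#' from the Kruskal-Wallis p-values for reference.  All reported p-values
#' are nominal, matching the confirmatory (not selective) role of the
#' tests.
#'
#' @param table a [feature_table()].
#' @param features optional feature names (default all).
#' @param alpha nominal significance level recorded in the output
#'   attributes.
#' @param exact see [kw_test()] / [pairwise_wilcoxon()].
#' @return Data frame: `feature`, `KW_H`, `KW_p`, one `WMW_<A>_vs_<B>`
#'   column per class pair, `BH_q`.
#' @export
feature_stats <- function(table, features = NULL, alpha = 0.05, exact = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(features)) features <- colnames(table$values)
  kw <- feature_kruskal(table, features, exact = exact)
  pw <- lapply(features, function(f)
    pairwise_wilcoxon(table$values[, f], table$class_labels, exact = exact))
  pair_names <- paste0("WMW_", pw[[1]]$class1, "_vs_", pw[[1]]$class2)
  pmat <- t(vapply(pw, function(d) d$p, numeric(nrow(pw[[1]]))))
  colnames(pmat) <- pair_names
  out <- data.frame(feature = kw$feature, KW_H = kw$H, KW_p = kw$p,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pmat))
  out$BH_q <- stats::p.adjust(out$KW_p, method = "BH")
  attr(out, "alpha") <- alpha
  attr(out, "p_values") <- "nominal (no multiplicity correction applied)"
  out
}

#' Two-way hierarchical clustering of samples and features
#'
#' Agglomerative clustering of the samples and of a feature subset using
#' Euclidean distance and Ward linkage, as used for abundance heatmaps.
#' Degenerate inputs (a single sample or single feature) return a trivial
#' ordering with a flag.
#'
#' @param table a [feature_table()].
#' @param features optional character vector of feature names (default
#'   all), typically the relevant features from [aggregate_relevance()].
#' @return Object of class `two_way_cluster`: `sample_order`,
#'   `feature_order`, `sample_hclust`, `feature_hclust`, `flags`.
#' @export
two_way_cluster <- function(table, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(v))
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    v <- v[, features, drop = FALSE]
  }
  flags <- character(0)
  if (nrow(v) < 2) {
    flags <- c(flags, "single sample: trivial sample order")
    sh <- NULL; so <- seq_len(nrow(v))
  } else {
    sh <- stats::hclust(stats::dist(v), method = "ward.D2")
    so <- sh$order
  }
  if (ncol(v) < 2) {
    flags <- c(flags, "single feature: trivial feature order")
    fh <- NULL; fo <- seq_len(ncol(v))
  } else {
    fh <- stats::hclust(stats::dist(t(v)), method = "ward.D2")
    fo <- fh$order
  }
  out <- list(sample_order = so, feature_order = fo,
              sample_hclust = sh, feature_hclust = fh,
              sample_ids = table$sample_ids, features = colnames(v),
              flags = flags)
  class(out) <- "two_way_cluster"
  out
}

#' @export
print.two_way_cluster <- function(x, ...) {
  cat("Two-way hierarchical clustering (Euclidean distance, Ward linkage)\n")
  cat("  samples:", length(x$sample_order),
      " features:", length(x$feature_order), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Heatmap of a clustered feature table
#'
#' Basic image of the abundance matrix with rows and columns permuted by
#' the two-way clustering.
#'
#' @param table a [feature_table()].
#' @param clustering a `two_way_cluster` for the same table/subset; computed
#'   if missing.
#' @param ... passed to [graphics::image()].
#' @export
relevance_heatmap <- function(table, clustering = NULL, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(clustering)) clustering <- two_way_cluster(table)
  v <- table$values[clustering$sample_order,
                    clustering$features[clustering$feature_order], drop = FALSE]
  graphics::image(z = t(v), x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                  xlab = "features", ylab = "samples", ...)
  invisible(clustering)
}
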