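#' Log-transform, centre and unit-variance scale a feature table
#'
#' Applies the standard metabolomics transformation chain: natural log of
#' abundance (plus an optional pseudo-count), per-feature mean subtraction,
#' and division by the per-feature sample standard deviation (denominator
#' n - 1).  The function is idempotence-guarded: applying it to an already
#' transformed table is an error, never a silent double transformation.
#'
#' @param table a [feature_table()] in `"raw"` state.
#' @param pseudo_count nonnegative value added before the log; default 0
#'   with a hard error on non-positive values, because pre-transformed
#'   supplementary tables never pass through here and synthetic abundances
#'   are strictly positive.
#' @return The transformed table, state `"log_centered_scaled"`.
#' @seealso [drop_constant_features()] to remove zero-variance features first.
#' @export
log_center_scale <- function(table, pseudo_count = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transform_state != "raw")
    stop("table is already in state '", table$transform_state,
         "'; refusing to transform twice")
  if (pseudo_count < 0) stop("'pseudo_count' must be nonnegative")
  v <- table$values + pseudo_count
  if (any(v <= 0))
    stop("values plus pseudo_count must be strictly positive for the log")
  lv <- log(v)
  mu <- colMeans(lv)
  sds <- apply(lv, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero-variance feature(s) after log transform: ",
         paste(colnames(v)[zero], collapse = ", "),
         " (drop them first, e.g. with drop_constant_features())")
  out <- table
  out$values <- sweep(sweep(lv, 2, mu, "-"), 2, sds, "/")
  out$transform_state <- "log_centered_scaled"
  out
}

#' Drop features that are constant after log transform
#'
#' @inheritParams log_center_scale
#' @return The table with zero-variance features removed.
#' @export
drop_constant_features <- function(table, pseudo_count = 0) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values + pseudo_count
  if (any(v <= 0))
    stop("values plus pseudo_count must be strictly positive for the log")
  sds <- apply(log(v), 2, stats::sd)
  keep <- sds > 0
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out$feature_meta <- table$feature_meta[keep, , drop = FALSE]
  out
}

#' Dummy-code class labels as a block response matrix
#'
#' Recodes a categorical label vector as a binary indicator matrix with one
#' column per class, classes ordered by first appearance.  This is the
#' multivariate response Y of the sPLS-DA.
#'
#' @param class_labels character or factor vector, at least two distinct
#'   classes.
#' @return A binary matrix of class `dummy_matrix` with attribute
#'   `class_order`.
#' @export
dummy_code <- function(class_labels) {
  class_labels <- as.character(class_labels)
  classes <- unique(class_labels)
  if (length(classes) < 2)
    stop("at least two distinct classes are required for discrimination")
  y <- matrix(0, length(class_labels), length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(class_labels), match(class_labels, classes))] <- 1
  attr(y, "class_order") <- classes
  class(y) <- c("dummy_matrix", class(y))
  y
}

#' PCA-based outlier screening of samples
#'
#' Performs a principal component analysis of the sample-by-feature matrix
#' (features as variables) and flags a sample when its robust z-score —
#' centred at the median and scaled by the MAD — on any of the first
#' `n_pcs` score vectors exceeds `robust_z_cut`.  The rule codifies the
#' "extreme outlier in the PCA" screen used on untargeted profiles, where a
#' faulty sample sits far outside the score range of the cohort.
#'
#' @param table a scaled [feature_table()] (state `"log_centered_scaled"`).
#' @param n_pcs number of leading principal components screened (default 2).
#' @param robust_z_cut flagging threshold on the robust z-score (default 5).
#' @return An object of class `qc_report`: per-sample PC scores, logical
#'   outlier flags, and the rule parameters.
#' @export
pca_outlier_qc <- function(table, n_pcs = 2, robust_z_cut = 5) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transform_state != "log_centered_scaled")
    stop("PCA QC expects a scaled table; call log_center_scale() first")
  v <- table$values
  n <- nrow(v)
  if (n_pcs < 1) stop("'n_pcs' must be at least 1")
  if (n_pcs > min(n - 1, ncol(v)))
    stop("'n_pcs' exceeds min(n_samples - 1, n_features) = ",
         min(n - 1, ncol(v)))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  z <- apply(scores, 2, function(s) {
    md <- stats::median(s)
    sc <- stats::mad(s)
    if (sc == 0) sc <- stats::IQR(s) / 1.349
    if (sc == 0) return(rep(0, length(s)))
    (s - md) / sc
  })
  z <- matrix(z, nrow = n)
  flags <- apply(abs(z) > robust_z_cut, 1, any)
  out <- list(pc_scores = scores,
              robust_z = z,
              outlier_flags = stats::setNames(flags, table$sample_ids),
              rule_params = list(n_pcs = n_pcs, robust_z_cut = robust_z_cut,
                                 center = "median", scale = "MAD"))
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  n_out <- sum(x$outlier_flags)
  cat("PCA outlier QC:", length(x$outlier_flags), "samples,",
      x$rule_params$n_pcs, "PCs, |robust z| >", x$rule_params$robust_z_cut, "\n")
  if (n_out) {
    cat("  flagged:", paste(names(which(x$outlier_flags)), collapse = ", "), "\n")
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param qc a `qc_report` from [pca_outlier_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_report"))
  obj <- list(rule_params = qc$rule_params,
              samples = names(qc$outlier_flags),
              outlier_flags = unname(qc$outlier_flags),
              pc_scores = unname(apply(qc$pc_scores, 1, as.numeric,
                                       simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Subset a feature table by samples
#'
#' @param table a [feature_table()].
#' @param keep logical or integer index of samples to retain.
#' @return The subsetted table (same transform state).
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$sample_ids <- table$sample_ids[keep]
  out$class_labels <- table$class_labels[keep]
  out$class_order <- unique(out$class_labels)
  out
}
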