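#' Fit a sparse PLS-DA model
#'
#' Sparse partial least squares discriminant analysis in regression mode:
#' the class labels are dummy-coded into a block response matrix Y and a
#' PLS2 model is built one component at a time.  For each component the
#' dominant covariance direction between the current X residual and Y is
#' computed, the loading-weight vector is hard-thresholded so that only the
#' `keepx` entries of largest magnitude survive (magnitude ties keep the
#' lower feature index), renormalised to unit length, and both blocks are
#' deflated through the score vector.  Sparsity acts on the X weights only;
#' the Y weights stay dense, and a single `keepx` is shared by all
#' components.
#'
#' If the residual becomes numerically rank-deficient before `ncomp`
#' components the fit stops early and records the achieved number (unless
#' `strict = TRUE`, in which case this is an error).  X and Y are centred
#' internally and the centring vectors are stored for prediction; the
#' caller is expected to supply a table already log-transformed and
#' unit-variance scaled.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y class labels (character/factor) or a `dummy_matrix` from
#'   [dummy_code()].
#' @param ncomp number of latent components requested (>= 1).
#' @param keepx number of features retained per component (>= 1); defaults
#'   to all features, i.e. the dense PLS2 fit.
#' @param strict error instead of stopping early when `ncomp` cannot be
#'   reached.
#' @param tol relative tolerance of the rank-deficiency early stop.
#' @return An object of class `spls_da` with elements `W` (unit-norm sparse
#'   loading weights, p x H), `scores` (n x H), `loadings` (p x H),
#'   `y_weights` (K x H), `coefficients` (p x K regression coefficients on
#'   the centred scale), `ssy` (Y sum of squares captured per component),
#'   `kept` (per-component kept feature indices), `x_center`, `y_center`,
#'   `class_order`, `ncomp`, `ncomp_used`, `keepx`.
#' @examples
#' sim <- simulate_feature_table(synthetic_spec(n_features = 40, seed = 1))
#' tab <- log_center_scale(sim$table)
#' fit <- spls_da(tab$values, tab$class_labels, ncomp = 2, keepx = 10)
#' fit
#' head(sort(vip(fit), decreasing = TRUE))
#' @export
spls_da <- function(x, y, ncomp, keepx = ncol(x), strict = FALSE, tol = 1e-9) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!inherits(y, "dummy_matrix")) y <- dummy_code(y)
  if (nrow(x) != nrow(y)) stop("'x' and 'y' have different numbers of samples")
  if (nrow(x) < 3) stop("at least 3 samples are required")
  if (length(ncomp) != 1 || ncomp < 1 || ncomp != round(ncomp))
    stop("'ncomp' must be a positive integer")
  if (length(keepx) != 1 || keepx < 1 || keepx != round(keepx))
    stop("'keepx' must be a positive integer")
  hmax <- min(nrow(x) - 1, ncol(x))
  if (strict && ncomp > hmax)
    stop("'ncomp' exceeds min(n - 1, p) = ", hmax, " in strict mode")
  fit <- cpp_spls_fit(x, unclass(y)[, , drop = FALSE], as.integer(ncomp),
                      as.integer(keepx), tol)
  if (fit$ncomp_used == 0)
    stop("no usable component: the covariance between blocks is numerically zero")
  if (strict && fit$ncomp_used < ncomp)
    stop("only ", fit$ncomp_used, " of ", ncomp,
         " components achievable in strict mode")
  feats <- colnames(x)
  if (is.null(feats)) feats <- sprintf("feat_%04d", seq_len(ncol(x)))
  dimnames(fit$W) <- list(feats, paste0("comp", seq_len(fit$ncomp_used)))
  dimnames(fit$B) <- list(feats, attr(y, "class_order"))
  out <- list(W = fit$W,
              scores = fit$scores,
              loadings = fit$P,
              y_weights = fit$C,
              coefficients = fit$B,
              ssy = as.numeric(fit$ssy),
              toty = fit$toty,
              kept = apply(fit$W != 0, 2, which, simplify = FALSE),
              x_center = as.numeric(fit$x_center),
              y_center = as.numeric(fit$y_center),
              class_order = attr(y, "class_order"),
              ncomp = as.integer(ncomp),
              ncomp_used = as.integer(fit$ncomp_used),
              keepx = as.integer(min(keepx, ncol(x))),
              call = match.call())
  class(out) <- "spls_da"
  out
}

#' @export
print.spls_da <- function(x, ...) {
  cat("Sparse PLS-DA fit\n")
  cat("  components:", x$ncomp_used,
      if (x$ncomp_used < x$ncomp) sprintf("(requested %d, early stop)", x$ncomp) else "",
      "\n")
  cat("  features kept per component:", x$keepx, "of", nrow(x$W), "\n")
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  ev <- cumsum(x$ssy) / x$toty
  cat("  cumulative Y variance explained:",
      paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.spls_da <- function(object, ...) object$coefficients

#' Predict from a sparse PLS-DA fit
#'
#' Applies the training centring, multiplies by the regression coefficients
#' and adds back the training response mean.  Class prediction is the
#' argmax over the predicted dummy columns (maximum-distance rule); ties go
#' to the lowest class index and are counted in the `"ties"` attribute.
#'
#' @param object an `spls_da` fit.
#' @param newdata matrix with the same feature columns as the training data.
#' @param type `"response"` for the predicted dummy matrix, `"class"` for
#'   labels.
#' @param ... unused.
#' @export
predict.spls_da <- function(object, newdata,
                            type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients))
    stop("'newdata' has ", ncol(newdata), " columns but the model was fitted with ",
         nrow(object$coefficients))
  yhat <- sweep(newdata, 2, object$x_center, "-") %*% object$coefficients
  yhat <- sweep(yhat, 2, object$y_center, "+")
  colnames(yhat) <- object$class_order
  if (type == "response") return(yhat)
  best <- max.col(yhat, ties.method = "first")
  n_tie <- sum(apply(yhat, 1, function(r) sum(r == max(r)) > 1))
  cls <- factor(object$class_order[best], levels = object$class_order)
  attr(cls, "ties") <- n_tie
  cls
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP for a PLS model:
#' `vip_j = sqrt(p * sum_h(ssy_h * w_jh^2) / sum_h(ssy_h))`, where `ssy_h`
#' is the response sum of squares captured by component h and `w_jh` the
#' unit-norm loading weights.  Because each weight column has unit norm,
#' the mean of the squared VIPs over all p features is exactly 1.  Features
#' outside every kept set have VIP 0.
#'
#' @param object an `spls_da` fit.
#' @param ncomp number of leading components to use (defaults to all
#'   achieved components).
#' @param ... passed to methods.
#' @return Named nonnegative vector of length p with attribute
#'   `n_components_used`.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.spls_da <- function(object, ncomp = object$ncomp_used, ...) {
  h <- min(ncomp, object$ncomp_used)
  W <- object$W[, seq_len(h), drop = FALSE]
  ssy <- object$ssy[seq_len(h)]
  v <- sqrt(nrow(W) * as.numeric(W^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(W)
  attr(v, "n_components_used") <- h
  v
}

#' Cumulative response variance explained
#'
#' Fraction of the total (centred) Y sum of squares captured by the fitted
#' components; non-decreasing in the component count and bounded by
#' \[0, 1\].
#'
#' @param object an `spls_da` fit.
#' @return List with `per_component` and `cumulative` fractions.
#' @export
explained_y_variance <- function(object) {
  stopifnot(inherits(object, "spls_da"))
  per <- object$ssy / object$toty
  list(per_component = per, cumulative = cumsum(per))
}

#' Serialize a sparse PLS-DA model to JSON
#'
#' Arrays are written row-major with dimensions and the class order, enough
#' for audit and exact re-prediction via [read_spls_model()].
#'
#' @param object an `spls_da` fit.
#' @param path output file.
#' @export
write_spls_model <- function(object, path) {
  stopifnot(inherits(object, "spls_da"))
  mat2rows <- function(m) unname(apply(m, 1, as.numeric, simplify = FALSE))
  obj <- list(class_order = object$class_order,
              features = rownames(object$W),
              ncomp_used = object$ncomp_used,
              keepx = object$keepx,
              W = mat2rows(object$W),
              coefficients = mat2rows(object$coefficients),
              y_weights = mat2rows(object$y_weights),
              ssy = object$ssy,
              toty = object$toty,
              x_center = object$x_center,
              y_center = object$y_center)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized sparse PLS-DA model
#'
#' @param path JSON file written by [write_spls_model()].
#' @return An `spls_da` object sufficient for prediction and VIP.
#' @export
read_spls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows2mat <- function(l, cn = NULL) {
    m <- if (is.matrix(l)) l else do.call(rbind, lapply(l, as.numeric))
    colnames(m) <- cn
    m
  }
  W <- rows2mat(obj$W)
  rownames(W) <- obj$features
  B <- rows2mat(obj$coefficients, obj$class_order)
  rownames(B) <- obj$features
  out <- list(W = W,
              y_weights = rows2mat(obj$y_weights),
              coefficients = B,
              ssy = as.numeric(obj$ssy),
              toty = obj$toty,
              kept = apply(W != 0, 2, which, simplify = FALSE),
              x_center = as.numeric(obj$x_center),
              y_center = as.numeric(obj$y_center),
              class_order = obj$class_order,
              ncomp = as.integer(obj$ncomp_used),
              ncomp_used = as.integer(obj$ncomp_used),
              keepx = as.integer(obj$keepx))
  class(out) <- "spls_da"
  out
}
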