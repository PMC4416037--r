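#' Specify a synthetic feature-table design
#'
#' The generator emulates the statistical structure of an untargeted
#' GC-MS/LC-MS study of a small cohort split into temperament-like classes:
#' log-scale Gaussian abundances with optional equicorrelation between
#' features, and a small planted set of class-discriminative features whose
#' log means are shifted per class in units of the base log SD.  The default
#' design mirrors a five-class cohort of 24 animals (class sizes 5,5,5,5,4).
#'
#' @param n_classes number of classes (default 5).
#' @param samples_per_class integer vector of class sizes (default
#'   `c(5, 5, 5, 5, 4)`).
#' @param n_features number of metabolite features.
#' @param n_informative number of planted class-discriminative features;
#'   ignored when `shifts` is supplied.
#' @param effect_size planted effect in SD units (default 2.5); feature i of
#'   the planted set is elevated by `effect_size` in class
#'   `((i - 1) %% n_classes) + 1` and unshifted elsewhere.
#' @param shifts optional explicit matrix (n_informative x n_classes) of
#'   per-class mean shifts in SD units; rows are assigned to the first
#'   `nrow(shifts)` features.
#' @param base_log_mean,base_log_sd location and scale of the log
#'   abundances (defaults 8 and 1, a typical log-intensity scale).
#' @param feature_correlation equicorrelation rho in \[0, 1) between the
#'   log abundances of different features (default 0).
#' @param seed RNG seed; the same spec is bit-reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 5,
                           samples_per_class = c(5, 5, 5, 5, 4),
                           n_features = 200,
                           n_informative = 10,
                           effect_size = 2.5,
                           shifts = NULL,
                           base_log_mean = 8,
                           base_log_sd = 1,
                           feature_correlation = 0,
                           seed = 1) {
  if (!is.null(shifts)) {
    shifts <- as.matrix(shifts)
    n_informative <- nrow(shifts)
    if (ncol(shifts) != n_classes)
      stop("'shifts' needs one column per class")
  } else {
    if (missing(n_classes) && !missing(samples_per_class))
      n_classes <- length(samples_per_class)
    shifts <- matrix(0, n_informative, n_classes)
    if (n_informative > 0)
      shifts[cbind(seq_len(n_informative),
                   ((seq_len(n_informative) - 1) %% n_classes) + 1)] <- effect_size
  }
  if (missing(samples_per_class)) {
    samples_per_class <- rep(5L, n_classes)
    if (n_classes == 5) samples_per_class <- c(5L, 5L, 5L, 5L, 4L)
  }
  if (length(samples_per_class) != n_classes)
    stop("'samples_per_class' needs one entry per class")
  if (n_informative > n_features)
    stop("more informative features than features")
  if (!all(is.finite(shifts))) stop("shifts must be finite")
  if (feature_correlation < 0 || feature_correlation >= 1)
    stop("'feature_correlation' must be in [0, 1)")
  if (base_log_sd <= 0) stop("'base_log_sd' must be positive")
  out <- list(n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              n_features = as.integer(n_features),
              informative = seq_len(n_informative),
              shifts = shifts,
              base_log_mean = base_log_mean,
              base_log_sd = base_log_sd,
              feature_correlation = feature_correlation,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' Generate a synthetic raw feature table
#'
#' Draws log abundances `base_log_mean + base_log_sd * (sqrt(rho) * u_i +
#' sqrt(1 - rho) * z_ij)` — `u_i` a per-sample shared factor inducing
#' equicorrelation `rho` between features — adds the planted per-class mean
#' shifts (in SD units) to the informative features, and exponentiates to
#' strictly positive raw abundances.  The table is returned in `"raw"`
#' state so the full preprocessing chain ([log_center_scale()]) is
#' exercised downstream.  The global RNG state is restored on exit; the
#' same spec always yields bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (a raw [feature_table()]) and `truth`
#'   (informative feature names/indices, the shift matrix, and the spec).
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- sum(spec$samples_per_class)
  p <- spec$n_features
  rho <- spec$feature_correlation
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    u <- stats::rnorm(n)
    z <- sqrt(rho) * matrix(u, n, p) + sqrt(1 - rho) * z
  }
  lv <- spec$base_log_mean + spec$base_log_sd * z
  cls <- rep(seq_len(spec$n_classes), spec$samples_per_class)
  if (length(spec$informative))
    lv[, spec$informative] <- lv[, spec$informative] +
      spec$base_log_sd * t(spec$shifts[, cls, drop = FALSE])
  labels <- class_names(spec$n_classes)[cls]
  feats <- sprintf("feat_%04d", seq_len(p))
  meta <- data.frame(name = feats,
                     technique = rep(c("GC-MS", "LC-MS"), length.out = p),
                     stringsAsFactors = FALSE)
  tab <- feature_table(exp(lv), labels,
                       sample_ids = sprintf("animal_%02d", seq_len(n)),
                       feature_meta = meta, transform_state = "raw")
  truth <- list(informative = spec$informative,
                informative_features = feats[spec$informative],
                shifts = spec$shifts,
                spec = spec)
  list(table = tab, truth = truth)
}

# class labels used by the generator; the five-class default carries the
# temperament-type vocabulary of the emulated study design
class_names <- function(k) {
  if (k == 5)
    return(c("fearful", "interested", "outgoing", "calm", "indistinct"))
  sprintf("class%02d", seq_len(k))
}
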