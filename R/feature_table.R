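#' Construct a feature table
#'
#' A feature table holds a sample-by-feature abundance matrix together with
#' sample identifiers, one class label per sample (e.g. a temperament type),
#' per-feature metadata (name and detection technique) and a record of the
#' transformation state of the values.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param class_labels character or factor, one label per sample.  Class
#'   order is fixed at first appearance and propagated to every downstream
#'   artifact.
#' @param sample_ids unique sample identifiers; defaults to the row names of
#'   `values`.
#' @param feature_meta data frame with columns `name` and `technique`
#'   (`"GC-MS"`, `"LC-MS"` or `"unknown"`); defaults to the column names of
#'   `values` with technique `"unknown"`.
#' @param transform_state one of `"raw"`, `"log"`, `"log_centered_scaled"`.
#'   The state is declared, not inferred: supplementary-style tables arrive
#'   already log-transformed, centred and unit-variance scaled.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, class_labels, sample_ids = rownames(values),
                          feature_meta = NULL,
                          transform_state = c("raw", "log", "log_centered_scaled")) {
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("length of 'sample_ids' (", length(sample_ids),
         ") does not match the number of rows (", n, ")")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (length(class_labels) != n)
    stop("length of 'class_labels' does not match the number of samples")
  class_labels <- as.character(class_labels)
  if (anyNA(values))
    stop("feature table contains missing values; missing cells are not supported")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("feat_%04d", seq_len(ncol(values)))
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(name = colnames(values),
                               technique = "unknown",
                               stringsAsFactors = FALSE)
  }
  if (!all(c("name", "technique") %in% names(feature_meta)))
    stop("'feature_meta' needs columns 'name' and 'technique'")
  if (nrow(feature_meta) != ncol(values))
    stop("'feature_meta' rows must match the number of features")
  dupf <- feature_meta$name[duplicated(feature_meta$name)]
  if (length(dupf))
    stop("duplicated feature name(s): ", paste(unique(dupf), collapse = ", "))
  colnames(values) <- feature_meta$name
  rownames(values) <- sample_ids
  out <- list(values = values,
              sample_ids = sample_ids,
              class_labels = class_labels,
              class_order = unique(class_labels),
              feature_meta = feature_meta,
              transform_state = transform_state)
  class(out) <- "feature_table"
  if (transform_state == "log_centered_scaled") {
    chk <- check_scaled(out, tol = 1e-8)
    if (!chk$ok)
      warning("table declared 'log_centered_scaled' but ", chk$msg)
  }
  out
}

# verify the per-feature mean-0 / sd-1 invariant of a scaled table
check_scaled <- function(table, tol = 1e-3) {
  v <- table$values
  mu <- colMeans(v)
  sds <- apply(v, 2, stats::sd)
  bad_mu <- max(abs(mu))
  bad_sd <- max(abs(sds - 1))
  ok <- bad_mu <= tol && bad_sd <= tol
  list(ok = ok,
       msg = sprintf("max |column mean| = %.3g, max |sd - 1| = %.3g", bad_mu, bad_sd))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  cat("  transform state:", x$transform_state, "\n")
  tab <- table(factor(x$class_labels, levels = x$class_order))
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  tech <- table(x$feature_meta$technique)
  cat("  techniques:", paste(sprintf("%s (%d)", names(tech), tech), collapse = ", "), "\n")
  invisible(x)
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature names, a first column of sample
#' identifiers, and either a designated class-label column inside the table
#' or a separate two-column sample-to-label map file.  Numeric parsing is
#' locale-independent (dot decimal separator).
#'
#' @param path file to read.
#' @param label_column name of the class-label column inside the table, or
#'   `NULL` if labels are supplied through `label_map`.
#' @param label_map optional path to a two-column delimited file (sample ID,
#'   class label) used when the table itself carries no label column.
#' @param delimiter field separator, tab by default.
#' @param transform_state declared transformation state of the values (see
#'   [feature_table()]); supplementary-style tables are already
#'   `"log_centered_scaled"`.
#' @param technique optional character vector of per-feature technique tags.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "class", label_map = NULL,
                               delimiter = "\t",
                               transform_state = "raw",
                               technique = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("table must have a sample-ID column plus features")
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  if (!is.null(label_column) && label_column %in% names(body)) {
    labels <- body[[label_column]]
    body <- body[, setdiff(names(body), label_column), drop = FALSE]
  } else if (!is.null(label_map)) {
    if (!file.exists(label_map)) stop("label map file does not exist: ", label_map)
    lm <- utils::read.table(label_map, sep = delimiter, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(lm) < 2) stop("label map needs two columns: sample ID, class label")
    idx <- match(ids, lm[[1]])
    if (anyNA(idx))
      stop("label map is missing sample(s): ",
           paste(ids[is.na(idx)], collapse = ", "))
    labels <- lm[[2]][idx]
  } else {
    stop("no label column '", label_column, "' in ", path,
         " and no 'label_map' supplied")
  }
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    x <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(x) & !is.na(body[[j]]))
    if (length(bad))
      stop("non-numeric value '", body[[j]][bad[1]], "' in feature '",
           names(body)[j], "', sample '", ids[bad[1]], "'")
    if (anyNA(x))
      stop("missing value in feature '", names(body)[j], "'")
    vals[, j] <- x
  }
  meta <- data.frame(name = colnames(vals),
                     technique = if (is.null(technique)) "unknown" else technique,
                     stringsAsFactors = FALSE)
  feature_table(vals, labels, sample_ids = ids, feature_meta = meta,
                transform_state = transform_state)
}

#' Write a feature table to delimited text
#'
#' Values are written with 15 significant digits so that a read/write
#' round trip preserves them to at least 12 significant digits.
#'
#' @param table a [feature_table()].
#' @param path output file.
#' @param label_column name to use for the class-label column.
#' @param delimiter field separator.
#' @export
write_feature_table <- function(table, path, label_column = "class",
                                delimiter = "\t") {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  txt <- matrix(sprintf("%.15g", v), nrow(v), ncol(v))
  df <- data.frame(sample = table$sample_ids,
                   class = table$class_labels,
                   stringsAsFactors = FALSE)
  names(df)[2] <- label_column
  df <- cbind(df, as.data.frame(txt, stringsAsFactors = FALSE))
  names(df)[-(1:2)] <- colnames(v)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
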