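#' Construct a point set
#'
#' A `pointset` is the package's basic container: an `n x d` numeric feature
#' matrix, optional integer ground-truth labels, and provenance metadata.
#' Missing feature values are carried as `NA` until [impute_mean()] runs.
#'
#' @param X Numeric matrix (or coercible data frame), rows are points.
#' @param y_true Optional integer vector of ground-truth labels, length `n`.
#' @param feature_names Optional character vector of column names.
#' @param source Character scalar describing where the data came from.
#' @return An object of class `pointset` with elements `X`, `y_true`,
#'   `feature_names`, `source`.
#' @export
pointset <- function(X, y_true = NULL, feature_names = NULL,
                     source = "memory") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L)
    stop("pointset needs at least one row and one column")
  if (!is.null(y_true)) {
    if (length(y_true) != nrow(X))
      stop("y_true must have one label per point")
    y_true <- as.integer(y_true)
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(X))
    colnames(X) <- feature_names
  }
  structure(list(X = X, y_true = y_true,
                 feature_names = colnames(X), source = source),
            class = "pointset")
}

#' @export
print.pointset <- function(x, ...) {
  cat(sprintf("pointset: %d points, %d features%s (source: %s)\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y_true)) "" else
                sprintf(", %d ground-truth clusters",
                        length(unique(x$y_true))),
              x$source))
  invisible(x)
}

#' @export
dim.pointset <- function(x) dim(x$X)

#' Read a point set from a delimited text file
#'
#' Reads the de-facto format of the clustering shape benchmarks: one point per
#' line, whitespace- or comma-delimited feature columns, with an optional
#' integer ground-truth label column.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter: `"auto"` (default) treats commas and any
#'   whitespace run as separators, otherwise a literal single-character
#'   delimiter such as `","`.
#' @param label_column One of `"none"`, `"first"`, `"last"`, or a 1-based
#'   column index giving the ground-truth label column.
#' @param missing_token Token marking a missing feature value (default `"?"`);
#'   such cells become `NA` and must be imputed before clustering.
#' @return A [pointset()]; missing cells are `NA` in `$X`.
#' @export
read_points <- function(path, delimiter = "auto", label_column = "last",
                        missing_token = "?") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  split_re <- if (identical(delimiter, "auto")) "[,[:space:]]+" else
    paste0("[", delimiter, "]")
  toks <- lapply(lines, function(l) {
    tt <- strsplit(trimws(l), split_re)[[1]]
    tt[nzchar(tt)]
  })
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows: column counts ", paste(unique(ncols), collapse = ", "))
  nc <- ncols[[1]]
  cells <- matrix(unlist(toks), nrow = length(toks), ncol = nc, byrow = TRUE)
  lab_idx <- switch(as.character(label_column),
                    none  = 0L,
                    first = 1L,
                    last  = nc,
                    {
                      i <- suppressWarnings(as.integer(label_column))
                      if (is.na(i) || i < 1L || i > nc)
                        stop("invalid label_column: ", label_column)
                      i
                    })
  if (lab_idx > 0L && nc < 2L)
    stop("file has a single column; cannot split off a label column")
  y <- NULL
  if (lab_idx > 0L) {
    ylab <- cells[, lab_idx]
    y <- suppressWarnings(as.integer(ylab))
    if (anyNA(y)) stop("non-integer value in label column: ",
                       ylab[which(is.na(y))[1L]])
    cells <- cells[, -lab_idx, drop = FALSE]
  }
  cells[cells == missing_token] <- NA_character_
  X <- suppressWarnings(matrix(as.numeric(cells),
                               nrow = nrow(cells), ncol = ncol(cells)))
  bad <- is.na(X) & !is.na(cells)
  if (any(bad))
    stop("non-numeric feature cell: ", cells[which(bad)[1L]])
  pointset(X, y_true = y, source = path)
}

new_preprocess_report <- function(n_features) {
  structure(list(imputed_count = integer(n_features),
                 min_j = rep(NA_real_, n_features),
                 max_j = rep(NA_real_, n_features),
                 constant_features = integer(0)),
            class = "preprocess_report")
}

#' Impute missing feature values by the feature mean
#'
#' Each `NA` cell is replaced by the arithmetic mean of the non-missing values
#' in its feature column. Non-missing cells are left bit-identical.
#'
#' @param P A [pointset()].
#' @return A list with elements `points` (imputed [pointset()]) and `report`
#'   (a `preprocess_report` whose `imputed_count` gives per-feature counts).
#' @export
impute_mean <- function(P) {
  stopifnot(inherits(P, "pointset"))
  X <- P$X
  rep <- new_preprocess_report(ncol(X))
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (all(miss)) stop("feature ", j, " is entirely missing")
    if (any(miss)) {
      X[miss, j] <- mean(X[!miss, j])
      rep$imputed_count[j] <- sum(miss)
    }
  }
  P$X <- X
  list(points = P, report = rep)
}

#' Min-max normalize each feature to [0, 1]
#'
#' Maps each feature column x to (x - min(x)) / (max(x) - min(x)). Constant
#' features (max equals min) are mapped to 0 and listed in the report's
#' `constant_features`; the map is idempotent.
#'
#' @param P A [pointset()] with no missing cells (run [impute_mean()] first).
#' @return A list with elements `points` and `report` (records per-feature
#'   `min_j`, `max_j` and `constant_features`).
#' @export
minmax_normalize <- function(P) {
  stopifnot(inherits(P, "pointset"))
  X <- P$X
  if (anyNA(X)) stop("missing cells present; impute before normalizing")
  rep <- new_preprocess_report(ncol(X))
  for (j in seq_len(ncol(X))) {
    mn <- min(X[, j]); mx <- max(X[, j])
    rep$min_j[j] <- mn; rep$max_j[j] <- mx
    if (mx == mn) {
      X[, j] <- 0
      rep$constant_features <- c(rep$constant_features, j)
    } else {
      X[, j] <- (X[, j] - mn) / (mx - mn)
    }
  }
  P$X <- X
  list(points = P, report = rep)
}

#' Write cluster labels, one integer per line
#'
#' @param labels Integer vector of cluster labels (length `n >= 1`).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  if (length(labels) == 0L) stop("empty label vector")
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA")
  writeLines(format(labels, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Read cluster labels written by [write_labels()]
#' @param path Path to a one-integer-per-line file.
#' @return Integer vector.
#' @export
read_labels <- function(path) {
  y <- suppressWarnings(as.integer(readLines(path, warn = FALSE)))
  if (anyNA(y)) stop("non-integer line in label file: ", path)
  y
}

#' Write a structured run report
#'
#' Serializes run metadata (parameters, sizes, seed) and any metrics as a
#' plain `key: value` text document.
#'
#' @param meta Named list of scalar metadata values.
#' @param path Output path.
#' @param metrics Optional named numeric vector/list of validation metrics.
#' @export
write_report <- function(meta, path, metrics = NULL) {
  fmt <- function(v) if (is.numeric(v)) format(v, digits = 15) else
    as.character(v)
  lines <- vapply(names(meta), function(k) paste0(k, ": ", fmt(meta[[k]])),
                  character(1))
  if (!is.null(metrics)) {
    lines <- c(lines, "", "metric\tvalue",
               vapply(names(metrics), function(k)
                 paste0(k, "\t", format(metrics[[k]], digits = 15)),
                 character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
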