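#' Construct a labelled tabular dataset
#'
#' The basic container used throughout the package: a feature table (numeric
#' matrix once preprocessed, a data frame while raw categorical columns are
#' still present), a class label vector, per-feature metadata, and an optional
#' ground-truth informative mask (available for synthetic data).
#'
#' @param X matrix or data frame of N samples by M features.
#' @param y class labels, length N, at least 2 distinct values for modelling
#'   (a single-class dataset is accepted at construction so partial pipelines
#'   can operate, but scoring operations reject it).
#' @param feature_meta data frame with columns `name`, `kind` (one of
#'   `"numeric"`, `"categorical"`, `"signal"`, `"omics"`) and `original` (the
#'   source column a derived feature came from). Defaults to all-numeric
#'   metadata named after `colnames(X)`.
#' @param informative_mask optional logical vector of length M flagging
#'   ground-truth informative features.
#' @param preprocessed logical; TRUE once [preprocess()] has run.
#' @return an object of class `skr_dataset`.
#' @export
skr_dataset <- function(X, y, feature_meta = NULL, informative_mask = NULL,
                        preprocessed = FALSE) {
  if (is.data.frame(X) && all(vapply(X, is.numeric, logical(1)))) {
    X <- as.matrix(X)
  }
  n <- nrow(X)
  m <- ncol(X)
  if (is.null(n) || n < 1L || m < 1L) stop_input("dataset must have at least 1 row and 1 column")
  if (length(y) != n) stop_input("length(y) = %d does not match rows(X) = %d", length(y), n)
  y <- as.factor(as.vector(y))
  if (anyNA(y)) stop_input("labels contain missing values")
  if (is.null(feature_meta)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("f", seq_len(m))
    kinds <- if (is.data.frame(X)) {
      ifelse(vapply(X, is.numeric, logical(1)), "numeric", "categorical")
    } else rep("numeric", m)
    feature_meta <- data.frame(name = nm, kind = kinds, original = nm,
                               stringsAsFactors = FALSE)
  }
  if (nrow(feature_meta) != m) {
    stop_input("feature_meta has %d rows but X has %d columns", nrow(feature_meta), m)
  }
  bad <- setdiff(unique(feature_meta$kind), c("numeric", "categorical", "signal", "omics"))
  if (length(bad)) stop_input("unknown feature kind(s): %s", paste(bad, collapse = ", "))
  if (!is.null(informative_mask)) {
    if (length(informative_mask) != m) stop_input("informative_mask length mismatch")
    informative_mask <- as.logical(informative_mask)
  }
  if (!is.data.frame(X)) colnames(X) <- feature_meta$name
  structure(
    list(X = X, y = y, feature_meta = feature_meta,
         informative_mask = informative_mask, preprocessed = isTRUE(preprocessed)),
    class = "skr_dataset"
  )
}

#' @export
print.skr_dataset <- function(x, ...) {
  cat(sprintf("<skr_dataset> %d samples x %d features, %d classes%s\n",
              nrow(x$X), ncol(x$X), nlevels(x$y),
              if (x$preprocessed) " (preprocessed)" else ""))
  tab <- table(x$feature_meta$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$informative_mask)) {
    cat("  informative features:", sum(x$informative_mask), "\n")
  }
  invisible(x)
}

#' @export
dim.skr_dataset <- function(x) dim(x$X)

# Numeric feature matrix or error: most modelling operations need this.
dataset_matrix <- function(ds) {
  X <- ds$X
  if (is.data.frame(X)) {
    if (!all(vapply(X, is.numeric, logical(1)))) {
      stop_input("dataset still contains non-numeric columns; run preprocess() first")
    }
    X <- as.matrix(X)
  }
  if (anyNA(X)) stop_input("feature matrix contains missing values")
  X
}

#' Preprocessing specification
#'
#' Records how a raw dataset is converted to a fully numeric matrix:
#' how numeric columns are scaled, how categorical columns are encoded, and
#' (for the high-dimensional archetype) the variance floor below which
#' near-constant features are dropped as noise.
#'
#' @param numeric_mode `"zscore"` (subtract mean, divide by population
#'   standard deviation), `"minmax"`, or `"none"`.
#' @param categorical_mode `"onehot"` (one indicator column per level) or
#'   `"ordinal"` (integer codes in level order, for genuinely ordered codes).
#' @param highdim_variance_floor nonnegative; features with variance strictly
#'   below it are removed when `archetype = "highdim"`.
#' @param archetype dataset archetype: `"numeric"`, `"categorical_mixed"`,
#'   `"signal"` or `"highdim"`.
#' @return an object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(numeric_mode = c("zscore", "minmax", "none"),
                            categorical_mode = c("onehot", "ordinal"),
                            highdim_variance_floor = 0,
                            archetype = c("numeric", "categorical_mixed",
                                          "signal", "highdim")) {
  numeric_mode <- match.arg(numeric_mode)
  categorical_mode <- match.arg(categorical_mode)
  archetype <- match.arg(archetype)
  if (!is.numeric(highdim_variance_floor) || highdim_variance_floor < 0) {
    stop_config("highdim_variance_floor must be a nonnegative real")
  }
  structure(list(numeric_mode = numeric_mode, categorical_mode = categorical_mode,
                 highdim_variance_floor = highdim_variance_floor,
                 archetype = archetype),
            class = "preprocess_spec")
}

#' Read a delimited table into a dataset
#'
#' Reads a CSV/TSV file with a header row, takes one column as the class
#' label, and types the remaining columns by inference: a column is numeric
#' if every entry parses as a number, otherwise categorical. Row order is
#' preserved.
#'
#' @param path path to the delimited text file (UTF-8).
#' @param label_column name of the label column in the header.
#' @param delimiter field delimiter, default `","`.
#' @return an [skr_dataset()] with raw (unpreprocessed) columns.
#' @export
read_table <- function(path, label_column = "label", delimiter = ",") {
  if (!file.exists(path)) stop_config("input file does not exist: %s", path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop_input("file %s has no data rows", path)
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop_input("unparseable row in %s at line %d: expected %d fields, found %d",
               path, bad[1], nf[1], nf[bad[1]])
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!label_column %in% names(raw)) {
    stop_config("label column '%s' not found in header of %s", label_column, path)
  }
  if (any(as.matrix(raw) == "" | as.matrix(raw) == "NA", na.rm = TRUE) || anyNA(raw)) {
    stop_input("file %s contains missing values; imputation is not supported", path)
  }
  y <- raw[[label_column]]
  feats <- raw[setdiff(names(raw), label_column)]
  if (ncol(feats) < 1L) stop_input("file %s has no feature columns", path)
  typed <- lapply(feats, function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (!anyNA(num)) num else col
  })
  df <- as.data.frame(typed, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(df)) stop_input("file %s contains missing values; imputation is not supported", path)
  skr_dataset(df, y)
}

#' Apply dataset-archetype preprocessing
#'
#' Scales numeric columns, encodes categorical columns, and for the
#' high-dimensional archetype drops features whose variance falls below the
#' configured floor. Constant numeric columns standardize to all-zeros (the
#' variance filter, not the scaler, is the remover of dead features). The row
#' count is never altered. Z-scoring uses the population (divide-by-N)
#' standard deviation, the same variance convention as the feature ranking,
#' and is idempotent: re-applying it to standardized data changes nothing.
#'
#' @param ds an [skr_dataset()].
#' @param spec a [preprocess_spec()].
#' @return a preprocessed [skr_dataset()] with a numeric feature matrix.
#' @export
preprocess <- function(ds, spec = preprocess_spec()) {
  stopifnot(inherits(ds, "skr_dataset"), inherits(spec, "preprocess_spec"))
  X <- ds$X
  if (nrow(X) < 1L || ncol(X) < 1L) stop_input("empty dataset")
  cols <- list()
  meta <- list()
  for (j in seq_len(ncol(X))) {
    colname <- ds$feature_meta$name[j]
    kind <- ds$feature_meta$kind[j]
    orig <- ds$feature_meta$original[j]
    v <- if (is.data.frame(X)) X[[j]] else X[, j]
    if (is.numeric(v)) {
      if (anyNA(v)) stop_input("column '%s' contains missing values", colname)
      out <- switch(spec$numeric_mode,
        zscore = { s <- pop_sd(v); if (s > 0) (v - mean(v)) / s else rep(0, length(v)) },
        minmax = rescale01(v),
        none = v)
      cols[[length(cols) + 1L]] <- out
      meta[[length(meta) + 1L]] <- data.frame(name = colname, kind = kind,
                                              original = orig, stringsAsFactors = FALSE)
    } else {
      f <- factor(v)
      if (anyNA(f)) stop_input("column '%s' contains missing values", colname)
      if (spec$categorical_mode == "onehot") {
        for (lev in levels(f)) {
          cols[[length(cols) + 1L]] <- as.numeric(f == lev)
          meta[[length(meta) + 1L]] <- data.frame(
            name = paste0(colname, "=", lev), kind = "categorical",
            original = orig, stringsAsFactors = FALSE)
        }
      } else {
        cols[[length(cols) + 1L]] <- as.numeric(f)
        meta[[length(meta) + 1L]] <- data.frame(name = colname, kind = "categorical",
                                                original = orig, stringsAsFactors = FALSE)
      }
    }
  }
  Xp <- do.call(cbind, cols)
  metap <- do.call(rbind, meta)
  colnames(Xp) <- metap$name
  mask <- ds$informative_mask
  if (!is.null(mask)) {
    # propagate the mask through derived columns via the originating column
    mask <- mask[match(metap$original, ds$feature_meta$name)]
  }
  if (spec$archetype == "highdim" && spec$highdim_variance_floor > 0) {
    vars <- apply(Xp, 2, function(x) mean((x - mean(x))^2))
    keep <- vars >= spec$highdim_variance_floor
    if (!any(keep)) stop_input("variance floor %g removed every feature", spec$highdim_variance_floor)
    Xp <- Xp[, keep, drop = FALSE]
    metap <- metap[keep, , drop = FALSE]
    if (!is.null(mask)) mask <- mask[keep]
  }
  out <- skr_dataset(Xp, ds$y, feature_meta = metap, informative_mask = mask,
                     preprocessed = TRUE)
  out$preprocess <- spec
  out
}

#' Write a dataset to CSV with a JSON metadata sidecar
#'
#' The CSV holds the features plus a final `label` column; the sidecar
#' (`<path>.meta.json`) records column kinds, the preprocessing applied and
#' the informative mask, so external tools can consume the fixture.
#'
#' @param ds an [skr_dataset()].
#' @param path output CSV path.
#' @param label_column name used for the label column.
#' @return invisibly, the paths written (csv, sidecar).
#' @export
write_dataset <- function(ds, path, label_column = "label") {
  X <- ds$X
  df <- as.data.frame(X, check.names = FALSE)
  df[[label_column]] <- as.character(ds$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  sidecar <- paste0(path, ".meta.json")
  meta <- list(
    label_column = label_column,
    feature_meta = ds$feature_meta,
    preprocessed = ds$preprocessed,
    preprocess = if (!is.null(ds$preprocess)) unclass(ds$preprocess),
    informative_mask = ds$informative_mask,
    generator = if (!is.null(ds$generator)) unclass(ds$generator)
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv = path, sidecar = sidecar))
}
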