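# Pair features: two per-protein RCC vectors become one PPI instance,
# either by elementwise sum (26 features) or by concatenation (52).
# Scaling (raw / normalize / standardize) is fitted on training data only.

#' Construct a PPI dataset
#'
#' A light container: a numeric feature matrix (instances in rows, columns
#' `RCC1..RCCd`), a label factor with levels `negative`/`positive`, and a
#' free-form provenance list.
#'
#' @param features Numeric matrix or data frame of features.
#' @param labels Character or factor vector of `"positive"`/`"negative"`.
#' @param provenance Optional named list (cutoff, atom mode, combine mode,
#'   scaling, sampling tag, seed ...).
#' @return A `ppi_dataset`.
#' @export
ppi_dataset <- function(features, labels, provenance = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("RCC", seq_len(ncol(features)))
  }
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (anyNA(labels)) stop("labels must be 'positive' or 'negative'")
  if (length(labels) != nrow(features)) {
    stop("labels length must match the number of instances")
  }
  structure(list(features = features, labels = labels,
                 provenance = provenance),
            class = "ppi_dataset")
}

#' @export
print.ppi_dataset <- function(x, ...) {
  cat("ppi_dataset:", nrow(x$features), "instances x", ncol(x$features),
      "features (", sum(x$labels == "positive"), "positive /",
      sum(x$labels == "negative"), "negative )\n")
  invisible(x)
}

#' Combine two RCC vectors into one pair feature vector
#'
#' `mode = "sum"` adds the two 26-dimensional count vectors elementwise;
#' `mode = "concat"` appends b after a for 52 features. Both inputs must
#' share cutoff and atom mode. Concatenation order is (a, b) as given; no
#' canonicalization is applied, so swapping the pair changes the
#' concatenated vector.
#'
#' @param rcc_a,rcc_b `rcc_vector` objects with identical provenance.
#' @param mode `"sum"` or `"concat"`.
#' @return Named numeric vector of length 26 or 52 (`RCC1..RCC52`).
#' @export
combine_rcc <- function(rcc_a, rcc_b, mode = c("sum", "concat")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rcc_a, "rcc_vector"), inherits(rcc_b, "rcc_vector"))
  same <- function(u, v) (is.na(u) && is.na(v)) || isTRUE(u == v)
  if (!same(rcc_a$cutoff, rcc_b$cutoff) ||
      !identical(rcc_a$atom_mode, rcc_b$atom_mode)) {
    stop("incompatible representations: cutoff/atom_mode differ")
  }
  if (mode == "sum") {
    out <- as.numeric(rcc_a$counts) + as.numeric(rcc_b$counts)
    names(out) <- paste0("RCC", seq_along(out))
  } else {
    out <- c(as.numeric(rcc_a$counts), as.numeric(rcc_b$counts))
    names(out) <- paste0("RCC", seq_along(out))
  }
  out
}

#' Fit a feature scaler on training data
#'
#' `"normalize"` learns per-feature min/max for a min-max map to \[0, 1\];
#' `"standardize"` learns per-feature mean/sd for a z-score map; `"raw"`
#' is the identity. Statistics come from the training table only — a
#' fitted scaler applied to test data never recomputes them.
#'
#' @param train_features Numeric matrix of training features.
#' @param method `"raw"`, `"normalize"` or `"standardize"`.
#' @return A `scaler_state`.
#' @export
fit_scaler <- function(train_features,
                       method = c("raw", "normalize", "standardize")) {
  method <- match.arg(method)
  train_features <- as.matrix(train_features)
  if (nrow(train_features) == 0L) stop("training table is empty")
  state <- list(method = method, p = ncol(train_features))
  if (method == "normalize") {
    state$min <- apply(train_features, 2L, min)
    state$max <- apply(train_features, 2L, max)
  } else if (method == "standardize") {
    state$mean <- colMeans(train_features)
    state$sd <- apply(train_features, 2L, stats::sd)
  }
  structure(state, class = "scaler_state")
}

#' Apply a fitted scaler
#'
#' Degenerate features map to 0: a zero training range under normalize and
#' a zero training sd under standardize both yield a constant 0 column.
#' Test values outside the training range may fall outside \[0, 1\].
#'
#' @param state A `scaler_state` from [fit_scaler()].
#' @param features Numeric matrix (or single vector) to transform.
#' @return Transformed matrix with the input's shape.
#' @export
apply_scaler <- function(state, features) {
  if (!inherits(state, "scaler_state")) stop("scaler not fitted")
  one <- is.null(dim(features))
  features <- if (one) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(features) != state$p) stop("feature count mismatch")
  out <- switch(state$method,
    raw = features,
    normalize = {
      rng <- state$max - state$min
      res <- sweep(features, 2L, state$min, "-")
      res <- sweep(res, 2L, ifelse(rng > 0, rng, 1), "/")
      res[, rng == 0] <- 0
      res
    },
    standardize = {
      res <- sweep(features, 2L, state$mean, "-")
      res <- sweep(res, 2L, ifelse(state$sd > 0, state$sd, 1), "/")
      res[, state$sd == 0] <- 0
      res
    }
  )
  if (one) drop(out) else out
}

#' Build a PPI dataset from per-protein RCC tables and a pair list
#'
#' @param rcc_table Data frame as produced by [rcc_grid()] rows (columns
#'   `structure_id`, `cutoff`, `atom_mode`, `RCC1..RCC26`) for a single
#'   (cutoff, atom_mode) configuration.
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param mode `"sum"` or `"concat"`.
#' @return A `ppi_dataset`.
#' @export
featurize_pairs <- function(rcc_table, pairs, mode = c("sum", "concat")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  cols <- paste0("RCC", 1:26)
  stopifnot(all(cols %in% names(rcc_table)))
  if (length(unique(rcc_table$cutoff)) > 1L ||
      length(unique(rcc_table$atom_mode)) > 1L) {
    stop("incompatible representations: rcc_table mixes configurations")
  }
  row_of <- match(c(pairs$id_a, pairs$id_b), rcc_table$structure_id)
  if (anyNA(row_of)) {
    stop("structure id(s) missing from rcc_table: ",
         paste(unique(c(pairs$id_a, pairs$id_b)[is.na(row_of)]),
               collapse = ", "))
  }
  a <- as.matrix(rcc_table[row_of[seq_len(nrow(pairs))], cols])
  b <- as.matrix(rcc_table[row_of[nrow(pairs) + seq_len(nrow(pairs))], cols])
  feats <- if (mode == "sum") a + b else cbind(a, b)
  colnames(feats) <- paste0("RCC", seq_len(ncol(feats)))
  ppi_dataset(feats, pairs$label,
              provenance = list(cutoff = rcc_table$cutoff[1L],
                                atom_mode = rcc_table$atom_mode[1L],
                                combine_mode = mode, scaling = "raw",
                                pair_ids = pairs[, c("id_a", "id_b")]))
}

#' Export a PPI dataset to ARFF
#'
#' Writes the feature columns plus a binary `class` attribute, for
#' interoperability with Weka-style tooling.
#'
#' @param dataset A `ppi_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arff <- function(dataset, path) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  df <- as.data.frame(dataset$features)
  df$class <- dataset$labels
  foreign::write.arff(df, path)
  invisible(path)
}

#' Write / read a PPI dataset as CSV
#'
#' Column layout: `label`, then the feature columns `RCC1..RCCd`.
#'
#' @param dataset A `ppi_dataset`.
#' @param path CSV file path.
#' @return `write_dataset_csv` returns `path` invisibly;
#'   `read_dataset_csv` returns a `ppi_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  df <- data.frame(label = as.character(dataset$labels),
                   dataset$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ppi_dataset(df[, setdiff(names(df), "label"), drop = FALSE], df$label)
}
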