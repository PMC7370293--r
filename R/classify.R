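# Locally weighted classification: a lazy kernel-weighted k-nearest-
# neighbour model, evaluated by percent correctly classified instances
# (%CCI) and ranked on the (test CCI, train-test CCI difference) surface.

#' Fit a locally weighted nearest-neighbour model
#'
#' A lazy learner: the model stores the training features, labels and
#' hyperparameters. At prediction time a query is classified by its k
#' nearest training neighbours (Euclidean distance) with a weighted vote.
#'
#' @param train A `ppi_dataset`.
#' @param k Neighbour count (default 50), or `"all"` to use the whole
#'   training set. Values above the training size are clamped with a
#'   warning.
#' @param kernel `"linear"` (weights decay linearly with distance, see
#'   [predict.lwl_model()]) or `"constant"` (unweighted vote, plain kNN).
#' @return An `lwl_model`.
#' @export
fit_lwl <- function(train, k = 50L, kernel = c("linear", "constant")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(train, "ppi_dataset"))
  n <- nrow(train$features)
  if (n == 0L) stop("empty training set")
  if (identical(k, "all")) {
    k <- n
  } else {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > n) {
      warning("k = ", k, " exceeds training size ", n, "; clamped")
      k <- n
    }
  }
  structure(list(features = train$features, labels = train$labels,
                 k = k, kernel = kernel),
            class = "lwl_model")
}

#' Predict with a locally weighted nearest-neighbour model
#'
#' For each query row: the k nearest training points vote with weights
#' `w_i = max(0, 1 - d_i / d_cut)` under the linear kernel, where `d_cut`
#' is the distance to the (k+1)-th neighbour (or the largest neighbour
#' distance when k equals the training size); the constant kernel gives
#' every neighbour weight 1. Training points tied with the k-th neighbour
#' distance all enter the vote, so the prediction does not depend on the
#' storage order of equidistant instances. When every weight vanishes
#' (all neighbours sit at the cut distance) the vote falls back to
#' constant weights over the same neighbour set. The class with the
#' larger summed weight wins; exact ties go to the negative class.
#'
#' @param object An `lwl_model`.
#' @param newdata Numeric matrix (or single vector) of query features.
#' @param ... Unused.
#' @return Data frame: `label`, `score_positive`, `score_negative`.
#' @export
predict.lwl_model <- function(object, newdata, ...) {
  one <- is.null(dim(newdata))
  Q <- if (one) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(Q) != ncol(object$features)) {
    stop("query feature length (", ncol(Q), ") does not match training (",
         ncol(object$features), ")")
  }
  X <- object$features
  n <- nrow(X)
  k <- object$k
  d2 <- outer(rowSums(Q^2), rep(1, n)) + outer(rep(1, nrow(Q)), rowSums(X^2)) -
    2 * Q %*% t(X)
  d2[d2 < 0] <- 0
  lab <- character(nrow(Q))
  sp <- numeric(nrow(Q)); sn <- numeric(nrow(Q))
  is_pos <- object$labels == "positive"
  for (q in seq_len(nrow(Q))) {
    d <- sqrt(d2[q, ])
    ord <- order(d)
    d_k <- d[ord[k]]
    nb <- which(d <= d_k)   # includes ties at the k-th distance
    if (object$kernel == "constant") {
      w <- rep(1, length(nb))
    } else {
      d_cut <- if (k < n) d[ord[k + 1L]] else d_k
      w <- if (d_cut > 0) pmax(0, 1 - d[nb] / d_cut) else numeric(length(nb))
      if (sum(w) == 0) w <- rep(1, length(nb))
    }
    sp[q] <- sum(w[is_pos[nb]])
    sn[q] <- sum(w[!is_pos[nb]])
    lab[q] <- if (sp[q] > sn[q]) "positive" else "negative"
  }
  data.frame(label = factor(lab, levels = c("negative", "positive")),
             score_positive = sp, score_negative = sn)
}

#' Evaluate a model on train and test partitions
#'
#' %CCI is `100 (TP + TN) / N`. The report carries the training and test
#' CCI, their difference (`delta = cci_test - cci_train`, 0 meaning no
#' train/test gap) and the test confusion counts.
#'
#' @param model An `lwl_model`.
#' @param train,test `ppi_dataset` partitions.
#' @param label Optional configuration label.
#' @return An `eval_report` list: `cci_train`, `cci_test`, `delta`, `tp`,
#'   `tn`, `fp`, `fn`, `label`.
#' @export
evaluate_model <- function(model, train, test, label = NA_character_) {
  stopifnot(inherits(model, "lwl_model"))
  if (nrow(test$features) == 0L) stop("empty test set")
  pr_tr <- predict(model, train$features)$label
  pr_te <- predict(model, test$features)$label
  cci <- function(pred, truth) 100 * mean(pred == truth)
  tp <- sum(pr_te == "positive" & test$labels == "positive")
  tn <- sum(pr_te == "negative" & test$labels == "negative")
  fp <- sum(pr_te == "positive" & test$labels == "negative")
  fn <- sum(pr_te == "negative" & test$labels == "positive")
  cci_train <- cci(pr_tr, train$labels)
  cci_test <- cci(pr_te, test$labels)
  structure(list(cci_train = cci_train, cci_test = cci_test,
                 delta = cci_test - cci_train,
                 tp = tp, tn = tn, fp = fp, fn = fn, label = label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report", if (!is.na(x$label)) x$label else "", "\n",
      sprintf(" CCI train %.1f%%  test %.1f%%  delta %+.1f\n",
              x$cci_train, x$cci_test, x$delta),
      sprintf(" test confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Rank evaluation reports on the selection surface
#'
#' The study's model-selection plot puts test CCI on the x-axis and the
#' test-minus-train CCI difference on the y-axis; the best models sit in
#' the top right corner. Reports are ranked by test CCI descending, then
#' |delta| ascending, then configuration label.
#'
#' @param reports List of `eval_report`s.
#' @return Data frame, best model first: `rank`, `label`, `cci_test`,
#'   `delta`, `cci_train`.
#' @export
model_selection_surface <- function(reports) {
  if (length(reports) == 0L) stop("no reports")
  if (inherits(reports, "eval_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(label = as.character(r$label), cci_test = r$cci_test,
               delta = r$delta, cci_train = r$cci_train,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-df$cci_test, abs(df$delta), df$label)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}
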