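# Separability diagnostics and per-feature screening: set diameter D
# versus inter-set distance d, exact linear separability by LP
# feasibility, rank-sum tests with Bonferroni / Benjamini-Hochberg
# correction, and nonzero-fraction profiling.

#' Diameter of a point set
#'
#' Maximum Euclidean distance between any pair of rows; a single row has
#' diameter 0.
#'
#' @param vectors Numeric matrix, one instance per row.
#' @return Non-negative scalar.
#' @export
set_diameter <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L) stop("empty input")
  if (nrow(vectors) == 1L) return(0)
  max(stats::dist(vectors))
}

#' Minimum distance between two point sets
#'
#' Smallest Euclidean distance over all cross pairs (one row from each
#' set). Zero when the sets share a point.
#'
#' @param set_a,set_b Numeric matrices with equal column counts.
#' @return Non-negative scalar.
#' @export
inter_set_min_distance <- function(set_a, set_b) {
  set_a <- as.matrix(set_a); set_b <- as.matrix(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) stop("empty input")
  cross <- rowSums(set_a^2) %*% t(rep(1, nrow(set_b))) +
    rep(1, nrow(set_a)) %*% t(rowSums(set_b^2)) -
    2 * set_a %*% t(set_b)
  sqrt(max(0, min(cross)))
}

#' Distance-separability report
#'
#' Computes the diameter D of the negative set (the study's designated
#' set), the minimum inter-set distance d between positives and
#' negatives, and flags the pair distance-separable when d > D (the gap
#' between classes exceeds the negative set's spread). The positive set's
#' diameter is reported alongside for context.
#'
#' @param pos,neg Numeric feature matrices (positive / negative class).
#' @param label Optional configuration label carried into the report.
#' @return A `separability_report` list: `D`, `d`, `D_pos`,
#'   `distance_separable`, `label`.
#' @export
distance_separability <- function(pos, neg, label = NA_character_) {
  D <- set_diameter(neg)
  d <- inter_set_min_distance(pos, neg)
  structure(list(D = D, d = d, D_pos = set_diameter(pos),
                 distance_separable = d > D, label = label),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat("separability:", if (!is.na(x$label)) x$label else "", "\n",
      " D (neg diameter) =", format(x$D), "\n",
      " d (inter-set)    =", format(x$d), "\n",
      " distance-separable:", x$distance_separable, "\n")
  invisible(x)
}

#' Exact linear separability by hard-margin feasibility
#'
#' Decides whether a hyperplane strictly separates the two classes by
#' solving the hard-margin problem: minimise ||w||^2 subject to
#' y_i (w . x_i + b) >= 1. The constraint system is feasible exactly when
#' the classes are strictly separable (the unit margin is
#' scale-normalized, so the answer does not depend on a tolerance). The
#' witness (w, b) is verified against every input point before being
#' returned; an infeasible system reports not separable.
#'
#' @param pos,neg Numeric feature matrices.
#' @return List: `separable` flag and, when separable, the witness `w`,
#'   `b` with `w . x + b > 0` for positives and `< 0` for negatives.
#' @export
linear_separability <- function(pos, neg) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) == 0L || nrow(neg) == 0L) stop("empty input")
  X <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  p <- ncol(X)
  # variables (w, b); a vanishing quadratic weight on b keeps the matrix
  # positive definite without changing feasibility
  Dmat <- diag(c(rep(1, p), 1e-8))
  dvec <- rep(0, p + 1L)
  Amat <- t(cbind(y * X, y))
  bvec <- rep(1, nrow(X))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec),
    error = function(e) NULL
  )
  if (is.null(sol)) return(list(separable = FALSE, w = NULL, b = NULL))
  w <- sol$solution[seq_len(p)]
  b <- sol$solution[p + 1L]
  margin <- y * (X %*% w + b)
  separable <- all(margin > 0)
  list(separable = separable,
       w = if (separable) as.numeric(w) else NULL,
       b = if (separable) b else NULL)
}

#' Exact two-sided rank-sum p-value by full enumeration
#'
#' Enumerates all choose(n, n1) assignments of the pooled (tie-averaged)
#' ranks to the first group and returns the two-sided permutation
#' p-value: the fraction of assignments whose rank sum deviates from its
#' permutation mean at least as much as the observed one. Handles ties;
#' on tie-free data it coincides with the classical exact two-sided
#' Wilcoxon rank-sum p-value.
#'
#' @param x,y Numeric samples (combined length kept small; the screening
#'   path uses this below a combined n of 20).
#' @return p-value in (0, 1].
#' @export
rank_sum_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(sums - mu) >= abs(s_obs - mu) - 1e-9)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Per-feature rank-sum screening of positive versus negative PPI
#'
#' For each feature column, a two-sided rank-sum (Mann-Whitney/Wilcoxon)
#' test of the positive against the negative values: exact permutation
#' enumeration when the combined sample size is below 20, tie-corrected
#' normal approximation otherwise. Raw p-values are corrected across the
#' 26 (or 52) features by Bonferroni or Benjamini-Hochberg and flagged at
#' `alpha`. A feature constant across both classes is degenerate and gets
#' p = 1 by convention.
#'
#' @param pos,neg Numeric feature matrices (>= 2 rows each).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha Significance level (default 0.05).
#' @param exact_below Combined sample size below which the exact
#'   enumeration path is used (default 20).
#' @return A `feature_screen_report` data frame: `feature`, `p_raw`,
#'   `p_adj`, `significant`, `degenerate`.
#' @export
feature_screen <- function(pos, neg, correction = c("bonferroni", "bh"),
                           alpha = 0.05, exact_below = 20L) {
  correction <- match.arg(correction)
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("both classes need at least 2 instances")
  }
  stopifnot(ncol(pos) == ncol(neg))
  m <- ncol(pos)
  p_raw <- numeric(m)
  degenerate <- logical(m)
  n_comb <- nrow(pos) + nrow(neg)
  for (j in seq_len(m)) {
    a <- pos[, j]; b <- neg[, j]
    if (length(unique(c(a, b))) == 1L) {
      p_raw[j] <- 1
      degenerate[j] <- TRUE
    } else if (n_comb < exact_below) {
      p_raw[j] <- rank_sum_exact(a, b)
    } else {
      p_raw[j] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
      )
    }
  }
  p_adj <- adjust_pvalues(p_raw, correction)
  out <- data.frame(
    feature = colnames(pos) %||% paste0("RCC", seq_len(m)),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < alpha, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- correction
  attr(out, "alpha") <- alpha
  class(out) <- c("feature_screen_report", "data.frame")
  out
}

#' Fraction of instances with a nonzero value, per feature
#'
#' The sparsity profile of a dataset: for each feature, the fraction of
#' instances whose value is strictly nonzero.
#'
#' @param dataset A `ppi_dataset` (or bare feature matrix).
#' @return Named numeric vector in \[0, 1\], one entry per feature.
#' @export
nonzero_fraction_profile <- function(dataset) {
  m <- if (inherits(dataset, "ppi_dataset")) dataset$features
       else as.matrix(dataset)
  if (nrow(m) == 0L) stop("empty dataset")
  colMeans(m != 0)
}
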