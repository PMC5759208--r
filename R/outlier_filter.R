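# Outlier filtering on PCA loading lengths.
#
# Each object is mapped to its D-dimensional loading vector: its entries in
# the first D eigenvectors of the objects' correlation matrix, scaled by the
# square root of the eigenvalues (classic component loadings). The squared
# length delta^2 is then the object's communality over D components, bounded
# by 1 because the correlation matrix has unit diagonal. Objects whose
# length falls below an absolute cutoff (default 0.3) contribute essentially
# nothing to the detected structure and are flagged as outliers.

#' Map objects to loading vectors and lengths
#'
#' @param data a `data_matrix`, assumed row-standardized (as produced by
#'   [standardize()]); the pipeline enforces this.
#' @param D number of components to keep (`0 <= D <=` numerical rank).
#' @param scaling `"sqrt_eigen"` (default): eigenvector entries scaled by
#'   the square root of the eigenvalue, so `delta` is the square root of the
#'   object's communality, in `[0, 1]`. `"unit"`: raw orthonormal
#'   eigenvector entries, so the squared lengths sum to `D` across objects.
#' @param pca optionally, a precomputed [object_pca()] result for `data`.
#' @return An object of class `loading_set`: `loadings` (`P x D`), `delta`
#'   (named per object), `D`, `scaling`, and placeholders `cutoff`,
#'   `is_outlier` filled by [flag_outliers()].
#' @examples
#' dm <- standardize(matrix(rnorm(300), 30, 10))
#' ld <- object_loadings(dm, D = 2)
#' ld$delta
#' @export
object_loadings <- function(data, D, scaling = c("sqrt_eigen", "unit"),
                            pca = NULL) {
  scaling <- match.arg(scaling)
  data <- as_data_matrix(data)
  if (is.null(pca)) pca <- object_pca(data)
  if (D < 0) stop("D must be nonnegative")
  rank <- sum(pca$eigenvalues > pca$eigenvalues[1] * 1e-8)
  if (D > rank) {
    stop("D = ", D, " exceeds the numerical rank (", rank,
         ") of the correlation structure")
  }
  P <- pca$n_objects
  if (D == 0) {
    lm <- matrix(0, P, 0)
  } else {
    lm <- pca$vectors[, seq_len(D), drop = FALSE]
    if (scaling == "sqrt_eigen") {
      lm <- sweep(lm, 2, sqrt(pca$eigenvalues[seq_len(D)]), `*`)
    }
  }
  delta <- sqrt(rowSums(lm^2))
  names(delta) <- data$object_ids
  rownames(lm) <- data$object_ids
  structure(list(loadings = lm,
                 delta = delta,
                 D = as.integer(D),
                 scaling = scaling,
                 object_ids = data$object_ids,
                 cutoff = NA_real_,
                 is_outlier = rep(NA, P)),
            class = "loading_set")
}

#' Flag outliers by loading length
#'
#' An object is an outlier exactly when its loading length is strictly below
#' the cutoff; a length equal to the cutoff is retained.
#'
#' @param loadings a `loading_set` from [object_loadings()].
#' @param cutoff nonnegative length threshold (default 0.3).
#' @return The `loading_set` with `cutoff` and logical `is_outlier` filled.
#' @export
flag_outliers <- function(loadings, cutoff = 0.3) {
  if (!inherits(loadings, "loading_set")) stop("expected a loading_set")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0) {
    stop("cutoff must be a single nonnegative number")
  }
  loadings$cutoff <- cutoff
  loadings$is_outlier <- loadings$delta < cutoff
  loadings
}

#' @export
print.loading_set <- function(x, ...) {
  cat("loading_set:", length(x$delta), "objects, D =", x$D,
      "(", x$scaling, ")\n")
  if (!is.na(x$cutoff)) {
    cat(sum(x$is_outlier), "outlier(s) at cutoff", x$cutoff, "\n")
  }
  invisible(x)
}

#' ROC table of outlier calls over a grid of cutoffs
#'
#' The "positive" class here is the \emph{good} (signal) objects, matching
#' the calibration table's orientation: at cutoff `c`, the true positive
#' rate is the fraction of good objects with `delta >= c` (retained) and the
#' false positive rate is the fraction of noise objects with `delta >= c`
#' (incorrectly retained). Both are nonincreasing in `c`.
#'
#' @param deltas loading lengths.
#' @param truth logical, `TRUE` for genuine signal ("good") objects.
#' @param cutoffs grid of cutoffs to evaluate.
#' @return data frame with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_over_cutoffs <- function(deltas, truth, cutoffs) {
  if (length(deltas) != length(truth)) {
    stop("deltas and truth must have equal length")
  }
  truth <- as.logical(truth)
  ng <- sum(truth)
  nb <- sum(!truth)
  if (ng == 0L || nb == 0L) {
    warning("degenerate truth (no ", if (ng == 0L) "good" else "noise",
            " objects); undefined rates reported as NaN")
  }
  tpr <- vapply(cutoffs, function(cc) {
    if (ng == 0L) NaN else mean(deltas[truth] >= cc)
  }, numeric(1))
  fpr <- vapply(cutoffs, function(cc) {
    if (nb == 0L) NaN else mean(deltas[!truth] >= cc)
  }, numeric(1))
  data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr)
}
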