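# Scoring: outlier-detection confusion summaries and cluster-count error,
# plus the Monte Carlo study drivers that batch them over simulated data.

# rank-sum AUC with "bad" as the positive class and low delta indicative:
# the probability that a random bad object has smaller delta than a random
# good object, ties counting one half
.auc_low_delta <- function(deltas, truth_bad) {
  nb <- sum(truth_bad)
  ng <- sum(!truth_bad)
  if (nb == 0L || ng == 0L) return(NaN)
  r <- rank(deltas)
  (sum(r[!truth_bad]) - ng * (ng + 1) / 2) / (nb * ng)
}

#' Confusion summary for outlier detection
#'
#' Positives are the "bad" (noise/outlier) objects: sensitivity is the
#' fraction of truly bad objects called bad, specificity the fraction of
#' truly good objects called good, FDR the fraction of good objects among
#' those called bad, and AUC the rank-sum probability that a random bad
#' object has a smaller loading length than a random good one (ties count
#' one half).
#'
#' @param called_bad logical calls.
#' @param truth_bad logical ground truth.
#' @param deltas loading lengths used as the (inverted) score for the AUC.
#' @return An object of class `confusion_summary`: `sensitivity`,
#'   `specificity`, `fdr`, `auc`, `n_good`, `n_bad`.
#' @examples
#' outlier_confusion(c(TRUE, TRUE, FALSE, FALSE),
#'                   c(TRUE, TRUE, FALSE, FALSE),
#'                   c(0.1, 0.2, 0.5, 0.6))
#' @export
outlier_confusion <- function(called_bad, truth_bad, deltas) {
  if (length(called_bad) != length(truth_bad) ||
      length(truth_bad) != length(deltas)) {
    stop("called_bad, truth_bad and deltas must have equal length")
  }
  called_bad <- as.logical(called_bad)
  truth_bad <- as.logical(truth_bad)
  nb <- sum(truth_bad)
  ng <- sum(!truth_bad)
  if (nb == 0L || ng == 0L) {
    warning("degenerate truth (only one class); undefined rates are NaN")
  }
  sens <- if (nb) mean(called_bad[truth_bad]) else NaN
  spec <- if (ng) mean(!called_bad[!truth_bad]) else NaN
  ncall <- sum(called_bad)
  fdr <- if (ncall) sum(called_bad & !truth_bad) / ncall else NaN
  structure(list(sensitivity = sens,
                 specificity = spec,
                 fdr = fdr,
                 auc = .auc_low_delta(deltas, truth_bad),
                 n_good = ng,
                 n_bad = nb),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("confusion_summary: sensitivity %.3f  specificity",
                     " %.3f  FDR %.3f  AUC %.3f (%d good, %d bad)\n"),
              x$sensitivity, x$specificity, x$fdr, x$auc, x$n_good, x$n_bad))
  invisible(x)
}

#' Mean absolute error of cluster-count estimates
#'
#' @param estimated_k integer estimates.
#' @param true_k matching true values.
#' @return `mean(|estimated_k - true_k|)`.
#' @export
abs_diff_score <- function(estimated_k, true_k) {
  if (length(estimated_k) == 0L) stop("empty input")
  if (length(estimated_k) != length(true_k)) {
    stop("estimated_k and true_k must have equal length")
  }
  mean(abs(estimated_k - true_k))
}

# the printed cutoff grid of the calibration study
.table1_cutoffs <- c(0.20, 0.25, 0.26, 0.27, 0.28, 0.29, 0.30, 0.31, 0.32,
                     0.33, 0.34, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60)

#' Monte Carlo calibration of the outlier cutoff
#'
#' Regenerates the cutoff-selection protocol: `reps_per_kind` datasets for
#' each of the five signal kinds, each pushed through stage 1 of the
#' pipeline (PC dimension and loading lengths), pooling every object's
#' `delta` with its good/noise truth and tabulating the retention ROC over
#' a cutoff grid.
#'
#' @param reps_per_kind datasets per signal kind (500 reproduces the
#'   original study scale; 100 gives a fast, slightly noisier table).
#' @param seed integer seed for the whole study.
#' @param cutoffs cutoff grid (default: the printed 0.20-0.60 grid).
#' @param criterion step-length criterion for stage 1.
#' @param cap_factor see [auer_gervini_steps()].
#' @return data frame with columns `cutoff`, `fpr`, `tpr`, plus attributes
#'   `n_datasets`, `n_good`, `n_bad`.
#' @examples
#' \donttest{
#' roc <- cutoff_roc_study(reps_per_kind = 20, seed = 1)
#' roc[roc$cutoff == 0.30, ]
#' }
#' @export
cutoff_roc_study <- function(reps_per_kind = 500, seed = NULL,
                             cutoffs = .table1_cutoffs,
                             criterion = c("TwiceMean", "CPT"),
                             cap_factor = .ag_cap_factor_default) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  deltas <- vector("list", 5L * reps_per_kind)
  good <- vector("list", 5L * reps_per_kind)
  i <- 0L
  for (kind in protocol_kinds()) {
    for (rep in seq_len(reps_per_kind)) {
      ds <- cutoff_protocol_dataset(kind)
      s1 <- .thresher_stage1(ds$data, criterion, "sqrt_eigen", cap_factor)
      i <- i + 1L
      deltas[[i]] <- unname(s1$loadings$delta)
      good[[i]] <- ds$truth_good
    }
  }
  deltas <- unlist(deltas)
  good <- unlist(good)
  roc <- roc_over_cutoffs(deltas, good, cutoffs)
  attr(roc, "n_datasets") <- 5L * reps_per_kind
  attr(roc, "n_good") <- sum(good)
  attr(roc, "n_bad") <- sum(!good)
  roc
}

#' Outlier-detection performance on a block-correlation preset
#'
#' Simulates `reps` datasets from a [fig1_preset()] structure, runs stage 1
#' of the pipeline with the default cutoff rule on each, and pools all
#' objects into one confusion summary.
#'
#' @param index preset index (1-16).
#' @param n_objects,n_variables dataset shape.
#' @param reps number of datasets.
#' @param seed integer seed.
#' @param cutoff outlier cutoff (default 0.3).
#' @param criterion step-length criterion.
#' @param cap_factor see [auer_gervini_steps()].
#' @return A `confusion_summary` pooled over all `reps * n_objects`
#'   objects.
#' @export
outlier_detection_study <- function(index, n_objects = 24, n_variables = 96,
                                    reps = 200, seed = NULL, cutoff = 0.3,
                                    criterion = c("TwiceMean", "CPT"),
                                    cap_factor = .ag_cap_factor_default) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  spec <- fig1_preset(index, n_objects)
  called <- truth <- logical(0)
  dd <- numeric(0)
  for (rep in seq_len(reps)) {
    ds <- sample_mvn(spec, n_variables)
    s1 <- .thresher_stage1(ds$data, criterion, "sqrt_eigen", cap_factor)
    called <- c(called, unname(s1$loadings$delta) < cutoff)
    truth <- c(truth, !ds$truth_good)
    dd <- c(dd, unname(s1$loadings$delta))
  }
  outlier_confusion(called, truth, dd)
}

#' Cluster-count accuracy on a block-correlation preset
#'
#' Runs the full pipeline on `reps` datasets simulated from a preset and
#' scores the estimated number of clusters against the construction truth.
#'
#' @inheritParams outlier_detection_study
#' @param n_starts EM restarts per mixture fit.
#' @return list with `estimated_k`, `k_true`, and `score` (the mean
#'   absolute difference).
#' @export
cluster_count_study <- function(index, n_objects = 24, n_variables = 96,
                                reps = 100, seed = NULL, cutoff = 0.3,
                                criterion = c("TwiceMean", "CPT"),
                                n_starts = 10,
                                cap_factor = .ag_cap_factor_default) {
  criterion <- match.arg(criterion)
  if (!is.null(seed)) set.seed(seed)
  spec <- fig1_preset(index, n_objects)
  est <- integer(reps)
  for (rep in seq_len(reps)) {
    ds <- sample_mvn(spec, n_variables)
    res <- suppressWarnings(
      thresher(ds$data, cutoff = cutoff, criterion = criterion,
               n_starts = n_starts, cap_factor = cap_factor))
    est[rep] <- res$n_clusters
  }
  list(estimated_k = est, k_true = spec$k_true,
       score = abs_diff_score(est, rep(spec$k_true, reps)))
}
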