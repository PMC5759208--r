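# End-to-end pipeline: PC dimension -> outlier filtering -> vMF clustering.

# stage 1 only: eigen-decompose the objects' correlation structure, select
# D, compute loadings. Object-level standardization happens inside
# object_pca (each column is centred and scaled across the variables, which
# is what makes the decomposition a correlation PCA); variable-level
# standardization is deliberately NOT applied here — centring each variable
# across the objects would subtract any signal shared by most objects.
# Shared by the full pipeline and the Monte Carlo calibration machinery.
.thresher_stage1 <- function(data, criterion, scaling, cap_factor) {
  std <- as_data_matrix(data)
  pca <- object_pca(std)
  ag <- auer_gervini_steps(pca$eigenvalues, pca$n_obs, cap_factor)
  D <- as.integer(select_dimension(ag, criterion))
  ld <- object_loadings(std, D, scaling, pca = pca)
  list(std = std, pca = pca, ag = ag, D = D, loadings = ld)
}

#' Run the full cluster-count-with-outlier-removal pipeline
#'
#' Three stages: (1) estimate the number `D` of significant principal
#' components of the objects' correlation structure with the Auer-Gervini
#' step-length procedure; (2) map every object to its `D`-dimensional
#' loading vector and flag objects whose length `delta` falls below
#' `cutoff` as outliers; (3) refit on the retained objects to get `D0`,
#' project their loading vectors onto the unit hypersphere, and choose the
#' number of clusters `N` in `D0..2 D0 + 1` by the minimum-BIC von
#' Mises-Fisher mixture. Directions matter: strongly anticorrelated objects
#' point at antipodal positions on the sphere and form separate clusters.
#'
#' @param data a `data_matrix` (or coercible): variables in rows, objects in
#'   columns.
#' @param cutoff outlier threshold on the loading length (default 0.3;
#'   objects with `delta < cutoff` are removed).
#' @param criterion step-length criterion, `"TwiceMean"` (default) or
#'   `"CPT"`.
#' @param scaling loading scaling, see [object_loadings()].
#' @param seed optional integer seed controlling the mixture-model restarts.
#' @param n_starts EM restarts per candidate `N`.
#' @param cap_factor see [auer_gervini_steps()].
#' @return An object of class `thresher_result` with fields `D`, `outliers`
#'   (object ids), `D0`, `n_clusters`, `labels` (cluster id per retained
#'   object; outliers are reported separately), `deltas` (per object), and
#'   `diagnostics` (step lengths before/after filtering, BIC table, seed,
#'   criterion, cutoff).
#' @examples
#' ds <- cutoff_protocol_dataset("one_signed", seed = 7)
#' res <- thresher(ds$data, seed = 7)
#' res
#' @export
thresher <- function(data, cutoff = 0.3, criterion = c("TwiceMean", "CPT"),
                     scaling = c("sqrt_eigen", "unit"), seed = NULL,
                     n_starts = 10, cap_factor = .ag_cap_factor_default) {
  criterion <- match.arg(criterion)
  scaling <- match.arg(scaling)
  data <- as_data_matrix(data)
  P <- length(data$object_ids)
  if (!is.null(seed)) set.seed(seed)

  s1 <- .thresher_stage1(data, criterion, scaling, cap_factor)
  ld <- flag_outliers(s1$loadings, cutoff)
  retained <- !ld$is_outlier
  outliers <- data$object_ids[!retained]

  diagnostics <- list(criterion = criterion, cutoff = cutoff,
                      scaling = scaling, seed = seed,
                      eigenvalues = s1$pca$eigenvalues,
                      step_lengths = s1$ag$step_lengths,
                      step_lengths_retained = NULL,
                      bic_table = NULL)
  result <- function(D0, n_clusters, labels) {
    structure(list(D = s1$D, outliers = outliers, D0 = D0,
                   n_clusters = n_clusters, labels = labels,
                   deltas = ld$delta, diagnostics = diagnostics),
              class = "thresher_result")
  }

  if (!any(retained)) {
    warning("all ", P, " objects flagged as outliers; nothing to cluster")
    return(result(NA_integer_, 0L,
                  stats::setNames(integer(0), character(0))))
  }
  if (sum(retained) < 3L) {
    warning("fewer than 3 retained objects; skipping mixture fitting")
    labels <- stats::setNames(rep(1L, sum(retained)),
                              data$object_ids[retained])
    return(result(NA_integer_, 1L, labels))
  }

  sub <- data_matrix(data$values[, retained, drop = FALSE],
                     object_ids = data$object_ids[retained],
                     variable_ids = data$variable_ids)
  std2 <- sub
  pca2 <- object_pca(std2)
  ag2 <- auer_gervini_steps(pca2$eigenvalues, pca2$n_obs, cap_factor)
  D0 <- as.integer(select_dimension(ag2, criterion))
  diagnostics$step_lengths_retained <- ag2$step_lengths

  if (D0 == 0L) {
    labels <- stats::setNames(rep(1L, sum(retained)), sub$object_ids)
    return(result(0L, 1L, labels))
  }

  ld2 <- object_loadings(std2, D0, scaling, pca = pca2)
  dn <- ld2$delta
  keep <- dn > 1e-12
  if (any(!keep)) {
    warning(sum(!keep), " retained object(s) with numerically zero loading",
            " length excluded from the hypersphere")
  }
  pts <- ld2$loadings[keep, , drop = FALSE] / dn[keep]
  seed2 <- if (is.null(seed)) NULL else (seed + 1000L) %% .Machine$integer.max
  cn <- choose_n_clusters(pts, D0, n_starts = n_starts, seed = seed2)
  diagnostics$bic_table <- cn$bic_table

  labels <- stats::setNames(rep(NA_integer_, sum(retained)), sub$object_ids)
  if (!is.null(cn$best_fit)) {
    labels[keep] <- cn$best_fit$labels
  } else {
    labels[keep] <- 1L
  }
  result(D0, cn$n_clusters, labels)
}

#' @rdname thresher
#' @export
run_thresher <- thresher

#' @export
print.thresher_result <- function(x, ...) {
  cat("thresher_result\n")
  cat("  PC dimension D:        ", x$D, "\n")
  cat("  outliers removed:      ", length(x$outliers),
      if (length(x$outliers)) paste0(" (",
        paste(utils::head(x$outliers, 6L), collapse = ", "),
        if (length(x$outliers) > 6L) ", ..." else "", ")") else "", "\n",
      sep = "")
  cat("  post-filter dimension D0:", x$D0, "\n")
  cat("  clusters N*:           ", x$n_clusters, "\n")
  if (length(x$labels)) {
    cat("  cluster sizes:         ",
        paste(table(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' @param result a `thresher_result`.
#' @return A JSON string.
#' @export
thresher_result_json <- function(result) {
  stopifnot(inherits(result, "thresher_result"))
  jsonlite::toJSON(list(
    D = result$D,
    D0 = result$D0,
    n_clusters = result$n_clusters,
    outliers = result$outliers,
    labels = as.list(result$labels),
    deltas = as.list(round(result$deltas, 10)),
    criterion = result$diagnostics$criterion,
    cutoff = result$diagnostics$cutoff,
    seed = result$diagnostics$seed
  ), auto_unbox = TRUE, digits = NA, na = "null")
}
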