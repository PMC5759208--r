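# PCA dimension via the Auer-Gervini step-length construction.
#
# The model: given the nonincreasing eigen-spectrum lambda_1..lambda_K of the
# objects' correlation matrix, candidate dimension d keeps the top d
# eigenvalues free and replaces the remaining K-d by their mean. The profile
# log-likelihood of n observations is
#   L(d) = -(n/2) [ sum_{j<=d} log lambda_j + (K-d) log mean(lambda_{d+1..K}) ].
# A prior that penalizes dimension with rate theta gives the MAP dimension
#   d_hat(theta) = argmax_d L(d) - theta * n * d,
# a nonincreasing step function of theta >= 0. Dimensions that persist over
# long theta-intervals are stable; the two automated criteria (TwiceMean and
# a single change-point split) call the long steps.

# default multiple of the last breakpoint used to close the d = 0 step
# (see select_dimension details; calibrated against the cutoff-selection
# simulation protocol, documented in the methods vignette)
.ag_cap_factor_default <- 4.5

#' Internal PCA of the objects' correlation structure
#'
#' Computes the eigen-spectrum and eigenvectors of the Pearson correlation
#' matrix between objects (columns), via SVD of the column-standardized
#' matrix. Row standardization (see [standardize()]) should be applied first
#' so that every variable contributes on the same scale.
#'
#' @param data a `data_matrix`.
#' @return list with `eigenvalues` (length `min(n, P)`), `vectors`
#'   (`P x min(n, P)` orthonormal columns), `n_obs` (number of variables) and
#'   `n_objects`.
#' @keywords internal
object_pca <- function(data) {
  data <- as_data_matrix(data)
  x <- data$values
  n <- nrow(x)
  P <- ncol(x)
  xc <- scale(x, center = TRUE, scale = TRUE)
  sds <- attr(xc, "scaled:scale")
  zero <- sds < 1e-12
  if (any(zero)) {
    stop("object(s) with zero variance across variables: ",
         paste(utils::head(data$object_ids[zero], 5L), collapse = ", "))
  }
  K <- min(n, P)
  sv <- svd(xc, nu = 0, nv = K)
  lam <- (sv$d[seq_len(K)]^2) / (n - 1)
  list(eigenvalues = lam, vectors = sv$v, n_obs = n, n_objects = P)
}

#' Eigen-spectrum of the objects' correlation structure
#'
#' @param data a `data_matrix`, assumed row-standardized.
#' @return Nonincreasing nonnegative eigenvalues, `min(n, P)` of them, of
#'   the objects' Pearson correlation matrix.
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' eigen_spectrum(x)
#' @export
eigen_spectrum <- function(data) {
  object_pca(as_data_matrix(data))$eigenvalues
}

#' Auer-Gervini step-length fit of an eigen-spectrum
#'
#' Builds the MAP-dimension step function \eqn{\hat d(\theta)} described
#' above and returns the width of the theta-interval on which each candidate
#' dimension is selected. Candidate dimensions run from 0 to one below the
#' numerical rank of the spectrum, so the residual ("noise") model always
#' keeps at least one trailing eigenvalue. The step function is closed on
#' the right at `theta_max = cap_factor * (last breakpoint)`, which assigns
#' dimension 0 a finite step length comparable with the others.
#'
#' @param eigenvalues nonincreasing, nonnegative spectrum.
#' @param n_obs number of observations (variables) behind the spectrum.
#' @param cap_factor multiple of the largest breakpoint at which the theta
#'   axis is truncated; dimension 0's step length is
#'   `(cap_factor - 1) * max(breakpoints)`.
#' @return An object of class `auer_gervini_fit` with elements
#'   `eigenvalues`, `n_obs`, `profile_loglik` (indexed by dimension
#'   `0..dmax`), `theta_breakpoints` (decreasing), `step_lengths` (named by
#'   dimension), `dims_visited` and `theta_max`.
#' @examples
#' fit <- auer_gervini_steps(c(10, 1, 1, 1, 1), n_obs = 50)
#' fit$step_lengths
#' @export
auer_gervini_steps <- function(eigenvalues, n_obs,
                               cap_factor = .ag_cap_factor_default) {
  if (length(eigenvalues) < 1L) stop("empty eigen-spectrum")
  if (n_obs < 2) stop("n_obs must be at least 2")
  if (any(diff(eigenvalues) > 1e-8 * max(abs(eigenvalues), 1))) {
    stop("eigenvalues must be nonincreasing")
  }
  if (any(eigenvalues < -1e-8 * max(abs(eigenvalues), 1))) {
    stop("eigenvalues must be nonnegative")
  }
  lam_all <- pmax(eigenvalues, 1e-12)
  # effectively-zero eigenvalues are rank artifacts (e.g. of centering);
  # they would drag every tail mean towards the floor and make the profile
  # likelihood rise without bound, so the equal-tail model sees only the
  # numerically nonzero part of the spectrum
  rank <- sum(lam_all > lam_all[1] * 1e-8)
  lam <- lam_all[seq_len(rank)]
  K <- length(lam)
  dmax <- max(K - 1L, 0L)

  L <- vapply(0:dmax, function(d) {
    m <- mean(lam[(d + 1):K])
    -(n_obs / 2) * (sum(log(lam[seq_len(d)])) + (K - d) * log(m))
  }, numeric(1))
  g <- L / n_obs

  # walk the upper concave envelope of (d, g(d)) from the theta = 0 argmax
  # down to d = 0; at each stage the next breakpoint is the smallest theta
  # at which some lower dimension overtakes the current one
  dims <- integer(0)
  thetas <- numeric(0)
  cur <- which.max(g) - 1L
  while (cur > 0L) {
    cand <- 0:(cur - 1L)
    th <- (g[cur + 1L] - g[cand + 1L]) / (cur - cand)
    j <- which.min(th)
    dims <- c(dims, cur)
    thetas <- c(thetas, th[j])
    cur <- cand[j]
  }

  steps <- numeric(dmax + 1L)
  names(steps) <- as.character(0:dmax)
  if (length(dims)) {
    widths <- diff(c(0, thetas))
    steps[as.character(dims)] <- widths
    theta_max <- cap_factor * thetas[length(thetas)]
    steps["0"] <- theta_max - thetas[length(thetas)]
  } else {
    # isotropic spectrum: d_hat(theta) = 0 everywhere
    theta_max <- 1
    steps["0"] <- theta_max
  }

  structure(list(eigenvalues = lam_all,
                 n_obs = n_obs,
                 profile_loglik = L,
                 theta_breakpoints = rev(thetas),
                 step_lengths = steps,
                 dims_visited = c(dims, 0L),
                 cap_factor = cap_factor,
                 theta_max = theta_max,
                 criterion = NA_character_,
                 dimension = NA_integer_),
            class = "auer_gervini_fit")
}

#' @export
print.auer_gervini_fit <- function(x, ...) {
  cat("Auer-Gervini fit:", length(x$eigenvalues), "eigenvalues,",
      length(x$step_lengths), "candidate dimensions\n")
  cat("step lengths:\n")
  print(signif(x$step_lengths, 4))
  if (!is.na(x$dimension)) {
    cat("selected dimension:", x$dimension, "(", x$criterion, ")\n")
  }
  invisible(x)
}

# at-most-one-changepoint split of the sorted step lengths: minimize the
# within-segment sum of squares (normal cost, single mean shift) and call
# everything in the upper segment "long"
.cpt_long <- function(steps) {
  m <- length(steps)
  if (m < 2L || diff(range(steps)) < 1e-12) {
    return(rep(FALSE, m))
  }
  o <- order(steps)
  s <- steps[o]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  tot <- cs[m]
  tot2 <- cs2[m]
  sse <- vapply(seq_len(m - 1L), function(tau) {
    (cs2[tau] - cs[tau]^2 / tau) +
      ((tot2 - cs2[tau]) - (tot - cs[tau])^2 / (m - tau))
  }, numeric(1))
  tau <- which.min(sse)
  long <- logical(m)
  long[o[(tau + 1L):m]] <- TRUE
  long
}

#' Select the PC dimension from Auer-Gervini step lengths
#'
#' Separates the step lengths into "short" and "long" with one of two
#' automated criteria and returns the largest candidate dimension whose step
#' is long (0 when none qualifies, or when only dimension 0 does):
#' \describe{
#'   \item{TwiceMean}{a step is long when its length is at least twice the
#'     mean of all step lengths (ties at exactly twice the mean count as
#'     long).}
#'   \item{CPT}{sort the step lengths, find the single most likely change in
#'     mean (at-most-one-changepoint, normal cost), and call the steps above
#'     the change long.}
#' }
#'
#' @param fit an `auer_gervini_fit`, or a bare numeric vector of step
#'   lengths named/indexed by candidate dimension `0, 1, ...`.
#' @param criterion `"TwiceMean"` (default) or `"CPT"`.
#' @return Integer dimension `D >= 0`, with attributes `long` (logical per
#'   candidate) and `criterion`.
#' @examples
#' select_dimension(c(`0` = 2, `1` = 50, `2` = 1, `3` = 1))  # 1
#' @export
select_dimension <- function(fit, criterion = c("TwiceMean", "CPT")) {
  criterion <- match.arg(criterion)
  steps <- if (inherits(fit, "auer_gervini_fit")) fit$step_lengths else fit
  if (length(steps) < 2L) {
    warning("fewer than 2 candidate steps; returning D = 0")
    return(structure(0L, long = rep(FALSE, length(steps)),
                     criterion = criterion))
  }
  long <- switch(criterion,
                 TwiceMean = steps >= 2 * mean(steps),
                 CPT = .cpt_long(steps))
  D <- if (any(long)) max(which(long)) - 1L else 0L
  structure(as.integer(D), long = long, criterion = criterion)
}

#' Estimate the number of significant principal components
#'
#' Convenience wrapper: compute the eigen-spectrum of the objects'
#' correlation matrix (each object is standardized across the variables
#' inside the correlation), build the Auer-Gervini step function and apply
#' the chosen criterion.
#'
#' @param data a `data_matrix` (or coercible).
#' @param criterion `"TwiceMean"` or `"CPT"`.
#' @param cap_factor see [auer_gervini_steps()].
#' @return The completed `auer_gervini_fit`, with `dimension` and
#'   `criterion` filled in.
#' @export
pc_dimension <- function(data, criterion = c("TwiceMean", "CPT"),
                         cap_factor = .ag_cap_factor_default) {
  criterion <- match.arg(criterion)
  pca <- object_pca(as_data_matrix(data))
  fit <- auer_gervini_steps(pca$eigenvalues, pca$n_obs, cap_factor)
  fit$dimension <- as.integer(select_dimension(fit, criterion))
  fit$criterion <- criterion
  fit
}
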