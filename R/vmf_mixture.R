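# von Mises-Fisher mixtures on the unit hypersphere, fit by EM.
#
# The vMF density on the (d-1)-sphere is
#   f(x; mu, kappa) = C_d(kappa) exp(kappa <mu, x>),
#   C_d(kappa) = kappa^(d/2-1) / ((2 pi)^(d/2) I_{d/2-1}(kappa)),
# the spherical analogue of an isotropic Gaussian: mu is the mean direction,
# kappa >= 0 the concentration (kappa = 0 is uniform). d = 1 degenerates to
# the two-point "sphere" {-1, +1} with f(x) = exp(kappa mu x) / (2 cosh kappa),
# which the same Bessel formula produces at order -1/2.

.kappa_max_default <- 1e5

# log C_d(kappa), numerically stable via the exponentially scaled Bessel
.log_vmf_const <- function(d, kappa) {
  if (kappa < 1e-10) {
    # uniform on S^{d-1}: minus the log surface area 2 pi^{d/2} / Gamma(d/2)
    return(lgamma(d / 2) - log(2) - (d / 2) * log(pi))
  }
  nu <- d / 2 - 1
  bi <- besselI(kappa, nu, expon.scaled = TRUE)
  nu * log(kappa) - (d / 2) * log(2 * pi) - (log(bi) + kappa)
}

#' von Mises-Fisher log density
#'
#' @param x unit vector, or matrix of unit row vectors.
#' @param mu unit mean direction (same dimension).
#' @param kappa nonnegative concentration.
#' @return Log density value(s).
#' @examples
#' vmf_logpdf(c(0, 1), c(0, 1), kappa = 5)
#' @export
vmf_logpdf <- function(x, mu, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  d <- length(mu)
  if (ncol(x) != d) stop("x and mu must have the same dimension")
  if (abs(sum(mu^2) - 1) > 1e-6) stop("mu must be a unit vector")
  nx <- sqrt(rowSums(x^2))
  if (any(abs(nx - 1) > 1e-6)) stop("x must contain unit vectors")
  drop(.log_vmf_const(d, kappa) + kappa * (x %*% mu))
}

#' Sample from a von Mises-Fisher distribution
#'
#' Wood's (1994) rejection sampler for the radial component, with a
#' Householder rotation taking the pole onto `mu`. `d = 1` reduces to a
#' two-point distribution on `{-1, +1}`.
#'
#' @param n number of draws.
#' @param mu unit mean direction.
#' @param kappa nonnegative concentration.
#' @return `n x length(mu)` matrix of unit row vectors.
#' @export
rvmf <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  d <- length(mu)
  mu <- mu / sqrt(sum(mu^2))
  if (d == 1L) {
    p <- 1 / (1 + exp(-2 * kappa))  # P(x = mu)
    return(matrix(ifelse(stats::runif(n) < p, mu, -mu), ncol = 1))
  }
  if (kappa < 1e-10) {
    z <- matrix(stats::rnorm(n * d), n, d)
    return(z / sqrt(rowSums(z^2)))
  }
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (d - 1) * log(1 - x0^2)
  w <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- stats::rbeta(m, (d - 1) / 2, (d - 1) / 2)
    ww <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- stats::runif(m)
    ok <- kappa * ww + (d - 1) * log(1 - x0 * ww) - c0 >= log(u)
    k <- sum(ok)
    if (k) w[(got + 1L):(got + k)] <- ww[ok]
    got <- got + k
  }
  v <- matrix(stats::rnorm(n * (d - 1)), n, d - 1)
  v <- v / sqrt(rowSums(v^2))
  out <- cbind(w, sqrt(pmax(1 - w^2, 0)) * v)
  # Householder reflection mapping e1 to mu
  e1 <- c(1, rep(0, d - 1))
  u <- e1 - mu
  nu2 <- sum(u^2)
  if (nu2 > 1e-12) {
    out <- out - 2 * (out %*% u) %*% t(u) / nu2
  }
  unname(out)
}

# spherical k-means++-style seeding: first centre at a random point, each
# subsequent centre drawn with probability proportional to the cosine
# dissimilarity to the nearest chosen centre
.vmf_seed_centres <- function(x, N) {
  P0 <- nrow(x)
  idx <- integer(N)
  idx[1] <- sample.int(P0, 1L)
  if (N > 1L) {
    sim <- x %*% t(x[idx[1], , drop = FALSE])
    for (k in 2:N) {
      dist <- pmax(1 - apply(sim, 1, max), 0)
      if (sum(dist) < 1e-12) {
        idx[k] <- sample.int(P0, 1L)
      } else {
        idx[k] <- sample.int(P0, 1L, prob = dist)
      }
      sim <- cbind(sim, x %*% t(x[idx[k], , drop = FALSE]))
    }
  }
  x[idx, , drop = FALSE]
}

# Banerjee et al. closed-form concentration estimate
.kappa_banerjee <- function(rbar, d, kappa_max) {
  if (rbar >= 1 - 1e-12) return(kappa_max)
  k <- (rbar * d - rbar^3) / (1 - rbar^2)
  min(max(k, 0), kappa_max)
}

# mean-resultant function A_d(kappa) = I_{d/2}(kappa) / I_{d/2-1}(kappa)
.vmf_Ad <- function(d, kappa) {
  besselI(kappa, d / 2, expon.scaled = TRUE) /
    besselI(kappa, d / 2 - 1, expon.scaled = TRUE)
}

# maximum-likelihood concentration: solve A_d(kappa) = rbar by Newton
# iterations from the Banerjee start; the exact solution keeps the M-step a
# true maximizer, which is what makes the EM log-likelihood monotone
.kappa_mle <- function(rbar, d, kappa_max) {
  if (rbar >= 1 - 1e-12) return(kappa_max)
  if (rbar < 1e-12) return(0)
  k <- min(max(.kappa_banerjee(rbar, d, kappa_max), 1e-8), kappa_max)
  for (i in 1:50) {
    A <- .vmf_Ad(d, k)
    Ap <- 1 - A^2 - (d - 1) / k * A
    knew <- k - (A - rbar) / Ap
    if (!is.finite(knew) || knew <= 0) knew <- k / 2
    knew <- min(knew, kappa_max)
    done <- abs(knew - k) < 1e-12 * (k + 1)
    k <- knew
    if (done || k >= kappa_max) break
  }
  min(max(k, 0), kappa_max)
}

.vmf_em_once <- function(x, N, max_iter, tol, kappa_max) {
  P0 <- nrow(x)
  d <- ncol(x)
  centres <- .vmf_seed_centres(x, N)
  # hard initial assignment to the nearest seed direction
  sim <- x %*% t(centres)
  gamma <- matrix(1e-6, P0, N)
  gamma[cbind(seq_len(P0), max.col(sim, ties.method = "first"))] <- 1
  gamma <- gamma / rowSums(gamma)

  mu <- matrix(0, N, d)
  kappa <- numeric(N)
  w <- numeric(N)
  ll <- -Inf
  trace <- numeric(0)
  degenerate <- FALSE

  for (it in seq_len(max_iter)) {
    nk <- colSums(gamma)
    if (any(nk < 1e-8)) {
      degenerate <- TRUE
      break
    }
    w <- nk / P0
    r <- t(x) %*% gamma            # d x N resultants
    rlen <- sqrt(colSums(r^2))
    for (k in seq_len(N)) {
      if (rlen[k] < 1e-12) {
        mu[k, ] <- c(1, rep(0, d - 1))
        kappa[k] <- 0
      } else {
        mu[k, ] <- r[, k] / rlen[k]
        kappa[k] <- .kappa_mle(rlen[k] / nk[k], d, kappa_max)
      }
    }
    logc <- vapply(kappa, function(kk) .log_vmf_const(d, kk), numeric(1))
    lp <- x %*% t(mu * kappa)      # P0 x N of kappa_k <mu_k, x_j>
    lp <- sweep(lp, 2, logc + log(w), `+`)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll_new <- sum(lse)
    gamma <- exp(lp - lse)
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  p_free <- N * d + (N - 1)
  list(mu = mu, kappa = kappa, weight = w, loglik = ll,
       bic = -2 * ll + p_free * log(P0),
       responsibilities = gamma, loglik_trace = trace,
       degenerate = degenerate, n_free_parameters = p_free)
}

#' Fit a von Mises-Fisher mixture by EM
#'
#' Expectation-maximization with soft responsibilities; mean directions are
#' normalized weighted resultants and concentrations solve the
#' maximum-likelihood equation `A_d(kappa) = rbar` by Newton iterations
#' started from the Banerjee closed form
#' `kappa = (rbar d - rbar^3) / (1 - rbar^2)`, capped at `kappa_max` (an
#' exact M-step keeps the log-likelihood nondecreasing across iterations).
#' The best of `n_starts` spherical k-means++-style initializations is
#' returned.
#'
#' @param points `P0 x d` matrix of unit row vectors.
#' @param n_components number of mixture components `N` (`1 <= N <= P0`).
#' @param n_starts random restarts (default 10).
#' @param seed optional RNG seed for reproducible restarts.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   relative log-likelihood change below `tol`.
#' @param kappa_max concentration ceiling.
#' @return An object of class `vmf_mixture_fit`: `components` (list of
#'   `mu`, `kappa`, `weight`), `loglik`, `bic`
#'   (`-2 loglik + (N d + N - 1) log(P0)`), `responsibilities`, `labels`
#'   (argmax responsibilities), and `loglik_trace` for the winning start.
#' @examples
#' set.seed(1)
#' pts <- rbind(rvmf(20, c(0, 1), 50), rvmf(20, c(0, -1), 50))
#' fit <- fit_vmf_mixture(pts, 2, seed = 1)
#' fit$bic
#' @export
fit_vmf_mixture <- function(points, n_components, n_starts = 10, seed = NULL,
                            max_iter = 200, tol = 1e-8,
                            kappa_max = .kappa_max_default) {
  x <- as.matrix(points)
  P0 <- nrow(x)
  d <- ncol(x)
  N <- as.integer(n_components)
  if (N < 1L) stop("need at least one component")
  if (N > P0) stop("n_components = ", N, " exceeds the number of points ", P0)
  nx <- sqrt(rowSums(x^2))
  if (any(abs(nx - 1) > 1e-6)) stop("points must be unit vectors")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  best_ok <- NULL
  for (s in seq_len(n_starts)) {
    fit <- .vmf_em_once(x, N, max_iter, tol, kappa_max)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (!fit$degenerate &&
        (is.null(best_ok) || fit$loglik > best_ok$loglik)) best_ok <- fit
  }
  if (!is.null(best_ok)) {
    best <- best_ok
  } else {
    # every restart collapsed a component: drop the empty ones
    warning("degenerate component(s) with vanishing weight dropped after ",
            n_starts, " restarts")
    keep <- colSums(best$responsibilities) >= 1e-8
    best$mu <- best$mu[keep, , drop = FALSE]
    best$kappa <- best$kappa[keep]
    best$weight <- best$weight[keep] / sum(best$weight[keep])
  }

  comps <- lapply(seq_along(best$kappa), function(k) {
    list(mu = best$mu[k, ], kappa = best$kappa[k], weight = best$weight[k])
  })
  structure(list(components = comps,
                 n_components = length(comps),
                 d = d,
                 loglik = best$loglik,
                 bic = best$bic,
                 n_free_parameters = best$n_free_parameters,
                 responsibilities = best$responsibilities,
                 labels = max.col(best$responsibilities,
                                  ties.method = "first"),
                 loglik_trace = best$loglik_trace),
            class = "vmf_mixture_fit")
}

#' @export
print.vmf_mixture_fit <- function(x, ...) {
  cat("vMF mixture:", x$n_components, "component(s) on S^", x$d - 1,
      " loglik ", signif(x$loglik, 6), " BIC ", signif(x$bic, 6), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a vMF mixture fit to JSON
#'
#' @param fit a `vmf_mixture_fit`.
#' @return A JSON string with per-component `mu`, `kappa`, `weight`, plus
#'   `loglik` and `bic`.
#' @export
vmf_fit_json <- function(fit) {
  stopifnot(inherits(fit, "vmf_mixture_fit"))
  jsonlite::toJSON(list(n_components = fit$n_components,
                        components = fit$components,
                        loglik = fit$loglik,
                        bic = fit$bic),
                   auto_unbox = TRUE, digits = NA)
}

#' Choose the number of clusters on the hypersphere by BIC
#'
#' Fits vMF mixtures for every candidate `N` in `D0, D0+1, ..., 2 D0 + 1`
#' (clipped to `[1, P0]`) and returns the `N` minimizing the BIC. At least
#' one cluster is expected per PC dimension; antipodal directions count as
#' separate clusters, which doubles the range, and the extra `+1` covers the
#' degenerate case `D0 = 0`, where there is a single cluster and no fitting
#' is attempted.
#'
#' @param points `P0 x D0` matrix of unit row vectors.
#' @param D0 PC dimension of the retained objects.
#' @param n_starts,seed,kappa_max passed to [fit_vmf_mixture()]; each
#'   candidate `N` gets a seed offset so fits are independent but
#'   reproducible.
#' @return list with `n_clusters` (the best `N`), `best_fit`, `fits`
#'   (one per candidate), and a `bic_table` data frame.
#' @export
choose_n_clusters <- function(points, D0, n_starts = 10, seed = NULL,
                              kappa_max = .kappa_max_default) {
  D0 <- as.integer(D0)
  if (D0 < 0L) stop("D0 must be nonnegative")
  if (D0 == 0L) {
    return(list(n_clusters = 1L, best_fit = NULL, fits = list(),
                bic_table = data.frame(N = integer(0), loglik = numeric(0),
                                       bic = numeric(0))))
  }
  x <- as.matrix(points)
  if (ncol(x) == 1L) {
    # one-dimensional loadings live on the two-point sphere {-1, +1}, where
    # a single vMF component already spans every possible distribution and
    # antipodal separation would be invisible to the BIC; embed the points
    # in the circle, where concentrated components are distinguishable
    x <- cbind(x, 0)
  }
  P0 <- nrow(x)
  Ns <- seq.int(max(1L, D0), max(1L, min(2L * D0 + 1L, P0)))
  fits <- vector("list", length(Ns))
  errs <- character(0)
  for (i in seq_along(Ns)) {
    si <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    fits[[i]] <- tryCatch(
      fit_vmf_mixture(x, Ns[i], n_starts = n_starts, seed = si,
                      kappa_max = kappa_max),
      error = function(e) {
        errs <<- c(errs, paste0("N = ", Ns[i], ": ", conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all mixture fits failed:\n", paste(errs, collapse = "\n"))
  }
  bic <- vapply(fits[ok], function(f) f$bic, numeric(1))
  ll <- vapply(fits[ok], function(f) f$loglik, numeric(1))
  best <- which.min(bic)
  list(n_clusters = as.integer(Ns[ok][best]),
       best_fit = fits[ok][[best]],
       fits = fits[ok],
       bic_table = data.frame(N = Ns[ok], loglik = ll, bic = bic))
}
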