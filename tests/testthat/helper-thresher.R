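# shared fixtures and independent oracles, all built in code

# matrix whose columns are exactly orthogonal, mean-zero, equal-norm:
# normalized Helmert contrasts embedded in n rows
centered_orthogonal_matrix <- function(n, P) {
  stopifnot(P < n)
  h <- stats::contr.helmert(n)[, seq_len(P), drop = FALSE]
  sweep(h, 2, sqrt(colSums(h^2)), `/`)
}

# brute-force MAP dimension over a fine theta grid, straight from the
# stored profile log-likelihood (independent of the breakpoint walk)
grid_map_dimension <- function(fit, thetas) {
  L <- fit$profile_loglik
  n <- fit$n_obs
  d <- seq_along(L) - 1
  vapply(thetas, function(th) d[which.max(L - th * n * d)], numeric(1))
}

# numeric quadrature of the vMF density over the circle
circle_vmf_mass <- function(mu, kappa) {
  stats::integrate(function(phi) {
    xs <- cbind(cos(phi), sin(phi))
    exp(vmf_logpdf(xs, mu, kappa))
  }, 0, 2 * pi, rel.tol = 1e-9)$value
}

random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rank-one signal plus small independent noise
rank1_noise_matrix <- function(n = 96, P = 24, sd = 0.3) {
  sig <- stats::rnorm(n)
  outer(sig, stats::runif(P, 0.8, 1.2)) + matrix(stats::rnorm(n * P, sd = sd), n, P)
}
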