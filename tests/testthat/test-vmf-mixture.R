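test_that("vMF log density: uniform limit, mode, and unit mass", {
  set.seed(30)
  mu <- c(0, 1)
  # kappa = 0 is uniform: the density no longer depends on x
  xs <- rvmf(20, mu, 0)
  lp <- vmf_logpdf(xs, mu, 0)
  expect_equal(lp, rep(-log(2 * pi), 20))

  # integrates to one on the circle
  for (kappa in c(0.5, 5, 50)) {
    expect_equal(circle_vmf_mass(mu, kappa), 1, tolerance = 1e-6)
  }

  # maximized at x = mu for kappa > 0
  expect_gt(vmf_logpdf(mu, mu, 3), max(vmf_logpdf(xs[1, , drop = FALSE],
                                                  mu, 3)))
  expect_error(vmf_logpdf(mu, mu, -1), "nonnegative")
  expect_error(vmf_logpdf(c(2, 0), mu, 1), "unit")

  # two-point sphere: mass sums to one
  p <- exp(vmf_logpdf(matrix(c(1, -1), 2, 1), 1, 2.5))
  expect_equal(sum(p), 1, tolerance = 1e-10)
})

test_that("Wood's sampler concentrates around the mean direction", {
  set.seed(31)
  mu <- c(1, 2, -2) / 3
  xs <- rvmf(500, mu, 50)
  expect_equal(unname(rowSums(xs^2)), rep(1, 500), tolerance = 1e-10)
  rbar <- colMeans(xs)
  expect_gt(sum(rbar * mu) / sqrt(sum(rbar^2)), 0.999)
})

test_that("EM: point-mass limit, restarts, and monotone log-likelihood", {
  pts <- matrix(rep(c(0.6, 0.8), each = 12), 12, 2)
  fit <- fit_vmf_mixture(pts, 1, seed = 1)
  expect_equal(fit$components[[1]]$mu, c(0.6, 0.8), tolerance = 1e-8)
  expect_equal(fit$components[[1]]$kappa, 1e5)

  set.seed(32)
  x <- rbind(rvmf(40, c(1, 0, 0), 5), rvmf(40, c(0, 1, 0), 8))
  f1 <- fit_vmf_mixture(x, 3, n_starts = 1, seed = 7)
  f5 <- fit_vmf_mixture(x, 3, n_starts = 5, seed = 7)
  expect_gte(f5$loglik, f1$loglik - 1e-8)

  # loglik trace nondecreasing for every fit
  for (f in list(f1, f5, fit)) {
    expect_true(all(diff(f$loglik_trace) >= -1e-8 *
                      (abs(f$loglik_trace[-length(f$loglik_trace)]) + 1)))
  }
  expect_error(fit_vmf_mixture(x, 100), "exceeds")
})

test_that("antipodal bundles are recovered within five degrees", {
  set.seed(33)
  mu <- c(cos(0.7), sin(0.7))
  x <- rbind(rvmf(50, mu, 50), rvmf(50, -mu, 50))
  fit <- fit_vmf_mixture(x, 2, seed = 9)
  mus <- t(vapply(fit$components, `[[`, numeric(2), "mu"))
  cosines <- abs(mus %*% mu)
  expect_true(all(cosines > cos(5 * pi / 180)))
})

test_that("mixture fit is invariant under rotations of the sphere", {
  set.seed(34)
  x <- rbind(rvmf(30, c(1, 0, 0), 20), rvmf(30, c(0, 0, 1), 20))
  q <- random_rotation(3)
  f0 <- fit_vmf_mixture(x, 2, seed = 5)
  fr <- fit_vmf_mixture(x %*% t(q), 2, seed = 5)
  expect_equal(fr$loglik, f0$loglik, tolerance = 1e-6)
  # same partition up to component relabelling
  tab <- table(f0$labels, fr$labels)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("single-component parameters are recovered across seeds", {
  mu <- c(0, 0, 1)
  ok_mu <- logical(20)
  ok_kappa <- logical(20)
  for (s in 1:20) {
    set.seed(300 + s)
    x <- rvmf(200, mu, 20)
    fit <- fit_vmf_mixture(x, 1, seed = s)
    ok_mu[s] <- sum(fit$components[[1]]$mu * mu) > 0.99
    ok_kappa[s] <- abs(fit$components[[1]]$kappa - 20) / 20 < 0.25
  }
  expect_true(all(ok_mu))
  expect_true(all(ok_kappa))
})

test_that("BIC equals its definition from the stored log-likelihood", {
  set.seed(35)
  x <- rbind(rvmf(25, c(1, 0, 0), 10), rvmf(25, c(-1, 0, 0), 10))
  for (N in 1:3) {
    fit <- fit_vmf_mixture(x, N, seed = N)
    p_N <- N * ncol(x) + (N - 1)
    expect_identical(fit$n_free_parameters, p_N)
    expect_equal(fit$bic, -2 * fit$loglik + p_N * log(nrow(x)),
                 tolerance = 1e-10)
  }
})

test_that("BIC model selection respects the dimension-driven range", {
  # D0 = 0: one cluster, no fitting
  cn0 <- choose_n_clusters(matrix(1, 5, 1), 0)
  expect_identical(cn0$n_clusters, 1L)
  expect_length(cn0$fits, 0)

  # D0 = 1 antipodal data selects two clusters in >= 90% of replicates
  set.seed(36)
  picks <- replicate(100, {
    sizes <- sample(8:16, 2)
    pts <- matrix(c(rep(1, sizes[1]), rep(-1, sizes[2])), ncol = 1)
    suppressWarnings(
      choose_n_clusters(pts, 1, n_starts = 5,
                        seed = sample.int(1e6, 1))$n_clusters)
  })
  expect_gte(mean(picks == 2), 0.9)

  # candidate range is D0..2 D0 + 1
  set.seed(37)
  x <- rbind(rvmf(30, c(1, 0), 30), rvmf(30, c(0, 1), 30))
  cn <- suppressWarnings(choose_n_clusters(x, 2, n_starts = 3, seed = 4))
  expect_true(all(cn$bic_table$N %in% 2:5))
  expect_equal(cn$bic_table$bic,
               -2 * cn$bic_table$loglik +
                 (cn$bic_table$N * 2 + cn$bic_table$N - 1) * log(60),
               tolerance = 1e-10)
  expect_identical(cn$n_clusters, 2L)
})
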