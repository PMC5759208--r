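test_that("eigen-spectrum matches direct eigendecomposition and edge cases", {
  # orthogonal, centred, equal-norm columns: correlation is the identity
  x <- centered_orthogonal_matrix(30, 8)
  expect_equal(unname(eigen_spectrum(x)), rep(1, 8), tolerance = 1e-10)

  # rank one: every column a multiple of one column
  set.seed(11)
  base <- rnorm(25)
  x1 <- outer(base, c(1, 2, -0.5, 3, 1.5))
  lam <- eigen_spectrum(x1)
  expect_equal(lam[1], 5, tolerance = 1e-10)
  expect_true(all(lam[-1] < 1e-8))

  # random matrix against an independent dense eigendecomposition
  set.seed(12)
  xr <- matrix(rnorm(200), 20, 10)
  oracle <- eigen(cor(xr), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(eigen_spectrum(xr)), oracle, tolerance = 1e-8)
})

test_that("step function follows the brute-force theta-grid MAP oracle", {
  fits <- list(
    auer_gervini_steps(c(10, 1, 1, 1, 1), n_obs = 50),
    auer_gervini_steps(eigen_spectrum(matrix(rnorm(96 * 12), 96, 12)),
                       n_obs = 96),
    {
      set.seed(13)
      ds <- sample_mvn(fig1_preset(6, 24), 96)
      auer_gervini_steps(eigen_spectrum(ds$data), n_obs = 96)
    })
  for (fit in fits) {
    grid <- seq(0, fit$theta_max, length.out = 4001)
    dhat <- grid_map_dimension(fit, grid)
    # nonincreasing in theta
    expect_true(all(diff(dhat) <= 0))
    # away from the breakpoints, the analytic step function (dimension held
    # between consecutive breakpoints) agrees with the brute-force argmax
    bp <- sort(fit$theta_breakpoints)
    dims_desc <- fit$dims_visited          # dimensions in decreasing order
    analytic <- dims_desc[findInterval(grid, bp, left.open = TRUE) + 1L]
    safe <- vapply(grid, function(th) {
      length(bp) == 0 || min(abs(th - bp)) > diff(grid)[1]
    }, logical(1))
    expect_identical(dhat[safe], as.numeric(analytic[safe]))
    # and the step lengths are the interval widths between breakpoints
    widths <- diff(c(0, bp, fit$theta_max))
    expect_equal(unname(fit$step_lengths[as.character(dims_desc)]),
                 widths, tolerance = 1e-10)
  }
})

test_that("spectrum shape drives the step lengths", {
  # strong first eigenvalue: dimension 1 holds the dominant interval
  fit <- auer_gervini_steps(c(10, 1, 1, 1, 1), n_obs = 50)
  s <- fit$step_lengths
  expect_gt(s["1"], max(s[as.character(2:4)]))

  # isotropic spectrum: only dimension 0 has a positive step
  fit0 <- auer_gervini_steps(rep(2, 6), n_obs = 40)
  expect_gt(fit0$step_lengths["0"], 0)
  expect_true(all(fit0$step_lengths[-1] == 0))

  expect_error(auer_gervini_steps(c(1, 2, 3), 50), "nonincreasing")
  expect_error(auer_gervini_steps(c(3, 2, 1), 1), "n_obs")
})

test_that("TwiceMean and CPT call the long steps as specified", {
  # the long step belongs to dimension 0: pure-noise spectrum shape
  expect_identical(as.integer(select_dimension(c(`0` = 100, `1` = 1, `2` = 1))),
                   0L)
  # hand-computed: mean 13.5, cutoff 27, long set {1}
  D <- select_dimension(c(`0` = 2, `1` = 50, `2` = 1, `3` = 1))
  expect_identical(as.integer(D), 1L)
  expect_identical(unname(which(attr(D, "long"))), 2L)
  # identical steps: nothing reaches twice the mean
  expect_identical(as.integer(select_dimension(rep(5, 4))), 0L)
  # a long step at dimension 0 alone still yields D = 0
  expect_identical(as.integer(select_dimension(c(3, 1, 0, 0))), 0L)
  # ties at exactly twice the mean count as long: steps (0,2,1,1), mean 1
  expect_identical(as.integer(select_dimension(c(0, 2, 1, 1))), 1L)

  # CPT: sorted (1,1,2,50) splits below 50
  expect_identical(as.integer(select_dimension(c(`0` = 2, `1` = 50, `2` = 1,
                                                 `3` = 1), "CPT")), 1L)
  # flat steps give no change point
  expect_identical(as.integer(select_dimension(rep(1, 5), "CPT")), 0L)
  expect_warning(D1 <- select_dimension(c(`0` = 1)), "fewer than 2")
  expect_identical(as.integer(D1), 0L)
})

test_that("selected dimension does not depend on which margin is n_obs", {
  # the margin-free claim: the standardized matrix has one singular
  # spectrum; swapping the roles of variables and objects only swaps n_obs,
  # and the breakpoints are invariant because the penalty scales with n
  set.seed(14)
  for (i in 1:20) {
    n <- sample(c(24, 48, 96), 1)
    P <- sample(c(8, 12, 24), 1)
    x <- if (i %% 2) matrix(rnorm(n * P), n, P) else
      sample_mvn(fig1_preset(sample(c(3, 6, 11, 15), 1), 24), n)$data$values
    lam <- eigen_spectrum(x)
    f1 <- auer_gervini_steps(lam, n_obs = nrow(x))
    f2 <- auer_gervini_steps(lam, n_obs = ncol(x))
    for (crit in c("TwiceMean", "CPT")) {
      expect_identical(as.integer(select_dimension(f1, crit)),
                       as.integer(select_dimension(f2, crit)))
    }
  }
})

test_that("pure noise gives D = 0 and a planted rank-1 signal gives D = 1", {
  set.seed(15)
  spec1 <- fig1_preset(1, 24)
  d_noise <- replicate(200, {
    pc_dimension(sample_mvn(spec1, 96)$data)$dimension
  })
  expect_gte(mean(d_noise == 0), 0.9)

  set.seed(16)
  d_sig <- replicate(200, pc_dimension(rank1_noise_matrix())$dimension)
  expect_gte(mean(d_sig == 1), 0.9)
})
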