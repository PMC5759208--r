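test_that("correlation specs imply valid matrices and truth labels", {
  sp <- correlation_spec(c(5, 5), within_corr = 0.8, between_corr = 0.1,
                         n_noise = 2)
  expect_equal(diag(sp$matrix), rep(1, 12))
  expect_true(isSymmetric(sp$matrix))
  expect_identical(sp$k_true, 2L)
  expect_identical(sum(!sp$truth_good), 2L)

  # signed block: two directional clusters
  sps <- correlation_spec(6, 0.8, sign_pattern = "signed")
  expect_identical(sps$k_true, 2L)
  expect_equal(sps$matrix[1, 6], -0.8)
  expect_equal(sps$matrix[1, 2], 0.8)

  # between-group correlation exceeding within-group breaks PSD
  expect_error(correlation_spec(c(3, 3), 0.1, between_corr = 0.9),
               "positive semidefinite")
})

test_that("sampled data reproduce the specified correlations", {
  sp <- correlation_spec(8, 0.8)
  ds <- sample_mvn(sp, 5000, seed = 51)
  emp <- cor(ds$data$values)
  off <- emp[upper.tri(emp)]
  expect_lt(max(abs(off - 0.8)), 0.05)

  # noise-only structure: mean absolute correlation near zero
  dn <- sample_mvn(fig1_preset(1, 24), 5000, seed = 52)
  en <- cor(dn$data$values)
  expect_lt(mean(abs(en[upper.tri(en)])), 0.03)

  # signed block: cross-half correlations near -0.8
  dsg <- sample_mvn(correlation_spec(10, 0.8, sign_pattern = "signed"),
                    5000, seed = 53)
  eg <- cor(dsg$data$values)
  expect_lt(max(abs(eg[1:5, 6:10] + 0.8)), 0.05)
})

test_that("sampling is bit-reproducible under a fixed seed", {
  sp <- fig1_preset(6, 24)
  a <- sample_mvn(sp, 96, seed = 54)
  b <- sample_mvn(sp, 96, seed = 54)
  expect_identical(a$data$values, b$data$values)

  d1 <- cutoff_protocol_dataset("mixed", seed = 55)
  d2 <- cutoff_protocol_dataset("mixed", seed = 55)
  expect_identical(d1$data$values, d2$data$values)
})

test_that("the calibration protocol matches its printed recipe", {
  set.seed(56)
  ktab <- c(one_unsigned = 1L, one_signed = 2L, two_unsigned = 2L,
            two_signed = 4L, mixed = 3L)
  for (kind in protocol_kinds()) {
    for (i in 1:20) {
      ds <- cutoff_protocol_dataset(kind)
      # exactly two noise objects, appended last
      expect_identical(sum(!ds$truth_good), 2L)
      P <- ds$params$n_objects - 2L
      expect_true(P %in% seq(10L, 20L, 2L))
      expect_gte(ds$params$n_variables, 30L)
      expect_gt(ds$params$corr, 0.05)
      expect_lt(ds$params$corr, 0.95)
      expect_identical(ds$k_true, ktab[[kind]])
    }
  }
})

test_that("the sixteen presets are valid and cover the documented cases", {
  for (idx in 1:16) {
    for (P in c(24, 96)) {
      sp <- fig1_preset(idx, P)
      expect_equal(diag(sp$matrix), rep(1, P))
      ev <- eigen(sp$matrix, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
    }
  }
  expect_identical(fig1_preset(1, 24)$k_true, 0L)
  expect_true(all(fig1_preset(1, 24)$matrix[upper.tri(diag(24))] == 0))
  p3 <- fig1_preset(3, 24)
  expect_identical(p3$k_true, 1L)
  expect_equal(p3$matrix[1, 24], 0.8)
  # half noise in the outlier-heavy structures
  expect_identical(sum(!fig1_preset(9, 24)$truth_good), 12L)
  expect_identical(sum(!fig1_preset(10, 96)$truth_good), 48L)
  expect_error(fig1_preset(17, 24), "1..16")
  expect_error(fig1_preset(2, 25), "multiple of 12")
})
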