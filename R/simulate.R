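# Synthetic data generators: block-correlation MVN datasets and the
# cutoff-calibration protocol.
#
# Every dataset is drawn as n_variables i.i.d. rows from MVN(mu, Sigma),
# where Sigma = sigma^2 * C and C is a block correlation matrix over the
# objects (the MVN coordinates). A per-dataset mean vector mu with standard
# normal coordinates shifts each object's location; correlations between
# objects are unaffected. "Signed" signals split a block into anticorrelated
# halves: within-half correlation +r, across-half -r, which is exactly a
# rank-one block with a sign vector.

#' Correlation-structure specification
#'
#' @param block_sizes positive integers, one per signal block.
#' @param within_corr within-block correlation, recycled per block.
#' @param between_corr correlation between objects of different blocks
#'   (single number, default 0).
#' @param sign_pattern `"unsigned"` or `"signed"` per block (recycled). A
#'   signed block has its first half positively and second half negatively
#'   loaded, giving within-half correlation `+within_corr` and cross-half
#'   `-within_corr`; it contributes two directional clusters.
#' @param n_noise number of uncorrelated noise objects appended after the
#'   blocks.
#' @param sigma2 marginal variance (default 1).
#' @return An object of class `correlation_spec` with the implied `matrix`
#'   (unit diagonal, PSD-checked), per-object `signs`, `truth_good`,
#'   `truth_cluster` (0 for noise) and `k_true`.
#' @examples
#' sp <- correlation_spec(c(5, 5), within_corr = 0.8, between_corr = 0.1)
#' sp$k_true
#' @export
correlation_spec <- function(block_sizes, within_corr, between_corr = 0,
                             sign_pattern = "unsigned", n_noise = 0,
                             sigma2 = 1) {
  block_sizes <- as.integer(block_sizes)
  nb <- length(block_sizes)
  if (nb > 0 && any(block_sizes < 1L)) stop("block sizes must be positive")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  within_corr <- rep_len(within_corr, nb)
  sign_pattern <- rep_len(sign_pattern, nb)
  if (nb > 0 && !all(sign_pattern %in% c("unsigned", "signed"))) {
    stop("sign_pattern entries must be 'unsigned' or 'signed'")
  }
  P <- sum(block_sizes) + n_noise
  if (P < 2L) stop("need at least 2 objects in total")

  block_id <- rep.int(seq_len(nb), block_sizes)
  block_id <- c(block_id, rep.int(0L, n_noise))
  signs <- rep.int(1, P)
  cluster <- integer(P)
  next_cluster <- 1L
  for (b in seq_len(nb)) {
    idx <- which(block_id == b)
    if (sign_pattern[b] == "signed") {
      neg <- idx[(ceiling(length(idx) / 2) + 1L):length(idx)]
      signs[neg] <- -1
      cluster[idx] <- ifelse(signs[idx] > 0, next_cluster, next_cluster + 1L)
      next_cluster <- next_cluster + 2L
    } else {
      cluster[idx] <- next_cluster
      next_cluster <- next_cluster + 1L
    }
  }

  C <- diag(1, P)
  for (b in seq_len(nb)) {
    ib <- which(block_id == b)
    C[ib, ib] <- within_corr[b] * tcrossprod(signs[ib])
    for (b2 in seq_len(nb)) {
      if (b2 != b) {
        ic <- which(block_id == b2)
        C[ib, ic] <- between_corr * tcrossprod(signs[ib], signs[ic])
      }
    }
  }
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied correlation matrix is not positive semidefinite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  }

  structure(list(block_sizes = block_sizes,
                 within_corr = within_corr,
                 between_corr = between_corr,
                 sign_pattern = sign_pattern,
                 n_noise = as.integer(n_noise),
                 sigma2 = sigma2,
                 matrix = C,
                 signs = signs,
                 block_id = block_id,
                 truth_good = block_id > 0L,
                 truth_cluster = cluster,
                 k_true = max(cluster, 0L)),
            class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat("correlation_spec:", length(x$block_sizes), "block(s),",
      x$n_noise, "noise object(s),", ncol(x$matrix), "objects,",
      "k_true =", x$k_true, "\n")
  invisible(x)
}

#' Sample a multivariate-normal dataset from a correlation specification
#'
#' @param spec a `correlation_spec`.
#' @param n_variables number of i.i.d. MVN draws (rows).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used, so enclosing loops stay reproducible under one outer seed.
#' @return An object of class `simulated_dataset`: `data` (a
#'   `data_matrix`), `truth_good`, `truth_cluster`, `k_true`, `spec`.
#' @export
sample_mvn <- function(spec, n_variables, seed = NULL) {
  stopifnot(inherits(spec, "correlation_spec"))
  if (n_variables < 2) stop("need at least 2 variables")
  if (!is.null(seed)) set.seed(seed)
  P <- ncol(spec$matrix)
  mu <- stats::rnorm(P)
  x <- MASS::mvrnorm(n_variables, mu = mu, Sigma = spec$sigma2 * spec$matrix)
  dm <- data_matrix(x)
  structure(list(data = dm,
                 truth_good = spec$truth_good,
                 truth_cluster = spec$truth_cluster,
                 k_true = spec$k_true,
                 spec = spec),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", nrow(x$data$values), "variables x",
      ncol(x$data$values), "objects, k_true =", x$k_true, ",",
      sum(!x$truth_good), "noise object(s)\n")
  invisible(x)
}

#' The five signal kinds of the cutoff-calibration protocol
#'
#' @return Character vector of the five kinds: one or two signals, each
#'   either unsigned (all positively correlated) or signed (roughly half
#'   negatively correlated), plus the mixed two-signal case.
#' @export
protocol_kinds <- function() {
  c("one_unsigned", "one_signed", "two_unsigned", "two_signed", "mixed")
}

#' Simulate one dataset of the cutoff-calibration protocol
#'
#' The generating protocol: the number of variables is drawn from
#' `round(Normal(300, 60))` (floored at 30); an even number of objects is
#' drawn uniformly from \{10, 12, ..., 20\}; the objects are split roughly
#' in half into two groups, and independently split in half into a positive
#' and a negative arm; a correlation coefficient is drawn from
#' `Normal(0.5, 0.1)` (truncated to (0.05, 0.95)); the dataset is built for
#' the requested signal kind; finally two standard-normal noise objects are
#' appended to play the role of outliers.
#'
#' @param kind one of [protocol_kinds()] (or its index 1-5).
#' @param seed optional integer seed (see [sample_mvn()]).
#' @return A `simulated_dataset`; exactly two objects have
#'   `truth_good = FALSE`.
#' @export
cutoff_protocol_dataset <- function(kind = protocol_kinds(), seed = NULL) {
  if (is.numeric(kind)) kind <- protocol_kinds()[kind]
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)

  n_variables <- max(30L, as.integer(round(stats::rnorm(1, 300, 60))))
  P <- sample(seq(10L, 20L, by = 2L), 1L)
  repeat {
    r <- stats::rnorm(1, 0.5, 0.1)
    if (r > 0.05 && r < 0.95) break
  }
  two <- kind %in% c("two_unsigned", "two_signed", "mixed")
  group <- rep.int(1L, P)
  if (two) {
    group[sample.int(P, floor(P / 2))] <- 2L
  }
  sgn <- rep.int(1, P)
  sgn[sample.int(P, floor(P / 2))] <- -1
  signed_groups <- switch(kind,
                          one_unsigned = integer(0),
                          one_signed = 1L,
                          two_unsigned = integer(0),
                          two_signed = c(1L, 2L),
                          mixed = 2L)
  sgn[!(group %in% signed_groups)] <- 1

  C <- diag(1, P + 2L)
  for (g in unique(group)) {
    idx <- which(group == g)
    C[idx, idx] <- r * tcrossprod(sgn[idx])
  }
  diag(C) <- 1

  mu <- stats::rnorm(P + 2L)
  x <- MASS::mvrnorm(n_variables, mu = mu, Sigma = C)
  dm <- data_matrix(x)

  cluster <- integer(P + 2L)
  nxt <- 1L
  for (g in unique(group)) {
    idx <- which(group == g)
    if (any(sgn[idx] < 0)) {
      cluster[idx] <- ifelse(sgn[idx] > 0, nxt, nxt + 1L)
      nxt <- nxt + 2L
    } else {
      cluster[idx] <- nxt
      nxt <- nxt + 1L
    }
  }
  structure(list(data = dm,
                 truth_good = c(rep(TRUE, P), FALSE, FALSE),
                 truth_cluster = cluster,
                 k_true = max(cluster),
                 kind = kind,
                 params = list(n_variables = n_variables, n_objects = P + 2L,
                               corr = r)),
            class = "simulated_dataset")
}

#' Block-correlation presets covering sixteen benchmark structures
#'
#' A parameterized family of correlation structures used in the Monte Carlo
#' benchmarks: pure noise (1), single homogeneous blocks at 0.3 / 0.8
#' (2-3), multi-block structures with within-group correlation in
#' \{0.8, 0.3\} and between-group correlation in \{0.3, 0.1, 0\} (4-8),
#' structures with a large proportion (half) of noise objects (9-10), and
#' signed / mixed variants at strength 0.8 or 0.3 (11-16). The block
#' layouts beyond the first three structures are this package's documented
#' defaults (equal-size blocks); they are one reasonable realization of the
#' family, not replicas of a specific layout.
#'
#' @param index preset index, 1 to 16.
#' @param n_objects total number of objects (24 or 96 in the benchmarks;
#'   any multiple of 12 works with the default layouts).
#' @return A `correlation_spec`.
#' @examples
#' fig1_preset(3, 24)$k_true  # one strong unsigned block
#' @export
fig1_preset <- function(index, n_objects = 24) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > 16L) {
    stop("preset index must be in 1..16")
  }
  P <- as.integer(n_objects)
  if (P < 12L || P %% 12L != 0L) {
    stop("n_objects must be a positive multiple of 12")
  }
  half <- P %/% 2L
  quarter <- P %/% 4L
  switch(index,
    correlation_spec(integer(0), numeric(0), n_noise = P),                  # 1
    correlation_spec(P, 0.3),                                               # 2
    correlation_spec(P, 0.8),                                               # 3
    correlation_spec(c(half, half), 0.8, between_corr = 0.3),               # 4
    correlation_spec(c(half, half), 0.8, between_corr = 0.1),               # 5
    correlation_spec(c(half, half), 0.8, between_corr = 0),                 # 6
    correlation_spec(rep((P - P %/% 12L) %/% 4L, 4),
                     c(0.8, 0.8, 0.3, 0.3), between_corr = 0.1,
                     n_noise = P - 4L * ((P - P %/% 12L) %/% 4L)),          # 7
    correlation_spec(rep((P - P %/% 12L) %/% 4L, 4), 0.3, between_corr = 0,
                     n_noise = P - 4L * ((P - P %/% 12L) %/% 4L)),          # 8
    correlation_spec(half, 0.8, n_noise = P - half),                        # 9
    correlation_spec(c(quarter, quarter), 0.8, between_corr = 0,
                     n_noise = P - 2L * quarter),                           # 10
    correlation_spec(P, 0.8, sign_pattern = "signed"),                      # 11
    correlation_spec(P, 0.3, sign_pattern = "signed"),                      # 12
    correlation_spec(c(half, half), 0.8, sign_pattern = "signed"),          # 13
    correlation_spec(c(half, half), 0.3, sign_pattern = "signed"),          # 14
    correlation_spec(c(half, half), 0.8,
                     sign_pattern = c("unsigned", "signed")),               # 15
    correlation_spec(c(half, half), 0.3,
                     sign_pattern = c("unsigned", "signed"))                # 16
  )
}
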