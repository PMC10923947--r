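# Independent re-implementation of the tuning-drift surrogate used as a
# Monte-Carlo oracle: same model, written separately from the package path.
oracle_drift_curves <- function(tunings, p_drift, noise_sd, n_sessions,
                                limit = 10) {
  n <- nrow(tunings)
  cum <- rep(0, n)
  noise <- matrix(0, n, ncol(tunings))
  r_mean <- numeric(n_sessions)
  r_mean[1] <- 1
  for (s in 2:n_sessions) {
    for (ci in seq_len(n)) {
      if (runif(1) < p_drift)
        cum[ci] <- cum[ci] + if (abs(cum[ci]) > limit)
          sample(c(-1, 1), 1) else 1
    }
    noise <- noise + matrix(rnorm(length(noise), 0, noise_sd), n,
                            ncol(tunings))
    rs <- vapply(seq_len(n), function(ci) {
      shifted <- tunings[ci, ]
      k <- ((cum[ci] %% 20) + 20) %% 20
      if (k > 0) shifted <- c(shifted[(20 - k + 1):20], shifted[1:(20 - k)])
      cor(tunings[ci, ], shifted + noise[ci, ])
    }, numeric(1))
    r_mean[s] <- mean(rs, na.rm = TRUE)
  }
  r_mean
}

ref_tunings <- function(n, seed = 21) {
  set.seed(seed)
  centers <- sample(20, n, replace = TRUE)
  t(vapply(centers, function(cc) {
    d <- pmin(abs(1:20 - cc), 20 - abs(1:20 - cc))
    exp(-0.5 * (d / 2)^2)
  }, numeric(20)))
}

test_that("drift surrogate honors its identity limits", {
  tun <- ref_tunings(15)
  out <- simulate_tuning_drift(tun, drift_config(p_drift = 0, noise_sd = 0,
                                                 n_sessions = 6), seed = 1)
  for (s in 2:6) expect_identical(out[[s]], out[[1]])

  # p_drift = 1 on a delta tuning: peak advances exactly 1 bin/session
  delta <- matrix(0, 1, 20); delta[1, 5] <- 1
  out1 <- simulate_tuning_drift(delta,
                                drift_config(p_drift = 1, noise_sd = 0,
                                             n_sessions = 13), seed = 2)
  for (s in 1:12)
    expect_equal(which.max(out1[[s]]), ((5 + s - 1 - 1) %% 20) + 1)
  # cumulative shift is 11 at session 12; the regularization makes the
  # session-13 step random -1/+1
  expect_equal(attr(out1, "cumulative_shift") %in% c(10, 12), TRUE)
})

test_that("drift surrogate decay matches an independent Monte-Carlo oracle", {
  tun <- ref_tunings(1500)
  cfg <- drift_config(p_drift = 0.5, noise_sd = 0.2, n_sessions = 6)
  out <- simulate_tuning_drift(tun, cfg, seed = 3)
  got <- vapply(1:6, function(s) {
    mean(vapply(seq_len(nrow(tun)), function(ci)
      cor(out[[1]][ci, ], out[[s]][ci, ]), numeric(1)), na.rm = TRUE)
  }, numeric(1))
  set.seed(99)
  want <- oracle_drift_curves(tun, 0.5, 0.2, 6)
  expect_lt(max(abs(got - want)), 0.03)
})

test_that("cross-day correlation pools directions and neurons", {
  s <- fix_two_days()$sessions
  tun1 <- session_tuning(s[[1]]); tun2 <- session_tuning(s[[2]])
  cc_self <- cross_day_correlation(tun1, tun1)
  expect_equal(cc_self$pooled, 1)
  cc <- cross_day_correlation(tun1, tun2)
  expect_true(cc$pooled > 0.7 && cc$pooled <= 1)
  expect_equal(dim(cc$per_neuron), c(nrow(s[[1]]$z), 2))

  # p_drift = 1 surrogate 10 sessions out equals the 10-bin shift oracle
  tun <- ref_tunings(300)
  out <- simulate_tuning_drift(tun, drift_config(p_drift = 1, noise_sd = 0,
                                                 n_sessions = 11), seed = 4)
  as_tun <- function(m) list(left = list(values = m, raw = m,
                                         occupancy = rep(0.05, 20)))
  got <- cross_day_correlation(as_tun(out[[1]]), as_tun(out[[11]]))$pooled
  oracle <- mean(vapply(seq_len(nrow(tun)), function(ci)
    cor(tun[ci, ], c(tun[ci, 11:20], tun[ci, 1:10])), numeric(1)))
  expect_lt(abs(got - oracle), 0.05)
})

test_that("shuffled-identity null behaves like chance and is reproducible", {
  # exhaustive 2-neuron case: the only fixed-point-free permutation is the
  # swap, so the null equals the swapped correlation exactly
  m1 <- rbind(ref_tunings(1, 31), ref_tunings(1, 32))
  m2 <- rbind(ref_tunings(1, 33), ref_tunings(1, 34))
  tun1 <- list(left = list(values = m1, raw = m1, occupancy = rep(0.05, 20)))
  tun2 <- list(left = list(values = m2, raw = m2, occupancy = rep(0.05, 20)))
  swap <- tun1; swap$left$values <- m1[2:1, ]; swap$left$raw <- m1[2:1, ]
  r_sw <- cross_day_correlation(swap, tun2)$pooled
  got <- shuffled_cross_day(tun1, tun2, n_iter = 20, seed = 5)
  expect_equal(got, r_sw, tolerance = 1e-12)

  # homogeneous population: shuffle equals the data value exactly
  mh <- ref_tunings(1, 35)[rep(1, 6), ]
  tunh <- list(left = list(values = mh, raw = mh, occupancy = rep(0.05, 20)))
  expect_equal(shuffled_cross_day(tunh, tunh, n_iter = 10, seed = 6),
               cross_day_correlation(tunh, tunh)$pooled)

  expect_identical(shuffled_cross_day(tun1, tun2, n_iter = 50, seed = 7),
                   shuffled_cross_day(tun1, tun2, n_iter = 50, seed = 7))

  # null sampling: random 20-bin maps correlate near zero on average
  set.seed(10)
  rs <- replicate(1000, cor(rnorm(20), rnorm(20)))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("edge-angle matrices match the brute-force oracle and invariances", {
  set.seed(11)
  for (nd in c(2, 5, 10)) {
    pv <- matrix(rnorm(nd * 6), nd, 6)
    A <- edge_angle_matrix(pv)
    expect_equal(dim(A), c(6, 10))
    expect_true(all(A >= 0 & A <= pi))
    expect_equal(A, oracle_edge_angles(pv), tolerance = 1e-9)

    # rigid rotation invariance
    Q <- qr.Q(qr(matrix(rnorm(nd * nd), nd)))
    expect_equal(edge_angle_matrix(Q %*% pv), A, tolerance = 1e-9)
    # scale invariance
    expect_equal(edge_angle_matrix(3.7 * pv), A, tolerance = 1e-9)
  }

  # regular 5-simplex: every corner angle is arccos(1/2) = pi/3
  simplex <- diag(6)[, 1:6]
  A_s <- edge_angle_matrix(simplex[1:6, ])
  expect_equal(A_s, matrix(pi / 3, 6, 10), tolerance = 1e-9)

  pv_bad <- matrix(rnorm(12), 2, 6); pv_bad[, 3] <- pv_bad[, 1]
  expect_error(edge_angle_matrix(pv_bad), "coincident")
})

test_that("edge-angle dissimilarity is a Frobenius pseudo-distance", {
  set.seed(12)
  A <- matrix(runif(60, 0, pi), 6, 10)
  expect_equal(edge_angle_dissimilarity(A, A), 0)
  B <- A; B[3, 4] <- B[3, 4] + 0.25
  expect_equal(edge_angle_dissimilarity(A, B), 0.25)
  C <- matrix(runif(60, 0, pi), 6, 10)
  expect_equal(edge_angle_dissimilarity(A, C),
               sqrt(sum((A - C)^2)), tolerance = 1e-12)
  # symmetry and triangle inequality on random triples
  for (i in 1:20) {
    x <- matrix(runif(60), 6, 10); y <- matrix(runif(60), 6, 10)
    z <- matrix(runif(60), 6, 10)
    expect_equal(edge_angle_dissimilarity(x, y),
                 edge_angle_dissimilarity(y, x))
    expect_lte(edge_angle_dissimilarity(x, z),
               edge_angle_dissimilarity(x, y) +
                 edge_angle_dissimilarity(y, z) + 1e-12)
  }
  expect_error(edge_angle_dissimilarity(A, A[1:5, ]), "mismatch")
})

test_that("normalized dissimilarity interpolates within and shuffled bounds", {
  expect_equal(normalized_dissimilarity(1.2, 1.2, 3), 0)
  expect_equal(normalized_dissimilarity(3, 1.2, 3), 1)
  expect_error(normalized_dissimilarity(2, 3, 2.5), "degenerate")
})

test_that("population vectors assemble per direction and reference bin", {
  raw_l <- rbind(c(1:20), c(20:1)) * 0.1
  raw_r <- rbind(seq(2, 4, length.out = 20), seq(5, 1, length.out = 20))
  tun <- list(left = list(values = raw_l, raw = raw_l,
                          occupancy = rep(0.05, 20)),
              right = list(values = raw_r, raw = raw_r,
                           occupancy = rep(0.05, 20)))
  pv <- population_vectors(tun)
  expect_equal(dim(pv), c(2, 6))
  expect_equal(pv[, "left.start"], c(0.1, 2.0))
  expect_equal(pv[, "left.end"], c(2.0, 0.1))
  expect_equal(pv[, "right.start"], c(2, 5))

  # 2-neuron hand-checkable angle: corners at known positions
  A <- edge_angle_matrix(pv)
  e1 <- pv[, 2] - pv[, 1]; e2 <- pv[, 3] - pv[, 1]
  expect_equal(A[1, 1],
               acos(sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2))))

  # identical left/right tuning: vectors coincide pairwise
  tun_same <- tun; tun_same$right <- tun$left
  pv_same <- population_vectors(tun_same)
  expect_equal(pv_same[, 1:3], pv_same[, 4:6], ignore_attr = TRUE)

  # zero bin flagged
  raw0 <- raw_l; raw0[, 1] <- 0
  tun0 <- tun; tun0$left$raw <- raw0
  expect_equal(attr(population_vectors(tun0), "zero_corners"), "left.start")
})

test_that("geometry normalization is ~0 for drift-free synthetic days", {
  s <- fix_two_days()$sessions
  g <- geometry_report(s, seed = 13)
  expect_equal(g$frobenius[1], 0)
  expect_true(is.finite(g$normalized[2]))
  expect_lt(abs(g$normalized[2]), 0.5)   # small sample; acceptance tests
                                         # the +-0.1 band at full scale
  expect_gt(g$shuffled, g$within_day)
  expect_true(all(g$pv_correlation <= 1 & g$pv_correlation >= -1))
  expect_equal(g$pv_correlation[1], 1)
})
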