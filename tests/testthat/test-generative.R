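test_that("neural derivative implements the bilinear form exactly", {
  n <- 3
  A <- diag(-0.5, n)
  p <- dcm_parameters(A, list(matrix(0, n, n)), matrix(0, n, 1))
  expect_equal(neural_derivative(c(1, 0, 0), 0, p), c(-0.5, 0, 0))

  # one active modulator equals the effective matrix A + B
  set.seed(21)
  B <- matrix(rnorm(n * n, sd = 0.1), n)
  C <- matrix(rnorm(n), n, 1)
  pb <- dcm_parameters(A, list(B), C)
  z <- rnorm(n)
  expect_equal(neural_derivative(z, 1, pb),
               drop((A + B) %*% z + C), tolerance = 1e-12)

  # brute-force term-by-term expansion oracle on a random instance
  m <- 2
  Bs <- list(matrix(rnorm(n * n, sd = 0.1), n), matrix(rnorm(n * n, sd = 0.1), n))
  C2 <- matrix(rnorm(n * m), n, m)
  p2 <- dcm_parameters(A, Bs, C2)
  u <- runif(m)
  z <- rnorm(n)
  expected <- numeric(n)
  for (i in 1:n) {
    for (j in 1:n) {
      expected[i] <- expected[i] + A[i, j] * z[j]
      for (k in 1:m) expected[i] <- expected[i] + u[k] * Bs[[k]][i, j] * z[j]
    }
    for (k in 1:m) expected[i] <- expected[i] + C2[i, k] * u[k]
  }
  expect_equal(neural_derivative(z, u, p2), expected, tolerance = 1e-14)

  expect_error(neural_derivative(z[1:2], u, p2), "dimension")
})

test_that("balloon dynamics have the resting fixed point and correct signs", {
  hp <- hemo_defaults(1)
  rest <- c(s = 0, f = 1, v = 1, q = 1)
  expect_equal(unname(hemo_derivative(rest, 0, hp)), rep(0, 4))
  expect_gt(hemo_derivative(rest, 0.5, hp)[["s"]], 0)
  expect_error(hemo_derivative(c(s = 0, f = -1, v = 1, q = 1), 0, hp), "positive")

  # steady-state inflow under constant drive: closed form f* = 1 + eps z / gamma,
  # cross-checked against a long RK4 integration of the s,f subsystem
  z <- 0.3
  f_star <- 1 + hp$epsilon[1] * z / hp$gamma[1]
  sf <- rk4_oracle(function(x) {
    c(hp$epsilon[1] * z - hp$kappa[1] * x[1] - hp$gamma[1] * (x[2] - 1), x[1])
  }, c(0, 1), t_end = 120, dt = 0.05)
  expect_equal(sf[2], f_star, tolerance = 1e-6)
})

test_that("BOLD observation equation matches its closed form", {
  hp <- hemo_defaults(1)
  expect_equal(bold_observation(1, 1, hp), 0)
  expect_gt(bold_observation(1, 0.9, hp), 0)
  v <- 1.1; q <- 0.95; rho <- hp$rho[1]
  by_hand <- hp$V0[1] * (7 * rho * (1 - q) + 2 * (1 - q / v) + (2 * rho - 0.2) * (1 - v))
  expect_equal(bold_observation(v, q, hp), by_hand)
  expect_error(bold_observation(-1, 1, hp), "positive")
})

test_that("compiled integrator agrees with the pure-R reference", {
  truth <- default_truth()
  run <- build_run(condition_labels()$label, epoch_s = 12)
  inp <- build_inputs(run, bins_per_tr = 8)
  y_cpp <- dcmnet:::predict_session(truth$params, hemo_defaults(7), inp, "cpp")
  y_r <- dcmnet:::predict_session(truth$params, hemo_defaults(7), inp, "R")
  expect_equal(y_cpp, y_r, tolerance = 1e-12)
})

test_that("simulation respects linearity and amplitude scaling", {
  sess <- fix_session1()
  inp <- build_inputs(sess)
  n <- 7
  A <- diag(-0.5, n)
  zeroB <- replicate(3, matrix(0, n, n), simplify = FALSE)
  C <- matrix(0, n, 3); C[1, 1] <- 0.01
  p1 <- dcm_parameters(A, zeroB, C, regions = region_names())
  C2 <- C * 2
  p2 <- dcm_parameters(A, zeroB, C2, regions = region_names())
  y1 <- simulate_bold(p1, inputs = inp)$values
  y2 <- simulate_bold(p2, inputs = inp)$values
  # at small amplitude BOLD approximately doubles with the drive
  sel <- abs(y1) > 0.1 * max(abs(y1))
  expect_lt(max(abs(y2[sel] / y1[sel] - 2)), 0.1)

  # C = 0: flat baseline before noise
  p0 <- dcm_parameters(A, zeroB, C * 0, regions = region_names())
  expect_true(all(simulate_bold(p0, inputs = inp)$values == 0))

  # neural-level superposition when B = 0 (independent RK4 oracle on z only)
  set.seed(3)
  As <- diag(-0.5, 3) + matrix(rnorm(9, sd = 0.05), 3)
  Cs <- matrix(rnorm(6), 3, 2)
  ps <- dcm_parameters(As, list(matrix(0, 3, 3), matrix(0, 3, 3)), Cs)
  zf <- function(u) function(z) neural_derivative(z, u, ps)
  u1 <- c(1, 0); u2 <- c(0, 1)
  z1 <- rk4_oracle(zf(u1), rep(0, 3), 10, 0.1)
  z2 <- rk4_oracle(zf(u2), rep(0, 3), 10, 0.1)
  z12 <- rk4_oracle(zf(u1 + u2), rep(0, 3), 10, 0.1)
  expect_equal(z12, z1 + z2, tolerance = 1e-12)
})

test_that("hemodynamic impulse response peaks at canonical latency", {
  # single region, 1-s input at t = 0, sampled every second
  p <- dcm_parameters(matrix(-0.5, 1, 1), list(matrix(0, 1, 1)),
                      matrix(1, 1, 1))
  u <- matrix(c(rep(1, 16), rep(0, 29 * 16)), nrow = 1)
  res <- dcmnet:::integrate_run(p, hemo_defaults(1), u, bins_per_tr = 16,
                                dt = 1 / 16, n_vol = 30)
  expect_false(res$diverged)
  peak_t <- which.max(res$y)  # seconds (1-s sampling)
  expect_gte(peak_t, 3)
  expect_lte(peak_t, 7)
})

test_that("integration converges and decays back to rest", {
  truth <- default_truth()
  sess <- fix_session1()
  y16 <- simulate_bold(truth$params, inputs = build_inputs(sess, 16))$values
  y32 <- simulate_bold(truth$params, inputs = build_inputs(sess, 32))$values
  expect_lt(max(abs(y16 - y32)), 1e-3)

  # inputs switched off: signal returns to the resting point
  run <- fix_run()
  run$epochs$kind[5:17] <- "rest"
  run$epochs$condition[5:17] <- NA_character_
  y <- simulate_bold(truth$params, inputs = build_inputs(run))$values
  expect_gt(max(abs(y)), 1e-3)         # there was a response
  expect_lt(max(abs(y[136, ])), 1e-5)  # and it decayed away
})

test_that("instability and divergence are reported", {
  inp <- build_inputs(fix_session1())
  n <- 7
  A <- diag(-0.5, n); A[2, 1] <- A[1, 2] <- 2  # positive eigenvalue
  p_bad <- dcm_parameters(A, replicate(3, matrix(0, n, n), simplify = FALSE),
                          matrix(0.2, n, 3), regions = region_names())
  expect_error(simulate_bold(p_bad, inputs = inp), "unstable")
  expect_true(dcmnet:::stability_margin(p_bad, inp) >= 0)
})

test_that("noise is seeded, per-region, and absent when sd = 0", {
  truth <- default_truth()
  inp <- build_inputs(fix_session1())
  a <- simulate_bold(truth$params, inputs = inp, noise_sd = 0.01, seed = 5)
  b <- simulate_bold(truth$params, inputs = inp, noise_sd = 0.01, seed = 5)
  d <- simulate_bold(truth$params, inputs = inp, noise_sd = 0.01, seed = 6)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
  clean <- simulate_bold(truth$params, inputs = inp)
  expect_identical(clean$values, simulate_bold(truth$params, inputs = inp)$values)
})

test_that("ROI time series round-trip through text + sidecar", {
  truth <- default_truth()
  ts <- simulate_bold(truth$params, inputs = build_inputs(fix_session1()),
                      noise_sd = 0.005, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roi_ts(ts, path)
  back <- read_roi_ts(path)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  expect_equal(back$tr, ts$tr)
  expect_equal(back$run_lengths, ts$run_lengths)
})
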