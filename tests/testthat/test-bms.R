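test_that("the Dirichlet fixed point matches an independent oracle", {
  # independently coded fixed-point iteration (scalar loops, no shortcuts)
  oracle_bms <- function(ev, alpha0 = 1, iters = 2000) {
    N <- nrow(ev); K <- ncol(ev)
    a <- rep(alpha0, K) + N / K
    for (it in 1:iters) {
      g <- matrix(0, N, K)
      for (n in 1:N) {
        lg <- numeric(K)
        for (k in 1:K) lg[k] <- ev[n, k] + digamma(a[k]) - digamma(sum(a))
        w <- exp(lg - max(lg))
        g[n, ] <- w / sum(w)
      }
      a_new <- rep(alpha0, K)
      for (k in 1:K) a_new[k] <- a_new[k] + sum(g[, k])
      if (max(abs(a_new - a)) < 1e-12) break
      a <- a_new
    }
    a
  }
  set.seed(13)
  ev <- matrix(rnorm(3 * 2, sd = 0.8), 3, 2)
  fit <- rfx_bms(ev, tol = 1e-10)
  expect_equal(unname(fit$alpha), oracle_bms(ev), tolerance = 1e-6)

  ev5 <- matrix(rnorm(6 * 4, sd = 1.5), 6, 4)
  expect_equal(unname(rfx_bms(ev5, tol = 1e-10)$alpha), oracle_bms(ev5),
               tolerance = 1e-6)
})

test_that("fixed point respects symmetry and saturation", {
  flat <- rfx_bms(matrix(0, 5, 3))
  expect_equal(unname(flat$alpha), rep(1 + 5 / 3, 3), tolerance = 1e-8)
  expect_true(all(abs(flat$responsibilities - 1 / 3) < 1e-10))

  ev <- matrix(0, 4, 3); ev[, 2] <- 1000
  sat <- rfx_bms(ev)
  expect_equal(unname(sat$alpha), c(1, 1 + 4, 1), tolerance = 1e-8)

  expect_error(rfx_bms(matrix(0, 3, 2), alpha0 = 0), "positive")
  expect_error(evidence_matrix(matrix(0, 3, 1)), "2 models")
  expect_error(evidence_matrix(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("exceedance probabilities match closed forms", {
  phi <- exceedance(c(1, 1), 1e6, seed = 2)
  expect_equal(sum(phi), 1)
  expect_equal(unname(phi[1]), 0.5, tolerance = 0.005)

  # P(Beta(2,1) > 1/2) = 1 - 0.25 = 0.75
  expect_equal(unname(exceedance(c(2, 1), 1e6, seed = 3)[1]), 0.75,
               tolerance = 0.005)

  phi16 <- exceedance(rep(1, 16), 1e5, seed = 4)
  expect_lt(max(abs(phi16 - 1 / 16)), 0.005)
  expect_error(exceedance(c(1, 1), n_samples = 100), "1e4")
})

test_that("exceedance is deterministic given the seed and monotone in evidence", {
  a <- exceedance(c(3, 2, 1), 1e5, seed = 7)
  b <- exceedance(c(3, 2, 1), 1e5, seed = 7)
  expect_identical(a, b)

  set.seed(23)
  for (i in 1:5) {
    ev <- matrix(rnorm(6 * 3), 6, 3)
    phi0 <- exceedance(rfx_bms(ev)$alpha, 1e5, seed = i)
    ev_up <- ev; ev_up[, 2] <- ev_up[, 2] + 1.5
    phi1 <- exceedance(rfx_bms(ev_up)$alpha, 1e5, seed = i)
    expect_gte(phi1[2], phi0[2] - 0.01)
  }
})

test_that("family inference matches a Beta quadrature oracle", {
  # 3 models, families {m1, m2} and {m3}: with posterior alpha, the family
  # exceedance is P(Beta(a1 + a2, a3) > 1/2) exactly
  ev <- matrix(c(0.5, 0.2, -0.3, 0.1, 0.4, -0.2), nrow = 2, byrow = TRUE)
  colnames(ev) <- c("1", "2", "3")
  part <- c("1" = "AB", "2" = "AB", "3" = "Conly")
  fam <- family_inference(ev, part, n_samples = 1e6, seed = 5)
  a <- fam$alpha
  exact <- 1 - pbeta(0.5, a[1] + a[2], a[3])
  expect_equal(unname(fam$exceedance["AB"]), unname(exact), tolerance = 0.005)
  expect_equal(sum(fam$exceedance), 1)
  expect_equal(sum(fam$expected), 1, tolerance = 1e-9)
  # rebalanced prior: each family the same prior mass
  expect_equal(unname(fam$bms$alpha0), c(0.5, 0.5, 1))

  # single family: exceedance 1
  one <- family_inference(ev, c("1" = "all", "2" = "all", "3" = "all"),
                          n_samples = 1e4 * 10, seed = 1)
  expect_equal(unname(one$exceedance), 1)

  # symmetric evidences and equal families: 1/4 each
  ev16 <- matrix(0, 3, 16, dimnames = list(NULL, as.character(1:16)))
  f4 <- family_inference(ev16, partitions()$input, n_samples = 1e5, seed = 2)
  expect_equal(unname(f4$exceedance), rep(0.25, 4), tolerance = 0.02)

  expect_error(family_inference(ev, c("1" = "A", "2" = "A")), "cover")
})

test_that("BMS recovers a favored model from noisy evidence", {
  # Delta = 3 nats per subject, N = 24, K = 16: the true model should attain
  # the maximum exceedance probability in at least 90% of replicates
  wins <- vapply(1:100, function(s) {
    ev <- generate_evidence(true_model = 7, delta = 3, n_subjects = 24,
                            n_models = 16, seed = 1000 + s)
    phi <- exceedance(rfx_bms(ev)$alpha, 2e4, seed = s)
    which.max(phi) == 7
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # saturation: a huge advantage for every subject of a large group drives
  # the exceedance probability toward 1
  ev <- generate_evidence(2, delta = 1000, n_subjects = 40, n_models = 4, seed = 1)
  fit <- rfx_bms(ev)
  expect_equal(unname(fit$alpha), c(1, 41, 1, 1), tolerance = 1e-6)
  expect_gt(exceedance(fit$alpha, 1e4 * 5, seed = 1)[2], 0.99)
})

test_that("evidence matrices round-trip through CSV", {
  ev <- generate_evidence(1, 2, 4, 6, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence(ev, path)
  back <- read_evidence(path)
  expect_equal(back$values, ev$values, tolerance = 1e-12)
})
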