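test_that("default priors enumerate the free parameters with stated variances", {
  pr1 <- default_priors(model_spec("mutual", "dual"))
  expect_equal(nrow(pr1$table), 78L)  # 25 A + 2 x 25 B + 3 C
  expect_true(all(pr1$mean == 0))
  expect_equal(unname(pr1$var[pr1$table$kind == "A"]), rep(0.25, 25))
  expect_equal(unname(pr1$var[pr1$table$kind == "B"]), rep(0.25, 50))
  expect_equal(unname(pr1$var[pr1$table$kind == "C"]), rep(1, 3))

  pr16 <- default_priors(model_spec("none", "none"))
  expect_equal(nrow(pr16$table), 70L)  # 23 A + 2 x 23 B + 1 C
  # disabled edges are simply absent from the free-parameter table
  expect_false("A:PMv->pSTS" %in% pr16$table$name)

  pr_tau <- default_priors(model_spec("none", "none"), estimate_tau = TRUE)
  expect_equal(nrow(pr_tau$table), 77L)
  expect_equal(unname(pr_tau$var[pr_tau$table$kind == "tau"]), rep(0.0156, 7))
})

test_that("inversion is self-consistent at the prior mean", {
  # data simulated at the prior mean (all couplings 0) is flat; the
  # posterior must stay at the prior mean
  sess <- fix_session1()
  inp <- build_inputs(sess)
  flat <- roi_ts(matrix(0, 133, 7), region_names(), 3, 133)
  post <- invert_dcm(model_spec("none", "none"), flat, inp,
                     opts = list(max_iter = 8))
  expect_lt(max(abs(post$mean)), 1e-6)
  expect_true(post$converged)
})

test_that("inversion recovers generating parameters at high SNR", {
  sub <- fix_subject(n_runs = 6, snr = 5, seed = 71)
  model1 <- model_spec("mutual", "dual")
  post <- invert_dcm(model1, sub$data, sub$inputs)
  expect_true(post$converged)

  # coverage: posterior mean within 2 posterior SDs of truth for >= 90%
  sd_post <- sqrt(diag(post$cov))
  covered <- abs(post$mean - sub$theta) <= 2 * sd_post
  expect_gte(mean(covered), 0.9)
  # point estimates carry real signal about the generating couplings
  expect_gt(cor(post$mean, sub$theta), 0.5)
  # strongly identified parameters (tight posteriors) are close to truth
  tight <- sqrt(diag(post$cov)) < 0.05
  expect_gt(sum(tight), 5)
  expect_lt(max(abs(post$mean - sub$theta)[tight]), 0.1)

  # invariants on the same fit
  expect_true(all(diff(post$F_trace) > -1e-6))    # monotone accepted F
  expect_true(all(diag(post$cov) > 0))
  expect_equal(free_energy(post), post$F)

  # deterministic: the same call reproduces F exactly
  post2 <- invert_dcm(model1, sub$data, sub$inputs)
  expect_identical(post2$F, post$F)
})

test_that("pure-noise data shrinks couplings toward zero", {
  sess <- fix_session1()
  inp <- build_inputs(sess)
  set.seed(55)
  noise <- roi_ts(matrix(rnorm(133 * 7, sd = 0.01), 133), region_names(), 3, 133)
  post <- invert_dcm(model_spec("mutual", "dual"), noise, inp)
  sel <- post$table$kind %in% c("A", "B")
  expect_lt(mean(abs(post$mean[sel])), 0.5)  # below the 0.5 Hz prior SD on average
})

test_that("sensitivity and finite-difference linearizations agree", {
  sub <- fix_subject(n_runs = 1, snr = 5, seed = 72)
  model <- model_spec("none", "none")
  o <- list(max_iter = 3L, tol = 1e-6)
  post_s <- invert_dcm(model, sub$data, sub$inputs,
                       opts = c(o, jacobian = "sensitivity"))
  post_f <- invert_dcm(model, sub$data, sub$inputs,
                       opts = c(o, jacobian = "fd"))
  expect_equal(post_s$F, post_f$F, tolerance = 1e-3)
  expect_equal(post_s$mean, post_f$mean, tolerance = 1e-3)
})

test_that("free energy penalizes a grossly wrong noise precision", {
  sub <- fix_subject(n_runs = 1, snr = 3, seed = 73)
  model <- model_spec("mutual", "dual")
  free <- invert_dcm(model, sub$data, sub$inputs)
  wrong <- invert_dcm(model, sub$data, sub$inputs,
                      opts = list(lambda_fixed = 1))
  expect_gt(free$F, wrong$F + 100)
})

test_that("irrelevant parameters never pay more than their complexity", {
  # data generated WITHOUT the PMv-pSTS edges or extra inputs: the richer
  # model may not beat the generating one on average (Occam)
  truth <- default_truth()
  p13 <- truth$params
  for (nm in c("A")) {
    p13$A["pSTS", "PMv"] <- 0; p13$A["PMv", "pSTS"] <- 0
  }
  p13$B$exec["pSTS", "PMv"] <- p13$B$exec["PMv", "pSTS"] <- 0
  p13$B$hand["pSTS", "PMv"] <- p13$B$hand["PMv", "pSTS"] <- 0
  p13$C["PMv", "exec"] <- p13$C["pSTS", "hand"] <- 0
  sess <- fix_session1()
  inp <- build_inputs(sess)
  y0 <- dcmnet:::predict_session(p13, hemo_defaults(7), inp)
  nsd <- apply(y0, 2, sd) / 3
  dF <- vapply(1:2, function(s) {
    y <- y0 + withr_seed_local(90 + s, {
      matrix(rnorm(length(y0), sd = rep(nsd, each = nrow(y0))), nrow(y0))
    })
    dat <- roi_ts(y, region_names(), 3, 133)
    f16 <- invert_dcm(model_spec("none", "none"), dat, inp)$F
    f1 <- invert_dcm(model_spec("mutual", "dual"), dat, inp)$F
    f1 - f16
  }, numeric(1))
  expect_lt(mean(dF), 3)  # no systematic advantage for the superfluous model
})

test_that("model evidence identifies the generating model", {
  # F(generating model) > F(minimal model) in >= 8/10 noise replicates at
  # SNR 3 with the full 798-volume design
  sub <- fix_subject(n_runs = 6, snr = Inf)
  y0 <- sub$noise_free
  nsd <- apply(y0, 2, sd) / 3
  model1 <- model_spec("mutual", "dual")
  model16 <- model_spec("none", "none")
  wins <- vapply(1:10, function(s) {
    y <- y0 + withr_seed_local(300 + s, {
      matrix(rnorm(length(y0), sd = rep(nsd, each = nrow(y0))), nrow(y0))
    })
    dat <- roi_ts(y, region_names(), 3, sub$data$run_lengths)
    invert_dcm(model1, dat, sub$inputs)$F >
      invert_dcm(model16, dat, sub$inputs)$F
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("posteriors serialize to JSON", {
  sub <- fix_subject(n_runs = 1, snr = 5, seed = 74)
  post <- invert_dcm(model_spec("none", "none"), sub$data, sub$inputs,
                     opts = list(max_iter = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_posterior(post, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$free_energy, post$F)
  expect_equal(unlist(back$mean), post$mean, tolerance = 1e-12)
})
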