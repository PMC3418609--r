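test_that("silent-window integration is exact on constructed signals", {
  sess <- build_session(list(fix_run()), discard = 0)
  win <- silent_windows(sess)
  rate <- 500
  ns <- 408 * rate

  zero <- integrate_windows(rep(0, ns), rate, win)
  expect_true(all(zero$value == 0))

  const <- integrate_windows(rep(-2, ns), rate, win)
  expect_equal(const$value, rep(0.6 * 2, nrow(win)), tolerance = 1e-12)

  # a burst confined to epoch 4 (the 2nd task epoch) raises only its windows
  sig <- rep(0, ns)
  t <- (seq_len(ns) - 0.5) / rate
  sig[t >= 72 & t < 96] <- 3
  burst <- integrate_windows(sig, rate, win)
  in_epoch <- win$start >= 72 & win$end <= 96
  expect_true(all(burst$value[in_epoch] > 1))
  expect_true(all(burst$value[!in_epoch] == 0))

  expect_error(integrate_windows(rep(0, 100), rate, win), "outside")
})

test_that("channel averaging feeds a mean across columns", {
  sess <- build_session(list(fix_run()), discard = 0)
  win <- silent_windows(sess)[1:10, ]
  rate <- 100
  two <- cbind(rep(2, 408 * rate), rep(4, 408 * rate))
  vals <- integrate_windows(two, rate, win)$value
  expect_equal(vals, rep(0.6 * 3, 10), tolerance = 1e-12)
})

test_that("normalization standardizes, is affine-invariant and monotone", {
  set.seed(8)
  x <- rgamma(50, 2)
  z <- normalize_scores(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(normalize_scores(3 * x + 5), z, tolerance = 1e-12)
  expect_equal(order(z), order(x))
  expect_error(normalize_scores(rep(1, 5)), "spread")
  expect_error(normalize_scores(1), "at least 2")
})

test_that("condition summaries subtract rest and collapse direction", {
  sess <- default_session(3, n_runs = 2)
  win <- silent_windows(sess)
  # deterministic construction: score 1 in Execution windows, 0 elsewhere
  cond <- decode_conditions(win$condition)
  scores <- as.numeric(win$kind == "task" & cond$execution)
  sum8 <- condition_summary(scores, win, collapse_direction = FALSE)
  expect_equal(nrow(sum8), 8L)
  expect_equal(sum8$value[grepl("^Exec", sum8$condition)], rep(1, 4))
  expect_equal(sum8$value[grepl("^Obs", sum8$condition)], rep(0, 4))
  sum4 <- condition_summary(scores, win)
  expect_equal(nrow(sum4), 4L)
  # direction collapse averages the CW/CCW pair
  expect_equal(sum4$value[sum4$condition == "Exec_Hand"],
               mean(sum8$value[sum8$condition %in% c("Exec_Hand_CW", "Exec_Hand_CCW")]))
  expect_equal(sum4$n_windows, rep(sum(win$kind == "task") / 4, 4))
})

test_that("stationary noise gives near-zero summaries", {
  sess <- default_session(5, n_runs = 2)
  trace <- generate_emg(sess, a_exec = 0, a_hand = 0, rate = 200, seed = 21)
  res <- emg_pipeline(trace$signal, trace$rate, sess)
  se <- 1 / sqrt(res$summary$n_windows)  # scores have unit variance
  expect_true(all(abs(res$summary$value) < 3 * se))
})

test_that("execution-only bursts elevate only Execution conditions", {
  sess <- default_session(6, n_runs = 3)
  trace <- generate_emg(sess, a_exec = 5, a_hand = 0, rate = 200, seed = 22)
  s <- emg_pipeline(trace$signal, trace$rate, sess)$summary
  expect_true(all(s$value[grepl("^Exec", s$condition)] > 0.5))
  expect_true(all(abs(s$value[grepl("^Obs", s$condition)]) < 0.2))
})

test_that("the full EMG pipeline recovers both factors across a group", {
  # group of subjects at the generator defaults (execution bursts at 5x
  # baseline, mimicry at 0.5x): paired contrasts on the 2x2 condition means
  n_sub <- 10
  sess <- default_session(9)  # full 6-run session: 48 windows per condition
  mat <- t(vapply(seq_len(n_sub), function(s) {
    trace <- generate_emg(sess, rate = 200, seed = 400 + s)
    res <- emg_pipeline(trace$signal, trace$rate, sess)$summary
    stats::setNames(res$value, res$condition)
  }, numeric(4)))
  exec_eff <- rowMeans(mat[, c("Exec_Hand", "Exec_NoHand")]) -
    rowMeans(mat[, c("Obs_Hand", "Obs_NoHand")])
  hand_eff <- rowMeans(mat[, c("Exec_Hand", "Obs_Hand")]) -
    rowMeans(mat[, c("Exec_NoHand", "Obs_NoHand")])
  expect_lt(one_sample_t(exec_eff)$p, 0.001)
  expect_gt(mean(exec_eff), 0)
  expect_lt(one_sample_t(hand_eff)$p, 0.05)
  expect_gt(mean(hand_eff), 0)
  # the key mimicry signature: Hand > No-hand within Observation
  obs_hand <- mat[, "Obs_Hand"] - mat[, "Obs_NoHand"]
  expect_lt(paired_t(mat[, "Obs_Hand"], mat[, "Obs_NoHand"])$p, 0.05)
  expect_gt(mean(obs_hand), 0)
})

test_that("EMG traces round-trip through text + sidecar", {
  set.seed(44)
  sig <- cbind(rnorm(500), rnorm(500))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_emg(sig, 1000, path, meta = list(seed = 44))
  back <- read_emg(path)
  expect_equal(unname(back$signal), unname(sig), tolerance = 1e-12)
  expect_equal(back$rate, 1000)
  expect_equal(back$meta$seed, 44)
})
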