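# Shared fixtures: everything is generated in code at test time.

# Canonical single-run design and inputs (136 volumes, TR 3 s).
fix_run <- function() build_run(condition_labels()$label)

fix_session1 <- function(seed = 1) default_session(seed, n_runs = 1)

# One synthetic subject simulated from the population-mean truth, with
# optional noise at a given SNR. Returns data plus the generating theta.
fix_subject <- function(n_runs = 1, snr = Inf, seed = 11, bins_per_tr = 16) {
  truth <- default_truth()
  sess <- default_session(1, n_runs = n_runs)
  inp <- build_inputs(sess, bins_per_tr)
  y0 <- dcmnet:::predict_session(truth$params, hemo_defaults(7), inp)
  y <- y0
  if (is.finite(snr)) {
    nsd <- apply(y0, 2, stats::sd) / snr
    y <- y0 + withr_seed_local(seed, {
      matrix(stats::rnorm(length(y0), sd = rep(nsd, each = nrow(y0))),
             nrow(y0), ncol(y0))
    })
  }
  run_lengths <- vapply(inp$per_run, function(u) {
    as.integer(ncol(u) / bins_per_tr - inp$discard)
  }, integer(1))
  list(data = roi_ts(y, truth$params$regions, sess$tr, run_lengths),
       inputs = inp,
       theta = dcmnet:::subject_theta(truth$params, truth$model),
       truth = truth, session = sess, noise_free = y0)
}

# Seed-scoped evaluation that restores the caller's RNG state.
withr_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Reference RK4 for a generic ODE, used as an independent oracle.
rk4_oracle <- function(f, x0, t_end, dt) {
  x <- x0
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
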