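# Synthetic-data generators: a stated ground-truth world with the statistical
# structure the analysis assumes, so every downstream stage is testable
# without any external download.

# Printed group-mean couplings (Hz) and their standard errors for the
# mutual-connection, dual-input generating model. (to, from, mean, se).
.truth_table <- function() {
  tab <- rbind(
    # baseline connectivity
    c("A", "OP",    "MT/V5", 0.387, 0.028), c("A", "pSTS",  "MT/V5", 0.169, 0.015),
    c("A", "aIPS",  "MT/V5", -0.018, 0.012), c("A", "IPL",  "MT/V5", -0.036, 0.014),
    c("A", "MT/V5", "pSTS", 0.115, 0.032), c("A", "aIPS",  "pSTS", -0.003, 0.014),
    c("A", "IPL",   "pSTS", -0.021, 0.014), c("A", "PMv",  "pSTS", 0.071, 0.020),
    c("A", "MT/V5", "aIPS", 0.103, 0.022), c("A", "pSTS",  "aIPS", 0.122, 0.014),
    c("A", "IPL",   "aIPS", 0.062, 0.018), c("A", "PMv",   "aIPS", 0.116, 0.022),
    c("A", "S/M1",  "aIPS", 0.067, 0.018),
    c("A", "MT/V5", "IPL", 0.011, 0.024), c("A", "pSTS",  "IPL", 0.051, 0.012),
    c("A", "aIPS",  "IPL", 0.054, 0.021), c("A", "PMv",   "IPL", 0.128, 0.019),
    c("A", "S/M1",  "IPL", 0.087, 0.024),
    c("A", "pSTS",  "PMv", 0.052, 0.017), c("A", "aIPS",  "PMv", 0.010, 0.014),
    c("A", "IPL",   "PMv", -0.008, 0.016), c("A", "S/M1", "PMv", -0.004, 0.018),
    c("A", "aIPS",  "S/M1", 0.053, 0.020), c("A", "IPL",  "S/M1", 0.121, 0.030),
    c("A", "PMv",   "S/M1", 0.229, 0.036),
    # Execution modulation
    c("Bexec", "OP",    "MT/V5", 0.034, 0.020), c("Bexec", "pSTS",  "MT/V5", 0.006, 0.010),
    c("Bexec", "aIPS",  "MT/V5", -0.012, 0.009), c("Bexec", "IPL",  "MT/V5", -0.009, 0.008),
    c("Bexec", "MT/V5", "pSTS", -0.039, 0.016), c("Bexec", "aIPS",  "pSTS", -0.018, 0.015),
    c("Bexec", "IPL",   "pSTS", 0.007, 0.010), c("Bexec", "PMv",   "pSTS", 0.077, 0.019),
    c("Bexec", "MT/V5", "aIPS", 0.022, 0.012), c("Bexec", "pSTS",  "aIPS", 0.022, 0.014),
    c("Bexec", "IPL",   "aIPS", 0.039, 0.012), c("Bexec", "PMv",   "aIPS", 0.119, 0.024),
    c("Bexec", "S/M1",  "aIPS", 0.055, 0.013),
    c("Bexec", "MT/V5", "IPL", 0.030, 0.011), c("Bexec", "pSTS",  "IPL", 0.031, 0.013),
    c("Bexec", "aIPS",  "IPL", 0.037, 0.011), c("Bexec", "PMv",   "IPL", 0.124, 0.022),
    c("Bexec", "S/M1",  "IPL", 0.069, 0.015),
    c("Bexec", "pSTS",  "PMv", -0.018, 0.012), c("Bexec", "aIPS",  "PMv", -0.008, 0.013),
    c("Bexec", "IPL",   "PMv", -0.008, 0.014), c("Bexec", "S/M1",  "PMv", 0.003, 0.019),
    c("Bexec", "aIPS",  "S/M1", 0.161, 0.018), c("Bexec", "IPL",   "S/M1", 0.160, 0.018),
    c("Bexec", "PMv",   "S/M1", 0.274, 0.040),
    # Hand-observation modulation
    c("Bhand", "OP",    "MT/V5", 0.203, 0.018), c("Bhand", "pSTS",  "MT/V5", 0.213, 0.020),
    c("Bhand", "aIPS",  "MT/V5", 0.051, 0.011), c("Bhand", "IPL",   "MT/V5", 0.030, 0.009),
    c("Bhand", "MT/V5", "pSTS", 0.002, 0.010), c("Bhand", "aIPS",  "pSTS", -0.016, 0.009),
    c("Bhand", "IPL",   "pSTS", -0.027, 0.008), c("Bhand", "PMv",   "pSTS", -0.040, 0.010),
    c("Bhand", "MT/V5", "aIPS", 0.050, 0.015), c("Bhand", "pSTS",  "aIPS", 0.123, 0.020),
    c("Bhand", "IPL",   "aIPS", -0.008, 0.007), c("Bhand", "PMv",   "aIPS", 0.013, 0.009),
    c("Bhand", "S/M1",  "aIPS", -0.029, 0.009),
    c("Bhand", "MT/V5", "IPL", 0.017, 0.010), c("Bhand", "pSTS",  "IPL", 0.056, 0.012),
    c("Bhand", "aIPS",  "IPL", 0.0002, 0.005), c("Bhand", "PMv",   "IPL", 0.017, 0.005),
    c("Bhand", "S/M1",  "IPL", -0.015, 0.005),
    c("Bhand", "pSTS",  "PMv", 0.045, 0.016), c("Bhand", "aIPS",  "PMv", 0.003, 0.009),
    c("Bhand", "IPL",   "PMv", -0.010, 0.008), c("Bhand", "S/M1",  "PMv", -0.021, 0.009),
    c("Bhand", "aIPS",  "S/M1", 0.002, 0.017), c("Bhand", "IPL",   "S/M1", 0.037, 0.012),
    c("Bhand", "PMv",   "S/M1", 0.061, 0.018)
  )
  data.frame(kind = tab[, 1], from = tab[, 2], to = tab[, 3],
             mean = as.numeric(tab[, 4]), se = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

#' Default group-level ground truth
#'
#' Population-mean coupling parameters for the generating model
#' (mutual-connection, dual-input: model 1): baseline and modulatory
#' couplings set to the published group means, between-subject SD per
#' parameter set to the published SE times sqrt(N) with N = 24. Driving-input
#' gains are not published; they are fixed population values
#' (task -> OP 0.2, exec -> PMv 0.1, hand -> pSTS 0.1 Hz, SD 0), chosen so
#' that peak BOLD excursions stay in the physiological 1-3% range.
#'
#' @param n_subjects Group size (default 24).
#' @param snr Per-region signal-to-noise ratio, signal SD / noise SD
#'   (default 3).
#' @return Object of class `group_truth`: `model`, `params` (population-mean
#'   `dcm_params`), `sd` (matched structure of between-subject SDs),
#'   `n_subjects`, `snr`.
#' @export
default_truth <- function(n_subjects = 24, snr = 3) {
  model <- model_spec("mutual", "dual")
  regions <- model$regions
  n <- length(regions)
  A <- diag(-0.5, n); dimnames(A) <- list(regions, regions)
  sdA <- matrix(0, n, n, dimnames = dimnames(A))
  Bx <- Bh <- sdBx <- sdBh <- matrix(0, n, n, dimnames = dimnames(A))
  tt <- .truth_table()
  for (i in seq_len(nrow(tt))) {
    r <- match(tt$to[i], regions); c <- match(tt$from[i], regions)
    sdv <- tt$se[i] * sqrt(24)
    switch(tt$kind[i],
      A = { A[r, c] <- tt$mean[i]; sdA[r, c] <- sdv },
      Bexec = { Bx[r, c] <- tt$mean[i]; sdBx[r, c] <- sdv },
      Bhand = { Bh[r, c] <- tt$mean[i]; sdBh[r, c] <- sdv })
  }
  Czero <- matrix(0, n, 3, dimnames = list(regions, c("task", "exec", "hand")))
  C <- Czero
  C["OP", "task"] <- 0.2
  C["PMv", "exec"] <- 0.1
  C["pSTS", "hand"] <- 0.1
  params <- dcm_parameters(
    A, list(task = matrix(0, n, n, dimnames = dimnames(A)), exec = Bx, hand = Bh),
    C, regions = regions, input_names = c("task", "exec", "hand"))
  structure(list(model = model, params = params,
                 sd = list(A = sdA,
                           B = list(task = matrix(0, n, n), exec = sdBx, hand = sdBh),
                           C = Czero),
                 n_subjects = as.integer(n_subjects), snr = snr),
            class = "group_truth")
}

# Draw one subject's parameters around the population means; NULL if the
# stability check fails for this draw.
.draw_subject <- function(truth, inputs) {
  p0 <- truth$params
  A <- p0$A + matrix(stats::rnorm(length(p0$A), sd = truth$sd$A), nrow(p0$A))
  B <- lapply(seq_along(p0$B), function(j) {
    p0$B[[j]] + matrix(stats::rnorm(length(p0$B[[j]]), sd = truth$sd$B[[j]]),
                       nrow(p0$A))
  })
  names(B) <- names(p0$B)
  C <- p0$C + matrix(stats::rnorm(length(p0$C), sd = truth$sd$C), nrow(p0$C))
  params <- dcm_parameters(A, B, C, regions = p0$regions,
                           input_names = p0$input_names)
  if (stability_margin(params, inputs) >= 0) return(NULL)
  params
}

# Flatten a subject's dcm_params to the free-parameter vector of the
# generating model (same order/names as param_table(model)).
subject_theta <- function(params, model) {
  tab <- param_table(model)
  n <- length(model$regions)
  theta <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    theta[i] <- switch(tab$kind[i],
      A = params$A[tab$idx[i]],
      B = params$B[[tab$slice[i]]][tab$idx[i]],
      C = params$C[tab$idx[i]])
  }
  stats::setNames(theta, tab$name)
}

#' Generate a synthetic subject group
#'
#' For each subject: draw coupling parameters from Normal(population mean,
#' between-subject SD) with stability rejection-resampling (at most 100
#' attempts), simulate noise-free BOLD through the forward model, and add
#' per-region Gaussian noise with SD = signal SD / SNR.
#'
#' @param truth A `group_truth` (default [default_truth()]).
#' @param session A `dcm_session` design.
#' @param n_subjects Number of subjects (default `truth$n_subjects`).
#' @param snr Signal-to-noise ratio (default `truth$snr`).
#' @param seed Master seed; per-subject seeds are derived from it and
#'   recorded.
#' @param bins_per_tr Microtime resolution for simulation.
#' @return List with `data` (list of `roi_ts`), `theta` (subjects x
#'   parameters matrix of true free parameters), `subject_seeds`, `inputs`,
#'   `truth`, `session`, `snr`, `seed`.
#' @export
generate_group <- function(truth = default_truth(), session,
                           n_subjects = truth$n_subjects, snr = truth$snr,
                           seed = 1L, bins_per_tr = 16) {
  inputs <- build_inputs(session, bins_per_tr)
  if (stability_margin(truth$params, inputs) >= 0) {
    stop("population-mean parameters are unstable")
  }
  subject_seeds <- withr_seed(seed, sample.int(2^30, n_subjects + 1L))
  data <- vector("list", n_subjects)
  thetas <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    # A draw is accepted only if it is eigenvalue-stable AND integrates
    # without divergence (near-critical draws can be stiff at microtime).
    drawn <- withr_seed(subject_seeds[s], {
      ok <- NULL
      for (attempt in 1:100) {
        d <- .draw_subject(truth, inputs)
        if (is.null(d)) next
        y <- predict_session(d, hemo_defaults(d$n), inputs)
        if (!is.null(y)) { ok <- list(params = d, y0 = y); break }
      }
      ok
    })
    if (is.null(drawn)) stop("more than 100 unstable draws for subject ", s)
    params <- drawn$params
    y0 <- drawn$y0
    sig_sd <- apply(y0, 2, stats::sd)
    noise_sd <- pmax(sig_sd, 1e-12) / snr
    y <- withr_seed(subject_seeds[n_subjects + 1L] + s, {
      y0 + matrix(stats::rnorm(length(y0), sd = rep(noise_sd, each = nrow(y0))),
                  nrow(y0), ncol(y0))
    })
    run_lengths <- vapply(inputs$per_run, function(u) {
      as.integer(ncol(u) / bins_per_tr - inputs$discard)
    }, integer(1))
    data[[s]] <- roi_ts(y, regions = params$regions, tr = inputs$tr,
                        run_lengths = run_lengths, noise_sd = noise_sd,
                        seed = subject_seeds[s])
    thetas[[s]] <- subject_theta(params, truth$model)
  }
  list(data = data,
       theta = do.call(rbind, thetas),
       subject_seeds = subject_seeds[seq_len(n_subjects)],
       inputs = inputs,
       truth = truth,
       session = session,
       snr = snr,
       seed = as.integer(seed))
}

#' Generate a synthetic evidence matrix
#'
#' Log evidences are i.i.d. Gaussian baseline noise with `delta` nats added
#' to the true model's column for every subject.
#'
#' @param true_model Index of the favored model (column).
#' @param delta Evidence advantage in nats per subject (>= 0).
#' @param n_subjects,n_models Matrix dimensions.
#' @param noise_sd SD of the baseline evidence noise.
#' @param seed Seed.
#' @return An `evidence_matrix`.
#' @export
generate_evidence <- function(true_model, delta, n_subjects, n_models = 16,
                              noise_sd = 1, seed = 1L) {
  if (delta < 0) stop("delta must be non-negative")
  vals <- withr_seed(seed, {
    matrix(stats::rnorm(n_subjects * n_models, sd = noise_sd), n_subjects)
  })
  vals[, true_model] <- vals[, true_model] + delta
  evidence_matrix(vals, models = as.character(seq_len(n_models)))
}

#' Generate a synthetic EMG trace for a session
#'
#' Zero-mean Gaussian baseline noise everywhere, with extra zero-mean burst
#' components (amplitude = SD) added during Execution epochs (`a_exec`) and
#' Hand-observation epochs (`a_hand`); both add during Execution+Hand epochs.
#' This emulates execution bursts and weaker automatic-mimicry activity.
#'
#' @param session A `dcm_session`.
#' @param a_exec,a_hand Burst amplitudes (a.u.), `a_exec >= a_hand >= 0`.
#' @param baseline_sd Baseline noise SD.
#' @param rate Sampling rate in Hz (default 1000).
#' @param seed Seed.
#' @return List with `signal` (numeric vector over the acquired timeline),
#'   `rate`, `session`, and the generation settings.
#' @export
generate_emg <- function(session, a_exec = 5, a_hand = 0.5, baseline_sd = 1,
                         rate = 1000, seed = 1L) {
  if (!(a_exec >= a_hand && a_hand >= 0)) stop("need a_exec >= a_hand >= 0")
  dur <- sum(vapply(session$runs, function(r) r$duration, numeric(1)))
  ns <- as.integer(round(dur * rate))
  tmid <- (seq_len(ns) - 0.5) / rate
  offset <- 0
  exec_on <- logical(ns); hand_on <- logical(ns)
  for (run in session$runs) {
    local_t <- tmid - offset
    inside <- local_t >= 0 & local_t < run$duration
    ei <- epoch_at(run, local_t[inside])
    cond <- decode_conditions(run$epochs$condition[ei])
    task <- run$epochs$kind[ei] == "task"
    exec_on[inside] <- task & cond$execution
    hand_on[inside] <- task & cond$hand
    offset <- offset + run$duration
  }
  signal <- withr_seed(seed, {
    x <- stats::rnorm(ns, sd = baseline_sd)
    if (a_exec > 0) x[exec_on] <- x[exec_on] + stats::rnorm(sum(exec_on), sd = a_exec)
    if (a_hand > 0) x[hand_on] <- x[hand_on] + stats::rnorm(sum(hand_on), sd = a_hand)
    x
  })
  list(signal = signal, rate = rate, session = session, a_exec = a_exec,
       a_hand = a_hand, baseline_sd = baseline_sd, seed = as.integer(seed))
}
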