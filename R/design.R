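#' Build a single block-design run
#'
#' A run alternates rest and task epochs, starting and ending with rest:
#' 9 rest epochs interleaved with 8 task epochs, one per condition. With the
#' default 24-s epochs and a 3-s repetition time this gives 17 * 24 = 408 s,
#' i.e. 136 acquired volumes.
#'
#' @param condition_order Character vector of the 8 condition labels
#'   (see [condition_labels()]), each exactly once, in presentation order.
#' @param epoch_s Epoch duration in seconds (must be divisible by `tr`).
#' @param tr Repetition time in seconds.
#' @return An object of class `dcm_run`: epochs table (kind, condition, onset,
#'   duration), `tr`, `epoch_s`, `n_volumes`.
#' @export
#' @examples
#' run <- build_run(condition_labels()$label)
#' run$n_volumes  # 136
build_run <- function(condition_order, epoch_s = 24, tr = 3) {
  labels <- condition_labels()$label
  if (length(condition_order) != 8L || !setequal(condition_order, labels) ||
      anyDuplicated(condition_order)) {
    stop("condition_order must contain each of the 8 condition labels exactly once")
  }
  if (epoch_s <= 0 || tr <= 0) stop("epoch_s and tr must be positive")
  if (abs(epoch_s / tr - round(epoch_s / tr)) > 1e-9) {
    stop("epoch duration must be divisible by the TR")
  }
  n_epochs <- 17L
  kind <- rep(c("rest", "task"), length.out = n_epochs)  # rest first and last
  condition <- rep(NA_character_, n_epochs)
  condition[kind == "task"] <- condition_order
  onset <- (seq_len(n_epochs) - 1L) * epoch_s
  epochs <- data.frame(kind = kind, condition = condition, onset = onset,
                       duration = epoch_s, stringsAsFactors = FALSE)
  out <- list(
    epochs = epochs,
    epoch_s = epoch_s,
    tr = tr,
    duration = n_epochs * epoch_s,
    n_volumes = as.integer(round(n_epochs * epoch_s / tr))
  )
  class(out) <- "dcm_run"
  out
}

#' Assemble runs into a session design
#'
#' Concatenates runs in order and marks the first `discard` volumes of each
#' run as discarded (magnetization stabilization); the remaining volumes form
#' the analyzed time series. The default study has 6 runs of 136 volumes with
#' 3 discarded each: 816 acquired, 798 retained.
#'
#' @param runs List of `dcm_run` objects (all with the same TR).
#' @param discard Number of leading volumes discarded per run.
#' @return Object of class `dcm_session`.
#' @export
build_session <- function(runs, discard = 3) {
  if (inherits(runs, "dcm_run")) runs <- list(runs)
  if (length(runs) < 1L) stop("at least one run required")
  trs <- vapply(runs, function(r) r$tr, numeric(1))
  if (max(trs) - min(trs) > 1e-12) stop("inconsistent TR across runs")
  vols <- vapply(runs, function(r) r$n_volumes, integer(1))
  if (discard < 0 || discard >= min(vols)) {
    stop("discard must be >= 0 and smaller than the per-run volume count")
  }
  out <- list(
    runs = runs,
    n_runs = length(runs),
    tr = trs[1],
    discard = as.integer(discard),
    volumes_per_run = vols,
    retained_per_run = vols - as.integer(discard),
    total_acquired = sum(vols),
    total_retained = sum(vols - as.integer(discard))
  )
  class(out) <- "dcm_session"
  out
}

#' Default six-run session with pseudo-randomized condition orders
#'
#' @param seed Integer seed used to pseudo-randomize the per-run condition
#'   order (recorded in the result).
#' @param n_runs Number of runs.
#' @param epoch_s,tr,discard Design parameters.
#' @return A `dcm_session`; `$seed` and `$condition_orders` record the
#'   randomization.
#' @export
default_session <- function(seed = 1L, n_runs = 6, epoch_s = 24, tr = 3,
                            discard = 3) {
  labels <- condition_labels()$label
  orders <- withr_seed(seed, {
    lapply(seq_len(n_runs), function(i) sample(labels))
  })
  runs <- lapply(orders, build_run, epoch_s = epoch_s, tr = tr)
  sess <- build_session(runs, discard = discard)
  sess$seed <- as.integer(seed)
  sess$condition_orders <- orders
  sess
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Epoch row index containing run-local time t (right-open intervals).
epoch_at <- function(run, t) {
  idx <- findInterval(t, run$epochs$onset)
  idx[t >= run$duration | t < 0] <- NA_integer_
  idx
}

#' Build the three external input time courses at microtime resolution
#'
#' Constructs 0/1 boxcars for the three modeled factors: `task` (any task
#' epoch), `exec` (Execution epochs) and `hand` (Hand-observation epochs).
#' Modulatory inputs are nested within the task boxcar by construction. For a
#' session the returned concatenated matrix covers the retained (analyzed)
#' volumes, with epoch timing referenced to the acquired run start; the
#' per-run acquired-volume boxcars are kept alongside for forward simulation.
#'
#' @param x A `dcm_run` or `dcm_session`.
#' @param bins_per_tr Microtime bins per TR (>= 1), default 16.
#' @param mean_center Logical; if `TRUE` the modulatory (`exec`, `hand`)
#'   boxcars are mean-centered over the covered bins. Default `FALSE`.
#' @return Object of class `dcm_inputs` with `u` (3 x bins matrix over the
#'   retained timeline), `per_run` (list of 3 x bins matrices over acquired
#'   volumes), `bins_per_tr`, `tr`, `discard`.
#' @export
build_inputs <- function(x, bins_per_tr = 16, mean_center = FALSE) {
  if (bins_per_tr < 1) stop("bins_per_tr must be >= 1")
  bins_per_tr <- as.integer(bins_per_tr)
  if (inherits(x, "dcm_run")) {
    sess <- build_session(list(x), discard = 0)
  } else if (inherits(x, "dcm_session")) {
    sess <- x
  } else {
    stop("x must be a dcm_run or dcm_session")
  }
  tr <- sess$tr
  dt <- tr / bins_per_tr
  per_run <- lapply(sess$runs, function(run) {
    nb <- run$n_volumes * bins_per_tr
    tmid <- (seq_len(nb) - 0.5) * dt
    ei <- epoch_at(run, tmid)
    kind <- run$epochs$kind[ei]
    cond <- decode_conditions(run$epochs$condition[ei])
    u <- rbind(
      task = as.numeric(kind == "task"),
      exec = as.numeric(kind == "task" & cond$execution),
      hand = as.numeric(kind == "task" & cond$hand)
    )
    u
  })
  keep <- sess$discard * bins_per_tr
  u <- do.call(cbind, lapply(per_run, function(m) {
    if (keep > 0) m[, -seq_len(keep), drop = FALSE] else m
  }))
  if (mean_center) {
    for (j in c("exec", "hand")) {
      u[j, ] <- u[j, ] - mean(u[j, ])
      per_run <- lapply(per_run, function(m) {
        m[j, ] <- m[j, ] - mean(m[j, ]); m
      })
    }
  }
  out <- list(
    u = u,
    per_run = per_run,
    input_names = c("task", "exec", "hand"),
    bins_per_tr = bins_per_tr,
    tr = tr,
    dt = dt,
    discard = sess$discard,
    mean_center = mean_center
  )
  class(out) <- "dcm_inputs"
  out
}

#' Enumerate per-volume silent windows
#'
#' Each 3-s volume ends with a 600-ms gradient- and RF-free "silent period"
#' (acquisition time 2400 ms, then silence) during which EMG is sampled
#' artifact-free. One window per acquired volume, labeled with the epoch that
#' contains it.
#'
#' @param session A `dcm_session` (or single `dcm_run`).
#' @param silent_s Silent-window duration in seconds (default 0.6).
#' @return data.frame with columns `run`, `volume`, `start`, `end` (run-local
#'   seconds), `session_start`, `session_end` (acquired-timeline seconds),
#'   `kind`, `condition`.
#' @export
silent_windows <- function(session, silent_s = 0.6) {
  if (inherits(session, "dcm_run")) session <- build_session(list(session), 0)
  stopifnot(inherits(session, "dcm_session"))
  tr <- session$tr
  offset <- 0
  out <- vector("list", session$n_runs)
  for (i in seq_len(session$n_runs)) {
    run <- session$runs[[i]]
    vol <- seq_len(run$n_volumes)
    start <- vol * tr - silent_s
    end <- vol * tr
    ei <- epoch_at(run, start)
    out[[i]] <- data.frame(
      run = i, volume = vol, start = start, end = end,
      session_start = start + offset, session_end = end + offset,
      kind = run$epochs$kind[ei],
      condition = run$epochs$condition[ei],
      stringsAsFactors = FALSE
    )
    offset <- offset + run$duration
  }
  do.call(rbind, out)
}

#' Tally silent windows by condition
#'
#' @param windows Output of [silent_windows()].
#' @return data.frame with columns `condition` ("rest" for rest epochs) and
#'   `n`. The default session yields 48 windows per task condition and 432
#'   rest windows.
#' @export
silent_window_tally <- function(windows) {
  lab <- ifelse(windows$kind == "rest", "rest", windows$condition)
  tab <- table(lab)
  data.frame(condition = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' @export
print.dcm_session <- function(x, ...) {
  cat("DCM session design: ", x$n_runs, " run(s), TR ", x$tr, " s, ",
      x$total_acquired, " acquired / ", x$total_retained,
      " retained volumes (discard ", x$discard, "/run)\n", sep = "")
  invisible(x)
}

#' Export an input matrix as delimited text
#'
#' Writes the retained-timeline boxcars as a bins x 3 table with a header row.
#' @param inputs A `dcm_inputs` object.
#' @param path Output file path (tab-separated).
#' @export
write_inputs <- function(inputs, path) {
  m <- t(inputs$u)
  colnames(m) <- inputs$input_names
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
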