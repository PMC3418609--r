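#' Integrate rectified EMG over silent windows
#'
#' For every per-volume silent window the signal is rectified and integrated:
#' value = mean(|signal in window|) * window duration. With multiple channels
#' (e.g. flexor carpi ulnaris and extensor digitorum communis) the per-window
#' values are averaged across channels.
#'
#' @param signal Numeric vector (samples) or samples x channels matrix,
#'   aligned to the acquired session timeline starting at 0 s.
#' @param rate Sampling rate in Hz.
#' @param windows data.frame from [silent_windows()] (uses `session_start`,
#'   `session_end`).
#' @return The `windows` data.frame with an added `value` column (a.u. * s).
#' @export
integrate_windows <- function(signal, rate, windows) {
  sig <- as.matrix(signal)
  n <- nrow(sig)
  i0 <- floor(windows$session_start * rate) + 1L
  i1 <- floor(windows$session_end * rate)
  if (any(i0 < 1) || any(i1 > n)) stop("window outside the recorded trace")
  dur <- windows$session_end - windows$session_start
  vals <- vapply(seq_len(nrow(windows)), function(w) {
    mean(rowMeans(abs(sig[i0[w]:i1[w], , drop = FALSE]))) * dur[w]
  }, numeric(1))
  out <- windows
  out$value <- vals
  out
}

#' Within-subject standardization of window values
#'
#' Standardizes integrated window amplitudes across all windows of a subject:
#' (x - mean) / SD. This normalizes inter-individual variation in overall EMG
#' amplitude before condition contrasts.
#'
#' @param values Numeric vector of integrated window values (>= 2, nonzero
#'   spread).
#' @return Standardized scores (mean 0, SD 1).
#' @export
normalize_scores <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 windows")
  s <- stats::sd(values)
  if (s == 0) stop("zero spread across windows")
  (values - mean(values)) / s
}

#' Task-minus-rest EMG summary per condition
#'
#' For each task condition, the mean normalized score of its windows minus the
#' mean score of all rest windows. Optionally collapses the rotation-direction
#' factor (averaging the Clockwise/Counter-clockwise pair of each
#' execution-by-hand cell).
#'
#' @param scores Numeric vector of normalized scores, one per window.
#' @param windows The matching data.frame from [silent_windows()].
#' @param collapse_direction Collapse CW/CCW (default TRUE), yielding 4
#'   values; otherwise 8.
#' @return data.frame with columns `condition`, `n_windows`, `value`.
#' @export
condition_summary <- function(scores, windows, collapse_direction = TRUE) {
  if (length(scores) != nrow(windows)) stop("scores must match windows")
  rest <- windows$kind == "rest"
  if (!any(rest)) stop("no rest windows present")
  rest_mean <- mean(scores[rest])
  lab <- windows$condition
  if (collapse_direction) lab <- sub("_(CW|CCW)$", "", lab)
  task <- !rest
  expected <- unique(if (collapse_direction) {
    sub("_(CW|CCW)$", "", condition_labels()$label)
  } else {
    condition_labels()$label
  })
  agg <- tapply(scores[task], factor(lab[task], levels = expected), mean)
  if (any(is.na(agg))) stop("missing condition in the window set")
  cnt <- tapply(rep(1, sum(task)), factor(lab[task], levels = expected), sum)
  data.frame(condition = expected,
             n_windows = as.integer(cnt),
             value = as.numeric(agg) - rest_mean,
             stringsAsFactors = FALSE)
}

#' Full single-subject EMG pipeline
#'
#' Rectify/integrate over silent windows, average channels, standardize
#' within subject and form task-minus-rest condition summaries.
#'
#' @inheritParams integrate_windows
#' @param session The `dcm_session` the trace was recorded under.
#' @param collapse_direction See [condition_summary()].
#' @return List with `windows` (with `value` and `score` columns) and
#'   `summary` (condition table).
#' @export
emg_pipeline <- function(signal, rate, session, collapse_direction = TRUE) {
  win <- silent_windows(session)
  win <- integrate_windows(signal, rate, win)
  win$score <- normalize_scores(win$value)
  list(windows = win,
       summary = condition_summary(win$score, win, collapse_direction))
}

#' Write/read an EMG trace as delimited text with a JSON sidecar
#'
#' The data file holds 1-2 columns (one per channel) of signed amplitudes;
#' the sidecar (`<path>.json`) records the sampling rate and any generation
#' settings.
#'
#' @param signal Numeric vector or samples x channels matrix.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param meta Optional named list merged into the sidecar.
#' @export
write_emg <- function(signal, rate, path, meta = list()) {
  sig <- as.matrix(signal)
  colnames(sig) <- paste0("ch", seq_len(ncol(sig)))
  utils::write.table(sig, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(rate = rate, n_channels = ncol(sig)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emg
#' @return `read_emg` returns a list with `signal` (matrix) and `rate`.
#' @export
read_emg <- function(path) {
  sig <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(signal = sig, rate = meta$rate, meta = meta)
}
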