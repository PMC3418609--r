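#' One-sample t test against zero
#'
#' @param values Numeric vector of per-subject estimates (N >= 2).
#' @return List with `t`, `df`, `p` (two-tailed), `mean`, `se`. Zero-variance
#'   input is degenerate: `t`/`p` are NA and `degenerate` is TRUE.
#' @export
one_sample_t <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean = m,
                se = 0, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tval <- m / se
  list(t = tval, df = n - 1L, p = t_to_p(tval, n - 1L), mean = m, se = se,
       degenerate = FALSE)
}

#' Two-tailed p value for a t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return p = 2 P(T_df > |t|).
#' @export
#' @examples
#' round(t_to_p(-3.143, 23), 3)  # 0.005
t_to_p <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Paired t test
#'
#' One-sample t test applied to the paired differences x - y.
#'
#' @param x,y Numeric vectors of equal length (N >= 2).
#' @return As [one_sample_t()].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  one_sample_t(as.numeric(x) - as.numeric(y))
}

#' Benjamini-Hochberg false-discovery-rate step-up procedure
#'
#' Rejects all ordered p-values p(1) <= ... <= p(k*) where
#' k* = max\{k : p(k) <= k q / m\}.
#'
#' @param pvals Numeric vector of p values in [0, 1] (NA allowed; never
#'   rejected, excluded from m).
#' @param q FDR level in (0, 1).
#' @return List with `reject` (logical, same order as input), `p_adj`
#'   (BH-adjusted p values) and `threshold` (largest rejected p, or 0).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p values must lie in [0, 1]")
  m <- sum(ok)
  reject <- rep(FALSE, length(pvals))
  p_adj <- rep(NA_real_, length(pvals))
  if (m > 0) {
    p <- pvals[ok]
    o <- order(p)
    ranked <- p[o]
    adj <- rev(cummin(rev(ranked * m / seq_len(m))))
    adj <- pmin(adj, 1)
    k <- which(ranked <= seq_len(m) * q / m)
    rej_sorted <- rep(FALSE, m)
    if (length(k)) rej_sorted[seq_len(max(k))] <- TRUE
    tmp_r <- tmp_a <- numeric(m)
    tmp_r[o] <- rej_sorted
    tmp_a[o] <- adj
    reject[ok] <- as.logical(tmp_r)
    p_adj[ok] <- tmp_a
  }
  list(reject = reject, p_adj = p_adj,
       threshold = if (any(reject, na.rm = TRUE)) max(pvals[reject], na.rm = TRUE) else 0)
}

#' Per-connection one-sample t tests with FDR correction
#'
#' One table per coupling factor (baseline A, Execution B, Hand B): every
#' enabled connection is tested against zero and the Benjamini-Hochberg
#' correction is applied across the connections of that table.
#'
#' @param estimates Subjects x connections numeric matrix; column names of the
#'   form "from->to" (or any identifier) label the connections.
#' @param factor_label Label stored in the table ("baseline", "exec", "hand",
#'   "contrast").
#' @param q FDR level.
#' @return data.frame of class `connection_table` with columns `connection`,
#'   `factor`, `mean`, `se`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
connection_tests <- function(estimates, factor_label = "baseline", q = 0.05) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop("need at least 2 subjects")
  conns <- colnames(estimates)
  if (is.null(conns)) conns <- paste0("c", seq_len(ncol(estimates)))
  rows <- lapply(seq_len(ncol(estimates)), function(j) {
    r <- one_sample_t(estimates[, j])
    data.frame(connection = conns[j], factor = factor_label, mean = r$mean,
               se = r$se, t = r$t, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fdr <- bh_fdr(tab$p, q)
  tab$p_adj <- fdr$p_adj
  tab$significant <- fdr$reject
  class(tab) <- c("connection_table", "data.frame")
  tab
}

#' Paired contrast of Execution vs Hand modulation
#'
#' Per-connection paired t tests of the Execution-minus-Hand modulatory
#' couplings, FDR-corrected across the table.
#'
#' @param B_exec,B_hand Subjects x connections matrices with matching shape
#'   and column names.
#' @param q FDR level.
#' @return A `connection_table` (factor "contrast").
#' @export
modulator_contrast <- function(B_exec, B_hand, q = 0.05) {
  B_exec <- as.matrix(B_exec)
  B_hand <- as.matrix(B_hand)
  if (!all(dim(B_exec) == dim(B_hand))) stop("shape mismatch")
  connection_tests(B_exec - B_hand, factor_label = "contrast", q = q)
}

#' Write a connection table as CSV
#' @param tab A `connection_table`.
#' @param path Output path.
#' @export
write_connection_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
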