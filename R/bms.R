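#' Assemble a subjects x models evidence matrix
#'
#' @param values Numeric matrix (subjects x models) of log evidences (nats),
#'   or a list of per-subject named vectors.
#' @param subjects,models Optional dimension names.
#' @return Object of class `evidence_matrix`.
#' @export
evidence_matrix <- function(values, subjects = NULL, models = NULL) {
  if (is.list(values) && !is.matrix(values)) {
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("evidence matrix must be finite")
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("need at least 1 subject and 2 models")
  }
  if (!is.null(subjects)) rownames(values) <- subjects
  if (!is.null(models)) colnames(values) <- models
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("m", seq_len(ncol(values)))
  structure(list(values = values), class = "evidence_matrix")
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of the Dirichlet posterior over model frequencies
#' in the population. Fixed-point iteration: subject-wise responsibilities
#' g_nk proportional to exp(ev_nk + psi(alpha_k) - psi(sum alpha)), then
#' alpha_k = alpha0_k + sum_n g_nk, until max |delta alpha| < tol.
#'
#' @param ev An `evidence_matrix` (or plain subjects x models matrix).
#' @param alpha0 Prior Dirichlet concentrations (scalar recycled; default 1,
#'   the uniform prior over models).
#' @param tol Convergence tolerance on alpha.
#' @param max_iter Maximum fixed-point iterations.
#' @return Object of class `bms_dirichlet`: `alpha`, `alpha0`,
#'   `responsibilities` (rows sum to 1), `expected` (alpha / sum(alpha)),
#'   `converged`, `iterations`.
#' @export
rfx_bms <- function(ev, alpha0 = 1, tol = 1e-6, max_iter = 500L) {
  if (inherits(ev, "evidence_matrix")) ev <- ev$values
  ev <- as.matrix(ev)
  K <- ncol(ev)
  alpha0 <- rep_len(alpha0, K)
  if (any(alpha0 <= 0)) stop("alpha0 must be positive")
  alpha <- alpha0 + nrow(ev) / K
  g <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    lg <- sweep(ev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  structure(list(alpha = stats::setNames(alpha, colnames(ev)),
                 alpha0 = stats::setNames(alpha0, colnames(ev)),
                 responsibilities = g,
                 expected = stats::setNames(alpha / sum(alpha), colnames(ev)),
                 converged = converged, iterations = iter),
            class = "bms_dirichlet")
}

# Monte-Carlo draws from Dirichlet(alpha), chunked to bound memory; applies
# `count_fun(r_chunk)` (rows = draws) and accumulates integer counts.
.dirichlet_mc <- function(alpha, n_samples, seed, count_fun, K_out) {
  counts <- integer(K_out)
  withr_seed(seed, {
    left <- n_samples
    chunk <- 100000L
    while (left > 0) {
      nb <- min(chunk, left)
      gm <- matrix(stats::rgamma(nb * length(alpha),
                                 shape = rep(alpha, each = nb)), nrow = nb)
      r <- gm / rowSums(gm)
      counts <- counts + count_fun(r)
      left <- left - nb
    }
  })
  counts
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo estimate of phi_k = P(r_k > r_j for all j != k) under
#' Dirichlet(alpha), by argmax counting (so sum(phi) is exactly 1).
#'
#' @param alpha Dirichlet concentration vector.
#' @param n_samples Number of draws (>= 1e4; default 1e6).
#' @param seed Seed for the draws.
#' @return Named numeric vector phi summing to 1.
#' @export
exceedance <- function(alpha, n_samples = 1e6, seed = 1L) {
  if (inherits(alpha, "bms_dirichlet")) alpha <- alpha$alpha
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  K <- length(alpha)
  counts <- .dirichlet_mc(alpha, n_samples, seed, function(r) {
    tabulate(max.col(r, ties.method = "first"), K)
  }, K)
  stats::setNames(counts / n_samples, names(alpha))
}

#' Family-level inference over a model-space partition
#'
#' Re-runs the random-effects estimation with the Dirichlet prior rebalanced
#' so every family carries equal prior mass (alpha0_k = 1 / |family(k)|),
#' then reports family expected probabilities (summed Dirichlet means) and
#' family exceedance probabilities (Monte-Carlo probability that the family's
#' summed frequency is the largest).
#'
#' @param ev An `evidence_matrix`; column names must be model ids present in
#'   the partition.
#' @param partition A `family_partition` (see [partitions()]) or a named
#'   character vector mapping model id to family.
#' @param n_samples Monte-Carlo draws (default 1e6).
#' @param seed Seed for the draws.
#' @param ... Passed to [rfx_bms()].
#' @return List with `families`, `expected`, `exceedance`, `alpha`, `bms`,
#'   `n_samples`, `seed`.
#' @export
family_inference <- function(ev, partition, n_samples = 1e6, seed = 1L, ...) {
  if (inherits(ev, "evidence_matrix")) ev <- ev$values
  assignment <- if (inherits(partition, "family_partition")) {
    partition$assignment
  } else {
    partition
  }
  ids <- colnames(ev)
  fam <- assignment[ids]
  if (any(is.na(fam))) stop("partition does not cover the model set")
  fams <- unique(unname(assignment[names(assignment) %in% ids]))
  sizes <- table(factor(fam, levels = fams))
  if (any(sizes == 0)) stop("empty family")
  alpha0 <- 1 / as.numeric(sizes[fam])
  bms <- rfx_bms(ev, alpha0 = alpha0, ...)
  fam_f <- factor(fam, levels = fams)
  expected <- tapply(bms$expected, fam_f, sum)
  Kf <- length(fams)
  fam_idx <- as.integer(fam_f)
  counts <- .dirichlet_mc(bms$alpha, n_samples, seed, function(r) {
    fr <- t(rowsum(t(r), fam_idx))  # draws x families
    tabulate(max.col(fr, ties.method = "first"), Kf)
  }, Kf)
  list(families = fams,
       expected = stats::setNames(as.numeric(expected), fams),
       exceedance = stats::setNames(counts / n_samples, fams),
       alpha = bms$alpha,
       bms = bms,
       n_samples = n_samples,
       seed = seed)
}

#' @export
print.bms_dirichlet <- function(x, ...) {
  cat("RFX BMS Dirichlet posterior over", length(x$alpha), "models",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(rbind(alpha = x$alpha, expected = x$expected), 4))
  invisible(x)
}

#' Write/read an evidence matrix as CSV (rows subjects, columns models)
#' @param ev An `evidence_matrix`.
#' @param path CSV path.
#' @export
write_evidence <- function(ev, path) {
  utils::write.csv(ev$values, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  evidence_matrix(as.matrix(m))
}
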