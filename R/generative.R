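#' Balloon-model hemodynamic parameters
#'
#' Canonical defaults for the hemodynamic forward model: signal decay
#' kappa = 0.65 1/s, flow-dependent elimination gamma = 0.41 1/s, mean transit
#' time tau = 0.98 s, Grubb exponent alpha = 0.32, resting oxygen extraction
#' rho = 0.34, resting venous volume fraction V0 = 0.04 and neuronal efficacy
#' epsilon = 1. All are per-region vectors and configurable.
#'
#' @param n Number of regions.
#' @param kappa,gamma,tau,alpha,rho,V0,epsilon Scalars or length-n vectors.
#' @return List of length-n parameter vectors (class `hemo_params`).
#' @export
hemo_defaults <- function(n = 7, kappa = 0.65, gamma = 0.41, tau = 0.98,
                          alpha = 0.32, rho = 0.34, V0 = 0.04, epsilon = 1) {
  expand <- function(x) {
    x <- rep_len(as.numeric(x), n)
    if (any(!is.finite(x)) || any(x <= 0)) stop("hemodynamic parameters must be positive")
    x
  }
  out <- list(kappa = expand(kappa), gamma = expand(gamma), tau = expand(tau),
              alpha = expand(alpha), rho = expand(rho), V0 = expand(V0),
              epsilon = expand(epsilon))
  if (any(out$alpha >= 1) || any(out$rho >= 1)) {
    stop("alpha and rho must lie in (0, 1)")
  }
  class(out) <- "hemo_params"
  out
}

#' Neural coupling parameter set
#'
#' Bundles the baseline coupling matrix A (Hz), the per-input modulatory
#' matrices B (Hz) and the direct input gains C (Hz) of the bilinear neural
#' model dz/dt = (A + sum_j u_j B^(j)) z + C u. Matrices are indexed
#' (to, from): entry [i, k] couples region k onto region i.
#'
#' @param A n x n baseline matrix, strictly negative diagonal.
#' @param B List of m n x n modulatory matrices (zero diagonal).
#' @param C n x m input gain matrix.
#' @param regions Region names (rows of A).
#' @param input_names Input names (columns of C).
#' @return Object of class `dcm_params`.
#' @export
dcm_parameters <- function(A, B, C, regions = rownames(A),
                           input_names = colnames(C)) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (any(diag(A) >= 0)) stop("diagonal of A must be strictly negative")
  if (!is.list(B)) B <- list(B)
  B <- lapply(B, as.matrix)
  if (any(vapply(B, function(b) any(dim(b) != n), logical(1)))) {
    stop("every B matrix must be n x n")
  }
  C <- as.matrix(C)
  if (nrow(C) != n || ncol(C) != length(B)) {
    stop("C must be n x m with m = length(B)")
  }
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  if (is.null(input_names)) input_names <- paste0("u", seq_along(B))
  structure(list(A = A, B = B, C = C, n = n, m = length(B),
                 regions = regions, input_names = input_names),
            class = "dcm_params")
}

#' Neural state derivative of the bilinear model
#'
#' Evaluates dz/dt = (A + sum_j u_j B^(j)) z + C u.
#'
#' @param z Length-n neural state vector.
#' @param u Length-m input vector at the current time.
#' @param params A `dcm_params` object.
#' @return Length-n derivative (Hz x activity units).
#' @export
neural_derivative <- function(z, u, params) {
  if (length(z) != params$n) stop("state dimension mismatch")
  if (length(u) != params$m) stop("input dimension mismatch")
  Aeff <- params$A
  for (j in seq_len(params$m)) Aeff <- Aeff + u[j] * params$B[[j]]
  drop(Aeff %*% z + params$C %*% u)
}

#' Balloon-model state derivative for one region
#'
#' States: vasodilatory signal s, inflow f, venous volume v, deoxyhemoglobin
#' q. With oxygen extraction E(f, rho) = 1 - (1 - rho)^(1/f):
#' ds/dt = eps z - kappa s - gamma (f - 1); df/dt = s;
#' tau dv/dt = f - v^(1/alpha); tau dq/dt = f E/rho - v^(1/alpha) q / v.
#'
#' @param h Named list or vector with `s`, `f`, `v`, `q` (f, v, q > 0).
#' @param z_i Neural activity of the region.
#' @param hp A `hemo_params` object.
#' @param region Region index into `hp`.
#' @return Named vector c(s, f, v, q) of time derivatives.
#' @export
hemo_derivative <- function(h, z_i, hp, region = 1) {
  s <- h[["s"]]; f <- h[["f"]]; v <- h[["v"]]; q <- h[["q"]]
  if (f <= 0 || v <= 0 || q <= 0) stop("f, v and q must be positive")
  i <- region
  fv <- v^(1 / hp$alpha[i])
  E <- 1 - (1 - hp$rho[i])^(1 / f)
  c(s = hp$epsilon[i] * z_i - hp$kappa[i] * s - hp$gamma[i] * (f - 1),
    f = s,
    v = (f - fv) / hp$tau[i],
    q = (f * E / hp$rho[i] - fv * q / v) / hp$tau[i])
}

#' BOLD observation equation
#'
#' y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)) with k1 = 7 rho, k2 = 2,
#' k3 = 2 rho - 0.2. Zero at the resting point v = q = 1.
#'
#' @param v,q Venous volume and deoxyhemoglobin (positive).
#' @param hp A `hemo_params` object.
#' @param region Region index.
#' @return Scalar BOLD signal (fraction of baseline).
#' @export
bold_observation <- function(v, q, hp, region = 1) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  i <- region
  rho <- hp$rho[i]
  hp$V0[i] * (7 * rho * (1 - q) + 2 * (1 - q / v) + (2 * rho - 0.2) * (1 - v))
}

# Collapse a (m x bins) input matrix to distinct input combinations.
# Returns Ucombo (n_combo x m) and idx (1-based combo per bin).
input_combos <- function(u) {
  key <- apply(u, 2, paste, collapse = "\r")
  uk <- unique(key)
  idx <- match(key, uk)
  Ucombo <- t(u[, match(uk, key), drop = FALSE])
  list(Ucombo = Ucombo, idx = as.integer(idx))
}

# Largest real eigenvalue part over the attainable effective matrices.
stability_margin <- function(params, inputs) {
  combos <- unique(do.call(rbind, lapply(inputs$per_run, function(m) {
    input_combos(m)$Ucombo
  })))
  worst <- -Inf
  for (r in seq_len(nrow(combos))) {
    Aeff <- params$A
    for (j in seq_len(params$m)) Aeff <- Aeff + combos[r, j] * params$B[[j]]
    worst <- max(worst, max(Re(eigen(Aeff, only.values = TRUE)$values)))
  }
  worst
}

# Integrate one run (all acquired volumes). u is m x (n_vol * bins_per_tr).
integrate_run <- function(params, hemo, u, bins_per_tr, dt, n_vol,
                          engine = "cpp") {
  cmb <- input_combos(u)
  if (engine == "cpp") {
    Bcube <- array(unlist(params$B), dim = c(params$n, params$n, params$m))
    res <- dcm_integrate_cpp(params$A, Bcube, params$C, cmb$Ucombo, cmb$idx,
                             as.integer(bins_per_tr), dt, as.integer(n_vol),
                             hemo$kappa, hemo$gamma, hemo$tau, hemo$alpha,
                             hemo$rho, hemo$V0, hemo$epsilon)
    return(res)
  }
  integrate_run_r(params, hemo, cmb, bins_per_tr, dt, n_vol)
}

# Pure-R reference RK4 integrator (oracle for the compiled path; slow).
integrate_run_r <- function(params, hemo, cmb, bins_per_tr, dt, n_vol) {
  n <- params$n
  Aeff <- lapply(seq_len(nrow(cmb$Ucombo)), function(r) {
    M <- params$A
    for (j in seq_len(params$m)) M <- M + cmb$Ucombo[r, j] * params$B[[j]]
    M
  })
  Cu <- lapply(seq_len(nrow(cmb$Ucombo)), function(r) {
    drop(params$C %*% cmb$Ucombo[r, ])
  })
  ia <- 1 / hemo$alpha
  l1r <- log(1 - hemo$rho)
  state <- c(rep(0, 2 * n), rep(1, 3 * n))  # z, s, f, v, q
  dfun <- function(x, M, d) {
    z <- x[1:n]; s <- x[(n + 1):(2 * n)]
    f <- x[(2 * n + 1):(3 * n)]; v <- x[(3 * n + 1):(4 * n)]
    q <- x[(4 * n + 1):(5 * n)]
    fv <- exp(log(v) * ia)
    E <- 1 - exp(l1r / f)
    c(drop(M %*% z + d),
      hemo$epsilon * z - hemo$kappa * s - hemo$gamma * (f - 1),
      s,
      (f - fv) / hemo$tau,
      (f * E / hemo$rho - fv * q / v) / hemo$tau)
  }
  y <- matrix(0, n_vol, n)
  bin <- 1L
  for (vol in seq_len(n_vol)) {
    for (b in seq_len(bins_per_tr)) {
      cidx <- cmb$idx[bin]
      M <- Aeff[[cidx]]; d <- Cu[[cidx]]
      k1 <- dfun(state, M, d)
      k2 <- dfun(state + 0.5 * dt * k1, M, d)
      k3 <- dfun(state + 0.5 * dt * k2, M, d)
      k4 <- dfun(state + dt * k3, M, d)
      state <- state + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(state)) || max(abs(state[1:n])) > 1e6) {
        return(list(y = y, diverged = TRUE))
      }
      bin <- bin + 1L
    }
    v <- state[(3 * n + 1):(4 * n)]; q <- state[(4 * n + 1):(5 * n)]
    if (any(v <= 0) || any(q <= 0)) return(list(y = y, diverged = TRUE))
    y[vol, ] <- hemo$V0 * (7 * hemo$rho * (1 - q) + 2 * (1 - q / v) +
                           (2 * hemo$rho - 0.2) * (1 - v))
  }
  list(y = y, diverged = FALSE)
}

# Noise-free session prediction: integrate each run over its acquired
# volumes, drop the discarded leading volumes, concatenate. Returns values
# matrix (retained volumes x regions) or NULL on divergence.
predict_session <- function(params, hemo, inputs, engine = "cpp") {
  out <- vector("list", length(inputs$per_run))
  for (r in seq_along(inputs$per_run)) {
    u <- inputs$per_run[[r]]
    n_vol <- ncol(u) / inputs$bins_per_tr
    res <- integrate_run(params, hemo, u, inputs$bins_per_tr, inputs$dt,
                         n_vol, engine)
    if (isTRUE(res$diverged)) return(NULL)
    y <- res$y
    if (inputs$discard > 0) y <- y[-seq_len(inputs$discard), , drop = FALSE]
    out[[r]] <- y
  }
  do.call(rbind, out)
}

#' Simulate region-of-interest BOLD time series
#'
#' Integrates the coupled neural and hemodynamic states at microtime
#' resolution (RK4), samples BOLD at the end of every TR, drops the discarded
#' leading volumes of each run and optionally adds i.i.d. Gaussian
#' observation noise per region at the volume level.
#'
#' @param params A `dcm_params` object.
#' @param hemo A `hemo_params` object (defaults for `params$n` regions).
#' @param inputs A `dcm_inputs` object from [build_inputs()].
#' @param noise_sd Per-region noise SD (scalar recycled); 0 = deterministic.
#' @param seed Optional seed for the noise draw.
#' @param engine "cpp" (compiled, default) or "R" (reference implementation).
#' @param check_stability If TRUE (default) error when any attainable
#'   effective coupling matrix has an eigenvalue with non-negative real part.
#' @return Object of class `roi_ts`: `values` (retained volumes x regions),
#'   `regions`, `tr`, `run_lengths`, `noise_sd`, `seed`.
#' @export
simulate_bold <- function(params, hemo = NULL, inputs, noise_sd = 0,
                          seed = NULL, engine = c("cpp", "R"),
                          check_stability = TRUE) {
  engine <- match.arg(engine)
  if (is.null(hemo)) hemo <- hemo_defaults(params$n)
  if (check_stability && stability_margin(params, inputs) >= 0) {
    stop("unstable parameter set: an attainable effective coupling matrix has a non-negative eigenvalue")
  }
  y <- predict_session(params, hemo, inputs, engine)
  if (is.null(y)) stop("forward integration diverged")
  noise_sd <- rep_len(noise_sd, params$n)
  if (any(noise_sd > 0)) {
    draw <- function() {
      y + matrix(stats::rnorm(length(y), sd = rep(noise_sd, each = nrow(y))),
                 nrow(y), ncol(y))
    }
    y <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  }
  run_lengths <- vapply(inputs$per_run, function(u) {
    as.integer(ncol(u) / inputs$bins_per_tr - inputs$discard)
  }, integer(1))
  roi_ts(y, regions = params$regions, tr = inputs$tr,
         run_lengths = run_lengths, noise_sd = noise_sd, seed = seed)
}

#' Construct a region-of-interest time-series object
#'
#' @param values Volumes x regions numeric matrix.
#' @param regions Region names (one per column).
#' @param tr Repetition time in seconds.
#' @param run_lengths Retained volumes per run (sums to nrow(values)).
#' @param noise_sd,seed Provenance, stored as attributes of the object.
#' @return Object of class `roi_ts`.
#' @export
roi_ts <- function(values, regions, tr, run_lengths = nrow(values),
                   noise_sd = NA_real_, seed = NULL) {
  values <- as.matrix(values)
  if (length(regions) != ncol(values)) stop("region names must match columns")
  if (sum(run_lengths) != nrow(values)) stop("run lengths must sum to the volume count")
  if (any(!is.finite(values))) stop("non-finite values in time series")
  colnames(values) <- regions
  structure(list(values = values, regions = regions, tr = tr,
                 run_lengths = as.integer(run_lengths),
                 noise_sd = noise_sd, seed = seed),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("ROI time series: ", nrow(x$values), " volumes x ", ncol(x$values),
      " regions, TR ", x$tr, " s, runs ",
      paste(x$run_lengths, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Write/read ROI time series as delimited text with a JSON sidecar
#'
#' The data file is tab-separated with a one-line header of region names; the
#' sidecar (`<path>.json`) records TR, run lengths, noise SD and seed.
#'
#' @param ts A `roi_ts` object.
#' @param path Output path for the data table.
#' @export
write_roi_ts <- function(ts, path) {
  utils::write.table(ts$values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(tr = ts$tr, run_lengths = ts$run_lengths,
               noise_sd = ts$noise_sd, seed = ts$seed, regions = ts$regions)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @return `read_roi_ts` returns the reconstructed `roi_ts`.
#' @export
read_roi_ts <- function(path) {
  values <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                        check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  roi_ts(values, regions = meta$regions, tr = meta$tr,
         run_lengths = meta$run_lengths, noise_sd = meta$noise_sd,
         seed = meta$seed)
}
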