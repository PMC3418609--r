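# Model inversion: Gauss-Newton updates of the posterior mode under shrinkage
# priors, interleaved with EM updates of per-region noise precision, scored by
# a Laplace free-energy approximation to the log model evidence.

# Table of free parameters for a model. Inputs are ordered (task, exec, hand);
# the task factor has no modulatory matrix. `idx` is the linear index of each
# entry within its (to, from) matrix, `slice` the B slice (input index).
param_table <- function(model, estimate_tau = FALSE) {
  regions <- model$regions
  n <- length(regions)
  rows <- list()
  a <- model$a_edges
  rows$A <- data.frame(
    kind = "A", input = NA_character_, from = a$from, to = a$to, slice = NA_integer_,
    idx = match(a$to, regions) + (match(a$from, regions) - 1L) * n,
    name = paste0("A:", a$from, "->", a$to),
    prior_mean = 0, prior_var = 0.25, stringsAsFactors = FALSE)
  input_names <- c("task", "exec", "hand")
  for (fac in names(model$b_edges)) {
    b <- model$b_edges[[fac]]
    rows[[paste0("B_", fac)]] <- data.frame(
      kind = "B", input = fac, from = b$from, to = b$to,
      slice = match(fac, input_names),
      idx = match(b$to, regions) + (match(b$from, regions) - 1L) * n,
      name = paste0("B[", fac, "]:", b$from, "->", b$to),
      prior_mean = 0, prior_var = 0.25, stringsAsFactors = FALSE)
  }
  cc <- model$c_inputs
  rows$C <- data.frame(
    kind = "C", input = cc$input, from = NA_character_, to = cc$region,
    slice = NA_integer_,
    idx = match(cc$region, regions) + (match(cc$input, input_names) - 1L) * n,
    name = paste0("C[", cc$input, "]->", cc$region),
    prior_mean = 0, prior_var = 1, stringsAsFactors = FALSE)
  if (estimate_tau) {
    rows$tau <- data.frame(
      kind = "tau", input = NA_character_, from = NA_character_, to = regions,
      slice = NA_integer_, idx = seq_len(n),
      name = paste0("tau:", regions),
      prior_mean = 0, prior_var = 0.0156, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Default shrinkage priors for a model's free parameters
#'
#' Enabled A off-diagonal and B entries get independent Normal(0, 0.25 Hz^2)
#' shrinkage priors; enabled C entries Normal(0, 1). Disabled entries are
#' fixed at zero (not part of the parameter vector). Hemodynamic parameters
#' are fixed at their defaults unless `estimate_tau = TRUE`, which adds one
#' log-scale transit-time parameter per region (Normal(0, 0.0156)).
#'
#' @param model A `dcm_model`.
#' @param estimate_tau Estimate per-region transit time tau?
#' @return Object of class `dcm_prior`: `mean`, `var` (named vectors) and the
#'   parameter `table`.
#' @export
default_priors <- function(model, estimate_tau = FALSE) {
  tab <- param_table(model, estimate_tau)
  structure(list(mean = stats::setNames(tab$prior_mean, tab$name),
                 var = stats::setNames(tab$prior_var, tab$name),
                 table = tab, estimate_tau = estimate_tau),
            class = "dcm_prior")
}

# Build (A, B-cube, C, hemo) from a parameter vector. Diagonal of A is fixed
# at -0.5 Hz (not estimated; guarantees baseline stability).
theta_to_matrices <- function(theta, tab, n, hemo0, a_diag = -0.5) {
  A <- diag(a_diag, n)
  Bc <- array(0, dim = c(n, n, 3L))
  C <- matrix(0, n, 3L)
  ka <- tab$kind == "A"; kb <- tab$kind == "B"; kc <- tab$kind == "C"
  A[tab$idx[ka]] <- theta[ka]
  if (any(kb)) Bc[tab$idx[kb] + (tab$slice[kb] - 1L) * n * n] <- theta[kb]
  C[tab$idx[kc]] <- theta[kc]
  hemo <- hemo0
  kt <- tab$kind == "tau"
  if (any(kt)) hemo$tau <- hemo0$tau * exp(theta[kt])
  list(A = A, B = Bc, C = C, hemo = hemo)
}

# Discrete-cosine confound basis per run: intercept plus DCT regressors with
# period above `cutoff` seconds, assembled block-diagonally over runs.
confound_matrix <- function(run_lengths, tr, cutoff = 128) {
  blocks <- lapply(run_lengths, function(T) {
    k <- floor(2 * T * tr / cutoff)
    t_idx <- seq_len(T) - 1L
    X <- matrix(1, T, 1L)
    if (k >= 1) {
      dct <- vapply(seq_len(k), function(r) {
        cos(pi * (2 * t_idx + 1) * r / (2 * T))
      }, numeric(T))
      X <- cbind(X, dct)
    }
    X
  })
  total <- sum(run_lengths)
  ncols <- vapply(blocks, ncol, integer(1))
  X0 <- matrix(0, total, sum(ncols))
  row0 <- 0L; col0 <- 0L
  for (i in seq_along(blocks)) {
    X0[row0 + seq_len(run_lengths[i]), col0 + seq_len(ncols[i])] <- blocks[[i]]
    row0 <- row0 + run_lengths[i]; col0 <- col0 + ncols[i]
  }
  X0
}

#' Invert a DCM for one subject and one model
#'
#' Alternates Gauss-Newton updates of the posterior mode (linearizing the
#' forward model by finite differences) with EM updates of per-region noise
#' precision, and scores the fit with the Laplace free energy
#' F = accuracy - KL(posterior || prior). Run-wise intercepts and a 128-s
#' discrete-cosine high-pass basis are projected out of both data and
#' prediction. Steps are accepted only when F improves (step-halving
#' otherwise), so the accepted-iteration F trace is non-decreasing.
#'
#' @param model A `dcm_model`.
#' @param data A `roi_ts` whose regions and volume count match the design.
#' @param inputs A `dcm_inputs` from [build_inputs()].
#' @param prior A `dcm_prior` (default [default_priors()]).
#' @param opts List of options: `tol` (nats, default 0.01), `max_iter` (64),
#'   `jacobian` ("sensitivity" for exact forward sensitivities, the default,
#'   or "fd" for finite differences), `fd_h` (finite-difference step, 1e-4),
#'   `max_halvings` (8), `lambda_fixed` (per-region noise precision held
#'   fixed, disables EM), `hp_cutoff` (high-pass seconds, 128), `hemo` (a
#'   `hemo_params`), `a_diag` (fixed self-decay, -0.5), `verbose`.
#' @return Object of class `dcm_posterior`: `mean`, `cov`, `F`, `F_trace`,
#'   `lambda`, `iterations`, `converged`, `table`, `model_id`.
#' @export
invert_dcm <- function(model, data, inputs, prior = default_priors(model),
                       opts = list()) {
  o <- utils::modifyList(list(tol = 0.01, max_iter = 64L,
                              jacobian = "sensitivity", fd_h = 1e-4,
                              max_halvings = 8L, lambda_fixed = NULL,
                              hp_cutoff = 128, hemo = NULL, a_diag = -0.5,
                              verbose = FALSE), opts)
  if (!identical(data$regions, model$regions)) {
    stop("data regions do not match model regions")
  }
  n <- length(model$regions)
  hemo0 <- if (is.null(o$hemo)) hemo_defaults(n) else o$hemo
  tab <- prior$table
  p <- nrow(tab)
  mu0 <- as.numeric(prior$mean)
  pv <- as.numeric(prior$var)
  if (any(pv <= 0)) stop("free parameters must have positive prior variance")
  P0d <- 1 / pv

  # Precompute per-run input combinations once (shared by all simulations).
  runs <- lapply(inputs$per_run, function(u) {
    cmb <- input_combos(u)
    list(Ucombo = cmb$Ucombo, idx = cmb$idx,
         n_vol = as.integer(ncol(u) / inputs$bins_per_tr))
  })
  retained <- vapply(runs, function(r) r$n_vol - inputs$discard, integer(1))
  if (sum(retained) != nrow(data$values)) {
    stop("data volume count does not match the input design")
  }

  X0 <- confound_matrix(retained, inputs$tr, o$hp_cutoff)
  qrX <- qr(X0)
  project <- function(M) qr.resid(qrX, M)
  Y <- project(data$values)
  T_vol <- nrow(Y)
  T_eff <- T_vol - qrX$rank

  simulate_theta <- function(theta) {
    mats <- theta_to_matrices(theta, tab, n, hemo0, o$a_diag)
    out <- vector("list", length(runs))
    for (r in seq_along(runs)) {
      res <- dcm_integrate_cpp(mats$A, mats$B, mats$C, runs[[r]]$Ucombo,
                               runs[[r]]$idx, inputs$bins_per_tr, inputs$dt,
                               runs[[r]]$n_vol, mats$hemo$kappa,
                               mats$hemo$gamma, mats$hemo$tau,
                               mats$hemo$alpha, mats$hemo$rho, mats$hemo$V0,
                               mats$hemo$epsilon)
      if (isTRUE(res$diverged)) return(NULL)
      y <- res$y
      if (inputs$discard > 0) y <- y[-seq_len(inputs$discard), , drop = FALSE]
      out[[r]] <- y
    }
    project(do.call(rbind, out))
  }

  jacobian_fd <- function(theta, g0) {
    J <- matrix(0, T_vol * n, p)
    for (k in seq_len(p)) {
      th <- theta; th[k] <- th[k] + o$fd_h
      gk <- simulate_theta(th)
      if (is.null(gk)) {
        th[k] <- theta[k] - o$fd_h  # fall back to a backward difference
        gk <- simulate_theta(th)
        if (is.null(gk)) stop("forward simulation diverged while linearizing")
        J[, k] <- as.numeric(g0 - gk) / o$fd_h
      } else {
        J[, k] <- as.numeric(gk - g0) / o$fd_h
      }
    }
    J
  }

  # Parameter spec for the compiled sensitivity integrator.
  kind_code <- match(tab$kind, c("A", "B", "C", "tau")) - 1L
  prow <- as.integer((tab$idx - 1L) %% n + 1L)
  pcol <- as.integer((tab$idx - 1L) %/% n + 1L)
  pslice <- ifelse(is.na(tab$slice), 1L, as.integer(tab$slice))

  # Simulate and linearize in one pass; returns list(g, J) or NULL.
  sens_theta <- function(theta) {
    mats <- theta_to_matrices(theta, tab, n, hemo0, o$a_diag)
    Ys <- vector("list", length(runs))
    Jarr <- array(0, dim = c(T_vol, n, p))
    row0 <- 0L
    for (r in seq_along(runs)) {
      res <- dcm_sensitivities_cpp(mats$A, mats$B, mats$C, runs[[r]]$Ucombo,
                                   runs[[r]]$idx, inputs$bins_per_tr,
                                   inputs$dt, runs[[r]]$n_vol, kind_code,
                                   prow, pcol, pslice, mats$hemo$kappa,
                                   mats$hemo$gamma, mats$hemo$tau,
                                   mats$hemo$alpha, mats$hemo$rho,
                                   mats$hemo$V0, mats$hemo$epsilon)
      if (isTRUE(res$diverged)) return(NULL)
      y <- res$y
      arr <- array(res$J, dim = c(runs[[r]]$n_vol, n, p))
      if (inputs$discard > 0) {
        y <- y[-seq_len(inputs$discard), , drop = FALSE]
        arr <- arr[-seq_len(inputs$discard), , , drop = FALSE]
      }
      Ys[[r]] <- y
      Jarr[row0 + seq_len(nrow(y)), , ] <- arr
      row0 <- row0 + nrow(y)
    }
    g <- project(do.call(rbind, Ys))
    Jflat <- qr.resid(qrX, matrix(Jarr, T_vol, n * p))
    list(g = g, J = matrix(Jflat, T_vol * n, p))
  }

  model_eval <- function(theta) {
    if (o$jacobian == "sensitivity") return(sens_theta(theta))
    g <- simulate_theta(theta)
    if (is.null(g)) return(NULL)
    list(g = g, J = jacobian_fd(theta, g))
  }

  region_of_row <- rep(seq_len(n), each = T_vol)

  # Posterior curvature and free energy for a given (theta, g, J, lambda).
  evaluate <- function(theta, g, J, lambda) {
    lam_rep <- lambda[region_of_row]
    Jw <- J * sqrt(lam_rep)
    H <- crossprod(Jw)
    diag(H) <- diag(H) + P0d
    ch <- tryCatch(chol(H), error = function(e) NULL)
    ridge <- 1e-8 * max(diag(H))
    while (is.null(ch)) {
      diag(H) <- diag(H) + ridge
      ch <- tryCatch(chol(H), error = function(e) NULL)
      ridge <- ridge * 10
      if (ridge > 1e6 * max(diag(H))) stop("singular curvature in inversion")
    }
    Sigma <- chol2inv(ch)
    logdet_Sigma <- -2 * sum(log(diag(ch)))
    E <- Y - g
    sse <- colSums(E^2)
    acc <- sum(-0.5 * lambda * sse + 0.5 * T_eff * log(lambda) -
               0.5 * T_eff * log(2 * pi))
    d <- theta - mu0
    kl <- 0.5 * (sum(P0d * diag(Sigma)) + sum(d^2 * P0d) - p +
                 sum(log(pv)) - logdet_Sigma)
    list(F = acc - kl, H = H, Sigma = Sigma, E = E, sse = sse,
         lam_rep = lam_rep)
  }

  theta <- mu0
  ev0 <- model_eval(theta)
  if (is.null(ev0)) stop("forward simulation diverged at the prior mean")
  g <- ev0$g
  J <- ev0$J
  lambda <- if (!is.null(o$lambda_fixed)) {
    rep_len(o$lambda_fixed, n)
  } else {
    1 / pmax(apply(Y, 2, stats::var), 1e-10)
  }
  st <- evaluate(theta, g, J, lambda)
  F_trace <- st$F
  converged <- FALSE
  iter <- 0L

  while (iter < o$max_iter) {
    iter <- iter + 1L
    # Gauss-Newton direction at the current mode.
    e_vec <- as.numeric(st$E)
    b <- crossprod(J, e_vec * st$lam_rep) - P0d * (theta - mu0)
    delta <- drop(st$Sigma %*% b)
    step <- 1
    improved <- FALSE
    for (h in 0:o$max_halvings) {
      th_new <- theta + step * delta
      ev_new <- model_eval(th_new)
      if (!is.null(ev_new)) {
        st_new <- evaluate(th_new, ev_new$g, ev_new$J, lambda)
        if (st_new$F > st$F) {
          theta <- th_new; g <- ev_new$g; J <- ev_new$J; st <- st_new
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (improved && is.null(o$lambda_fixed)) {
      # EM update of per-region noise precision, kept only if F improves.
      JS <- J %*% st$Sigma
      tr_rows <- rowSums(JS * J)
      tr_reg <- vapply(seq_len(n), function(r) {
        sum(tr_rows[region_of_row == r])
      }, numeric(1))
      lam_new <- T_eff / pmax(st$sse + tr_reg, 1e-12)
      st_lam <- evaluate(theta, g, J, lam_new)
      if (st_lam$F > st$F) {
        lambda <- lam_new
        st <- st_lam
      }
    }
    if (!improved) { converged <- TRUE; break }
    dF <- st$F - F_trace[length(F_trace)]
    F_trace <- c(F_trace, st$F)
    if (o$verbose) message(sprintf("iter %d: F = %.4f (dF = %.4g)", iter, st$F, dF))
    if (dF < o$tol) { converged <- TRUE; break }
  }

  structure(list(
    mean = stats::setNames(theta, tab$name),
    cov = st$Sigma,
    F = st$F,
    F_trace = F_trace,
    lambda = stats::setNames(lambda, model$regions),
    iterations = iter,
    converged = converged,
    table = tab,
    model_id = model$id,
    prior = prior,
    T_eff = T_eff,
    n_volumes = T_vol
  ), class = "dcm_posterior")
}

#' Free-energy approximation to the log model evidence
#'
#' Returns the Laplace free energy (nats) of a fitted posterior:
#' log-likelihood at the posterior mode minus the KL divergence from the
#' prior (accuracy minus complexity).
#'
#' @param posterior A `dcm_posterior` from [invert_dcm()].
#' @return Scalar F in nats.
#' @export
free_energy <- function(posterior) {
  stopifnot(inherits(posterior, "dcm_posterior"))
  posterior$F
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat("DCM posterior (model ", x$model_id, "): ", length(x$mean),
      " parameters, F = ", format(x$F, digits = 6), " nats, ",
      x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Extract posterior coupling estimates by kind
#'
#' @param posterior A `dcm_posterior`.
#' @param kind "A", "B" or "C"; for "B" supply `input` ("exec" or "hand").
#' @param input Modulatory factor when `kind = "B"`.
#' @return Named numeric vector of posterior means.
#' @export
coupling_estimates <- function(posterior, kind = "A", input = NULL) {
  tab <- posterior$table
  sel <- tab$kind == kind
  if (!is.null(input)) sel <- sel & tab$input == input
  stats::setNames(as.numeric(posterior$mean[sel]), tab$name[sel])
}

#' Serialize a posterior to JSON
#'
#' Stores means, posterior variances, noise precisions, free energy and the
#' iteration trace (covariance off-diagonals are omitted from the JSON
#' summary).
#' @param posterior A `dcm_posterior`.
#' @param path Output path.
#' @export
write_posterior <- function(posterior, path) {
  payload <- list(
    model_id = posterior$model_id,
    free_energy = posterior$F,
    converged = posterior$converged,
    iterations = posterior$iterations,
    F_trace = posterior$F_trace,
    lambda = as.list(posterior$lambda),
    mean = as.list(posterior$mean),
    var = as.list(stats::setNames(diag(posterior$cov), names(posterior$mean)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
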