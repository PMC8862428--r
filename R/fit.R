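#' Extract a steady-state rate from a phosphate-release time course
#'
#' Fits an ordinary least-squares line (free intercept; the trace is not
#' forced through the origin, so a nonzero blank is tolerated) to released
#' phosphate versus time and divides the slope by the molar transporter
#' concentration, giving a specific rate in min^-1 per transporter.
#'
#' @param tc A time-course tibble as produced by [simulate_timecourse()]
#'   (columns `time_min`, `pi_uM`, plus condition metadata).
#' @param ctx A [reconstitution_context()].
#' @return A one-row rate-observation tibble.
#' @export
extract_rate <- function(tc, ctx) {
  stopifnot(is.data.frame(tc), inherits(ctx, "reconstitution_context"))
  if (length(unique(tc$time_min)) < 2L) {
    stop("degenerate-timecourse: need >= 2 distinct time points",
         call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(pi_uM ~ time_min, data = tc))[2L])
  E_uM <- transporter_molarity(ctx) * 1e6
  tibble::tibble(condition = ctx$condition_name,
                 atp_mM = tc$atp_mM[1L], gssg_mM = tc$gssg_mM[1L],
                 replicate = as.integer(tc$replicate[1L]),
                 rate_per_min = slope / E_uM,
                 orientation_corrected = FALSE)
}

# Replicate-mean rates per concentration cell, in a deterministic order.
cell_means <- function(obs, by = c("atp_mM", "gssg_mM")) {
  agg <- stats::aggregate(obs["rate_per_min"], obs[by], mean)
  agg <- agg[do.call(order, agg[rev(by)]), , drop = FALSE]
  rownames(agg) <- NULL
  tibble::as_tibble(agg)
}

LM_CONTROL <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-12, gtol = 1e-8,
                             maxfev = 10000, maxiter = 500)
}

# One Levenberg-Marquardt run over log-scale parameters. Returns NULL on error.
lm_run <- function(theta0, resid_fn) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = resid_fn, control = LM_CONTROL()),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  list(theta = fit$par, ssr = fit$deviance, niter = fit$niter)
}

# Central-difference Jacobian of a model vector w.r.t. log-scale parameters.
num_jacobian <- function(model_fn, theta, h = 1e-6) {
  f0 <- model_fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    up <- dn <- theta
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (model_fn(up) - model_fn(dn)) / (2 * h)
  }
  J
}

# Moore-Penrose fallback keeps the covariance finite on flat ridges.
safe_solve <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(A)
  keep <- s$d > max(s$d) * 1e-12
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Asymptotic Gauss-Newton covariance at the optimum, back-transformed from
# log scale to the parameters' own scale by the delta method.
gn_covariance <- function(model_fn, theta, residuals, n_par) {
  n <- length(residuals)
  dof <- max(n - n_par, 1L)
  sigma2 <- sum(residuals^2) / dof
  J <- num_jacobian(model_fn, theta)
  cov_log <- sigma2 * safe_solve(crossprod(J))
  D <- diag(exp(theta), n_par)
  cov_lin <- D %*% cov_log %*% D
  cov_lin <- (cov_lin + t(cov_lin)) / 2
  cov_lin
}

r_squared <- function(observed, fitted) {
  sstot <- sum((observed - mean(observed))^2)
  ssr <- sum((observed - fitted)^2)
  if (sstot == 0) return(NA_real_)
  1 - ssr / sstot
}

new_fit_result <- function(model_kind, params, estimates, covariance,
                           data, fitted, r2_per_curve, converged,
                           n_restarts_used, restarts = NULL) {
  se <- sqrt(pmax(diag(covariance), 0))
  names(se) <- names(estimates)
  structure(list(model_kind = model_kind,
                 params = params,
                 estimates = estimates,
                 standard_errors = se,
                 covariance = covariance,
                 r_squared = list(global = r_squared(data$rate_per_min, fitted),
                                  per_curve = r2_per_curve),
                 n_points = nrow(data),
                 data = data,
                 fitted = fitted,
                 residuals = data$rate_per_min - fitted,
                 converged = converged,
                 n_restarts_used = n_restarts_used,
                 restarts = restarts),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d points, %s)\n",
              if (x$model_kind == "activator") "Nonessential activator"
              else "Michaelis-Menten",
              x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %8.4g +/- %.4g\n", nm, est[[nm]],
                x$standard_errors[[nm]]))
  }
  cat(sprintf("  global R^2 = %.4f\n", x$r_squared$global))
  invisible(x)
}

#' Fit the Michaelis-Menten model at one activator level
#'
#' Unweighted least squares of the hyperbolic rate law on the replicate-mean
#' rates of a single activator (GSSG) level. Parameters are optimized on the
#' log scale (positive by construction) by Levenberg-Marquardt, initialized
#' at kcat0 = the largest mean rate and Km0 = the MgATP concentration whose
#' mean rate is nearest kcat0/2. Standard errors come from the
#' residual-scaled Gauss-Newton covariance at the optimum.
#'
#' @param obs Rate observations (columns `atp_mM`, `rate_per_min`, optionally
#'   `gssg_mM` which must then be constant) with >= 3 distinct MgATP
#'   concentrations, at least one positive.
#' @return A `kinetic_fit` with `model_kind = "michaelis"`.
#' @export
#' @examples
#' p <- michaelis_params(18, 0.82)
#' obs <- tibble::tibble(atp_mM = c(0, 0.2, 0.5, 1, 2, 5, 10),
#'                       rate_per_min = mm_rate(p, c(0, 0.2, 0.5, 1, 2, 5, 10)))
#' fit_michaelis(obs)
fit_michaelis <- function(obs) {
  stopifnot(is.data.frame(obs))
  if (!is.null(obs[["gssg_mM"]]) && length(unique(obs[["gssg_mM"]])) > 1L) {
    stop("design error: fit_michaelis expects observations at a single GSSG level",
         call. = FALSE)
  }
  means <- cell_means(obs, by = "atp_mM")
  if (nrow(means) < 3L || all(means$atp_mM == 0)) {
    stop("degenerate-data: need >= 3 distinct MgATP concentrations with one > 0",
         call. = FALSE)
  }
  if (all(means$rate_per_min == 0)) {
    stop("degenerate-data: all rates are zero", call. = FALSE)
  }
  Tc <- means$atp_mM
  y <- means$rate_per_min
  kcat0 <- max(y)
  pos <- Tc > 0
  Km0 <- Tc[pos][which.min(abs(y[pos] - kcat0 / 2))]
  model_fn <- function(theta) {
    q <- exp(theta)
    q[1L] * Tc / (q[2L] + Tc)
  }
  resid_fn <- function(theta) model_fn(theta) - y
  theta0 <- log(c(kcat0, Km0))
  run <- lm_run(theta0, resid_fn)
  if (is.null(run)) {
    # fall back to a small deterministic grid of starts around theta0
    for (f in c(0.25, 0.5, 2, 4)) {
      run <- lm_run(theta0 + log(f), resid_fn)
      if (!is.null(run)) break
    }
  }
  if (is.null(run)) {
    stop("convergence error: Michaelis-Menten fit did not converge",
         call. = FALSE)
  }
  est <- exp(run$theta)
  names(est) <- c("kcat", "Km")
  fitted <- model_fn(run$theta)
  covar <- gn_covariance(model_fn, run$theta, y - fitted, 2L)
  dimnames(covar) <- list(names(est), names(est))
  r2 <- tibble::tibble(gssg_mM = if (is.null(obs[["gssg_mM"]])) NA_real_
                       else obs[["gssg_mM"]][1L],
                       r_squared = r_squared(y, fitted))
  new_fit_result("michaelis",
                 michaelis_params(est[["kcat"]], est[["Km"]]),
                 est, covar, means, fitted, r2,
                 converged = TRUE, n_restarts_used = 1L)
}

ACTIVATOR_PAR_NAMES <- c("k", "K_T", "K_S", "alpha", "beta")

#' Global fit of the nonessential activator model
#'
#' Minimizes the unweighted sum of squared residuals between the activator
#' rate law (specific-rate form of [activator_velocity()]) and the
#' replicate-mean rates over the full MgATP x activator grid, estimating all
#' five parameters jointly. Parameters are optimized on the log scale so
#' positivity holds by construction. The optimizer is Levenberg-Marquardt
#' with multi-start: the first start is data-driven (basal Michaelis-Menten
#' fit at S = 0 for k and K_T; the stimulation of the top activator level
#' for beta; the median activator concentration for K_S; alpha = 1) and the
#' remaining starts are a Latin-hypercube over a 4-fold box around it, to
#' cope with the correlation ridge between `alpha` and `K_S`. The best-SSR
#' start wins; ties break on fewest iterations. Standard errors and the full
#' covariance come from the residual-scaled Gauss-Newton approximation at
#' the optimum, delta-method back-transformed from the log scale.
#'
#' @param obs Rate observations over the grid: >= 2 activator levels
#'   including S = 0 (otherwise the basal rate constant is unidentifiable)
#'   and >= 3 MgATP levels.
#' @param restarts Number of optimizer starts (default 16).
#' @param seed Seed for the Latin-hypercube start sampling (drawn in an
#'   isolated RNG state); the default gives a deterministic fit.
#' @param replicate_means Fit the per-cell replicate means (default, the
#'   conventional choice for this assay) or every replicate row.
#' @return A `kinetic_fit` with `model_kind = "activator"`, carrying global
#'   and per-activator-level R-squared and the per-start search record in
#'   `$restarts`.
#' @export
#' @examples
#' p <- naatm1_params("detergent")
#' obs <- simulate_dataset(p, reconstitution_context("detergent"),
#'                         paper_design("detergent"),
#'                         noise = noise_spec(0, 0), seed = 1)
#' fit <- fit_activator_global(obs)
#' fit$estimates
fit_activator_global <- function(obs, restarts = 16L, seed = 1L,
                                 replicate_means = TRUE) {
  stopifnot(is.data.frame(obs))
  if (is.null(obs[["gssg_mM"]]) || length(unique(obs[["gssg_mM"]])) < 2L) {
    stop("design error: need >= 2 GSSG levels to fit the activator model",
         call. = FALSE)
  }
  if (!any(obs$gssg_mM == 0)) {
    stop("design error: grid lacks S = 0, basal rate unidentifiable",
         call. = FALSE)
  }
  if (length(unique(obs$atp_mM)) < 3L) {
    stop("design error: need >= 3 MgATP levels", call. = FALSE)
  }
  data <- if (replicate_means) cell_means(obs) else
    tibble::as_tibble(obs[c("atp_mM", "gssg_mM", "rate_per_min")])
  if (all(data$rate_per_min == 0)) {
    stop("degenerate-data: all rates are zero", call. = FALSE)
  }
  Tc <- data$atp_mM; Sc <- data$gssg_mM; y <- data$rate_per_min

  basal <- tryCatch(fit_michaelis(obs[obs$gssg_mM == 0, , drop = FALSE]),
                    error = function(e) NULL)
  k0 <- if (!is.null(basal)) basal$estimates[["kcat"]] else max(y[Sc == 0], 1e-3)
  KT0 <- if (!is.null(basal)) basal$estimates[["Km"]] else
    stats::median(unique(Tc[Tc > 0]))
  top <- max(Sc)
  beta0 <- max(max(y[Sc == top]) / k0, 2)
  KS0 <- stats::median(unique(Sc[Sc > 0]))
  theta0 <- log(c(k0, KT0, KS0, 1, beta0))

  starts <- matrix(theta0, nrow = 1L)
  if (restarts > 1L) {
    box <- log(4)
    u <- if (is.null(seed)) lhs::randomLHS(restarts - 1L, 5L) else
      withr::with_seed(seed, lhs::randomLHS(restarts - 1L, 5L))
    extra <- sweep(2 * box * u - box, 2L, theta0, `+`)
    starts <- rbind(starts, extra)
  }

  model_fn <- function(theta) {
    q <- exp(theta)
    activator_specific_rate(q[1L], q[2L], q[3L], q[4L], q[5L], Tc, Sc)
  }
  resid_fn <- function(theta) model_fn(theta) - y

  runs <- lapply(seq_len(nrow(starts)),
                 function(i) lm_run(starts[i, ], resid_fn))
  ok <- !vapply(runs, is.null, logical(1L))
  if (!any(ok)) {
    stop("convergence error: no optimizer start converged", call. = FALSE)
  }
  ssr <- vapply(runs, function(r) if (is.null(r)) Inf else r$ssr, numeric(1L))
  nit <- vapply(runs, function(r) if (is.null(r)) NA_integer_ else r$niter,
                integer(1L))
  best <- order(ssr, nit)[1L]
  run <- runs[[best]]

  est <- exp(run$theta)
  names(est) <- ACTIVATOR_PAR_NAMES
  fitted <- model_fn(run$theta)
  covar <- gn_covariance(model_fn, run$theta, y - fitted, 5L)
  dimnames(covar) <- list(names(est), names(est))

  per_curve <- do.call(rbind, lapply(sort(unique(Sc)), function(s) {
    idx <- Sc == s
    tibble::tibble(gssg_mM = s,
                   r_squared = r_squared(y[idx], fitted[idx]))
  }))
  restart_tbl <- tibble::tibble(start = seq_along(ssr), ssr = ssr,
                                iterations = nit, converged = ok)

  new_fit_result("activator",
                 activator_params(est[["k"]], est[["K_T"]], est[["K_S"]],
                                  est[["alpha"]], est[["beta"]]),
                 est, covar, data, fitted, tibble::as_tibble(per_curve),
                 converged = TRUE, n_restarts_used = sum(ok),
                 restarts = restart_tbl)
}

#' Derived activator curves
#'
#' Evaluates the apparent rate constant [kobs()], apparent Michaelis constant
#' [kt_app()] and [fold_stimulation()] of a converged activator fit (or of a
#' parameter set directly) on the observed activator levels and, optionally,
#' a dense grid for plotting.
#'
#' @param fit A converged `kinetic_fit` of the activator model, or an
#'   [activator_params()] object.
#' @param s_levels Activator concentrations, mM; defaults to the fit's
#'   observed levels.
#' @param dense_n Number of extra dense-grid points from 0 to `max(s_levels)`
#'   (0 to skip).
#' @return A tibble with columns `gssg_mM`, `kobs`, `kt_app`, `fold`,
#'   `fold_nearest`, `grid` ("observed" or "dense").
#' @export
derived_curves <- function(fit, s_levels = NULL, dense_n = 101L) {
  if (inherits(fit, "kinetic_fit")) {
    if (fit$model_kind != "activator" || !isTRUE(fit$converged)) {
      stop("derived_curves needs a converged activator fit", call. = FALSE)
    }
    p <- fit$params
    if (is.null(s_levels)) s_levels <- sort(unique(fit$data$gssg_mM))
  } else {
    p <- as_activator_params(fit)
    if (is.null(s_levels)) stop("s_levels required when passing parameters",
                                call. = FALSE)
  }
  grids <- list(tibble::tibble(gssg_mM = s_levels, grid = "observed"))
  if (dense_n > 0L) {
    grids <- c(grids, list(tibble::tibble(
      gssg_mM = seq(0, max(s_levels), length.out = dense_n), grid = "dense")))
  }
  out <- do.call(rbind, grids)
  out$kobs <- kobs(p, out$gssg_mM)
  out$kt_app <- kt_app(p, out$gssg_mM)
  out$fold <- fold_stimulation(p, out$gssg_mM)
  out$fold_nearest <- round(out$fold)
  out[c("gssg_mM", "kobs", "kt_app", "fold", "fold_nearest", "grid")]
}
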