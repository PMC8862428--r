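#' Bootstrap uncertainty for the global activator fit
#'
#' Case-resampling bootstrap: within every (MgATP, activator) cell the
#' replicate rates are resampled with replacement, the cell means are
#' recomputed, and the five-parameter model is refit starting from the
#' full-data optimum. Percentile intervals on the parameters' own scale are
#' returned. A complement to the asymptotic Gauss-Newton standard errors,
#' which lean on local linearity that the `alpha`-`K_S` ridge can strain.
#'
#' @param obs Replicate-level rate observations (as from
#'   [simulate_dataset()]).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the resampling stream.
#' @param level Interval coverage level (default 0.95).
#' @param fit Optional pre-computed full-data `kinetic_fit` to reuse.
#' @return An object of class `kinetic_bootstrap`: percentile intervals,
#'   the bootstrap draws, and the count of failed refits. More than 20%
#'   failures triggers an `unstable-fit` warning.
#' @export
bootstrap_uncertainty <- function(obs, n_boot = 200L, seed = 1L,
                                  level = 0.95, fit = NULL) {
  stopifnot(is.data.frame(obs))
  if (!is.numeric(n_boot) || n_boot < 100L) {
    stop("invalid-argument: n_boot must be >= 100", call. = FALSE)
  }
  if (is.null(fit)) fit <- fit_activator_global(obs)
  if (!isTRUE(fit$converged)) {
    stop("convergence error: full-data fit did not converge", call. = FALSE)
  }
  theta_hat <- log(fit$estimates)

  cells <- split(seq_len(nrow(obs)),
                 interaction(obs$atp_mM, obs$gssg_mM, drop = TRUE))
  draw_one <- function() {
    idx <- unlist(lapply(cells, function(i) i[sample.int(length(i),
                                                         length(i),
                                                         replace = TRUE)]),
                  use.names = FALSE)
    means <- cell_means(obs[idx, , drop = FALSE])
    Tc <- means$atp_mM; Sc <- means$gssg_mM; y <- means$rate_per_min
    resid_fn <- function(theta) {
      q <- exp(theta)
      activator_specific_rate(q[1L], q[2L], q[3L], q[4L], q[5L], Tc, Sc) - y
    }
    run <- lm_run(theta_hat, resid_fn)
    if (is.null(run)) return(rep(NA_real_, 5L))
    exp(run$theta)
  }
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) draw_one(), numeric(5L)))
  })
  colnames(draws) <- ACTIVATOR_PAR_NAMES
  failed <- sum(!stats::complete.cases(draws))
  if (failed > 0.2 * n_boot) {
    warning("unstable-fit: ", failed, "/", n_boot,
            " bootstrap refits failed", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(draws, 2L, stats::quantile, probs = probs, na.rm = TRUE)
  intervals <- tibble::tibble(parameter = ACTIVATOR_PAR_NAMES,
                              estimate = unname(fit$estimates),
                              lower = qs[1L, ], upper = qs[2L, ])
  structure(list(intervals = intervals, draws = draws,
                 n_boot = as.integer(n_boot), n_failed = failed,
                 level = level, seed = seed),
            class = "kinetic_bootstrap")
}

#' @export
print.kinetic_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (%d resamples, %.0f%%, %d failed):\n",
              x$n_boot, 100 * x$level, x$n_failed))
  print(x$intervals)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Scores the whole simulate-and-fit pipeline: `n_sims` synthetic datasets
#' are generated from known parameters and each is refit with
#' [fit_activator_global()]. Per parameter the report gives bias, RMSE, the
#' fraction of simulations recovered within tolerance, and (when reference
#' standard errors are available) z-scores of the recovery errors against
#' them. A parameter passes in a simulation when its relative error is
#' within `max(tol_rel, 2 * SE / truth)` — two reported standard errors or
#' the relative tolerance, whichever is larger.
#'
#' @param p Generating [activator_params()].
#' @param ctx A [reconstitution_context()].
#' @param noise A [noise_spec()].
#' @param n_sims Number of simulate-fit rounds (>= 1).
#' @param seed Integer seed; simulation `i` uses `seed + i`.
#' @param grid A [design_grid()]; defaults to [paper_design()] for the
#'   context's condition.
#' @param reference_se Named numeric vector of reference standard errors for
#'   the z-scores and the SE arm of the tolerance; defaults to the published
#'   values when the condition is a named one, otherwise `NULL`.
#' @param tol_rel Relative-error arm of the pass tolerance (default 0.15).
#' @return An object of class `recovery_report` with elements `per_sim`,
#'   `summary`, and the generator settings.
#' @export
#' @examples
#' rep <- recovery_experiment(naatm1_params("detergent"),
#'                            reconstitution_context("detergent"),
#'                            noise_spec(0, 0), n_sims = 1, seed = 1)
#' all(rep$summary$frac_pass == 1)
recovery_experiment <- function(p, ctx, noise, n_sims, seed,
                                grid = NULL, reference_se = NULL,
                                tol_rel = 0.15) {
  p <- as_activator_params(p)
  stopifnot(inherits(ctx, "reconstitution_context"),
            inherits(noise, "noise_spec"))
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1 ||
      n_sims != round(n_sims)) {
    stop("invalid-argument: n_sims must be a whole number >= 1",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- paper_design(ctx$condition_name)
  if (is.null(reference_se) && ctx$condition_name %in% CONDITIONS) {
    reference_se <- naatm1_params(ctx$condition_name, se = TRUE)
  }
  truth <- unlist(unclass(p))[ACTIVATOR_PAR_NAMES]
  tol <- pmax(tol_rel, if (is.null(reference_se)) 0 else
    2 * reference_se[ACTIVATOR_PAR_NAMES] / truth)

  per_sim <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim_seed <- (seed + i) %% .Machine$integer.max
    obs <- simulate_dataset(p, ctx, grid, noise = noise, seed = sim_seed)
    fit <- fit_activator_global(obs)
    est <- fit$estimates
    rel <- est / truth - 1
    per_sim[[i]] <- tibble::tibble(
      sim = i, seed = sim_seed,
      parameter = ACTIVATOR_PAR_NAMES,
      truth = unname(truth), estimate = unname(est),
      rel_error = unname(rel),
      z = if (is.null(reference_se)) NA_real_ else
        unname((est - truth) / reference_se[ACTIVATOR_PAR_NAMES]),
      pass = unname(abs(rel) <= tol))
  }
  per_sim <- do.call(rbind, per_sim)
  summary <- do.call(rbind, lapply(ACTIVATOR_PAR_NAMES, function(nm) {
    d <- per_sim[per_sim$parameter == nm, ]
    tibble::tibble(parameter = nm, truth = d$truth[1L],
                   median_estimate = stats::median(d$estimate),
                   bias = mean(d$estimate) - d$truth[1L],
                   rmse = sqrt(mean((d$estimate - d$truth[1L])^2)),
                   frac_pass = mean(d$pass))
  }))
  structure(list(per_sim = per_sim, summary = summary,
                 generator = unclass(p), noise = unclass(noise),
                 n_sims = as.integer(n_sims), seed = seed,
                 tol_rel = tol_rel, reference_se = reference_se),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulations (seed %s):\n",
              x$n_sims, format(x$seed)))
  print(x$summary)
  invisible(x)
}
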