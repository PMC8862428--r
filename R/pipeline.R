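#' Pipeline run configuration
#'
#' Validated configuration for the end-to-end pipeline steps
#' [run_simulate()], [run_fit()] and [run_recover()]. A seed is mandatory
#' for every stochastic command; existing output files are never silently
#' overwritten unless `force = TRUE`.
#'
#' @param command One of `"simulate"`, `"fit-mm"`, `"fit-activator"`,
#'   `"recover"`.
#' @param out_dir Output directory (created if absent).
#' @param condition Named reconstitution condition supplying default
#'   generator parameters and context; see [naatm1_params()].
#' @param params Optional [activator_params()] overriding the condition's
#'   defaults.
#' @param input Input rates CSV (fit commands).
#' @param noise_cv,additive_floor Noise specification for simulation.
#' @param seed Integer seed (required for simulate/recover).
#' @param restarts Optimizer starts for the global fit.
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param n_sims Simulate-fit rounds for recover.
#' @param replicate_level Fit every replicate row instead of cell means.
#' @param orientation_correct Apply the context's orientation factor to
#'   simulated rates.
#' @param force Overwrite existing outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(command,
                       out_dir,
                       condition = "detergent",
                       params = NULL,
                       input = NULL,
                       noise_cv = 0.05,
                       additive_floor = 0.5,
                       seed = NULL,
                       restarts = 16L,
                       n_boot = 0L,
                       n_sims = 20L,
                       replicate_level = FALSE,
                       orientation_correct = FALSE,
                       force = FALSE) {
  commands <- c("simulate", "fit-mm", "fit-activator", "recover")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands) {
    stop("config error: 'command' must be one of ",
         paste(sQuote(commands), collapse = ", "), call. = FALSE)
  }
  if (!is.character(out_dir) || length(out_dir) != 1L) {
    stop("config error: 'out_dir' must be a single path", call. = FALSE)
  }
  stochastic <- command %in% c("simulate", "recover")
  if (stochastic && (is.null(seed) || !is.numeric(seed) || !is.finite(seed))) {
    stop("config error: 'seed' is required for command '", command, "'",
         call. = FALSE)
  }
  if (command %in% c("fit-mm", "fit-activator") && is.null(input)) {
    stop("config error: 'input' is required for command '", command, "'",
         call. = FALSE)
  }
  noise <- noise_spec(noise_cv, additive_floor)  # validates
  if (!is.null(params)) params <- as_activator_params(params)
  structure(list(command = command, out_dir = out_dir,
                 condition = condition, params = params, input = input,
                 noise = noise, seed = if (is.null(seed)) NULL else
                   as.integer(seed),
                 restarts = as.integer(restarts),
                 n_boot = as.integer(n_boot), n_sims = as.integer(n_sims),
                 replicate_level = isTRUE(replicate_level),
                 orientation_correct = isTRUE(orientation_correct),
                 force = isTRUE(force)),
            class = "run_config")
}

cfg_params <- function(cfg) {
  if (!is.null(cfg$params)) cfg$params else naatm1_params(cfg$condition)
}

cfg_provenance <- function(cfg) {
  p <- cfg_params(cfg)
  c(list(command = cfg$command, condition = cfg$condition),
    as.list(unlist(unclass(p))),
    list(noise_cv = cfg$noise$cv, additive_floor = cfg$noise$additive_floor,
         restarts = cfg$restarts,
         orientation_correct = cfg$orientation_correct))
}

out_path <- function(cfg, name) {
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  path <- file.path(cfg$out_dir, name)
  if (file.exists(path) && !cfg$force) {
    stop("config error: output exists (use force = TRUE): ", path,
         call. = FALSE)
  }
  path
}

#' Simulate an assay dataset to disk
#'
#' Generates a synthetic dataset for the configured condition with
#' [simulate_dataset()] and writes the rate table, the raw time courses,
#' and a provenance file (flat `key=value`) capturing every generator
#' setting and the seed. Rerunning the same configuration produces
#' byte-identical files.
#'
#' @param cfg A [run_config()] with `command = "simulate"`.
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$command != "simulate") {
    stop("config error: run_simulate needs command = 'simulate'",
         call. = FALSE)
  }
  p <- cfg_params(cfg)
  ctx <- reconstitution_context(cfg$condition)
  grid <- paper_design(cfg$condition)
  obs <- simulate_dataset(p, ctx, grid, noise = cfg$noise, seed = cfg$seed,
                          keep_timecourses = TRUE)
  tcs <- attr(obs, "timecourses")
  if (cfg$orientation_correct) {
    obs <- apply_orientation_correction(obs, ctx)
  }
  prov <- cfg_provenance(cfg)
  paths <- list(
    rates = out_path(cfg, sprintf("rates_%s.csv", cfg$condition)),
    timecourses = out_path(cfg, sprintf("timecourses_%s.csv", cfg$condition)),
    provenance = out_path(cfg, sprintf("provenance_%s.txt", cfg$condition)))
  write_rates_csv(obs, paths$rates, seed = cfg$seed, config = prov)
  write_timecourses_csv(tcs, paths$timecourses, seed = cfg$seed,
                        config = prov)
  writeLines(c(config_lines(prov), paste0("seed=", cfg$seed)),
             paths$provenance)
  invisible(paths)
}

#' Fit models to a rates table and write reports
#'
#' With `command = "fit-activator"`: runs [fit_activator_global()] and
#' writes (i) a five-row parameter report (estimate, SE, asymptotic 95% CI),
#' (ii) a per-activator-level Michaelis-Menten table ([fit_michaelis()] per
#' GSSG level: kcat, Km and their SEs), (iii) the derived curves from
#' [derived_curves()], and (iv) global and per-curve R-squared. With
#' `command = "fit-mm"` only the per-level table and its R-squared are
#' written.
#'
#' @param cfg A [run_config()] with a fit command and `input` pointing at a
#'   rates CSV.
#' @return Invisibly, a list with the fit object(s) and written paths.
#' @export
run_fit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!cfg$command %in% c("fit-mm", "fit-activator")) {
    stop("config error: run_fit needs command 'fit-mm' or 'fit-activator'",
         call. = FALSE)
  }
  obs <- read_rates_csv(cfg$input)
  prov <- cfg_provenance(cfg)
  paths <- list()

  mm_tbl <- do.call(rbind, lapply(sort(unique(obs$gssg_mM)), function(s) {
    f <- fit_michaelis(obs[obs$gssg_mM == s, , drop = FALSE])
    tibble::tibble(gssg_mM = s,
                   kcat = f$estimates[["kcat"]],
                   kcat_se = f$standard_errors[["kcat"]],
                   Km = f$estimates[["Km"]],
                   Km_se = f$standard_errors[["Km"]],
                   r_squared = f$r_squared$global)
  }))
  paths$michaelis <- out_path(cfg, "fit_michaelis_per_gssg.csv")
  write_csv_with_header(mm_tbl, paths$michaelis,
                        provenance_header(config_lines(prov), cfg$seed))
  result <- list(michaelis = mm_tbl, paths = paths)

  if (cfg$command == "fit-activator") {
    fit <- fit_activator_global(obs, restarts = cfg$restarts,
                                replicate_means = !cfg$replicate_level)
    z <- stats::qnorm(0.975)
    report <- tibble::tibble(
      parameter = names(fit$estimates),
      estimate = unname(fit$estimates),
      se = unname(fit$standard_errors),
      ci_low = unname(fit$estimates - z * fit$standard_errors),
      ci_high = unname(fit$estimates + z * fit$standard_errors),
      r_squared_global = fit$r_squared$global)
    paths$activator <- out_path(cfg, "fit_activator_params.csv")
    write_csv_with_header(report, paths$activator,
                          provenance_header(config_lines(prov), cfg$seed))
    paths$derived <- out_path(cfg, "derived_curves.csv")
    write_csv_with_header(derived_curves(fit), paths$derived,
                          provenance_header(config_lines(prov), cfg$seed))
    paths$r2 <- out_path(cfg, "r_squared_per_gssg.csv")
    write_csv_with_header(fit$r_squared$per_curve, paths$r2,
                          provenance_header(config_lines(prov), cfg$seed))
    result$activator <- fit
    result$report <- report
    result$paths <- paths
  }
  invisible(result)
}

#' End-to-end parameter-recovery run
#'
#' Simulate-fit-score with [recovery_experiment()] for the configured
#' condition, writing the per-simulation table and the machine-readable
#' summary (bias, RMSE, pass fraction per parameter).
#'
#' @param cfg A [run_config()] with `command = "recover"`.
#' @return Invisibly, the `recovery_report` plus written paths.
#' @export
run_recover <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$command != "recover") {
    stop("config error: run_recover needs command = 'recover'",
         call. = FALSE)
  }
  p <- cfg_params(cfg)
  ctx <- reconstitution_context(cfg$condition)
  rep <- recovery_experiment(p, ctx, cfg$noise, n_sims = cfg$n_sims,
                             seed = cfg$seed)
  prov <- cfg_provenance(cfg)
  paths <- list(per_sim = out_path(cfg, "recovery_per_sim.csv"),
                summary = out_path(cfg, "recovery_summary.csv"))
  write_csv_with_header(rep$per_sim, paths$per_sim,
                        provenance_header(config_lines(prov), cfg$seed))
  write_csv_with_header(rep$summary, paths$summary,
                        provenance_header(config_lines(prov), cfg$seed))
  rep$paths <- paths
  invisible(rep)
}
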