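#' Measurement-noise specification for simulated phosphate readings
#'
#' Each simulated phosphate reading is perturbed by independent Gaussian
#' noise with standard deviation `cv * reading + additive_floor`, then
#' truncated at zero (released phosphate cannot be negative; the floor allows
#' a nonzero blank at t = 0). The defaults (5% relative, 0.5 uM floor) put
#' the per-curve R-squared of simulated assays in the 0.9-1.0 band typical of
#' careful colorimetric ATPase measurements.
#'
#' @param cv Relative standard deviation per reading (>= 0).
#' @param additive_floor Additive noise floor, uM (>= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.05, additive_floor = 0.5) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0 ||
      !is.numeric(additive_floor) || length(additive_floor) != 1L ||
      !is.finite(additive_floor) || additive_floor < 0) {
    stop("invalid-noise: cv and additive_floor must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(cv = cv, additive_floor = additive_floor),
            class = "noise_spec")
}

#' Simulate a phosphate-release time course
#'
#' Under steady state the released phosphate accumulates linearly:
#' `Pi(t) = v * E_T * t`, with `v` the specific rate from
#' [activator_velocity()] at the cell's MgATP and activator concentrations
#' and `E_T` the molar transporter concentration from the reconstitution
#' context. Each reading is then perturbed per the [noise_spec()].
#'
#' @param p An [activator_params()] object.
#' @param ctx A [reconstitution_context()].
#' @param atp,gssg Condition concentrations, mM.
#' @param noise A [noise_spec()]; `noise_spec(0, 0)` gives the exact line.
#' @param seed Optional integer; when given, the time course is drawn in an
#'   isolated RNG state so repeated calls are identical and the caller's RNG
#'   is untouched.
#' @param replicate Replicate index recorded in the output.
#' @param time_points Sampling times, minutes.
#' @param measure_t0 If `TRUE` (default) the t = 0 sample is a measured
#'   reading carrying the same noise model; if `FALSE` it is assumed zero.
#'
#' @return A tibble with columns `condition`, `atp_mM`, `gssg_mM`,
#'   `replicate`, `time_min`, `pi_uM`.
#' @export
#' @examples
#' p <- naatm1_params("detergent")
#' ctx <- reconstitution_context("detergent")
#' simulate_timecourse(p, ctx, atp = 10, gssg = 0, noise = noise_spec(0, 0))
simulate_timecourse <- function(p, ctx, atp, gssg,
                                noise = noise_spec(),
                                seed = NULL,
                                replicate = 1L,
                                time_points = c(0, 5, 10, 15),
                                measure_t0 = TRUE) {
  p <- as_activator_params(p)
  stopifnot(inherits(ctx, "reconstitution_context"),
            inherits(noise, "noise_spec"))
  check_conc(atp, "atp"); check_conc(gssg, "gssg")
  check_grid_axis(time_points, "time_points")
  E_uM <- transporter_molarity(ctx) * 1e6
  mean_pi <- activator_velocity(p, atp, gssg) * E_uM * time_points
  draw <- function() {
    sd <- noise$cv * mean_pi + noise$additive_floor
    y <- mean_pi + stats::rnorm(length(mean_pi), 0, sd)
    if (!measure_t0) y[time_points == 0] <- 0
    pmax(y, 0)
  }
  pi_uM <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(condition = ctx$condition_name,
                 atp_mM = atp, gssg_mM = gssg,
                 replicate = as.integer(replicate),
                 time_min = time_points, pi_uM = pi_uM)
}

#' Simulate a full steady-state assay dataset
#'
#' Generates one time course per (MgATP, activator, replicate) cell of the
#' design grid and extracts each steady-state rate with [extract_rate()]
#' (ordinary least-squares slope over transporter molarity), mirroring how
#' rates are obtained from the colorimetric assay. Cells are simulated in a
#' fixed order (activator outer, MgATP inner, replicate innermost) from a
#' single RNG stream, so a given seed reproduces the dataset bitwise.
#'
#' @inheritParams simulate_timecourse
#' @param grid A [design_grid()], e.g. [paper_design()].
#' @param keep_timecourses If `TRUE`, attach the raw time courses as the
#'   `timecourses` attribute.
#'
#' @return A tibble of rate observations with columns `condition`, `atp_mM`,
#'   `gssg_mM`, `replicate`, `rate_per_min`, `orientation_corrected`, plus a
#'   `generator` attribute recording parameters, noise, and seed for
#'   recovery scoring.
#' @export
#' @examples
#' obs <- simulate_dataset(naatm1_params("nanodiscs"),
#'                         reconstitution_context("nanodiscs"),
#'                         paper_design("nanodiscs"), seed = 1)
#' nrow(obs)  # 8 * 6 * 3 = 144
simulate_dataset <- function(p, ctx, grid,
                             noise = noise_spec(),
                             seed = NULL,
                             measure_t0 = TRUE,
                             keep_timecourses = FALSE) {
  p <- as_activator_params(p)
  stopifnot(inherits(ctx, "reconstitution_context"),
            inherits(grid, "design_grid"),
            inherits(noise, "noise_spec"))
  gen <- function() {
    cells <- expand.grid(replicate = seq_len(grid$n_replicates),
                         atp = grid$atp, gssg = grid$gssg,
                         KEEP.OUT.ATTRS = FALSE)
    tcs <- vector("list", nrow(cells))
    rates <- numeric(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      tc <- simulate_timecourse(p, ctx, cells$atp[i], cells$gssg[i],
                                noise = noise, replicate = cells$replicate[i],
                                time_points = grid$time_points,
                                measure_t0 = measure_t0)
      rates[i] <- extract_rate(tc, ctx)$rate_per_min
      if (keep_timecourses) tcs[[i]] <- tc
    }
    obs <- tibble::tibble(condition = ctx$condition_name,
                          atp_mM = cells$atp, gssg_mM = cells$gssg,
                          replicate = as.integer(cells$replicate),
                          rate_per_min = rates,
                          orientation_corrected = FALSE)
    if (keep_timecourses) {
      attr(obs, "timecourses") <- do.call(rbind, tcs)
    }
    obs
  }
  obs <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(obs, "generator") <- list(params = unclass(p), noise = unclass(noise),
                                 seed = seed, condition = ctx$condition_name,
                                 measure_t0 = measure_t0)
  obs
}
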