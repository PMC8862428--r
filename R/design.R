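CONDITIONS <- c("detergent", "nanodiscs", "proteoliposomes")

#' Reference kinetic parameters for NaAtm1
#'
#' Published point estimates (with standard errors) of the nonessential
#' activator parameters for the ABC exporter NaAtm1 stimulated by oxidized
#' glutathione, under three reconstitution conditions: detergent micelles
#' (DDM/C12E8), MSP1D1 nanodiscs, and proteoliposomes. These drive the
#' synthetic assay generator and serve as ground truth in parameter-recovery
#' experiments. Proteoliposome values are as measured, i.e. not corrected for
#' transporter orientation.
#'
#' @param condition One of `"detergent"`, `"nanodiscs"`, `"proteoliposomes"`.
#' @param se If `TRUE`, return the reported standard errors instead of the
#'   point estimates.
#'
#' @return An [activator_params()] object, or (for `se = TRUE`) a named
#'   numeric vector of standard errors.
#' @export
#' @examples
#' naatm1_params("detergent")
naatm1_params <- function(condition, se = FALSE) {
  condition <- match_condition(condition)
  est <- switch(condition,
    detergent       = c(k = 17.58, K_T = 0.82, K_S = 13.34, alpha = 1.03, beta = 8.30),
    nanodiscs       = c(k = 31.86, K_T = 1.41, K_S = 9.65,  alpha = 10.05, beta = 76.60),
    proteoliposomes = c(k = 9.49,  K_T = 1.64, K_S = 12.79, alpha = 2.64, beta = 28.69)
  )
  if (se) {
    return(switch(condition,
      detergent       = c(k = 0.75, K_T = 0.07, K_S = 2.20, alpha = 0.20, beta = 0.46),
      nanodiscs       = c(k = 1.04, K_T = 0.08, K_S = 0.74, alpha = 1.73, beta = 8.68),
      proteoliposomes = c(k = 1.26, K_T = 0.34, K_S = 4.09, alpha = 1.26, beta = 6.30)
    ))
  }
  activator_params(est[["k"]], est[["K_T"]], est[["K_S"]],
                   est[["alpha"]], est[["beta"]])
}

match_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% CONDITIONS) {
    stop("unknown-condition: condition must be one of ",
         paste(sQuote(CONDITIONS), collapse = ", "), call. = FALSE)
  }
  condition
}

#' Assay design grid
#'
#' Construct the concentration grid, replicate structure and sampling times
#' of a steady-state ATPase assay. [paper_design()] returns the standard
#' NaAtm1 design: 8 MgATP concentrations (0, 0.1, 0.2, 0.5, 1, 2, 5, 10 mM)
#' crossed with 6 GSSG concentrations (0, 1, 2.5, 5, 10, 20 mM), sampled
#' every 5 min for 4 time points over 15 min, in sextuplicate for detergent
#' and proteoliposome preparations and triplicate for nanodiscs.
#'
#' @param atp,gssg Strictly increasing non-negative concentration vectors, mM.
#' @param n_replicates Replicates per concentration cell (>= 1).
#' @param time_points Sampling times in minutes (>= 2 points, strictly
#'   increasing).
#'
#' @return An object of class `design_grid`.
#' @export
#' @examples
#' paper_design("nanodiscs")$n_replicates  # 3
design_grid <- function(atp, gssg, n_replicates, time_points) {
  check_grid_axis(atp, "atp")
  check_grid_axis(gssg, "gssg")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("invalid-design: n_replicates must be a whole number >= 1",
         call. = FALSE)
  }
  check_grid_axis(time_points, "time_points")
  if (length(time_points) < 2L) {
    stop("invalid-design: need >= 2 time points", call. = FALSE)
  }
  structure(list(atp = atp, gssg = gssg,
                 n_replicates = as.integer(n_replicates),
                 time_points = time_points),
            class = "design_grid")
}

check_grid_axis <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(diff(x) <= 0)) {
    stop("invalid-design: '", name,
         "' must be non-negative and strictly increasing", call. = FALSE)
  }
  invisible(x)
}

#' @rdname design_grid
#' @param condition Named reconstitution condition (see [naatm1_params()]).
#' @export
paper_design <- function(condition) {
  condition <- match_condition(condition)
  design_grid(
    atp  = c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10),
    gssg = c(0, 1, 2.5, 5, 10, 20),
    n_replicates = if (condition == "nanodiscs") 3L else 6L,
    time_points = c(0, 5, 10, 15)
  )
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("Assay design: %d ATP x %d GSSG concentrations, %d replicates, %d time points\n",
              length(x$atp), length(x$gssg), x$n_replicates,
              length(x$time_points)))
  invisible(x)
}

#' Reconstitution context
#'
#' Condition metadata converting the mass-based protein amount of an ATPase
#' assay to a molar transporter concentration, and correcting for scaffold
#' protein content and transporter orientation. For nanodiscs the transporter
#' mass fraction follows from the scaffold stoichiometry:
#' `MW_T / (MW_T + n_scaffold * MW_scaffold)`; with a 135 kDa transporter and
#' two 25 kDa scaffold proteins this is 135/185 = 0.73. Proteoliposomes carry
#' an orientation factor of 2 by default: roughly half the reconstituted
#' transporters face away from the added MgATP, so the measured activity
#' understates the per-transporter rate about two-fold.
#'
#' @param condition_name Label; `"detergent"`, `"nanodiscs"`,
#'   `"proteoliposomes"` get field defaults, anything else must specify all
#'   fields.
#' @param protein_mass_conc Total protein mass concentration, mg/ml.
#' @param transporter_mw Transporter molecular weight, kDa (per homodimer).
#' @param scaffold_mw,scaffold_per_transporter Optional scaffold protein MW
#'   (kDa) and copy number per transporter; when both are given the mass
#'   fraction is derived from them.
#' @param transporter_mass_fraction Fraction of the protein mass that is
#'   transporter, in (0, 1]. Ignored (recomputed) when scaffold fields are set.
#' @param orientation_factor Scalar >= 1 multiplying measured rates to
#'   correct for inaccessible transporters.
#'
#' @return An object of class `reconstitution_context`.
#' @export
#' @examples
#' ctx <- reconstitution_context("nanodiscs")
#' ctx$transporter_mass_fraction  # 0.73
reconstitution_context <- function(condition_name,
                                   protein_mass_conc = 0.05,
                                   transporter_mw = 135,
                                   scaffold_mw = NULL,
                                   scaffold_per_transporter = NULL,
                                   transporter_mass_fraction = NULL,
                                   orientation_factor = NULL) {
  if (!is.character(condition_name) || length(condition_name) != 1L) {
    stop("invalid-context: condition_name must be a single string",
         call. = FALSE)
  }
  if (condition_name == "nanodiscs") {
    if (is.null(scaffold_mw)) scaffold_mw <- 25
    if (is.null(scaffold_per_transporter)) scaffold_per_transporter <- 2
  }
  if (is.null(orientation_factor)) {
    orientation_factor <- if (condition_name == "proteoliposomes") 2 else 1
  }
  if (!is.numeric(protein_mass_conc) || protein_mass_conc <= 0 ||
      !is.numeric(transporter_mw) || transporter_mw <= 0) {
    stop("invalid-context: protein mass concentration and transporter MW must be > 0",
         call. = FALSE)
  }
  if (!is.null(scaffold_mw) && !is.null(scaffold_per_transporter)) {
    if (scaffold_mw <= 0 || scaffold_per_transporter < 0) {
      stop("invalid-context: scaffold fields must be positive", call. = FALSE)
    }
    transporter_mass_fraction <-
      transporter_mw / (transporter_mw + scaffold_per_transporter * scaffold_mw)
  } else if (is.null(transporter_mass_fraction)) {
    transporter_mass_fraction <- 1
  }
  if (transporter_mass_fraction <= 0 || transporter_mass_fraction > 1) {
    stop("invalid-context: transporter_mass_fraction must be in (0, 1]",
         call. = FALSE)
  }
  if (orientation_factor < 1) {
    stop("invalid-context: orientation_factor must be >= 1", call. = FALSE)
  }
  structure(list(condition_name = condition_name,
                 protein_mass_conc = protein_mass_conc,
                 transporter_mw = transporter_mw,
                 scaffold_mw = scaffold_mw,
                 scaffold_per_transporter = scaffold_per_transporter,
                 transporter_mass_fraction = transporter_mass_fraction,
                 orientation_factor = orientation_factor),
            class = "reconstitution_context")
}

#' Molar transporter concentration
#'
#' Converts the mass-based protein concentration of a reconstitution context
#' to a molar transporter concentration:
#' `protein_mass_conc * transporter_mass_fraction / transporter_mw`
#' (mg/ml over g/mol gives mol/L). At 0.05 mg/ml of a pure 135 kDa
#' transporter this is 0.37 uM.
#'
#' @param ctx A [reconstitution_context()].
#' @return Transporter concentration in mol/L.
#' @export
transporter_molarity <- function(ctx) {
  stopifnot(inherits(ctx, "reconstitution_context"))
  # mg/ml == g/L; kDa * 1000 == g/mol
  ctx$protein_mass_conc * ctx$transporter_mass_fraction /
    (ctx$transporter_mw * 1000)
}

#' Orientation correction of measured rates
#'
#' Multiplies measured rates by the context's orientation factor, converting
#' activity per accessible transporter population into activity per total
#' transporter. Correcting an already-corrected table is an error, so the
#' factor cannot be applied twice.
#'
#' @param obs A rate-observation tibble from [simulate_dataset()] or
#'   [read_rates_csv()]; must carry an `orientation_corrected` column (added
#'   with `FALSE` if absent).
#' @param ctx A [reconstitution_context()].
#' @return `obs` with `rate_per_min` scaled and `orientation_corrected` set.
#' @export
apply_orientation_correction <- function(obs, ctx) {
  stopifnot(is.data.frame(obs), inherits(ctx, "reconstitution_context"))
  if (is.null(obs[["orientation_corrected"]])) {
    obs$orientation_corrected <- FALSE
  }
  if (any(obs$orientation_corrected)) {
    stop("double-correction: observations are already orientation-corrected",
         call. = FALSE)
  }
  obs$rate_per_min <- obs$rate_per_min * ctx$orientation_factor
  obs$orientation_corrected <- TRUE
  obs
}
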