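#' Kinetic parameters of the nonessential activator model
#'
#' Bundles the five parameters of the nonessential activator rate law for a
#' transporter whose basal ATPase activity is stimulated by a transported
#' substrate: the basal catalytic rate constant `k`, the Michaelis binding
#' constants for MgATP (`K_T`) and for the activating substrate (`K_S`), the
#' dimensionless interaction factor `alpha` coupling the two binding events,
#' and the dimensionless acceleration factor `beta` for hydrolysis with the
#' activator bound. `alpha = 1` means MgATP and activator bind independently
#' (`alpha > 1` negative, `alpha < 1` positive cooperativity); `beta = 1`
#' means the activator does not change the hydrolysis rate.
#'
#' Rate constants are expressed per transporter homodimer; concentrations are
#' in mM.
#'
#' @param k Basal catalytic rate constant, min^-1 per transporter.
#' @param K_T Michaelis binding constant for MgATP, mM.
#' @param K_S Michaelis binding constant for the activating substrate, mM.
#' @param alpha Dimensionless MgATP-activator interaction factor.
#' @param beta Dimensionless acceleration factor for hydrolysis with the
#'   activator bound.
#'
#' @return An object of class `activator_params`.
#' @seealso [michaelis_params()], [activator_velocity()], [kobs()], [kt_app()]
#' @export
#' @examples
#' activator_params(k = 17.58, K_T = 0.82, K_S = 13.34, alpha = 1.03, beta = 8.30)
activator_params <- function(k, K_T, K_S, alpha, beta) {
  p <- list(k = k, K_T = K_T, K_S = K_S, alpha = alpha, beta = beta)
  check_positive_params(p)
  structure(p, class = "activator_params")
}

#' Michaelis-Menten parameters
#'
#' Turnover number and Michaelis constant of the hyperbolic rate law
#' `v = kcat * T / (Km + T)`.
#'
#' @param kcat Turnover number, min^-1 per transporter.
#' @param Km Michaelis constant, mM.
#'
#' @return An object of class `michaelis_params`.
#' @export
#' @examples
#' michaelis_params(kcat = 18, Km = 0.82)
michaelis_params <- function(kcat, Km) {
  p <- list(kcat = kcat, Km = Km)
  check_positive_params(p)
  structure(p, class = "michaelis_params")
}

# Eqs. for kobs/kt_app divide by alpha*K_S: enforce a positive floor well above
# denormals so every downstream expression is finite.
PARAM_FLOOR <- 1e-12

check_positive_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < PARAM_FLOOR) {
      stop("invalid-parameter: '", nm, "' must be a finite numeric > ",
           PARAM_FLOOR, " (got ", deparse(v), ")", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.activator_params <- function(x, ...) {
  cat("Nonessential activator parameters (per transporter dimer):\n")
  cat(sprintf("  k     = %.4g min^-1\n  K_T   = %.4g mM\n  K_S   = %.4g mM\n",
              x$k, x$K_T, x$K_S))
  cat(sprintf("  alpha = %.4g\n  beta  = %.4g\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
print.michaelis_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten parameters: kcat = %.4g min^-1, Km = %.4g mM\n",
              x$kcat, x$Km))
  invisible(x)
}

as_activator_params <- function(x) {
  if (inherits(x, "activator_params")) return(x)
  x <- as.list(x)
  activator_params(x$k, x$K_T, x$K_S, x$alpha, x$beta)
}
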