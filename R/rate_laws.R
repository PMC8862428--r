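#' Michaelis-Menten rate
#'
#' Hyperbolic steady-state rate `kcat * T / (Km + T)` as a function of MgATP
#' concentration.
#'
#' @param p A [michaelis_params()] object.
#' @param T MgATP concentration, mM (vectorized, non-negative).
#'
#' @return Specific rate in min^-1 per transporter, same length as `T`.
#' @export
#' @examples
#' mm_rate(michaelis_params(10, 1), T = 4)  # 8
mm_rate <- function(p, T) {
  stopifnot(inherits(p, "michaelis_params"))
  check_conc(T, "T")
  p$kcat * T / (p$Km + T)
}

#' Nonessential activator velocity
#'
#' Steady-state velocity of the nonessential activator scheme: the enzyme
#' turns over on MgATP (`T`) alone at rate constant `k`, while the bound
#' activator (`S`) rescales the MgATP binding constant by `alpha` and the
#' hydrolysis rate constant by `beta`:
#'
#' \deqn{v = E_T \, k \, \frac{T/K_T + \beta S T/(\alpha K_S K_T)}
#'   {1 + T/K_T + S/K_S + S T/(\alpha K_S K_T)}}
#'
#' With `E_total = NULL` (default) the specific rate `v / E_T` is returned in
#' min^-1 per transporter, matching how ATPase activities are usually
#' reported; supplying `E_total` (molar units) scales it to an absolute
#' velocity in concentration per minute.
#'
#' @param p An [activator_params()] object.
#' @param T MgATP concentration, mM (vectorized, non-negative).
#' @param S Activator concentration, mM (vectorized, non-negative).
#' @param E_total Optional total transporter concentration (molar units).
#'
#' @return Velocity, recycled over `T`/`S`.
#' @export
#' @examples
#' p <- activator_params(17.58, 0.82, 13.34, 1.03, 8.30)
#' activator_velocity(p, T = 10, S = 0)  # ~16.25 min^-1
activator_velocity <- function(p, T, S, E_total = NULL) {
  p <- as_activator_params(p)
  check_conc(T, "T")
  check_conc(S, "S")
  v <- activator_specific_rate(p$k, p$K_T, p$K_S, p$alpha, p$beta, T, S)
  if (!is.null(E_total)) {
    if (!is.numeric(E_total) || any(!is.finite(E_total)) || any(E_total <= 0)) {
      stop("invalid-parameter: E_total must be finite and > 0", call. = FALSE)
    }
    v <- v * E_total
  }
  v
}

# Plain-vector core shared by simulation and fitting (no class dispatch in the
# optimizer's inner loop).
activator_specific_rate <- function(k, K_T, K_S, alpha, beta, T, S) {
  aKsKt <- alpha * K_S * K_T
  num <- k * (T / K_T + beta * S * T / aKsKt)
  den <- 1 + T / K_T + S / K_S + S * T / aKsKt
  num / den
}

#' Apparent catalytic rate constant
#'
#' The apparent turnover number at activator concentration `S`:
#' `kobs = k (1 + beta S / (alpha K_S)) / (1 + S / (alpha K_S))`.
#' Equals `k` at `S = 0` and approaches `beta * k` at saturating activator;
#' monotone increasing in `S` whenever `beta > 1`.
#'
#' @inheritParams activator_velocity
#' @return Rate constant in min^-1, same length as `S`.
#' @export
kobs <- function(p, S) {
  p <- as_activator_params(p)
  check_conc(S, "S")
  x <- S / (p$alpha * p$K_S)
  p$k * (1 + p$beta * x) / (1 + x)
}

#' Apparent Michaelis constant for MgATP
#'
#' `K_T^app = K_T (1 + S/K_S) / (1 + S/(alpha K_S))`: equals `K_T` at
#' `S = 0`, is constant in `S` when `alpha = 1`, and increases with `S`
#' exactly when `alpha > 1` (negative cooperativity), approaching
#' `alpha * K_T` at saturating activator.
#'
#' @inheritParams activator_velocity
#' @return Apparent Michaelis constant in mM, same length as `S`.
#' @export
kt_app <- function(p, S) {
  p <- as_activator_params(p)
  check_conc(S, "S")
  p$K_T * (1 + S / p$K_S) / (1 + S / (p$alpha * p$K_S))
}

#' Fold stimulation of the ATPase rate by the activator
#'
#' Ratio `kobs(S) / kobs(0) = kobs(S) / k`: 1 at `S = 0`, bounded above by
#' `beta`. Reported both as the raw ratio and rounded to the nearest integer
#' by [derived_curves()], since stimulation factors are conventionally quoted
#' as whole numbers.
#'
#' @inheritParams activator_velocity
#' @return Dimensionless fold stimulation, same length as `S`.
#' @export
#' @examples
#' p <- activator_params(17.58, 0.82, 13.34, 1.03, 8.30)
#' round(fold_stimulation(p, 20))  # 5
fold_stimulation <- function(p, S) {
  p <- as_activator_params(p)
  kobs(p, S) / p$k
}

check_conc <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("invalid-concentration: '", name, "' must be finite and >= 0",
         call. = FALSE)
  }
  invisible(x)
}
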