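#' Sigmoid steady-state gating function
#'
#' `x_inf(V) = 1 / (1 + exp((V - Vx) / sx))`.  With a negative slope `sx`
#' this is an activation curve (increasing in V), with a positive slope an
#' inactivation curve.
#'
#' @param V membrane potential, mV (vectorised).
#' @param Vx half-activation voltage, mV.
#' @param sx slope factor, mV; must be non-zero.
#' @return gating fraction in (0, 1).
#' @export
gate_steady_state <- function(V, Vx, sx) {
  if (!is.numeric(sx) || length(sx) != 1L || sx == 0)
    stop("invalid parameter: slope sx must be a non-zero scalar")
  1 / (1 + exp((V - Vx) / sx))
}

#' Voltage-dependent gating time constant
#'
#' `tau_x(V) = tau_bar / cosh((V - Vx) / (2 sx))`: bell-shaped, maximal
#' (`tau_bar`) at `V = Vx`, symmetric about the midpoint.
#'
#' @param V membrane potential, mV (vectorised).
#' @param tau_bar maximal time constant, ms; must be positive.
#' @inheritParams gate_steady_state
#' @return time constant, ms.
#' @export
gate_time_constant <- function(V, tau_bar, Vx, sx) {
  if (!is.numeric(sx) || length(sx) != 1L || sx == 0)
    stop("invalid parameter: slope sx must be a non-zero scalar")
  if (!is.numeric(tau_bar) || length(tau_bar) != 1L || tau_bar <= 0)
    stop("invalid parameter: tau_bar must be a positive scalar")
  tau_bar / cosh((V - Vx) / (2 * sx))
}

#' Construct an ODE state vector
#'
#' State of the single-cell model: membrane potential `V` (mV), NaP
#' inactivation `h`, delayed-rectifier gate `n`, cytosolic calcium `ca_i`
#' (uM), total calcium `ca_tot` (uM, cytosol plus ER content expressed per
#' cytosolic volume) and the IP3-receptor gate `l`.  The ER concentration is
#' derived as `ca_er = (ca_tot - ca_i) / sigma`.
#'
#' @param V,h,n,ca_i,ca_tot,l state components.
#' @param sigma cytosol-to-ER volume ratio used to check `ca_er >= 0`.
#' @return named numeric vector of class `model_state`.
#' @export
model_state <- function(V, h, n, ca_i, ca_tot, l, sigma = 0.185) {
  s <- c(V = V, h = h, n = n, ca_i = ca_i, ca_tot = ca_tot, l = l)
  if (any(!is.finite(s))) stop("non-finite state component: ",
                               paste(names(s)[!is.finite(s)], collapse = ", "))
  if (h < 0 || h > 1 || n < 0 || n > 1 || l < 0 || l > 1)
    stop("gating variables h, n, l must lie in [0, 1]")
  if (ca_i < 0) stop("cytosolic calcium must be >= 0")
  if ((ca_tot - ca_i) / sigma < 0) stop("derived ER calcium must be >= 0")
  class(s) <- c("model_state", "numeric")
  s
}

#' Membrane current breakdown
#'
#' Evaluates every membrane current (outward positive) at a given state:
#' \itemize{
#'   \item `INaP = gNaP * m_inf(V) * h * (V - VNaP)`
#'   \item `INa  = gNa * m_na_inf(V)^3 * (1 - n) * (V - VNa)` (reconciled mode)
#'   \item `IK   = gK * n^4 * (V - VK)` (reconciled) or `gK * (V - VK)`
#'         (as-printed ohmic potassium leak)
#'   \item `IL   = gL * (V - VL)` (reconciled mode only)
#'   \item `ICa  = gCa * m_inf(V) * (V - VCa)` (activation shared with I_NaP)
#'   \item `ICAN = gCAN * ca_i / (ca_i + KCAN) * (V - VNaP)`
#'   \item `Ih   = gh * n_inf(V) * (V - Vh)` (gh = 0 by default)
#' }
#'
#' @param s a `model_state` (or named vector with the same components).
#' @param p a `model_parameters` object.
#' @return list of class `current_breakdown` with components `INaP`, `INa`,
#'   `IK`, `IL`, `ICa`, `ICAN`, `Ih` and their sum `total` (pA).
#' @export
compute_currents <- function(s, p) {
  stopifnot(inherits(p, "model_parameters"))
  V <- s[["V"]]; h <- s[["h"]]; n <- s[["n"]]; ca <- s[["ca_i"]]
  minf <- gate_steady_state(V, p$vm, p$sm)
  ninf <- gate_steady_state(V, p$vn, p$sn)
  reconciled <- identical(p$spiking_mode, "reconciled")
  out <- list(
    INaP = p$gNaP * minf * h * (V - p$VNaP),
    INa  = if (reconciled)
      p$gNa * gate_steady_state(V, p$vm_na, p$sm_na)^3 * (1 - n) * (V - p$VNa)
    else 0,
    IK   = if (reconciled) p$gK * n^4 * (V - p$VK) else p$gK * (V - p$VK),
    IL   = if (reconciled) p$gL * (V - p$VL) else 0,
    ICa  = p$gCa * minf * (V - p$VCa),
    ICAN = p$gCAN * ca / (ca + p$KCAN) * (V - p$VNaP),
    Ih   = p$gh * ninf * (V - p$Vh))
  out$total <- out$INaP + out$INa + out$IK + out$IL + out$ICa + out$ICAN + out$Ih
  class(out) <- "current_breakdown"
  out
}

#' Calcium flux breakdown
#'
#' ER release through IP3 receptors plus leak,
#' `J_ER_in = (LIP3R + PIP3R * (IP3 ca_i l / ((IP3 + KI)(ca_i + Ka)))^3) *
#' (ca_er - ca_i)`; SERCA re-uptake `J_ER_out = VSERCA ca_i^2 / (KSERCA^2 +
#' ca_i^2)`; plasma-membrane influx `J_PM_in = -alpha * ICa` (inward calcium
#' current is negative, so influx is positive); PMCA extrusion
#' `J_PM_out = VPMCA ca_i^2 / (KPMCA^2 + ca_i^2)`.
#'
#' Fluxes are in the model's per-second rate units; the right-hand side
#' converts them to uM/ms via `fi / Vi` and `flux_scale`.
#'
#' @inheritParams compute_currents
#' @param ICa voltage-gated calcium current, pA.
#' @return list of class `flux_breakdown` with `J_ER_in`, `J_ER_out`,
#'   `J_PM_in`, `J_PM_out` and the derived `ca_er` (uM).
#' @export
calcium_fluxes <- function(s, p, ICa) {
  stopifnot(inherits(p, "model_parameters"))
  ca <- s[["ca_i"]]
  ca_er <- (s[["ca_tot"]] - ca) / p$sigma
  if (ca_er < 0) stop("invalid state: derived ER calcium is negative")
  q <- p$IP3 * ca * s[["l"]] / ((p$IP3 + p$KI) * (ca + p$Ka))
  out <- list(
    J_ER_in  = (p$LIP3R + p$PIP3R * q^3) * (ca_er - ca),
    J_ER_out = p$VSERCA * ca^2 / (p$KSERCA^2 + ca^2),
    J_PM_in  = -p$alpha * ICa,
    J_PM_out = p$VPMCA * ca^2 / (p$KPMCA^2 + ca^2),
    ca_er = ca_er)
  class(out) <- "flux_breakdown"
  out
}

#' Right-hand side of the model ODE system (reference R implementation)
#'
#' Pure-R evaluation of the full vector field; the production integrator
#' uses the identical compiled version, and the two are cross-checked in the
#' test suite.  Equations:
#' `Cm dV/dt = -(INaP + INa + IK + IL + ICa + ICAN + Ih) + I_app`;
#' `dh/dt = (h_inf - h)/tau_h(V)`; `dn/dt = (n_inf - n)/tau_n(V)`;
#' `dca_i/dt = (fi/Vi) ((1/lam)(J_PM_in - J_PM_out) + (J_ER_in - J_ER_out))`;
#' `dca_tot/dt = (fi/Vi)(1/lam)(J_PM_in - J_PM_out)`;
#' `dl/dt = A (Kd - l (ca_i + Kd))`.
#'
#' @param t time, ms (unused; the system is autonomous).
#' @param s state vector (see [model_state()]).
#' @param p a `model_parameters` object.
#' @param I_app applied current, pA (positive depolarizes).
#' @param clamp if `TRUE`, hold V fixed (voltage clamp): `dV/dt = 0`.
#' @return named numeric vector of time derivatives (per ms).
#' @export
model_rhs <- function(t, s, p, I_app = 0, clamp = FALSE) {
  if (any(!is.finite(s)))
    stop("non-finite state component: ",
         paste(names(s)[!is.finite(s)], collapse = ", "))
  cur <- compute_currents(s, p)
  flx <- calcium_fluxes(s, p, cur$ICa)
  V <- s[["V"]]
  fv <- p$fi / p$Vi * p$flux_scale
  dpm <- (flx$J_PM_in - flx$J_PM_out) / p$lam
  der <- (flx$J_ER_in - flx$J_ER_out)
  c(V = if (clamp) 0 else (-cur$total + I_app) / p$Cm,
    h = (gate_steady_state(V, p$vh, p$sh) - s[["h"]]) /
      gate_time_constant(V, p$tau_h_bar, p$vh, p$sh),
    n = (gate_steady_state(V, p$vn, p$sn) - s[["n"]]) /
      gate_time_constant(V, p$tau_n_bar, p$vn, p$sn),
    ca_i = fv * (dpm + der),
    ca_tot = fv * dpm,
    l = p$A * (p$Kd - s[["l"]] * (s[["ca_i"]] + p$Kd)))
}
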