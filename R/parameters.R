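#' Model parameters for the embryonic preBotC pacemaker neuron
#'
#' Constructs the full parameter set of the single-cell model: a fast
#' Hodgkin-Huxley spiking subsystem (I_Na, I_K, I_L), the two
#' burst-generating currents I_NaP (persistent sodium) and I_CAN
#' (calcium-activated nonspecific cation), a non-inactivating voltage-gated
#' calcium current I_Ca feeding the calcium pools, an optional
#' hyperpolarization-activated current I_h (disabled by default), and a
#' two-pool cytosol/ER calcium subsystem with IP3-receptor release, SERCA
#' re-uptake, plasma-membrane influx proportional to I_Ca, and PMCA
#' extrusion.
#'
#' Units are mV, ms, nS, pF and pA on the electrical side (so nS x mV = pA
#' and pA / pF = mV/ms) and uM for calcium.  The calcium flux rates carry a
#' single dimensionless calibration factor `flux_scale` that converts the
#' published per-second pump/permeability rates into the effective cytosolic
#' uM/ms scale; its default is calibrated once so that the three canonical
#' discharge regimes (plateau, mixed, oscillatory) appear at the reference
#' conductance balance (gNaP = 2.5 nS with gCAN = 2.5 / 1 / 0 nS).
#'
#' The fast sodium activation (`vm_na`, `sm_na`) and the delayed-rectifier
#' gating (`vn`, `sn`) default to the classic Butera-model values; the slow
#' NaP activation (`vm`, `sm`) is shared with I_Ca.
#'
#' @param ... named overrides of any default parameter, e.g. `gCAN = 0`.
#' @param spiking_mode `"reconciled"` (default) uses the full spiking
#'   subsystem with I_Na and n^4 delayed-rectifier I_K; `"as_printed"` uses
#'   a purely ohmic potassium-dominated leak for I_K and omits I_Na and I_L,
#'   i.e. the minimal membrane-equation variant without action potentials.
#'
#' @return An object of class `model_parameters`: a named list of validated
#'   numeric parameters.
#' @examples
#' p <- model_parameters(gNaP = 2.5, gCAN = 0)
#' p$gCAN
#' @export
model_parameters <- function(..., spiking_mode = c("reconciled", "as_printed")) {
  spiking_mode <- match.arg(spiking_mode)
  p <- default_parameter_list()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(over)) p[[nm]] <- as.numeric(over[[nm]])
  }
  p$spiking_mode <- spiking_mode
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

# Single source of truth for the published constants.  Electrical side in
# mV/ms/nS/pF/pA, calcium in uM.  Conductance defaults are the reference
# configuration of the conductance-balance simulations (gNaP = gCAN = 2.5 nS).
default_parameter_list <- function() {
  list(
    # membrane
    Cm = 21,                                  # pF
    gNaP = 2.5, gNa = 28, gK = 11.2, gL = 2.7,
    gCAN = 2.5, gCa = 0.05, gh = 0,           # nS
    VNaP = 50, VNa = 50, VK = -65, VL = -60, VCa = 150, Vh = -30,  # mV
    # gating: shared NaP/Ca activation, NaP inactivation, fast Na activation,
    # delayed-rectifier n
    vm = -40, sm = -6,
    vh = -48, sh = 5, tau_h_bar = 10000,      # ms
    vm_na = -34, sm_na = -5,
    vn = -29, sn = -4, tau_n_bar = 10,        # ms
    KCAN = 0.74,                              # uM
    # calcium handling
    lam = 0.03, fi = 1e-4, Vi = 4, sigma = 0.185,
    IP3 = 1, A = 5e-4, Kd = 0.4, KI = 1, Ka = 0.4,
    LIP3R = 0.37, PIP3R = 31000,
    VSERCA = 400, KSERCA = 0.2,
    alpha = 0.055, VPMCA = 2, KPMCA = 0.3,
    flux_scale = 0.5
  )
}

#' Validate a model parameter set
#'
#' Checks positivity/range constraints: non-negative conductances, positive
#' capacitance, time constants and half-activation constants, `fi` in (0, 1],
#' positive `lam` and `sigma`, non-zero sigmoid slopes.
#'
#' @param p a `model_parameters` object (or plain named list).
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  num <- p[setdiff(names(p), "spiking_mode")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "))
  chk <- function(cond, msg) if (!cond) stop("invalid parameters: ", msg)
  for (g in c("gNaP", "gNa", "gK", "gL", "gCAN", "gCa", "gh"))
    chk(p[[g]] >= 0, paste(g, "must be >= 0"))
  chk(p$Cm > 0, "Cm must be > 0")
  chk(p$tau_h_bar > 0 && p$tau_n_bar > 0, "time-constant scales must be > 0")
  for (k in c("KCAN", "Kd", "KI", "Ka", "KSERCA", "KPMCA"))
    chk(p[[k]] > 0, paste(k, "must be > 0"))
  chk(p$fi > 0 && p$fi <= 1, "fi must be in (0, 1]")
  chk(p$lam > 0, "lam must be > 0")
  chk(p$sigma > 0, "sigma must be > 0")
  chk(p$flux_scale > 0, "flux_scale must be > 0")
  for (s in c("sm", "sh", "sn", "sm_na"))
    chk(p[[s]] != 0, paste(s, "must be non-zero"))
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> (", x$spiking_mode, " spiking subsystem)\n", sep = "")
  cat(sprintf("  gNaP = %g nS, gCAN = %g nS, gNa = %g nS, gK = %g nS, gL = %g nS\n",
              x$gNaP, x$gCAN, x$gNa, x$gK, x$gL))
  cat(sprintf("  Cm = %g pF, flux_scale = %g; %d parameters total\n",
              x$Cm, x$flux_scale, length(x) - 1L))
  invisible(x)
}

#' Write / read a parameter set as a flat key-value file
#'
#' One `key = value` line per parameter; `spiking_mode` is stored alongside
#' the numeric constants.  `read_params()` rejects unknown keys so a config
#' file cannot silently misname a parameter.
#'
#' @param p a `model_parameters` object.
#' @param path file path.
#' @return `read_params()` returns a `model_parameters` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "model_parameters"))
  num <- setdiff(names(p), "spiking_mode")
  lines <- c(
    sprintf("%s = %s", num,
            vapply(p[num], function(x) format(x, digits = 17), character(1))),
    sprintf("spiking_mode = %s", p$spiking_mode))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed parameter line in ", path)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  mode <- "reconciled"
  if ("spiking_mode" %in% keys) {
    mode <- vals[keys == "spiking_mode"]
    vals <- vals[keys != "spiking_mode"]
    keys <- keys[keys != "spiking_mode"]
  }
  over <- as.list(as.numeric(vals))
  names(over) <- keys
  do.call(model_parameters, c(over, list(spiking_mode = mode)))
}

#' Apply an in-silico channel blocker to a parameter set
#'
#' Pharmacology is modelled purely as conductance scaling: riluzole targets
#' gNaP only, flufenamic acid (FFA) and 9-phenanthrol target gCAN only, each
#' scaled by `(1 - efficacy)`.  The synaptic-blockade cocktail (CNQX / AP5 /
#' strychnine / bicuculline) acts on chemical synapses, which the single-cell
#' model does not contain, so it is a documented no-op here.
#'
#' @param p a `model_parameters` object.
#' @param drug one of `"riluzole"`, `"FFA"`, `"phenanthrol9"`, `"cocktail"`.
#' @param efficacy blocked fraction in \[0, 1\]; default 1 (full block).
#' @return a modified copy of `p`; non-target parameters are untouched.
#' @examples
#' p <- model_parameters(gNaP = 2.5, gCAN = 1)
#' apply_blocker(p, "riluzole")$gNaP  # 0
#' @export
apply_blocker <- function(p, drug = c("riluzole", "FFA", "phenanthrol9", "cocktail"),
                          efficacy = 1) {
  stopifnot(inherits(p, "model_parameters"))
  drug <- match.arg(drug)
  if (!is.numeric(efficacy) || efficacy < 0 || efficacy > 1)
    stop("efficacy must be a fraction in [0, 1]")
  target <- switch(drug,
    riluzole = "gNaP",
    FFA = "gCAN",
    phenanthrol9 = "gCAN",
    cocktail = NULL)
  if (!is.null(target)) p[[target]] <- p[[target]] * (1 - efficacy)
  p
}
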