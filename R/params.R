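#' Model parameters for the tripartite synapse
#'
#' Builds the full parameter set of the coupled two-neuron/one-astrocyte
#' model.  Defaults are the standard shifted-frame squid-axon
#' Hodgkin-Huxley constants, Terman-style synapse constants, and the
#' Li-Rinzel calcium constants of the model's parameter table.  All rate
#' constants quoted per second in the literature (`va`, `vb`, `vc`, `a2`,
#' `rP`) are supplied here in per-second units and converted to per-ms
#' internally, so the whole system integrates on a millisecond clock.
#'
#' @param Cm membrane capacitance, uF/cm^2.
#' @param gNa,gK,gL maximal Na+/K+/leak conductances, mS/cm^2.
#' @param vNa,vK,vL reversal potentials, mV (shifted frame, rest ~ 0 mV).
#' @param thetaS,sigmaS half-activation voltage (mV) and slope (mV) of the
#'   presynaptic transmitter-release sigmoid.
#' @param alphaS,betaS synaptic gate opening/closing rates, 1/ms.
#' @param gse,gsi maximal conductance of the excitatory (N1 to N2) and
#'   inhibitory (N2 to N1) synapses, mS/cm^2.
#' @param Eexc,Einh shifted-frame synaptic reversal potentials, mV.  The
#'   excitatory default (100 mV, near the action-potential peak) is
#'   calibrated so that the onset of N1-to-N2 transmission and the
#'   vanishing of the missed-spike fraction land at their published
#'   coupling strengths; both are configurable.
#' @param c0 total free calcium per cytosol volume, uM.
#' @param c1 ER-to-cytosol volume ratio, dimensionless.
#' @param va,vb,vc maximal IP3R channel flux, leak rate and SERCA pump rate,
#'   1/s (vc in uM/s).
#' @param d1,d2,d3,d5 IP3R dissociation constants, uM.
#' @param a2 IP3R inactivation binding rate, 1/(uM s).
#' @param k3 SERCA pump half-activation, uM.
#' @param P0 baseline IP3 concentration, uM.
#' @param tauP IP3 degradation rate, 1/ms.
#' @param rP IP3 production rate while the presynaptic trigger is on, uM/s.
#'   Stands in for the astrocytic mGluR expression level.
#' @param lambda astrocyte-effect weight in `[0, 1]`; 0 ignores the
#'   astrocyte, 1 applies its feedback current fully.
#' @param Ie1,Ie2 constant injected currents into N1 and N2, uA/cm^2.
#' @param kAstro coefficient of the calcium-to-current transfer function,
#'   uA/cm^2.
#' @param Ctheta calcium threshold of the feedback current, nM.
#' @param vg presynaptic voltage above which IP3 production is triggered, mV
#'   (used when `trigger = "step"`).
#' @param trigger IP3 production trigger: `"step"` (Heaviside on `v1 > vg`)
#'   or `"sigmoid"` (the transmitter-release sigmoid of `v1`).
#'
#' @return An object of class `tripartiteParams`: a named list of resolved
#'   parameter values (rates converted to per-ms).
#' @examples
#' p <- modelParams(Ie1 = 10, gse = 0.9, lambda = 0.5, rP = 0.8)
#' p$gse
#' @export
modelParams <- function(Cm = 1, gNa = 120, gK = 36, gL = 0.3,
                        vNa = 115, vK = -12, vL = 10.6,
                        thetaS = 85, sigmaS = 2, alphaS = 0.1, betaS = 0.05,
                        gse = 0.9, gsi = 0.1, Eexc = 100, Einh = -20,
                        c0 = 2, c1 = 0.185, va = 6, vb = 0.11, vc = 0.9,
                        d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234,
                        a2 = 0.2, k3 = 0.1,
                        P0 = 0.16, tauP = 0.00014, rP = 0.8,
                        lambda = 0, Ie1 = 10, Ie2 = 0,
                        kAstro = 2.11, Ctheta = 196.69, vg = 50,
                        trigger = c("step", "sigmoid")) {
  trigger <- match.arg(trigger)
  p <- list(Cm = Cm, gNa = gNa, gK = gK, gL = gL,
            vNa = vNa, vK = vK, vL = vL,
            thetaS = thetaS, sigmaS = sigmaS, alphaS = alphaS, betaS = betaS,
            gse = gse, gsi = gsi, Eexc = Eexc, Einh = Einh,
            c0 = c0, c1 = c1, va = va, vb = vb, vc = vc,
            d1 = d1, d2 = d2, d3 = d3, d5 = d5, a2 = a2, k3 = k3,
            P0 = P0, tauP = tauP, rP = rP,
            lambda = lambda, Ie1 = Ie1, Ie2 = Ie2,
            kAstro = kAstro, Ctheta = Ctheta, vg = vg,
            trigger = trigger)
  validateParams(p)
  class(p) <- "tripartiteParams"
  p
}

#' @export
print.tripartiteParams <- function(x, ...) {
  cat("Tripartite synapse parameters\n")
  cat(sprintf("  drive: Ie1 = %g, Ie2 = %g uA/cm^2\n", x$Ie1, x$Ie2))
  cat(sprintf("  synapses: gse = %g, gsi = %g mS/cm^2 (Eexc = %g, Einh = %g mV)\n",
              x$gse, x$gsi, x$Eexc, x$Einh))
  cat(sprintf("  astrocyte: lambda = %g, rP = %g uM/s, trigger = %s\n",
              x$lambda, x$rP, x$trigger))
  invisible(x)
}

validateParams <- function(p) {
  nonneg <- c("Cm", "gNa", "gK", "gL", "sigmaS", "alphaS", "betaS",
              "gse", "gsi", "c0", "c1", "va", "vb", "vc",
              "d1", "d2", "d3", "d5", "a2", "k3", "P0", "tauP", "rP",
              "kAstro", "Ctheta")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("parameter '%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  for (nm in c("vNa", "vK", "vL", "thetaS", "Eexc", "Einh", "Ie1", "Ie2", "vg")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  if (p$lambda < 0 || p$lambda > 1)
    stop("'lambda' must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# Flat named vector handed to the C++ kernels: per-second astrocyte rates
# converted to per-ms here, once.
packParams <- function(p, freezeAstro = FALSE) {
  stopifnot(inherits(p, "tripartiteParams"))
  c(Cm = p$Cm, gNa = p$gNa, gK = p$gK, gL = p$gL,
    vNa = p$vNa, vK = p$vK, vL = p$vL,
    thetaS = p$thetaS, sigmaS = p$sigmaS, alphaS = p$alphaS, betaS = p$betaS,
    gse = p$gse, gsi = p$gsi, Eexc = p$Eexc, Einh = p$Einh,
    c0 = p$c0, c1 = p$c1,
    va = p$va / 1000, vb = p$vb / 1000, vc = p$vc / 1000,
    d1 = p$d1, d2 = p$d2, d3 = p$d3, d5 = p$d5,
    a2 = p$a2 / 1000, k3 = p$k3,
    P0 = p$P0, tauP = p$tauP, rP = p$rP / 1000,
    lambda = p$lambda, Ie1 = p$Ie1, Ie2 = p$Ie2,
    kAstro = p$kAstro, Ctheta = p$Ctheta, vg = p$vg,
    trigger = if (p$trigger == "sigmoid") 1 else 0,
    freezeAstro = as.integer(freezeAstro))
}

# State vector layout shared by every function in the package.
stateNames <- function() {
  c("v1", "m1", "h1", "n1", "v2", "m2", "h2", "n2",
    "s1", "s2", "C", "q", "P")
}

currentNames <- function() {
  c("Is1", "Is2", "Iastro", "Ia1", "Ia2", "Itot1")
}
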