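#' Hodgkin-Huxley gate opening and closing rates
#'
#' Shifted-frame squid-axon rate functions (resting potential ~ 0 mV).
#' The removable singularities of `alpha_m` at v = 25 mV and `alpha_n` at
#' v = 10 mV are evaluated by their limits.
#'
#' @param v membrane potential, mV.
#' @return Named numeric vector `(alpha_m, beta_m, alpha_h, beta_h,
#'   alpha_n, beta_n)`, all in 1/ms.
#' @examples
#' gateRates(0)
#' gateRates(25)[["alpha_m"]]  # limit value 1
#' @export
gateRates <- function(v) {
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    stop("'v' must be a single finite number", call. = FALSE)
  um <- 25 - v
  alpha_m <- if (abs(um) < 1e-7) 1 else 0.1 * um / (exp(um / 10) - 1)
  un <- 10 - v
  alpha_n <- if (abs(un) < 1e-7) 0.1 else 0.01 * un / (exp(un / 10) - 1)
  c(alpha_m = alpha_m,
    beta_m = 4 * exp(-v / 18),
    alpha_h = 0.07 * exp(-v / 20),
    beta_h = 1 / (exp((30 - v) / 10) + 1),
    alpha_n = alpha_n,
    beta_n = 0.125 * exp(-v / 80))
}

#' Membrane and gate derivatives of a single neuron
#'
#' @param state named numeric vector with components `v`, `m`, `h`, `n`.
#' @param Iapplied total applied current (injected + synaptic + astrocytic
#'   feedback), uA/cm^2; positive = depolarizing.
#' @param params a [modelParams()] object.
#' @return Named vector of time derivatives `(v, m, h, n)` per ms.
#' @export
neuronRhs <- function(state, Iapplied, params = modelParams()) {
  v <- state[["v"]]; m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  r <- gateRates(v)
  Iion <- -params$gNa * m^3 * h * (v - params$vNa) -
    params$gK * n^4 * (v - params$vK) -
    params$gL * (v - params$vL)
  c(v = (Iion + Iapplied) / params$Cm,
    m = r[["alpha_m"]] * (1 - m) - r[["beta_m"]] * m,
    h = r[["alpha_h"]] * (1 - h) - r[["beta_h"]] * h,
    n = r[["alpha_n"]] * (1 - n) - r[["beta_n"]] * n)
}

#' Presynaptic transmitter concentration
#'
#' Sigmoid release function of the presynaptic membrane potential: near zero
#' at rest, ~1 at the spike peak.
#'
#' @param vPre presynaptic membrane potential, mV.
#' @param params a [modelParams()] object (uses `thetaS`, `sigmaS`).
#' @return Dimensionless concentration in (0, 1).
#' @export
transmitterConcentration <- function(vPre, params = modelParams()) {
  1 / (1 + exp(-(vPre - params$thetaS) / params$sigmaS))
}

#' Synaptic gate kinetics
#'
#' @param s gate variable in `[0, 1]`.
#' @param Tpre presynaptic transmitter concentration in `[0, 1]`.
#' @param params a [modelParams()] object (uses `alphaS`, `betaS`).
#' @return ds/dt in 1/ms.
#' @export
synapseRhs <- function(s, Tpre, params = modelParams()) {
  params$alphaS * Tpre * (1 - s) - params$betaS * s
}

#' Synaptic currents between the two neurons
#'
#' The excitatory synapse (gate `s1`, driven by N1) depolarizes N2; the
#' inhibitory synapse (gate `s2`, driven by N2) hyperpolarizes N1.
#'
#' @param v1,v2 membrane potentials of N1 and N2, mV.
#' @param s1,s2 synaptic gate variables.
#' @param params a [modelParams()] object.
#' @return Named vector `(Is1, Is2)`: current received by N1 and by N2,
#'   uA/cm^2.
#' @export
synapticCurrents <- function(v1, v2, s1, s2, params = modelParams()) {
  c(Is1 = params$gsi * s2 * (params$Einh - v1),
    Is2 = params$gse * s1 * (params$Eexc - v2))
}

#' Astrocyte calcium, IP3-receptor and IP3 derivatives
#'
#' Li-Rinzel two-variable reduction of IP3-receptor gating (ER release
#' channel, leak, SERCA pump) plus first-order IP3 turnover with
#' activity-triggered production: while the presynaptic potential exceeds
#' the trigger, IP3 is produced at rate `rP`.
#'
#' @param astro named vector with components `C` (cytosolic Ca2+, uM),
#'   `q` (fraction of non-inactivated IP3 receptors), `P` (IP3, uM).
#' @param v1 presynaptic (N1) membrane potential, mV.
#' @param params a [modelParams()] object.
#' @return Named vector of derivatives `(C, q, P)` per ms.
#' @export
astrocyteRhs <- function(astro, v1, params = modelParams()) {
  C <- astro[["C"]]; q <- astro[["q"]]; P <- astro[["P"]]
  Cer <- (params$c0 - C) / params$c1
  minf <- P / (P + params$d1)
  ninf <- C / (C + params$d5)
  Jchan <- params$c1 * (params$va / 1000) * (minf * ninf * q)^3 * (Cer - C)
  Jleak <- params$c1 * (params$vb / 1000) * (Cer - C)
  Jpump <- (params$vc / 1000) * C^2 / (params$k3^2 + C^2)
  alphaQ <- (params$a2 / 1000) * params$d2 * (P + params$d1) / (P + params$d3)
  drive <- if (params$trigger == "sigmoid") {
    transmitterConcentration(v1, params)
  } else {
    as.numeric(v1 > params$vg)
  }
  c(C = Jchan + Jleak - Jpump,
    q = alphaQ * (1 - q) - (params$a2 / 1000) * C * q,
    P = params$tauP * (params$P0 - P) + (params$rP / 1000) * drive)
}

#' Calcium-dependent astrocyte transfer current
#'
#' Logarithmic transfer function of the cytosolic calcium excess above a
#' threshold of `Ctheta` nanomolar; zero at or below threshold, continuous
#' and monotone increasing above it.
#'
#' @param C cytosolic calcium concentration, uM.
#' @param params a [modelParams()] object (uses `kAstro`, `Ctheta`).
#' @return Non-negative current, uA/cm^2.
#' @examples
#' astroFeedbackCurrent(0.19)  # below threshold: 0
#' astroFeedbackCurrent(0.5)
#' @export
astroFeedbackCurrent <- function(C, params = modelParams()) {
  y <- C * 1000 - params$Ctheta
  out <- numeric(length(y))
  pos <- y > 1
  out[pos] <- params$kAstro * log(y[pos])
  out
}

#' Feedback currents onto the two neurons
#'
#' The astrocyte transfer current is weighted by `lambda` and applied with
#' opposite signs: it inhibits the pyramidal cell N1 and excites the
#' interneuron N2.
#'
#' @param Iastro astrocyte transfer current, uA/cm^2 (non-negative).
#' @param lambda astrocyte-effect weight in `[0, 1]`.
#' @return Named vector `(Ia1, Ia2)`, uA/cm^2.
#' @export
feedbackCurrents <- function(Iastro, lambda) {
  c(Ia1 = -lambda * Iastro, Ia2 = lambda * Iastro)
}

#' Full system right-hand side
#'
#' Assembles the 13 coupled derivatives (two 4-variable neurons, two
#' synaptic gates, three astrocyte variables) and the diagnostic currents.
#' This pure-R composition of the component functions mirrors the compiled
#' kernel used by [simulateModel()]; the two are cross-checked in the test
#' suite.
#'
#' @param state named 13-vector in the order
#'   `v1,m1,h1,n1, v2,m2,h2,n2, s1,s2, C,q,P`.
#' @param params a [modelParams()] object.
#' @return List with `deriv` (named 13-vector, per ms) and `currents`
#'   (named vector `Is1, Is2, Iastro, Ia1, Ia2, Itot1`, uA/cm^2;
#'   `Itot1 = Ie1 + Ia1 + Is1`).
#' @export
systemRhs <- function(state, params = modelParams()) {
  stopifnot(length(state) == 13)
  names(state) <- stateNames()
  Iastro <- astroFeedbackCurrent(state[["C"]], params)
  Ia <- feedbackCurrents(Iastro, params$lambda)
  Is <- synapticCurrents(state[["v1"]], state[["v2"]],
                         state[["s1"]], state[["s2"]], params)
  d1 <- neuronRhs(c(v = state[["v1"]], m = state[["m1"]],
                    h = state[["h1"]], n = state[["n1"]]),
                  params$Ie1 + Ia[["Ia1"]] + Is[["Is1"]], params)
  d2 <- neuronRhs(c(v = state[["v2"]], m = state[["m2"]],
                    h = state[["h2"]], n = state[["n2"]]),
                  params$Ie2 + Ia[["Ia2"]] + Is[["Is2"]], params)
  dS <- c(synapseRhs(state[["s1"]],
                     transmitterConcentration(state[["v1"]], params), params),
          synapseRhs(state[["s2"]],
                     transmitterConcentration(state[["v2"]], params), params))
  dA <- astrocyteRhs(state[c("C", "q", "P")], state[["v1"]], params)
  deriv <- c(d1, d2, dS, dA)
  names(deriv) <- stateNames()
  list(deriv = deriv,
       currents = c(Is, Iastro = Iastro, Ia,
                    Itot1 = unname(params$Ie1 + Ia[["Ia1"]] + Is[["Is1"]])))
}
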