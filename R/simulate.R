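#' Default initial condition
#'
#' Both neurons start at the shifted-frame resting potential (v = 0) with
#' gates at their voltage-clamped steady states, closed synapses, and the
#' astrocyte at low calcium (0.1 uM) with q at its steady state and IP3 at
#' its baseline `P0`.
#'
#' @param params a [modelParams()] object.
#' @return Named 13-vector in the canonical state order.
#' @export
defaultInitialState <- function(params = modelParams()) {
  r <- gateRates(0)
  m0 <- r[["alpha_m"]] / (r[["alpha_m"]] + r[["beta_m"]])
  h0 <- r[["alpha_h"]] / (r[["alpha_h"]] + r[["beta_h"]])
  n0 <- r[["alpha_n"]] / (r[["alpha_n"]] + r[["beta_n"]])
  C0 <- 0.1
  P0 <- params$P0
  alphaQ <- params$a2 * params$d2 * (P0 + params$d1) / (P0 + params$d3)
  q0 <- alphaQ / (alphaQ + params$a2 * C0)
  st <- c(0, m0, h0, n0, 0, m0, h0, n0, 0, 0, C0, q0, P0)
  names(st) <- stateNames()
  st
}

#' Single fixed-step RK4 update
#'
#' Advances the full 13-component state by one classical Runge-Kutta step.
#' Gate and fraction variables that overshoot `[0, 1]` by less than 1e-9
#' are clipped; larger overshoot or a non-finite component raises an error
#' naming the offending variable.
#'
#' @param state named 13-vector (see [defaultInitialState()]).
#' @param params a [modelParams()] object.
#' @param dt step size, ms.
#' @return Updated named 13-vector.
#' @export
rk4Step <- function(state, params = modelParams(), dt = 0.05) {
  stopifnot(dt > 0, length(state) == 13)
  out <- rk4StepCpp(as.numeric(state), packParams(params), dt)
  names(out) <- stateNames()
  out
}

#' Simulate the coupled model
#'
#' Fixed-step fourth-order Runge-Kutta integration of the full system,
#' recording the state and the diagnostic currents every `recordStride`
#' steps (the initial and final steps are always recorded).  The
#' integration is fully deterministic: identical inputs give identical
#' trajectories.
#'
#' @param params a [modelParams()] object.
#' @param duration simulated time, ms.
#' @param init initial state; defaults to [defaultInitialState()].
#' @param dt integration step, ms (default 0.05).
#' @param recordStride record every this-many steps (default 4, i.e.
#'   0.2 ms sampling).
#' @param freezeAstro if `TRUE` the astrocyte block (C, q, P) is held
#'   fixed; used to verify that `lambda = 0` decouples the neurons from the
#'   astrocyte.
#' @param t0 time stamp of the initial state, ms.
#' @return A `trajectory` object: a data frame with columns `t`, the 13
#'   state components, and the currents `Is1, Is2, Iastro, Ia1, Ia2,
#'   Itot1`, with the parameters attached as attribute `params`.
#' @examples
#' tr <- simulateModel(modelParams(Ie1 = 10, gse = 0), duration = 200)
#' range(tr$v1)
#' @export
simulateModel <- function(params = modelParams(), duration,
                          init = defaultInitialState(params),
                          dt = 0.05, recordStride = 4,
                          freezeAstro = FALSE, t0 = 0) {
  stopifnot(duration > 0, dt > 0, recordStride >= 1, length(init) == 13)
  nsteps <- max(1L, as.integer(round(duration / dt)))
  mat <- simulateCpp(as.numeric(init), packParams(params, freezeAstro),
                     dt, nsteps, as.integer(recordStride), t0)
  df <- as.data.frame(mat)
  names(df) <- c("t", stateNames(), currentNames())
  attr(df, "params") <- params
  attr(df, "dt") <- dt
  class(df) <- c("trajectory", "data.frame")
  df
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over [%g, %g] ms (dt = %g ms)\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "dt")))
  p <- attr(x, "params")
  if (!is.null(p))
    cat(sprintf("  lambda = %g, gse = %g, rP = %g, Ie1 = %g\n",
                p$lambda, p$gse, p$rP, p$Ie1))
  invisible(x)
}

#' Write / read a trajectory as CSV with a JSON parameter sidecar
#'
#' The CSV holds one row per recorded sample with a mandatory header
#' (`t_ms, v1, m1, h1, n1, v2, m2, h2, n2, s1, s2, C_uM, q, P_uM, I_s1,
#' I_s2, I_astro, I_a1, I_a2, I_total1`); the sidecar `<path>.json` stores
#' the full resolved parameter set so every artifact is self-describing.
#'
#' @param traj a `trajectory` from [simulateModel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  out <- as.data.frame(traj)
  names(out) <- c("t_ms", "v1", "m1", "h1", "n1", "v2", "m2", "h2", "n2",
                  "s1", "s2", "C_uM", "q", "P_uM",
                  "I_s1", "I_s2", "I_astro", "I_a1", "I_a2", "I_total1")
  utils::write.csv(format(out, digits = 9, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  p <- attr(traj, "params")
  meta <- c(unclass(p), list(dt = attr(traj, "dt")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- c("t", stateNames(), currentNames())
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dt <- meta$dt
    meta$dt <- NULL
    attr(df, "params") <- do.call(modelParams, meta)
    attr(df, "dt") <- dt
  }
  class(df) <- c("trajectory", "data.frame")
  df
}
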