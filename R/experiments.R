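#' Shared bisection on a persistence predicate
#' @noRd
bisectOn <- function(predicate, lo, hi, tol) {
  if (!(hi > lo)) stop("invalid bracket: need hi > lo", call. = FALSE)
  pLo <- predicate(lo); pHi <- predicate(hi)
  if (pLo == pHi)
    stop("invalid bracket: predicate identical at both ends", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (predicate(mid) == pHi) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Rheobase of the isolated neuron
#'
#' Minimal constant injected current for persistent periodic firing of a
#' single uncoupled neuron (astrocyte weight and both synapses zeroed),
#' found by bisection with the persistence predicate of [isPersistent()]
#' applied to a 2 s analysis window after a 1 s transient.
#'
#' @param params base [modelParams()]; `lambda`, `gse`, `gsi`, `Ie2` are
#'   forced to the isolated-neuron configuration.
#' @param lo,hi bisection bracket, uA/cm^2 (`lo` sub-, `hi`
#'   supra-threshold).
#' @param tol bracket tolerance, uA/cm^2.
#' @param warmup,analysis transient discard and analysis window, ms.
#' @param subwindow persistence segment, ms.
#' @return The bracket midpoint, uA/cm^2.
#' @export
rheobaseSearch <- function(params = modelParams(), lo = 5, hi = 8,
                           tol = 0.01, warmup = 1000, analysis = 2000,
                           subwindow = 500) {
  base <- unclass(params)
  base$lambda <- 0; base$gse <- 0; base$gsi <- 0; base$Ie2 <- 0
  predicate <- function(I) {
    p <- do.call(modelParams, utils::modifyList(base, list(Ie1 = I)))
    tr <- simulateModel(p, duration = warmup + analysis)
    isPersistent(trajectorySpikes(tr, warmup = warmup)$N1, subwindow)
  }
  bisectOn(predicate, lo, hi, tol)
}

#' Critical excitatory coupling for information transmission
#'
#' Smallest excitatory conductance `gse` at which the interneuron N2,
#' receiving no injected current of its own, fires persistently in
#' response to the driven pyramidal cell N1.  Found by bisection on a
#' 10 s window after a 2 s warm-up with the transmission-persistence
#' predicate of [isTransmitted()]: N2 must spike in every 500 ms segment
#' in which N1 is active.  Judging N2 relative to N1's activity makes the
#' threshold independent of the astrocyte weight, because the episodic
#' quiescence that astrocytic feedback imposes on both neurons
#' simultaneously does not count against transmission.
#'
#' @param params base [modelParams()] (typically `Ie1 = 10`, `Ie2 = 0`).
#' @param lo,hi bisection bracket on `gse`.
#' @param tol bracket tolerance.
#' @param warmup,analysis transient discard and analysis window, ms.
#' @param subwindow persistence segment, ms.
#' @return The bracket midpoint (critical `gse`).
#' @export
criticalCoupling <- function(params = modelParams(), lo = 0.3, hi = 1,
                             tol = 0.01, warmup = 2000, analysis = 10000,
                             subwindow = 500) {
  base <- unclass(params)
  predicate <- function(g) {
    p <- do.call(modelParams, utils::modifyList(base, list(gse = g)))
    tr <- simulateModel(p, duration = warmup + analysis)
    st <- trajectorySpikes(tr, warmup = warmup)
    isTransmitted(st$N1, st$N2, subwindow)
  }
  bisectOn(predicate, lo, hi, tol)
}

#' Construct a sweep result
#' @noRd
sweepResult <- function(grid, values, statistic, meta = list()) {
  structure(list(grid = grid, values = values, statistic = statistic,
                 meta = meta),
            class = "sweepResult")
}

#' @export
print.sweepResult <- function(x, ...) {
  cat(sprintf("sweepResult: %s over %d cells\n", x$statistic, nrow(x$grid)))
  invisible(x)
}

#' Convert a sweep result to a long-format data frame
#'
#' @param x a `sweepResult`.
#' @param ... unused.
#' @return Data frame: one row per cell, grid columns plus the statistic.
#' @export
as.data.frame.sweepResult <- function(x, ...) {
  cbind(x$grid, value = x$values)
}

#' Bursting-like-spike region and rate map
#'
#' For every (lambda, gse) cell: simulate, segment the N1 spike train into
#' episodes, and classify the cell as bursting-like (BLS) when at least two
#' episodes separated by quiescence are present; report the episode rate.
#' Calcium oscillation periods are multi-second, so the per-cell duration
#' must cover several periods (default 100 s after a 20 s warm-up).
#'
#' @param lambdaGrid,gseGrid grid values.
#' @param params base [modelParams()].
#' @param duration analysis window per cell, ms.
#' @param warmup discarded transient, ms.
#' @param gap,minSpikes burst segmentation, see [detectBursts()].
#' @return List of two `sweepResult`s: `bls` (logical) and `rate`
#'   (episodes per second).
#' @export
blsMap <- function(lambdaGrid, gseGrid, params = modelParams(),
                   duration = 100000, warmup = 20000,
                   gap = 100, minSpikes = 2) {
  grid <- expand.grid(lambda = lambdaGrid, gse = gseGrid,
                      KEEP.OUT.ATTRS = FALSE)
  base <- unclass(params)
  bls <- logical(nrow(grid)); rate <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- do.call(modelParams, utils::modifyList(
      base, list(lambda = grid$lambda[i], gse = grid$gse[i])))
    ok <- try({
      tr <- simulateModel(p, duration = warmup + duration)
      bursts <- detectBursts(trajectorySpikes(tr, warmup = warmup)$N1,
                             gap, minSpikes)
      n <- nrow(bursts$episodes)
      bls[i] <- n >= 2
      rate[i] <- bursts$rate
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      bls[i] <- NA; rate[i] <- NA_real_
    }
  }
  meta <- list(duration = duration, warmup = warmup, gap = gap,
               minSpikes = minSpikes, params = params)
  list(bls = sweepResult(grid, bls, "BLS present", meta),
       rate = sweepResult(grid, rate, "BLS rate (1/s)", meta))
}

#' Mean transmission delay along a coupling sweep
#'
#' Computes the mean nearest-spike delay from N1 to N2 for each `gse` on
#' the grid and locates the minimizing coupling, optionally refining the
#' grid around the coarse minimum.
#'
#' @param gseGrid coupling grid (all points should exceed the critical
#'   coupling).
#' @param params base [modelParams()] (set `lambda` and `rP` here).
#' @param duration,warmup analysis window and discarded transient, ms.
#'   The default 20 s warm-up lets the slow calcium dynamics reach their
#'   attractor before delays are measured.
#' @param refineStep if non-`NULL`, the grid is refined at this step over
#'   one coarse cell on each side of the coarse minimum.
#' @param pairing passed to [transmissionDelay()].
#' @return A `sweepResult` with the mean delay per cell and `meta$argmin`,
#'   the `gse` minimizing the mean delay.
#' @export
delayCurve <- function(gseGrid, params = modelParams(),
                       duration = 10000, warmup = 20000,
                       refineStep = NULL, pairing = "nearest") {
  base <- unclass(params)
  evalCell <- function(g) {
    p <- do.call(modelParams, utils::modifyList(base, list(gse = g)))
    tr <- simulateModel(p, duration = warmup + duration)
    st <- trajectorySpikes(tr, warmup = warmup)
    # bursting-like episodes leave multi-second quiescent gaps in both
    # trains; delays remain well-defined on the matched spikes, so a cell
    # is skipped only when too few receiver spikes exist to average over
    if (length(st$N1$times) < 5 || length(st$N2$times) < 5) return(NA_real_)
    transmissionDelay(st$N1, st$N2, pairing = pairing)$mean
  }
  gseGrid <- sort(gseGrid)
  tau <- vapply(gseGrid, evalCell, numeric(1))
  if (!is.null(refineStep) && any(is.finite(tau))) {
    i <- which.min(tau)
    stepC <- if (length(gseGrid) > 1) max(diff(gseGrid)) else refineStep
    fine <- seq(max(min(gseGrid), gseGrid[i] - stepC),
                min(max(gseGrid), gseGrid[i] + stepC), by = refineStep)
    fine <- setdiff(round(fine, 10), round(gseGrid, 10))
    if (length(fine)) {
      tauF <- vapply(fine, evalCell, numeric(1))
      ord <- order(c(gseGrid, fine))
      gseGrid <- c(gseGrid, fine)[ord]
      tau <- c(tau, tauF)[ord]
    }
  }
  argmin <- if (any(is.finite(tau))) gseGrid[which.min(tau)] else NA_real_
  sweepResult(data.frame(gse = gseGrid), tau, "mean tau (ms)",
              list(argmin = argmin, duration = duration, warmup = warmup,
                   params = params))
}

#' Distortion ratio along a coupling sweep
#'
#' Computes the missed-spike fraction `Rd` for each `gse` and reports the
#' smallest coupling at which it reaches zero (faithful transmission).
#' The matched estimator of [distortionRatio()] is used so that the zero
#' crossing is not blurred by sender spikes at the very end of the window
#' whose response falls outside it.
#'
#' @inheritParams delayCurve
#' @param zeroTol accidental-miss allowance: the cutoff is the smallest
#'   grid `gse` with `Rd <= zeroTol`.  The default 0 demands exact
#'   spike-for-spike transmission; a small fraction (e.g. 0.01) treats the
#'   occasional astrocyte-induced miss of a single spike as faithful
#'   transmission rather than distortion.
#' @return A `sweepResult` with `Rd` per cell and `meta$cutoff`, the
#'   smallest grid `gse` with `Rd <= zeroTol`.
#' @export
distortionCurve <- function(gseGrid, params = modelParams(),
                            duration = 10000, warmup = 2000,
                            zeroTol = 0) {
  base <- unclass(params)
  gseGrid <- sort(gseGrid)
  rd <- vapply(gseGrid, function(g) {
    p <- do.call(modelParams, utils::modifyList(base, list(gse = g)))
    tr <- simulateModel(p, duration = warmup + duration)
    st <- trajectorySpikes(tr, warmup = warmup)
    if (length(st$N1$times) == 0) return(NA_real_)
    distortionRatio(st$N1, st$N2, method = "matched")$Rd
  }, numeric(1))
  zero <- which(!is.na(rd) & rd <= zeroTol)
  cutoff <- if (length(zero)) gseGrid[min(zero)] else NA_real_
  sweepResult(data.frame(gse = gseGrid), rd, "Rd",
              list(cutoff = cutoff, duration = duration, warmup = warmup,
                   params = params))
}

#' Write a sweep result as long-format CSV plus a JSON index
#'
#' @param sweep a `sweepResult`.
#' @param path output CSV path; the JSON index goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeSweep <- function(sweep, path) {
  df <- as.data.frame(sweep)
  utils::write.csv(format(df, digits = 9, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- sweep$meta
  if (!is.null(meta$params)) meta$params <- unclass(meta$params)
  jsonlite::write_json(c(list(statistic = sweep$statistic), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
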