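#' Synthetic two-channel spike fixture
#'
#' Generates a pair of voltage traces with fully known ground truth for
#' unit-testing the spike metrics: channel 1 carries spikes at given (or
#' jittered-periodic) times, channel 2 repeats them shifted by `lag` with
#' an optional missed-spike pattern.  Spikes are rendered as Gaussian
#' pulses of `amplitude` mV on a 0 mV baseline, mimicking the shifted-frame
#' action-potential shape.  This is the only stochastic code path in the
#' package and always requires an explicit seed.
#'
#' @param nSpikes number of channel-1 spikes.
#' @param isi mean inter-spike interval, ms.
#' @param jitter standard deviation of the ISI jitter, ms.
#' @param lag channel-2 lag behind channel 1, ms.
#' @param keep logical vector recycled over channel-1 spikes: `FALSE`
#'   drops the corresponding channel-2 spike (missed-spike pattern).
#' @param seed integer seed (required).
#' @param dt sample spacing of the rendered traces, ms.
#' @param amplitude pulse height, mV.
#' @param width Gaussian pulse standard deviation, ms.
#' @param burstEvery if positive, spikes are emitted in bursts of
#'   `burstEvery` spikes separated by `burstGap` ms of silence.
#' @param burstGap silence between bursts, ms.
#' @return A `spikeFixture`: list with `times`, `v1`, `v2` (traces) and
#'   `truth` (spike times per channel, lag, keep pattern).
#' @examples
#' fx <- makeSpikeFixture(nSpikes = 10, lag = 3, seed = 1)
#' length(fx$truth$spikes1)
#' @export
makeSpikeFixture <- function(nSpikes = 20, isi = 50, jitter = 0, lag = 0,
                             keep = TRUE, seed, dt = 0.05, amplitude = 100,
                             width = 0.1, burstEvery = 0, burstGap = 500) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  set.seed(seed)
  if (burstEvery > 0) {
    nBursts <- ceiling(nSpikes / burstEvery)
    s1 <- unlist(lapply(seq_len(nBursts) - 1, function(b) {
      b * (burstEvery * isi + burstGap) + seq_len(burstEvery) * isi
    }))[seq_len(nSpikes)]
  } else {
    s1 <- cumsum(pmax(isi / 4, isi + stats::rnorm(nSpikes, 0, jitter)))
  }
  keep <- rep_len(keep, nSpikes)
  s2 <- s1[keep] + lag
  tEnd <- max(s1, s2) + max(10 * isi / 10, 20) + abs(lag)
  times <- seq(0, tEnd, by = dt)
  render <- function(sp) {
    v <- numeric(length(times))
    for (t0 in sp) v <- v + amplitude * exp(-(times - t0)^2 / (2 * width^2))
    v
  }
  structure(list(times = times, v1 = render(s1), v2 = render(s2),
                 truth = list(spikes1 = s1, spikes2 = s2, lag = lag,
                              keep = keep, seed = seed)),
            class = "spikeFixture")
}

#' @export
print.spikeFixture <- function(x, ...) {
  cat(sprintf("spikeFixture: %d/%d spikes, lag %g ms, seed %d\n",
              length(x$truth$spikes1), length(x$truth$spikes2),
              x$truth$lag, x$truth$seed))
  invisible(x)
}
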