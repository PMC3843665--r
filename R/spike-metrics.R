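#' Spike train object
#'
#' @param times sorted spike times, ms.
#' @param source label of the neuron the train came from.
#' @param window length-2 numeric, the detection window (ms).
#' @return A `spikeTrain` object.
#' @export
spikeTrain <- function(times, source = "N1", window = range(times, 0)) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(times = times, source = source,
                 window = as.numeric(window)),
            class = "spikeTrain")
}

#' @export
print.spikeTrain <- function(x, ...) {
  cat(sprintf("spikeTrain: %d spikes from %s over [%g, %g] ms\n",
              length(x$times), x$source, x$window[1], x$window[2]))
  invisible(x)
}

#' Write spike trains as two-column CSV
#'
#' @param trains a named list of [spikeTrain()] objects (e.g. the result
#'   of [trajectorySpikes()]).
#' @param path output CSV path; columns `neuron`, `t_ms`.
#' @return `path`, invisibly.
#' @export
writeSpikeTrains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(neuron = tr$source, t_ms = tr$times)))
  utils::write.csv(format(df, digits = 9, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect spikes by threshold crossing
#'
#' A spike is recorded at each upward crossing of `threshold`, with the
#' crossing time refined by linear interpolation between samples, and a
#' refractory constraint of `minSeparation` ms between accepted spikes.
#' With the shifted-frame convention (rest ~ 0 mV, peaks ~ 100 mV) the
#' default 50 mV threshold sits mid-spike, making detection insensitive to
#' the exact threshold over roughly 30--70 mV.
#'
#' @param v voltage trace, mV.
#' @param times sample times, ms (same length as `v`).
#' @param threshold detection threshold, mV.
#' @param minSeparation minimal separation between spikes, ms.
#' @param source neuron label stored on the result.
#' @return A [spikeTrain()].
#' @export
detectSpikes <- function(v, times, threshold = 50, minSeparation = 2,
                         source = "N1") {
  if (length(v) == 0) stop("empty voltage trace", call. = FALSE)
  stopifnot(length(v) == length(times))
  n <- length(v)
  below <- v[-n] < threshold
  above <- v[-1] >= threshold
  idx <- which(below & above)
  if (length(idx) == 0)
    return(spikeTrain(numeric(0), source, range(times)))
  frac <- (threshold - v[idx]) / (v[idx + 1] - v[idx])
  tc <- times[idx] + frac * (times[idx + 1] - times[idx])
  keep <- rep(TRUE, length(tc))
  last <- tc[1]
  if (length(tc) > 1) {
    for (i in 2:length(tc)) {
      if (tc[i] - last < minSeparation) keep[i] <- FALSE else last <- tc[i]
    }
  }
  spikeTrain(tc[keep], source, range(times))
}

#' Extract spike trains from a trajectory
#'
#' Convenience wrapper: detects spikes of N1 and N2 on the recorded window
#' after discarding `warmup` ms.
#'
#' @param traj a `trajectory` from [simulateModel()].
#' @param warmup initial transient to discard, ms.
#' @param threshold,minSeparation passed to [detectSpikes()].
#' @return List with elements `N1` and `N2`, each a [spikeTrain()].
#' @export
trajectorySpikes <- function(traj, warmup = 0, threshold = 50,
                             minSeparation = 2) {
  keep <- traj$t >= traj$t[1] + warmup
  list(N1 = detectSpikes(traj$v1[keep], traj$t[keep], threshold,
                         minSeparation, "N1"),
       N2 = detectSpikes(traj$v2[keep], traj$t[keep], threshold,
                         minSeparation, "N2"))
}

#' Persistent-firing predicate
#'
#' A train is persistent when every `subwindow`-length segment of its
#' detection window contains at least one spike — equivalently, no gap
#' between consecutive spikes (including the window edges) exceeds
#' `subwindow`.
#'
#' @param train a [spikeTrain()].
#' @param subwindow segment length, ms (default 500).
#' @return Logical.
#' @export
isPersistent <- function(train, subwindow = 500) {
  stopifnot(inherits(train, "spikeTrain"))
  if (length(train$times) == 0) return(FALSE)
  gaps <- diff(c(train$window[1], train$times, train$window[2]))
  max(gaps) <= subwindow
}

#' Burst segmentation of a spike train
#'
#' Greedy inter-spike-interval partition: a new episode starts whenever the
#' interval to the previous spike exceeds `gap`; episodes with fewer than
#' `minSpikes` spikes are discarded.  The burst rate is the number of
#' retained episodes divided by the window length in seconds.  With tonic
#' inter-spike intervals of ~10-15 ms and astrocytic quiescent phases of
#' seconds, the default 100 ms gap separates bursting-like episodes
#' robustly (the partition is stable across gaps of 50-500 ms).
#'
#' @param train a [spikeTrain()].
#' @param gap episode-splitting inter-spike interval, ms.
#' @param minSpikes minimal spikes per retained episode.
#' @return A `burstSet`: list with `episodes` (data frame `start`, `end`,
#'   `nSpikes`), `window`, `rate` (episodes per second of window).
#' @export
detectBursts <- function(train, gap = 100, minSpikes = 2) {
  stopifnot(inherits(train, "spikeTrain"))
  tt <- train$times
  if (length(tt) == 0) {
    ep <- data.frame(start = numeric(0), end = numeric(0),
                     nSpikes = integer(0))
  } else {
    grp <- cumsum(c(1, as.integer(diff(tt) > gap)))
    start <- tapply(tt, grp, min)
    end <- tapply(tt, grp, max)
    n <- tapply(tt, grp, length)
    keep <- n >= minSpikes
    ep <- data.frame(start = as.numeric(start[keep]),
                     end = as.numeric(end[keep]),
                     nSpikes = as.integer(n[keep]))
  }
  winS <- diff(train$window) / 1000
  structure(list(episodes = ep, window = train$window,
                 rate = nrow(ep) / winS),
            class = "burstSet")
}

#' @export
print.burstSet <- function(x, ...) {
  cat(sprintf("burstSet: %d episodes over %g s (rate %.4g /s)\n",
              nrow(x$episodes), diff(x$window) / 1000, x$rate))
  invisible(x)
}

#' Spike transmission delay between two neurons
#'
#' For each spike of `train2` (the receiver, N2), the delay is the time
#' interval to the closest spike of `train1` (the sender, N1): an absolute,
#' non-negative interval, with the signed version kept alongside.  Receiver
#' spikes with no sender spike within the matching `horizon` are excluded
#' rather than assigned saturated delays; the default horizon is half the
#' median sender inter-spike interval.
#'
#' @param train1,train2 [spikeTrain()] objects (sender, receiver).
#' @param horizon matching horizon, ms (default: half the median
#'   inter-spike interval of `train1`).
#' @param pairing `"nearest"` matches the closest sender spike on either
#'   side; `"preceding"` restricts matches to the closest earlier sender
#'   spike.
#' @return A `delaySeries`: list with per-spike `delays` (absolute
#'   intervals, ms), `signed` (negative when the receiver spike precedes
#'   its matched sender spike), `mean` (of the absolute delays),
#'   `amplitude` (half the peak-to-peak range of the delays, ms), and
#'   `nUnmatched`.
#' @export
transmissionDelay <- function(train1, train2, horizon = NULL,
                              pairing = c("nearest", "preceding")) {
  pairing <- match.arg(pairing)
  t1 <- train1$times; t2 <- train2$times
  if (length(t1) == 0 || length(t2) == 0)
    stop("transmission delay undefined for an empty spike train",
         call. = FALSE)
  if (is.null(horizon)) {
    horizon <- if (length(t1) > 1) stats::median(diff(t1)) / 2 else Inf
  }
  idx <- findInterval(t2, t1)                    # last t1 <= t2
  prevT <- ifelse(idx >= 1, t1[pmax(idx, 1)], -Inf)
  nextT <- ifelse(idx < length(t1), t1[pmin(idx + 1, length(t1))], Inf)
  if (pairing == "preceding") {
    delay <- t2 - prevT
  } else {
    usePrev <- (t2 - prevT) <= (nextT - t2)
    delay <- ifelse(usePrev, t2 - prevT, t2 - nextT)
  }
  matched <- abs(delay) <= horizon
  d <- abs(delay[matched])
  structure(list(delays = d, signed = delay[matched],
                 mean = if (length(d)) mean(d) else NA_real_,
                 amplitude = if (length(d)) diff(range(d)) / 2 else NA_real_,
                 nUnmatched = sum(!matched)),
            class = "delaySeries")
}

#' @export
print.delaySeries <- function(x, ...) {
  cat(sprintf("delaySeries: %d matched spikes, mean tau = %.4g ms (amplitude %.3g ms, %d unmatched)\n",
              length(x$delays), x$mean, x$amplitude, x$nUnmatched))
  invisible(x)
}

#' Information-distortion ratio
#'
#' Fraction of sender (N1) spikes that are not reproduced in the receiver
#' (N2) over a common window, so `Rd = 0` means faithful spike-for-spike
#' transmission.  Two estimators are available: `"counts"` compares raw
#' spike counts, `Rd = (n1 - n2)/n1` clamped below at zero; `"matched"`
#' counts the sender spikes with no receiver spike within the matching
#' `horizon`, excluding sender spikes closer than `horizon` to the window
#' end (whose response would fall outside the common window).  The literal
#' sender/receiver count ratio is reported alongside.
#'
#' @param train1,train2 [spikeTrain()] objects (sender, receiver).
#' @param method `"counts"` or `"matched"` (see above).
#' @param horizon matching horizon for `method = "matched"`, ms; defaults
#'   to half the median sender inter-spike interval.
#' @return List with `Rd`, the spike counts `n1`, `n2`, and the raw count
#'   `ratio` (`n1/n2`, `Inf` when the receiver is silent).
#' @export
distortionRatio <- function(train1, train2, method = c("counts", "matched"),
                            horizon = NULL) {
  method <- match.arg(method)
  t1 <- train1$times; t2 <- train2$times
  n1 <- length(t1); n2 <- length(t2)
  if (n1 == 0)
    stop("distortion ratio undefined: sender train is empty", call. = FALSE)
  if (method == "counts") {
    rd <- max(0, (n1 - n2) / n1)
  } else {
    if (is.null(horizon))
      horizon <- if (n1 > 1) stats::median(diff(t1)) / 2 else Inf
    use <- t1 <= train1$window[2] - horizon
    if (!any(use))
      stop("no sender spikes clear of the window end", call. = FALSE)
    missed <- vapply(t1[use], function(x) {
      length(t2) == 0 || min(abs(t2 - x)) > horizon
    }, logical(1))
    rd <- mean(missed)
  }
  list(Rd = rd, n1 = n1, n2 = n2,
       ratio = if (n2 > 0) n1 / n2 else Inf)
}

#' Transmission-persistence predicate
#'
#' Judges whether the receiver follows the sender whenever the sender is
#' active: the sender train is split into active stretches at gaps longer
#' than `subwindow`, and within every sufficiently long stretch the
#' receiver must spike in each `subwindow`-length segment.  When the
#' sender is tonically active this reduces to [isPersistent()] applied to
#' the receiver; when astrocytic feedback silences both neurons
#' episodically, the shared quiescent phases do not count against the
#' receiver.
#'
#' @param sender,receiver [spikeTrain()] objects.
#' @param subwindow segment length, ms.
#' @return Logical: `FALSE` when the sender never sustains activity for a
#'   full subwindow, otherwise whether every active stretch is covered.
#' @export
isTransmitted <- function(sender, receiver, subwindow = 500) {
  t1 <- sender$times
  if (length(t1) == 0) return(FALSE)
  blocks <- cumsum(c(1, as.integer(diff(t1) > subwindow)))
  anyLong <- FALSE
  for (b in unique(blocks)) {
    tb <- t1[blocks == b]
    if (diff(range(tb)) < subwindow) next
    anyLong <- TRUE
    t2 <- receiver$times[receiver$times >= min(tb) &
                           receiver$times <= max(tb)]
    if (length(t2) == 0) return(FALSE)
    gaps <- diff(c(min(tb), t2, max(tb)))
    if (max(gaps) > subwindow) return(FALSE)
  }
  anyLong
}
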