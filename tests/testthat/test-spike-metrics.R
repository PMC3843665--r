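test_that("spike detection recovers fixture ground truth", {
  fx <- makeSpikeFixture(nSpikes = 7, isi = 40, seed = 7)
  st <- detectSpikes(fx$v1, fx$times)
  expect_equal(length(st$times), 7)
  expect_lt(max(abs(st$times - fx$truth$spikes1)), 0.2)
})

test_that("degenerate traces are handled", {
  expect_error(detectSpikes(numeric(0), numeric(0)), "empty")
  flat <- detectSpikes(rep(0, 1000), seq(0, 99.9, by = 0.1))
  expect_equal(length(flat$times), 0)
  expect_false(isPersistent(flat))
})

test_that("spike detection is equivariant under a uniform time shift", {
  fx <- makeSpikeFixture(nSpikes = 9, isi = 30, jitter = 4, seed = 3)
  a <- detectSpikes(fx$v1, fx$times)
  b <- detectSpikes(fx$v1, fx$times + 123.4)
  expect_equal(b$times, a$times + 123.4, tolerance = 1e-9)
})

test_that("spike counts are insensitive to the threshold over 30-70 mV", {
  tr <- simulateModel(paramsLambda0(gse = 0), duration = 1000)
  counts <- vapply(c(30, 40, 50, 60, 70), function(th)
    length(detectSpikes(tr$v1, tr$t, threshold = th)$times), numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("persistence requires a spike in every subwindow", {
  tonic <- spikeTrain(seq(10, 990, by = 15), window = c(0, 1000))
  expect_true(isPersistent(tonic, subwindow = 500))
  gappy <- spikeTrain(c(seq(10, 200, by = 15), seq(900, 990, by = 15)),
                      window = c(0, 1000))
  expect_false(isPersistent(gappy, subwindow = 500))
})

test_that("burst segmentation recovers a known burst structure", {
  fx <- makeSpikeFixture(nSpikes = 50, isi = 20, seed = 5,
                         burstEvery = 10, burstGap = 500)
  st <- detectSpikes(fx$v1, fx$times)
  b <- detectBursts(st, gap = 100, minSpikes = 2)
  expect_equal(nrow(b$episodes), 5)
  expect_equal(b$episodes$nSpikes, rep(10L, 5))
  # a tonic train is a single episode, not bursting
  tonic <- spikeTrain(seq(10, 990, by = 15), window = c(0, 1000))
  expect_equal(nrow(detectBursts(tonic)$episodes), 1)
})

test_that("episode count is monotone non-increasing in the gap parameter", {
  fx <- makeSpikeFixture(nSpikes = 60, isi = 25, jitter = 6, seed = 11,
                         burstEvery = 6, burstGap = 300)
  st <- detectSpikes(fx$v1, fx$times)
  nEp <- vapply(c(30, 50, 100, 200, 400), function(g)
    nrow(detectBursts(st, gap = g)$episodes), numeric(1))
  expect_true(all(diff(nEp) <= 0))
})

test_that("transmission delay recovers a constructed lag", {
  fx <- makeSpikeFixture(nSpikes = 20, isi = 50, jitter = 3, lag = 3,
                         seed = 2)
  s1 <- detectSpikes(fx$v1, fx$times)
  s2 <- detectSpikes(fx$v2, fx$times)
  d <- transmissionDelay(s1, s2)
  expect_equal(d$mean, 3, tolerance = 0.1)
  expect_equal(d$nUnmatched, 0)
  # a train against itself has identically zero delay
  d0 <- transmissionDelay(s1, s1)
  expect_true(all(d0$delays == 0))
  # absolute intervals are direction-symmetric for a pure lag
  dRev <- transmissionDelay(s2, s1)
  expect_equal(dRev$mean, d$mean, tolerance = 0.1)
  expect_equal(mean(dRev$signed), -mean(d$signed), tolerance = 0.1)
  expect_error(transmissionDelay(s1, spikeTrain(numeric(0))), "empty")
})

test_that("the preceding-only pairing never yields negative delays", {
  fx <- makeSpikeFixture(nSpikes = 25, isi = 40, jitter = 5, lag = 4,
                         seed = 9)
  s1 <- detectSpikes(fx$v1, fx$times)
  s2 <- detectSpikes(fx$v2, fx$times)
  d <- transmissionDelay(s1, s2, pairing = "preceding")
  expect_true(all(d$signed >= 0))
  expect_equal(d$mean, 4, tolerance = 0.1)
})

test_that("distortion ratio counts missed spikes", {
  t1 <- spikeTrain(seq(10, 1000, by = 10), window = c(0, 1010))
  expect_equal(distortionRatio(t1, t1)$Rd, 0)
  half <- spikeTrain(t1$times[seq(1, length(t1$times), by = 2)],
                     window = c(0, 1010))
  expect_equal(distortionRatio(t1, half)$Rd, 0.5)
  expect_equal(distortionRatio(t1, half)$ratio, 2)
  expect_error(distortionRatio(spikeTrain(numeric(0)), t1), "empty")
  # fixture dropping every 2nd spike
  fx <- makeSpikeFixture(nSpikes = 20, isi = 50, seed = 4,
                         keep = c(TRUE, FALSE))
  s1 <- detectSpikes(fx$v1, fx$times)
  s2 <- detectSpikes(fx$v2, fx$times)
  expect_equal(distortionRatio(s1, s2)$Rd, 0.5)
})

test_that("matched distortion ignores sender spikes at the window edge", {
  # receiver misses only the response to the sender's final spike, which
  # falls beyond the common window: matched Rd stays 0
  t1 <- spikeTrain(seq(10, 1000, by = 10), window = c(0, 1002))
  t2 <- spikeTrain(seq(13, 993, by = 10), window = c(0, 1002))
  expect_gt(distortionRatio(t1, t2)$Rd, 0)
  expect_equal(distortionRatio(t1, t2, method = "matched")$Rd, 0)
})

test_that("spike trains export as two-column CSV", {
  fx <- makeSpikeFixture(nSpikes = 5, isi = 50, lag = 3, seed = 8)
  trains <- list(N1 = detectSpikes(fx$v1, fx$times, source = "N1"),
                 N2 = detectSpikes(fx$v2, fx$times, source = "N2"))
  path <- tempfile(fileext = ".csv")
  writeSpikeTrains(trains, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("neuron", "t_ms"))
  expect_equal(nrow(df), 10)
  expect_setequal(unique(df$neuron), c("N1", "N2"))
})

test_that("transmission predicate tolerates shared quiescent episodes", {
  # two bursts with a long shared silence: receiver follows sender
  s1 <- spikeTrain(c(seq(0, 1000, by = 20), seq(4000, 5000, by = 20)),
                   window = c(0, 5100))
  s2 <- spikeTrain(s1$times + 3, window = c(0, 5100))
  expect_true(isTransmitted(s1, s2, subwindow = 500))
  expect_false(isPersistent(s2, subwindow = 500))
  # receiver silent during the second episode: not transmitted
  s2b <- spikeTrain(seq(3, 1003, by = 20), window = c(0, 5100))
  expect_false(isTransmitted(s1, s2b, subwindow = 500))
  # reduces to plain persistence for a tonically active sender
  tonic <- spikeTrain(seq(10, 4990, by = 15), window = c(0, 5000))
  expect_true(isTransmitted(tonic, tonic))
})
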