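# Shared configurations used across test files.

# Driven pyramidal cell, silent interneuron, astrocyte ignored.
paramsLambda0 <- function(...) {
  modelParams(Ie1 = 10, Ie2 = 0, lambda = 0, rP = 0.8, ...)
}

# Full tripartite configuration in the bursting-like-spike regime.
paramsBls <- function(...) {
  modelParams(Ie1 = 10, Ie2 = 0, lambda = 0.5, gse = 0.9, rP = 0.8, ...)
}

# A random valid state within the invariant set, for property-style loops.
randomState <- function() {
  st <- c(stats::runif(1, -20, 110), stats::runif(3),
          stats::runif(1, -20, 110), stats::runif(3),
          stats::runif(2),
          stats::runif(1, 0.05, 1), stats::runif(1), stats::runif(1, 0.1, 1))
  names(st) <- c("v1", "m1", "h1", "n1", "v2", "m2", "h2", "n2",
                 "s1", "s2", "C", "q", "P")
  st
}
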