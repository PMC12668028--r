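# Avalanche distributions and the sub/critical/supercritical classifier
# on generated data with known shapes.

drawDiscretePowerLaw <- function(n, tau, smax, seed) {
  withr::local_seed(seed)
  supp <- 1:smax
  sample(supp, n, replace = TRUE, prob = supp^(-tau))
}

fakeCatalog <- function(sizes) {
  data.frame(start = seq_along(sizes) * 10, duration = pmax(1, round(sqrt(sizes))),
             size = sizes)
}

test_that("log-binned distributions are exact for degenerate bins", {
  d <- avalancheDistributions(fakeCatalog(c(1, 1, 2)))
  expect_equal(d$size$p[d$size$center == 1], 2 / 3)
  expect_equal(d$size$p[d$size$center == 2], 1 / 3)
  # normalization over the support (probability x integers per bin)
  full <- avalancheDistributions(fakeCatalog(drawDiscretePowerLaw(5000, 1.5, 200, 1)))
  expect_equal(sum(full$size$p * (full$size$upper - full$size$lower + 1)), 1)
  expect_error(avalancheDistributions(fakeCatalog(numeric(0))), "empty")
})

test_that("power-law exponent is recovered from generated sizes", {
  s <- drawDiscretePowerLaw(1e5, 1.5, 1000, 2)
  fit <- spikeMaxEnt:::fitDiscretePowerLaw(s)
  expect_equal(fit$exponent, 1.5, tolerance = 0.1)
  # and the power law beats the exponential on its own data
  w <- spikeMaxEnt:::exponentialWeight(s)
  expect_lt(w$weight, 0.5)
})

test_that("exponential sizes reject the power law and classify subcritical", {
  withr::local_seed(3)
  s <- 1 + rgeom(2e4, 1 / 4)           # mean ~ 4, exponential tail
  w <- spikeMaxEnt:::exponentialWeight(s)
  expect_gt(w$weight, 0.5)
  cls <- classifyState(avalancheDistributions(fakeCatalog(s)), nNeurons = 100)
  expect_equal(cls$label, "subcritical")
})

test_that("truncated power law with a system-size cutoff classifies critical", {
  s <- drawDiscretePowerLaw(2e4, 1.5, 300, 4)   # cutoff ~ 3N for N = 100
  cls <- classifyState(avalancheDistributions(fakeCatalog(s)), nNeurons = 100)
  expect_equal(cls$label, "critical")
})

test_that("a probability bump near the system size classifies supercritical", {
  withr::local_seed(5)
  s <- c(drawDiscretePowerLaw(18000, 1.5, 60, 6),
         round(rnorm(2000, 120, 15)))    # excess mass at S ~ N
  s <- s[s >= 1]
  cls <- classifyState(avalancheDistributions(fakeCatalog(s)), nNeurons = 100)
  expect_equal(cls$label, "supercritical")
})

test_that("classification is stable across halves of a large catalog", {
  s <- drawDiscretePowerLaw(4e4, 1.5, 300, 7)
  half1 <- classifyState(avalancheDistributions(fakeCatalog(s[1:2e4])), 100)
  half2 <- classifyState(avalancheDistributions(fakeCatalog(s[2e4 + 1:2e4])), 100)
  expect_equal(half1$label, half2$label)
})

test_that("too few avalanches is an error, not an unstable label", {
  expect_error(classifyState(avalancheDistributions(fakeCatalog(rep(1, 50))), 100),
               "at least")
})
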