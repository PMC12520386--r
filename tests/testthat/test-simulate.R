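test_that("eventProfile evaluates the exponential decay law", {
  expect_equal(eventProfile(0, A = 2, tauFrames = 5, B = 1), 3)
  expect_equal(eventProfile(5, A = 2, tauFrames = 5, B = 1), 2 / exp(1) + 1)
  expect_equal(eventProfile(1e6, A = 2, tauFrames = 5, B = 1), 1,
               tolerance = 1e-12)
  expect_error(eventProfile(1, A = 2, tauFrames = 0, B = 1), "positive")
})

test_that("renderEvent uses the unit-peak convention and spreads as
           sigma^2 = sigma0^2 + 2 D dt", {
  fr <- matrix(0, 41, 41)
  out <- renderEvent(fr, 20, 20, 0, A = 7, tauFrames = 3, sigma0 = 1)
  expect_equal(out[21, 21], 7)

  # width after spreading: fit the rendered profile's second moment
  out2 <- renderEvent(fr, 20, 20, 2, A = 1, tauFrames = 1e9,
                      sigma0 = 1, D = 1.5)
  xs <- 0:40
  prof <- out2[21, ]
  s2 <- sum(prof * (xs - 20)^2) / sum(prof)
  expect_equal(sqrt(s2), sqrt(1 + 2 * 1.5 * 2), tolerance = 1e-3)

  # additivity over events
  a <- renderEvent(fr, 10, 10, 0, A = 3, tauFrames = 2)
  b <- renderEvent(fr, 30, 28, 1, A = 5, tauFrames = 4)
  both <- renderEvent(renderEvent(fr, 10, 10, 0, A = 3, tauFrames = 2),
                      30, 28, 1, A = 5, tauFrames = 4)
  expect_equal(both, a + b - fr)
})

test_that("noise-free, event-free movies are static; same seed is
           bit-identical", {
  p <- simulationParams(width = 48, height = 40, nFrames = 6, nEvents = 0,
                        nDocked = 3, gain = 0, readNoiseSd = 0, seed = 5)
  sim <- simulateMovie(p)
  arr <- movieData(sim$movie)
  expect_equal(max(apply(arr, c(2, 3), var)), 0)

  p2 <- simulationParams(width = 48, height = 40, nFrames = 40,
                         nEvents = 4, nDocked = 3, seed = 99)
  s1 <- simulateMovie(p2); s2 <- simulateMovie(p2)
  expect_identical(movieData(s1$movie), movieData(s2$movie))
  expect_identical(events(s1$truth$events), events(s2$truth$events))
})

test_that("ground-truth events lie inside the cell, start at frame >= 5,
           and respect the minimum separation", {
  p <- simulationParams(width = 96, height = 96, nFrames = 120,
                        nEvents = 15, seed = 17)
  sim <- simulateMovie(p)
  ev <- events(sim$truth$events)
  expect_equal(nrow(ev), 15L)
  m <- maskData(sim$truth$cellMask)
  expect_true(all(m[cbind(ev$y + 1, ev$x + 1)]))
  expect_true(all(ev$t >= 5))
  for (i in seq_len(nrow(ev) - 1)) for (j in (i + 1):nrow(ev)) {
    dxy <- sqrt((ev$x[i] - ev$x[j])^2 + (ev$y[i] - ev$y[j])^2)
    dtt <- abs(ev$t[i] - ev$t[j])
    expect_true(dxy >= 10 || dtt >= 20)
  }
})

test_that("impossible event packing raises an informative error", {
  p <- simulationParams(width = 32, height = 32, nFrames = 30,
                        nEvents = 200, seed = 1)
  expect_error(simulateMovie(p), "separation")
})

test_that("with default parameters the exocytosis class stays under 0.1%
           of voxels", {
  p <- simulationParams(seed = 23)   # 128 x 128 x 300, 40 events
  sim <- simulateMovie(p)
  lm <- buildLabelMap(sim$truth$events, NULL, dim(sim$movie))
  expect_lt(classFractions(lm)[["1"]], 0.001)
  expect_gt(classFractions(lm)[["1"]], 0)
})

test_that("averaging noisy realizations converges to the noiseless scene", {
  base <- simulationParams(width = 24, height = 24, nFrames = 2,
                           nEvents = 0, nDocked = 2, gain = 0,
                           readNoiseSd = 0, seed = 8)
  clean <- movieData(simulateMovie(base)$movie)
  nRep <- 200L
  acc <- array(0, dim = dim(clean))
  noisy <- base; noisy$gain <- 1; noisy$readNoiseSd <- 2
  for (r in seq_len(nRep)) {
    noisy$noiseSeed <- 8000 + r   # same scene layout, fresh noise
    acc <- acc + movieData(simulateMovie(noisy)$movie)
  }
  avg <- acc / nRep
  # per-voxel SE of the mean: sqrt(var_poisson + var_read) / sqrt(n)
  se <- sqrt(clean + 4) / sqrt(nRep)
  frac <- mean(abs(avg - clean) <= 3 * se)
  expect_gt(frac, 0.98)
})

test_that("analyticEventSbr predicts the simulator's noiseless F/F0", {
  mv <- flatEventMovie(A = 600, B0 = 120, sigma0 = 1.5)
  sb <- eventSbr(mv, EventList(x = 24, y = 24, t = 8))
  expect_equal(sb$sbr, analyticEventSbr(600, 120, 1.5), tolerance = 1e-9)
})
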