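test_that("event F/F0 matches the closed-form window average on noiseless
           renders", {
  mv <- TirfMovie(array(50, dim = c(12, 32, 32)))
  sb <- eventSbr(mv, EventList(x = 16, y = 16, t = 8))
  expect_equal(sb$sbr, 1)
  expect_equal(sb$flag, "ok")

  mv2 <- flatEventMovie(A = 500, B0 = 100, sigma0 = 1.5, tau = 4)
  sb2 <- eventSbr(mv2, EventList(x = 24, y = 24, t = 8))
  expect_equal(sb2$sbr, analyticEventSbr(500, 100, 1.5), tolerance = 1e-9)

  # insufficient baseline
  sb3 <- eventSbr(mv2, EventList(x = 24, y = 24, t = 3))
  expect_true(is.na(sb3$sbr))
  expect_equal(sb3$flag, "no_baseline")

  # clipped window flagged but computed
  sb4 <- eventSbr(mv, EventList(x = 1, y = 1, t = 8))
  expect_equal(sb4$flag, "clipped")
  expect_equal(sb4$sbr, 1)

  # F/F0 is invariant under positive rescaling of the movie
  mv3 <- TirfMovie(movieData(mv2) * 3.7)
  expect_equal(eventSbr(mv3, EventList(x = 24, y = 24, t = 8))$sbr, sb2$sbr)
})

test_that("cell SBR is the in/out intensity ratio", {
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  arr <- array(100, dim = c(4, 20, 20))
  for (tt in 1:4) arr[tt, , ][mask] <- 200
  mv <- TirfMovie(arr)
  cm <- CellMask(mask)
  expect_equal(cellSbr(mv, cm), 2)
  expect_equal(cellSbr(mv, CellMask(!mask)), 0.5)
  expect_error(cellSbr(mv, CellMask(matrix(TRUE, 20, 20))), "mask")

  # noisy synthetic cell: ratio approaches the generator's plateau ratio
  p <- simulationParams(width = 64, height = 64, nFrames = 20, nEvents = 0,
                        nDocked = 0, backgroundIn = 200, backgroundOut = 50,
                        seed = 67)
  sim <- simulateMovie(p)
  r <- cellSbr(sim$movie, sim$truth$cellMask)
  # the generator softens the cell edge, which raises the near-boundary
  # outside mean, so the plateau ratio is recovered only approximately
  expect_equal(r, 4, tolerance = 0.2)
})

test_that("the decay lifetime fit recovers the generator constant", {
  # noiseless: with no lateral spreading the window trace is exactly
  # A' exp(-t/tau) + B'
  p <- simulationParams(width = 64, height = 64, nFrames = 80, nEvents = 3,
                        nDocked = 0, gain = 0, readNoiseSd = 0,
                        diffusionPx2PerFrame = 0,
                        decayTauRange = c(1.2, 1.2), seed = 71)
  sim <- simulateMovie(p)
  fit <- decayLifetime(sim$movie, sim$truth$events)
  tauF <- 1.2 / 0.3
  expect_lt(abs(fit$tHalf - tauF) / tauF, 0.01)
  expect_false(fit$degenerate)
  expect_equal(fit$tHalfSeconds, fit$tHalf * 0.3)

  # constant movie: no decaying component
  flat <- TirfMovie(array(80, dim = c(30, 32, 32)))
  fitF <- decayLifetime(flat, EventList(x = 16, y = 16, t = 5))
  expect_true(fitF$degenerate)

  # trailing-window rule: an event too close to the end is excluded
  expect_error(decayLifetime(flat, EventList(x = 16, y = 16, t = 25)),
               "no usable events")
})

test_that("lifetime recovery holds within 5% under noise over 50 events", {
  # 50 events whose 7x7 windows carry the exact exponential plus
  # Gaussian noise of sd 0.02 (trace SNR >= 10)
  set.seed(73)
  A <- 0.8; B <- 0.2; tauF <- 4
  dims <- c(30L, 80L, 80L)
  arr <- array(1, dim = dims)
  xs <- rep(seq(4, 76, by = 8), each = 10)[1:50]
  ys <- rep(seq(4, 76, by = 8), times = 10)[1:50]
  for (i in 1:50) {
    for (k in 0:15) {
      val <- A * exp(-k / tauF) + B + rnorm(1, 0, 0.02)
      arr[10 + k + 1, ys[i] + (-3:3) + 1, xs[i] + (-3:3) + 1] <- max(val, 0)
    }
  }
  mv <- TirfMovie(arr)
  fit <- decayLifetime(mv, EventList(x = xs, y = ys, t = rep(10, 50)))
  expect_lt(abs(fit$tHalf - tauF) / tauF, 0.05)
})

test_that("the Otsu cell mask recovers a bright ellipse and is affine
           invariant", {
  set.seed(79)
  p <- simulationParams(width = 96, height = 80, nFrames = 2, nEvents = 0,
                        nDocked = 0, backgroundIn = 200, backgroundOut = 50,
                        readNoiseSd = 3, seed = 83)
  sim <- simulateMovie(p)
  cm <- makeCellMask(sim$movie)
  truthM <- maskData(sim$truth$cellMask)
  gotM <- maskData(cm)
  iou <- sum(gotM & truthM) / sum(gotM | truthM)
  expect_gt(iou, 0.95)

  scaled <- TirfMovie(movieData(sim$movie) * 2 + 30)
  expect_identical(maskData(makeCellMask(scaled)), gotM)

  expect_warning(cmF <- makeCellMask(TirfMovie(array(5, c(2, 8, 8)))),
                 "constant")
  expect_true(all(maskData(cmF)))
})
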