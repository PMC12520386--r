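test_that("LoG response is zero on constants, linear, and scale-selective", {
  expect_equal(max(abs(logResponse(matrix(5, 32, 32), 2))), 0)

  # linearity of convolution
  set.seed(3)
  i1 <- matrix(runif(32 * 32), 32, 32)
  i2 <- matrix(runif(32 * 32), 32, 32)
  expect_equal(logResponse(2 * i1 + 3 * i2, 1.5),
               2 * logResponse(i1, 1.5) + 3 * logResponse(i2, 1.5),
               tolerance = 1e-10)

  # a Gaussian blob of width s peaks near scale s
  blob <- function(s) {
    d <- seq(-24, 24)
    g <- exp(-d^2 / (2 * s^2))
    outer(g, g)
  }
  expect_equal(selectScale(blob(2), c(1, 2, 4)), 2)

  # brighter (larger-amplitude) blob wins the selection
  img <- blob(2)
  img[10:20, 30:40] <- img[10:20, 30:40] + 0.2 * blob(1)[20:30, 20:30]
  expect_equal(selectScale(img, c(1, 2, 4)), 2)

  expect_warning(s <- selectScale(matrix(1, 16, 16), c(2, 1, 4)),
                 "degenerate")
  expect_equal(s, 1)
  expect_error(selectScale(matrix(1, 4, 4), numeric(0)), "empty")
})

test_that("local Gaussian-window statistics behave on reference fields", {
  # constant response: mean = c, sd floored at ~0
  st <- localStats(matrix(3.5, 40, 40), windowSigma = 5)
  expect_equal(max(abs(st$mean - 3.5)), 0, tolerance = 1e-10)
  expect_lt(max(st$sd), 1e-6)

  # iid standard normal: local sd ~ 1 within 10% almost everywhere
  set.seed(11)
  R <- matrix(rnorm(256 * 256), 256, 256)
  st <- localStats(R, windowSigma = 21)
  expect_gt(mean(abs(st$sd - 1) < 0.1), 0.95)

  # linear ramp: interior mean reproduces the ramp (window symmetry)
  ramp <- matrix(rep(1:64, each = 64), 64, 64)
  st <- localStats(ramp, windowSigma = 4)
  interior <- st$mean[20:44, 20:44]
  expect_equal(interior, ramp[20:44, 20:44], tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("the PFA threshold uses the standard normal quantile", {
  mu <- matrix(1, 4, 4); s <- matrix(2, 4, 4)
  expect_equal(pfaThreshold(mu, s, 0.5), mu)            # z = 0
  expect_equal(pfaThreshold(mu, s, 0.001),
               mu + qnorm(0.999) * s)                   # z ~ 3.0902
  expect_equal(qnorm(1 - 0.001), 3.0902, tolerance = 1e-4)
  expect_equal(pfaThreshold(mu, s, 1 - pnorm(1)), mu + 1 * s,
               tolerance = 1e-12)
  expect_error(pfaThreshold(mu, s, 0), "pfa")
  expect_error(pfaThreshold(mu, s, 0.7), "pfa")
})

test_that("detection is calibrated on pure noise and empty on constants", {
  d <- detectSpots(matrix(7, 64, 64), atlasParams())
  expect_equal(length(d$spots), 0L)
  expect_false(any(d$mask))

  set.seed(13)
  img <- matrix(rnorm(512 * 512), 512, 512)
  p <- atlasParams()
  sigma <- suppressWarnings(selectScale(img, p$scales))
  R <- logResponse(img, sigma)
  st <- localStats(R, p$windowSigmaPx)
  exceed <- mean(R > pfaThreshold(st$mean, st$sd, 0.001))
  expect_gt(exceed, 0.0005)
  expect_lt(exceed, 0.002)

  # monotonicity: lowering pfa never adds exceedances
  exceed2 <- mean(R > pfaThreshold(st$mean, st$sd, 0.0002))
  expect_lte(exceed2, exceed)
})

test_that("raising the component-size floor never adds components and the
           mask ignores global offsets", {
  set.seed(19)
  img <- matrix(rnorm(128 * 128), 128, 128)
  for (i in 1:4)
    img <- renderEvent(img, runif(1, 30, 100), runif(1, 30, 100), 0,
                       A = 10, tauFrames = 1, sigma0 = 2, D = 0)
  d3 <- detectSpots(img, atlasParams(minComponentPx = 3))
  d8 <- detectSpots(img, atlasParams(minComponentPx = 8))
  expect_lte(length(d8$spots), length(d3$spots))

  dOff <- detectSpots(img + 100, atlasParams(minComponentPx = 3))
  expect_identical(dOff$mask, d3$mask)
})

test_that("a bright docked spot is found within 1 px and per-frame mode
           stacks masks", {
  set.seed(23)
  img <- matrix(rnorm(128 * 128), 128, 128)
  img <- renderEvent(img, 61, 44, 0, A = 10, tauFrames = 1,
                     sigma0 = 2, D = 0)
  d <- detectSpots(img, atlasParams())
  expect_equal(length(d$spots), 1L)
  ev <- events(d$spots)
  expect_lt(sqrt((ev$x - 61)^2 + (ev$y - 44)^2), 1)

  # 3-frame movie: per-frame mode returns a 3D mask with the spot on
  # every frame
  arr <- array(0, dim = c(3, 128, 128))
  for (tt in 1:3) arr[tt, , ] <- img - min(img)
  mv <- TirfMovie(arr)
  dm <- detectSpots(mv, atlasParams(mode = "per_frame"))
  expect_equal(dim(dm$mask), dim(arr))
  expect_equal(length(dm$spots), 3L)
  expect_setequal(events(dm$spots)$t, 0:2)
})
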