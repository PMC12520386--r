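test_that("quantile normalization pins the 1st and 99th percentiles", {
  arr <- array(rep(0:100, length.out = 101 * 4), dim = c(4, 101, 1))
  nz <- quantileNormalize(arr)
  # with 0..100 uniformly present, p1 = 1 and p99 = 99
  expect_equal(min(abs(nz)), 0, tolerance = 1e-9)
  expect_equal(nz[arr == 1][1], 0)
  expect_equal(nz[arr == 99][1], 1)

  expect_warning(z <- quantileNormalize(array(7, dim = c(2, 3, 3))),
                 "degenerate")
  expect_true(all(z == 0))

  set.seed(41)
  a <- array(runif(500), dim = c(5, 10, 10))
  expect_equal(quantileNormalize(3 * a + 11), quantileNormalize(a),
               tolerance = 1e-12)
})

test_that("the patch-size curriculum is left-closed piecewise constant", {
  rounds <- trainConfig()$rounds   # 8/16/32/48 x 10k
  expect_equal(curriculumPatchSize(0, rounds), 8L)
  expect_equal(curriculumPatchSize(9999, rounds), 8L)
  expect_equal(curriculumPatchSize(10000, rounds), 16L)
  expect_equal(curriculumPatchSize(29999, rounds), 32L)
  expect_equal(curriculumPatchSize(35000, rounds), 48L)
  expect_equal(curriculumPatchSize(1e6, rounds), 48L)
})

test_that("train config validates the curriculum invariants", {
  expect_error(trainConfig(rounds = data.frame(patchSize = 7L, maxShift = 1L,
                                               batchSize = 1L,
                                               nIterations = 1L)), "even")
  expect_error(trainConfig(rounds = data.frame(patchSize = c(16L, 8L),
                                               maxShift = c(2L, 2L),
                                               batchSize = c(1L, 1L),
                                               nIterations = c(1L, 1L))),
               "nondecreasing")
  expect_error(trainConfig(rounds = data.frame(patchSize = 8L, maxShift = 4L,
                                               batchSize = 1L,
                                               nIterations = 1L)),
               "maxShift")
  expect_error(trainConfig(learningRate = 0), "learningRate")
})

test_that("patch sampling centres, clamps, and reproduces the tube
           fraction", {
  arr <- array(seq_len(24 * 24 * 24) * 1.0, dim = c(24, 24, 24))
  lab <- array(0L, dim = c(24, 24, 24))
  sp <- samplePatch(arr, lab, c(12, 12, 12), patchSize = 8, maxShift = 0)
  # centring convention: annotation voxel lands at index L/2 (0-based) in
  # each axis, i.e. R index L/2 + 1
  expect_equal(sp$intensity[5, 5, 5], arr[13, 13, 13])
  expect_equal(sp$origin, c(8, 8, 8))

  # clamping near the border: window stays inside
  sp2 <- samplePatch(arr, lab, c(2, 2, 2), patchSize = 16, maxShift = 0)
  expect_equal(sp2$origin, c(0, 0, 0))
  expect_equal(dim(sp2$intensity), c(16L, 16L, 16L))

  expect_error(samplePatch(arr, lab, c(5, 5, 5), patchSize = 32), "larger")

  # label fraction of an annotation-centred 8-window
  lm <- buildLabelMap(EventList(x = 12, y = 12, t = 12), NULL, c(24, 24, 24))
  sp3 <- samplePatch(arr, labels3d(lm), c(12, 12, 12), 8, 0)
  expect_equal(mean(sp3$labels == 1L), 65 / 512)
})

test_that("(x, y) dihedral augmentations preserve class counts and
           invert cleanly", {
  set.seed(43)
  int <- array(runif(6 * 8 * 8), dim = c(6, 8, 8))
  lab <- array(sample(0:2, 6 * 8 * 8, TRUE), dim = c(6, 8, 8))
  a0 <- augmentXY(int, lab, transform = 0)
  expect_identical(a0$intensity, int)

  for (tr in 0:7) {
    a <- augmentXY(int, lab, transform = tr)
    expect_equal(tabulate(a$labels + 1L, 3), tabulate(lab + 1L, 3))
    expect_equal(dim(a$intensity), dim(int))
    # t-axis untouched: per-frame sums invariant
    expect_equal(apply(a$intensity, 1, sum), apply(int, 1, sum))
  }

  # mirror applied twice is the identity
  a4 <- augmentXY(int, lab, transform = 4)
  a44 <- augmentXY(a4$intensity, a4$labels, transform = 4)
  expect_identical(a44$intensity, int)

  expect_error(augmentXY(array(0, dim = c(2, 4, 6)), array(0L, c(2, 4, 6))),
               "square")
})

test_that("Tversky loss hits its anchor values", {
  oh <- function(v, C = 2) {
    m <- matrix(0, C, length(v)); m[cbind(v + 1, seq_along(v))] <- 1; m
  }
  tgt <- oh(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_lt(tverskyLoss(tgt, tgt)$loss, 1e-5)
  flip <- tgt[2:1, ]
  expect_gt(tverskyLoss(flip, tgt)$loss, 1 - 1e-4)

  # prediction covers half the positive class, no false positives: the
  # positive-class index is TI = 2 / (2 + 0.5 * 0 + 0.5 * 2) = 2/3; the
  # background class scores 4 / (4 + 0.5 * 2 + 0) = 0.8, and the loss is
  # one minus the class mean
  pred <- oh(c(1, 1, 0, 0, 0, 0, 0, 0))
  lv <- tverskyLoss(pred, tgt, alpha = 0.5, beta = 0.5)
  expect_equal(lv$ti[[2]], 2 / 3, tolerance = 1e-5)
  expect_equal(lv$loss, 1 - (0.8 + 2 / 3) / 2, tolerance = 1e-5)
  expect_error(tverskyLoss(pred, tgt, alpha = -1), "non-negative")
})

test_that("analytic gradients match numerical differentiation through the
           whole network", {
  set.seed(47)
  m <- initSegmenter(depth = 2, baseFilters = 2)
  L <- 8L
  x <- matrix(runif(L^3), nrow = 1)
  target <- exopuff:::.labelsToOneHot(
    array(sample(0:2, L^3, TRUE), dim = c(L, L, L)))
  lossOf <- function(mm)
    tverskyLoss(exopuff:::.segForward(mm, x, dims = c(L, L, L),
                                      wantCache = FALSE)$probs,
                target)$loss
  fw <- exopuff:::.segForward(m, x, dims = c(L, L, L))
  lv <- tverskyLoss(fw$probs, target, gradient = TRUE)
  g <- exopuff:::.segBackward(m, fw$cache,
                              exopuff:::.softmaxBackward(fw$probs, lv$dProbs))
  for (nm in names(m@weights)) {
    W <- m@weights[[nm]]$W
    for (i in sample(length(W), 3)) {
      m2 <- m; m2@weights[[nm]]$W[i] <- W[i] + 1e-6
      m3 <- m; m3@weights[[nm]]$W[i] <- W[i] - 1e-6
      num <- (lossOf(m2) - lossOf(m3)) / 2e-6
      expect_equal(g[[nm]]$W[i], num, tolerance = 1e-3)
    }
  }
})

test_that("the forward pass preserves shape, handles a single frame, and
           pooling never touches t", {
  set.seed(53)
  m <- initSegmenter(depth = 2, baseFilters = 4)
  for (dims in list(c(8L, 8L, 8L), c(16L, 8L, 5L), c(4L, 12L, 1L))) {
    x <- matrix(runif(prod(dims)), nrow = 1)
    fw <- exopuff:::.segForward(m, x, dims = dims, wantCache = FALSE)
    expect_equal(dim(fw$probs), c(3L, prod(dims)))
    expect_equal(colSums(fw$probs), rep(1, prod(dims)), tolerance = 1e-9)
  }
  expect_error(exopuff:::.segForward(m, matrix(runif(6^3), 1),
                                     dims = c(6L, 6L, 6L)), "divisible")
})

test_that("training is deterministic under a fixed seed and the loss falls
           on a separable toy task", {
  # noiseless bright tubes on a dim textured background (texture keeps
  # the intensity quantiles non-degenerate)
  set.seed(76)
  dims <- c(40L, 32L, 32L)
  arr <- array(runif(prod(dims)), dim = dims)
  ev <- EventList(x = c(10, 22, 16), y = c(10, 22, 8), t = c(8, 20, 30))
  lm <- buildLabelMap(ev, NULL, dims)
  arr[labels3d(lm) == 1L] <- 100
  ds <- list(list(movie = TirfMovie(arr), labels = lm,
                  annotations = ev))
  cfg <- trainConfig(rounds = data.frame(patchSize = 8L, maxShift = 1L,
                                         batchSize = 2L, nIterations = 60L),
                     baseFilters = 4, depth = 1, seed = 77)
  mA <- trainSegmenter(ds, cfg)
  mB <- trainSegmenter(ds, cfg)
  expect_equal(mA@history$loss[1], mB@history$loss[1])
  expect_identical(mA@weights$out$W, mB@weights$out$W)
  h <- mA@history$loss
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))

  expect_error(trainSegmenter(list(list(movie = TirfMovie(arr + 1),
                                        labels = lm,
                                        annotations = EventList())), cfg),
               "no exocytosis annotation")
})
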