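tol <- matchTolerances()

test_that("matching applies the printed spatial and temporal tolerances", {
  g <- data.frame(x = 10, y = 10, t = 100, class = "exocytosis",
                  score = NA_real_)
  ok <- function(p) matchEvents(EventList(p), EventList(g), tol)$nTp == 1L
  expect_true(ok(data.frame(x = 10, y = 10, t = 100)))
  expect_true(ok(data.frame(x = 12, y = 10, t = 103)))   # dx=2, dt=3
  expect_true(ok(data.frame(x = 14.5, y = 10, t = 100))) # dx=4.5 boundary
  expect_true(ok(data.frame(x = 10, y = 10, t = 98)))    # dt=-2 boundary
  expect_true(ok(data.frame(x = 10, y = 10, t = 105)))   # dt=+5 boundary
  expect_false(ok(data.frame(x = 14, y = 13, t = 100)))  # dx=5
  expect_false(ok(data.frame(x = 10, y = 10, t = 97)))   # dt=-3
  expect_false(ok(data.frame(x = 10, y = 10, t = 106)))  # dt=+6
})

test_that("each truth is used at most once so FN = N - TP stays
           non-negative", {
  g <- EventList(x = c(10, 50), y = c(10, 50), t = c(100, 100))
  p <- EventList(x = c(10, 11, 12), y = c(10, 10, 10), t = c(100, 100, 100))
  r <- matchEvents(p, g, tol)
  expect_equal(r$nTp, 1L)
  expect_equal(r$nFp, 2L)
  expect_equal(r$nFn, 1L)
})

test_that("greedy matching agrees with the exhaustive optimal-assignment
           oracle on random instances", {
  set.seed(29)
  dims <- c(40L, 30L, 30L)
  for (trial in 1:300) {
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    p <- randomEvents(np, dims, continuous = TRUE)
    g <- randomEvents(ng, dims)
    r <- matchEvents(EventList(p), EventList(g), tol)
    o <- bruteForceMatch(p, g)
    expect_equal(r$nTp, o$tp)
    expect_gte(r$nFn, 0)
  }
})

test_that("scores reproduce the printed formulas and flag the
           all-zero case", {
  s <- scores(2, 1, 1)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  expect_false(s$undefined)

  s0 <- scores(0, 5, 3)
  expect_equal(c(s0$precision, s0$recall, s0$f1), c(0, 0, 0))
  expect_true(scores(0, 0, 0)$undefined)
  expect_error(scores(-1, 0, 0), "non-negative")

  # identities on enumerated triples
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) {
    if (tp + fp + fn == 0) next
    s <- scores(tp, fp, fn)
    expect_equal(s$f1, 2 * tp / (2 * tp + fp + fn))
    expect_gte(s$precision, 0); expect_lte(s$precision, 1)
    expect_gte(s$recall, 0); expect_lte(s$recall, 1)
    expect_lte(s$f1, min(1, s$precision + s$recall) + 1e-12)
  }
})

test_that("localization errors pass through the matched pairs", {
  g <- EventList(x = c(10, 40), y = c(10, 40), t = c(100, 200))
  p <- EventList(x = c(10, 42), y = c(10, 40), t = c(102, 200)) # dt=2; dx=2
  r <- matchEvents(p, g, tol)
  e <- localizationErrors(r)
  expect_equal(length(e$dx), r$nTp)
  expect_setequal(round(e$dx, 6), c(0, 2))
  expect_setequal(e$dt, c(2, 0))
})

test_that("cross-method overlap uses the symmetric 7-frame window", {
  a <- EventList(x = c(10, 50), y = c(10, 50), t = c(100, 200))
  expect_equal(crossMethodOverlap(a, a),
               c(A = 0, B = 0, AB = 2))
  bNear <- EventList(x = c(10, 50), y = c(10, 50), t = c(107, 208))
  ov <- crossMethodOverlap(a, bNear)
  expect_equal(ov[["AB"]], 1)   # |dt| = 7 shared, |dt| = 8 separate
  far <- EventList(x = c(90, 95), y = c(90, 95), t = c(10, 20))
  expect_equal(crossMethodOverlap(a, far),
               c(A = 2, B = 2, AB = 0))

  # 3 lists: identical triple -> everything in the core intersection
  ov3 <- crossMethodOverlap(a, a, a)
  expect_equal(ov3[["ABC"]], 2)
  expect_equal(sum(ov3), 2)
})

test_that("exocytosis rate converts counts to events per minute", {
  expect_equal(exocytosisRate(30, 1001, 0.3), 30 / (1001 * 0.3 / 60))
  expect_equal(exocytosisRate(0, 500, 0.3), 0)
  expect_equal(exocytosisRate(60, 1001, 0.3),
               2 * exocytosisRate(30, 1001, 0.3))
  el <- EventList(x = 1, y = 1, t = 1)
  expect_equal(exocytosisRate(el, 200, 0.3), 1 / (200 * 0.3 / 60))
})

test_that("paired Cohen's d matches hand computation and its invariances", {
  r <- cohensDPaired(c(0, 0, 0, 0), c(1, 2, 3, 2))
  expect_equal(r$meanDiff, 2)
  expect_equal(r$sdDiff, sqrt(2 / 3))
  expect_equal(r$d, 2 / sqrt(2 / 3))

  expect_true(cohensDPaired(c(1, 2, 3), c(2, 3, 4))$undefined)
  expect_lt(cohensDPaired(c(5, 6, 9), c(1, 2, 4))$d, 0)

  set.seed(31)
  b <- rnorm(10); a <- rnorm(10, 1)
  expect_equal(cohensDPaired(b, a)$d, cohensDPaired(b + 7, a + 7)$d)
  expect_equal(cohensDPaired(b, a)$d, cohensDPaired(3 * b, 3 * a)$d)
  expect_error(cohensDPaired(1:3, 1:4), "length")
})
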