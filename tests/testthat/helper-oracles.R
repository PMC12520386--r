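# Brute-force oracles and shared fixtures, independent of the package's
# own implementations.

# exhaustive tube membership test over every voxel of the grid
bruteForceTube <- function(event, gridDims,
                           offsets = c(0L, 1L, 2L), radii = c(4, 2, 1)) {
  x0 <- round(event[1L]); y0 <- round(event[2L]); t0 <- round(event[3L])
  vox <- NULL
  for (tt in 0:(gridDims[1L] - 1L)) for (yy in 0:(gridDims[2L] - 1L))
    for (xx in 0:(gridDims[3L] - 1L)) {
      k <- match(tt - t0, offsets)
      if (is.na(k)) next
      if ((xx - x0)^2 + (yy - y0)^2 <= radii[k]^2)
        vox <- rbind(vox, c(t = tt, y = yy, x = xx))
    }
  if (is.null(vox)) matrix(integer(0), 0, 3) else vox
}

# exhaustive optimal one-to-one assignment: maximise TP, then minimise the
# total spatial distance, over all injections of predictions into truths
bruteForceMatch <- function(pred, truth, dxMax = 4.5, dtMin = -2,
                            dtMax = 5) {
  np <- nrow(pred); ng <- nrow(truth)
  dx <- sqrt(outer(pred$x, truth$x, "-")^2 + outer(pred$y, truth$y, "-")^2)
  dt <- outer(pred$t, truth$t, "-")
  ok <- dx <= dxMax & dt >= dtMin & dt <= dtMax
  best <- list(tp = -1L, cost = Inf)
  assign <- integer(np)        # 0 = unmatched
  recurse <- function(i, used, tp, cost) {
    if (i > np) {
      if (tp > best$tp || (tp == best$tp && cost < best$cost))
        best <<- list(tp = tp, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, tp, cost)                 # leave i unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && ok[i, g]) {
        used[g] <- TRUE
        recurse(i + 1L, used, tp + 1L, cost + dx[i, g])
        used[g] <- FALSE
      }
    }
  }
  recurse(1L, logical(ng), 0L, 0)
  best
}

# random event table bound to a geometry
randomEvents <- function(n, dims, continuous = FALSE) {
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), t = numeric(0),
                      class = character(0), score = numeric(0)))
  r <- function(k) if (continuous) runif(n, 0, k - 1) else
    sample(0:(k - 1), n, replace = TRUE)
  data.frame(x = r(dims[3L]), y = r(dims[2L]), t = r(dims[1L]),
             class = "exocytosis", score = NA_real_)
}

# small noiseless movie with one rendered event on a flat background
flatEventMovie <- function(A = 500, B0 = 100, sigma0 = 1.5, tau = 4,
                           D = 0, dims = c(24L, 48L, 48L),
                           x0 = 24, y0 = 24, t0 = 8L) {
  arr <- array(B0, dim = dims)
  for (k in 0:(dims[1L] - 1L - t0))
    arr[t0 + k + 1L, , ] <- renderEvent(arr[t0 + k + 1L, , ], x0, y0, k,
                                        A, tau, sigma0, D)
  TirfMovie(arr)
}
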