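# Internal network plumbing for the PuffSegmenter: parameter
# initialisation, forward/backward passes and the ADAM update. Feature maps
# are (C x N) matrices over voxels n = ix + X*(iy + Y*it); max-pooling and
# upsampling act on (x, y) only, so the temporal axis keeps full
# resolution.

#' Initialise an untrained segmentation network
#'
#' Builds the anisotropic 3-class encoder--decoder: `depth` levels of two
#' 3x3x3 convolutions + ReLU followed by (x, y)-only 2x2 max-pooling, a
#' two-convolution bottleneck, and a mirrored decoder with nearest-neighbour
#' (x, y) upsampling and skip connections; a final 1x1x1 convolution maps to
#' per-voxel class scores. Weights are He-initialised from the session RNG.
#'
#' @param depth number of pooling stages (input x, y dims must be divisible
#'   by `2^depth`).
#' @param baseFilters channel width of the first encoder block; doubles per
#'   level.
#' @param nClasses number of output classes.
#' @return an untrained [PuffSegmenter-class].
#' @export
initSegmenter <- function(depth = 2, baseFilters = 8, nClasses = 3) {
  F0 <- as.integer(baseFilters)
  mk <- function(cin, cout) {
    fanin <- cin * 27
    list(W = matrix(rnorm(cout * fanin, sd = sqrt(2 / fanin)),
                    nrow = cout, ncol = fanin),
         b = numeric(cout))
  }
  w <- list()
  cin <- 1L
  for (l in seq_len(depth) - 1L) {
    cf <- F0 * 2^l
    w[[sprintf("enc%da", l)]] <- mk(cin, cf)
    w[[sprintf("enc%db", l)]] <- mk(cf, cf)
    cin <- cf
  }
  cb <- F0 * 2^depth
  w[["botta"]] <- mk(cin, cb)
  w[["bottb"]] <- mk(cb, cb)
  for (l in rev(seq_len(depth) - 1L)) {
    cf <- F0 * 2^l
    up <- F0 * 2^(l + 1)
    w[[sprintf("dec%da", l)]] <- mk(up + cf, cf)
    w[[sprintf("dec%db", l)]] <- mk(cf, cf)
  }
  fin <- F0
  w[["out"]] <- list(W = matrix(rnorm(nClasses * fin, sd = sqrt(2 / fin)),
                                nrow = nClasses, ncol = fin),
                     b = numeric(nClasses))
  new("PuffSegmenter", weights = w, depth = depth, baseFilters = F0,
      nClasses = nClasses)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.softmaxCols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# forward pass; x is a (1 x N) matrix over dims = c(X, Y, T)
# returns list(probs, cache) -- cache holds everything backward needs
.segForward <- function(model, x, dims, wantCache = TRUE) {
  w <- model@weights
  depth <- model@depth
  X <- dims[1L]; Y <- dims[2L]; T <- dims[3L]
  if (X %% 2^depth != 0 || Y %% 2^depth != 0)
    stop("x and y dims must be divisible by 2^depth = ", 2^depth)
  cache <- list(dims = dims)
  conv <- function(m, name, XX, YY) {
    pre <- .conv3Fwd(m, XX, YY, T, w[[name]]$W, w[[name]]$b)
    act <- .relu(pre)
    if (wantCache) {
      cache[[paste0(name, ".in")]] <<- m
      cache[[paste0(name, ".mask")]] <<- pre > 0
    }
    act
  }
  cur <- x
  XX <- X; YY <- Y
  skips <- list()
  for (l in seq_len(depth) - 1L) {
    cur <- conv(cur, sprintf("enc%da", l), XX, YY)
    cur <- conv(cur, sprintf("enc%db", l), XX, YY)
    skips[[l + 1L]] <- cur
    p <- .poolXYFwd(cur, XX, YY, T)
    if (wantCache) {
      cache[[sprintf("pool%d.argmax", l)]] <- p$argmax
      cache[[sprintf("pool%d.N", l)]] <- ncol(cur)
    }
    cur <- p$out
    XX <- XX %/% 2L; YY <- YY %/% 2L
  }
  cur <- conv(cur, "botta", XX, YY)
  cur <- conv(cur, "bottb", XX, YY)
  for (l in rev(seq_len(depth) - 1L)) {
    cur <- .upXYFwd(cur, XX, YY, T)
    XX <- XX * 2L; YY <- YY * 2L
    cur <- rbind(cur, skips[[l + 1L]])
    cur <- conv(cur, sprintf("dec%da", l), XX, YY)
    cur <- conv(cur, sprintf("dec%db", l), XX, YY)
  }
  logits <- w$out$W %*% cur + w$out$b
  if (wantCache) cache[["out.in"]] <- cur
  list(probs = .softmaxCols(logits), cache = cache)
}

# backward pass from dLogits (nClasses x N); returns gradient list keyed
# like the weights
.segBackward <- function(model, cache, dLogits) {
  w <- model@weights
  depth <- model@depth
  dims <- cache$dims
  X <- dims[1L]; Y <- dims[2L]; T <- dims[3L]
  g <- list()
  g[["out"]] <- list(W = dLogits %*% t(cache[["out.in"]]),
                     b = rowSums(dLogits))
  cur <- t(w$out$W) %*% dLogits
  convBwd <- function(d, name, XX, YY) {
    d <- d * cache[[paste0(name, ".mask")]]
    bw <- .conv3Bwd(cache[[paste0(name, ".in")]], XX, YY, T,
                    w[[name]]$W, d)
    g[[name]] <<- list(W = bw$dW, b = as.numeric(bw$db))
    bw$dM
  }
  # decoder level l runs at resolution (X, Y) / 2^l; traverse outermost
  # (l = 0) first, the reverse of the forward pass
  dSkips <- list()
  for (l in seq_len(depth) - 1L) {
    XX <- X %/% 2^l; YY <- Y %/% 2^l
    cur <- convBwd(cur, sprintf("dec%db", l), XX, YY)
    cur <- convBwd(cur, sprintf("dec%da", l), XX, YY)
    upC <- model@baseFilters * 2^(l + 1)
    dSkips[[l + 1L]] <- cur[-seq_len(upC), , drop = FALSE]
    cur <- .upXYBwd(cur[seq_len(upC), , drop = FALSE],
                    XX %/% 2L, YY %/% 2L, T)
  }
  XX <- X %/% 2^depth; YY <- Y %/% 2^depth
  cur <- convBwd(cur, "bottb", XX, YY)
  cur <- convBwd(cur, "botta", XX, YY)
  for (l in rev(seq_len(depth) - 1L)) {
    cur <- .poolXYBwd(cur, cache[[sprintf("pool%d.argmax", l)]],
                      cache[[sprintf("pool%d.N", l)]])
    cur <- cur + dSkips[[l + 1L]]
    XX <- X %/% 2^l; YY <- Y %/% 2^l
    cur <- convBwd(cur, sprintf("enc%db", l), XX, YY)
    cur <- convBwd(cur, sprintf("enc%da", l), XX, YY)
  }
  g
}

.zeroLike <- function(w)
  lapply(w, function(p) list(W = p$W * 0, b = p$b * 0))

.adamInit <- function(w)
  list(m = .zeroLike(w), v = .zeroLike(w), t = 0L)

.adamStep <- function(weights, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    for (p in c("W", "b")) {
      gr <- grads[[nm]][[p]]
      state$m[[nm]][[p]] <- beta1 * state$m[[nm]][[p]] + (1 - beta1) * gr
      state$v[[nm]][[p]] <- beta2 * state$v[[nm]][[p]] + (1 - beta2) * gr^2
      mhat <- state$m[[nm]][[p]] / c1
      vhat <- state$v[[nm]][[p]] / c2
      weights[[nm]][[p]] <- weights[[nm]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

.scaleGrads <- function(g, s)
  lapply(g, function(p) list(W = p$W * s, b = p$b * s))
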