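#' Parameters of the synthetic TIRF movie generator
#'
#' The generator reproduces the phenomenology the detector is built for:
#' rare exocytosis "puffs" (a sudden burst of intensity at the fusion
#' site followed by exponential decay and lateral 2D spreading of the
#' reporter), stationary bright docked vesicles, a cell-shaped background
#' plateau, and Poisson + Gaussian camera noise.
#'
#' With the defaults (amplitudes 350--1060 on a cell background of 100,
#' initial spot width 1.5 px) event F/F0 signal-to-background ratios span
#' about 2--4, a realistic range for pHluorin fusion reporters; decay
#' constants of 0.6--1.8 s correspond to 2--6 frames at the default 0.3 s
#' frame interval.
#'
#' @param width,height frame size in pixels.
#' @param nFrames number of frames.
#' @param frameIntervalS seconds per frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param nEvents number of exocytosis events; all are placed inside the
#'   cell, at least 5 frames after the movie start (so baseline photometry
#'   is defined) and with a minimum pairwise spatiotemporal separation.
#' @param amplitudeRange `(A_min, A_max)` added peak intensity of an event.
#' @param decayTauRange `(tau_min, tau_max)` e-folding decay constant in
#'   seconds.
#' @param sigma0Px initial Gaussian spot width (px); default 1.5 px, about
#'   the diffraction-limited spot at 0.16 um/px.
#' @param diffusionPx2PerFrame lateral spreading rate D: the spot variance
#'   grows as `sigma(dt)^2 = sigma0^2 + 2 * D * dt`.
#' @param nDocked number of stationary docked-vesicle spots.
#' @param dockedAmplitudeRange amplitude range of docked spots (constant
#'   through frames).
#' @param backgroundIn,backgroundOut mean intensity inside / outside the
#'   cell footprint.
#' @param gain camera gain of the Poisson stage (`Poisson(scene*gain)/gain`);
#'   `0` disables shot noise.
#' @param readNoiseSd additive Gaussian read-noise SD; `0` disables it.
#' @param bleachTauS photobleaching time constant in seconds (`Inf`
#'   disables bleaching).
#' @param minSepPx,minSepFrames two events closer than `minSepPx` AND
#'   within `minSepFrames` frames of each other are disallowed, so ground
#'   truth matching is unambiguous.
#' @param seed RNG seed used by [simulateMovie()]; mandatory for
#'   reproducible runs.
#' @param noiseSeed optional separate seed applied just before the noise
#'   stage, so one scene layout can be observed under independent noise
#'   realizations.
#' @return a validated list of class `"simulationParams"`.
#' @export
simulationParams <- function(width = 128L, height = 128L, nFrames = 300L,
                             frameIntervalS = 0.3, pixelSizeUm = 0.160,
                             nEvents = 40L,
                             amplitudeRange = c(350, 1060),
                             decayTauRange = c(0.6, 1.8),
                             sigma0Px = 1.5,
                             diffusionPx2PerFrame = 0.5,
                             nDocked = 30L,
                             dockedAmplitudeRange = c(100, 300),
                             backgroundIn = 100, backgroundOut = 20,
                             gain = 1, readNoiseSd = 2,
                             bleachTauS = Inf,
                             minSepPx = 10, minSepFrames = 20,
                             seed = NULL, noiseSeed = NULL) {
  p <- as.list(environment())
  stopifnot(width > 0, height > 0, nFrames >= 1, frameIntervalS > 0,
            nEvents >= 0, nDocked >= 0,
            all(amplitudeRange > 0), all(decayTauRange > 0),
            sigma0Px > 0, diffusionPx2PerFrame >= 0,
            backgroundIn > 0, backgroundOut >= 0,
            gain >= 0, readNoiseSd >= 0, bleachTauS > 0)
  structure(p, class = "simulationParams")
}

#' Intensity time-profile of an exocytosis event
#'
#' The decaying branch of a puff: `A * exp(-dt / tau) + B`, evaluated
#' `dt` frames after the peak.
#'
#' @param dtFrames frames since the peak (`>= 0`).
#' @param A amplitude above baseline at the peak.
#' @param tauFrames e-folding decay constant in frames.
#' @param B baseline offset.
#' @return intensity values.
#' @examples
#' eventProfile(0, A = 2, tauFrames = 5, B = 1)   # 3
#' eventProfile(5, A = 2, tauFrames = 5, B = 1)   # 2/e + 1
#' @export
eventProfile <- function(dtFrames, A, tauFrames, B = 0) {
  if (any(tauFrames <= 0)) stop("tauFrames must be positive")
  if (any(dtFrames < 0)) stop("dtFrames must be >= 0")
  A * exp(-dtFrames / tauFrames) + B
}

#' Render one event onto a frame
#'
#' Adds `A * exp(-dt/tau) * G(x, y)` to the frame, where `G` is a
#' unit-peak 2D Gaussian centred at `(x0, y0)` whose variance grows with
#' the time since fusion: `sigma(dt)^2 = sigma0^2 + 2 * D * dt` (lateral
#' spreading of the reporter at the membrane). The unit-peak convention
#' makes the added peak intensity exactly the amplitude, so F/F0 is
#' analytically predictable. Rendering is additive over events;
#' out-of-frame tails are clipped.
#'
#' @param frame numeric `(y, x)` matrix, modified copy returned.
#' @param x0,y0 event centre (0-based pixel centres).
#' @param dtFrames frames since the peak.
#' @param A,tauFrames,sigma0,D profile and spreading parameters.
#' @return the frame with the event added.
#' @export
renderEvent <- function(frame, x0, y0, dtFrames, A, tauFrames,
                        sigma0 = 1.5, D = 0.5) {
  amp <- eventProfile(dtFrames, A, tauFrames, 0)
  s2 <- sigma0^2 + 2 * D * dtFrames
  r <- ceiling(5 * sqrt(s2))
  xs <- max(0, floor(x0) - r):min(ncol(frame) - 1, ceiling(x0) + r)
  ys <- max(0, floor(y0) - r):min(nrow(frame) - 1, ceiling(y0) + r)
  if (length(xs) == 0L || length(ys) == 0L) return(frame)
  gx <- exp(-(xs - x0)^2 / (2 * s2))
  gy <- exp(-(ys - y0)^2 / (2 * s2))
  frame[ys + 1L, xs + 1L] <- frame[ys + 1L, xs + 1L] + amp * outer(gy, gx)
  frame
}

#' Predicted F/F0 of a simulated event
#'
#' Closed-form window average of the rendered unit-peak Gaussian: the
#' F/F0 ratio of a noiseless simulated event on a flat background `B0`
#' equals `1 + A * W / B0`, where `W` is the mean of the Gaussian over the
#' photometry window.
#'
#' @param A event amplitude.
#' @param background flat background intensity under the event.
#' @param sigma0 spot width at the peak (px).
#' @param window photometry window side (px).
#' @return the predicted F/F0 ratio.
#' @export
analyticEventSbr <- function(A, background, sigma0 = 1.5, window = 7L) {
  h <- (window - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma0^2))
  W <- sum(outer(g, g)) / window^2
  1 + A * W / background
}

# elliptical cell footprint used by the generator
.cellFootprint <- function(width, height) {
  x <- matrix(rep(0:(width - 1), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1), times = width), nrow = height)
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  rx <- 0.42 * width; ry <- 0.36 * height
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Simulate a ground-truthed synthetic TIRF movie
#'
#' Builds the noiseless scene (cell-shaped background + stationary docked
#' spots + event renders, optionally bleached as `exp(-t / bleachTau)`),
#' then observes it through `Poisson(scene * gain) / gain +
#' N(0, readNoiseSd)`. Ground truth (event coordinates with per-event
#' amplitude and decay constant, docked spot positions, cell mask) is
#' returned exactly.
#'
#' @param params a [simulationParams()].
#' @return list with `movie` (a [TirfMovie-class]) and `truth`, itself a
#'   list with `events` (an [EventList-class] whose data.frame carries
#'   extra columns `A`, `tauFrames`), `docked` (data.frame x, y,
#'   amplitude), `cellMask` (a [CellMask-class]) and `params`.
#' @export
simulateMovie <- function(params = simulationParams()) {
  stopifnot(inherits(params, "simulationParams"))
  if (!is.null(params$seed)) set.seed(params$seed)
  W <- params$width; H <- params$height; TT <- params$nFrames
  foot <- .cellFootprint(W, H)
  base <- matrix(params$backgroundOut, H, W)
  base[foot] <- params$backgroundIn
  # soften the cell edge slightly (real footprints are not knife-edged)
  base <- as.matrix(EBImage::gblur(EBImage::Image(base), sigma = 1.5))

  # docked vesicles: stationary constant-amplitude spots inside the cell
  docked <- data.frame(x = numeric(0), y = numeric(0),
                       amplitude = numeric(0))
  inside <- which(foot, arr.ind = TRUE)
  inner <- inside[inside[, 1L] > 6 & inside[, 1L] <= H - 6 &
                  inside[, 2L] > 6 & inside[, 2L] <= W - 6, , drop = FALSE]
  if (params$nDocked > 0) {
    pick <- inner[sample.int(nrow(inner), params$nDocked), , drop = FALSE]
    docked <- data.frame(x = pick[, 2L] - 1, y = pick[, 1L] - 1,
                         amplitude = runif(params$nDocked,
                                           params$dockedAmplitudeRange[1L],
                                           params$dockedAmplitudeRange[2L]))
    for (i in seq_len(nrow(docked)))
      base <- renderEvent(base, docked$x[i], docked$y[i], 0,
                          docked$amplitude[i], tauFrames = 1,
                          sigma0 = params$sigma0Px, D = 0)
  }

  # exocytosis events: rejection-sampled with minimum spatiotemporal
  # separation so ground truth is unambiguous
  tauF <- params$decayTauRange / params$frameIntervalS
  ev <- data.frame(x = numeric(0), y = numeric(0), t = numeric(0),
                   A = numeric(0), tauFrames = numeric(0))
  if (params$nEvents > 0) {
    tMax <- TT - 6L
    if (tMax < 5L) stop("movie too short to place events")
    attempts <- 0L
    while (nrow(ev) < params$nEvents) {
      attempts <- attempts + 1L
      if (attempts > 200L * params$nEvents)
        stop("cannot place ", params$nEvents,
             " events under the separation constraints")
      pick <- inner[sample.int(nrow(inner), 1L), ]
      cand <- data.frame(x = pick[[2L]] - 1, y = pick[[1L]] - 1,
                         t = sample(5:tMax, 1L),
                         A = runif(1, params$amplitudeRange[1L],
                                   params$amplitudeRange[2L]),
                         tauFrames = runif(1, tauF[1L], tauF[2L]))
      if (nrow(ev) > 0) {
        dxy <- sqrt((ev$x - cand$x)^2 + (ev$y - cand$y)^2)
        dtt <- abs(ev$t - cand$t)
        if (any(dxy < params$minSepPx & dtt < params$minSepFrames)) next
      }
      ev <- rbind(ev, cand)
    }
  }

  # assemble noiseless scene and observe it
  if (!is.null(params$noiseSeed)) set.seed(params$noiseSeed)
  data <- array(0, dim = c(TT, H, W))
  supp <- if (nrow(ev)) ceiling(8 * ev$tauFrames) else integer(0)
  for (tt in 0:(TT - 1L)) {
    fr <- base
    if (nrow(ev)) {
      act <- which(ev$t <= tt & tt <= ev$t + supp)
      for (i in act)
        fr <- renderEvent(fr, ev$x[i], ev$y[i], tt - ev$t[i], ev$A[i],
                          ev$tauFrames[i], sigma0 = params$sigma0Px,
                          D = params$diffusionPx2PerFrame)
    }
    if (is.finite(params$bleachTauS))
      fr <- fr * exp(-(tt * params$frameIntervalS) / params$bleachTauS)
    if (params$gain > 0)
      fr <- matrix(rpois(length(fr), fr * params$gain) / params$gain, H, W)
    if (params$readNoiseSd > 0)
      fr <- fr + matrix(rnorm(length(fr), 0, params$readNoiseSd), H, W)
    data[tt + 1L, , ] <- pmax(fr, 0)
  }

  evl <- EventList(if (nrow(ev)) cbind(ev[, c("x", "y", "t")],
                                       class = "exocytosis",
                                       score = NA_real_,
                                       ev[, c("A", "tauFrames")])
                   else ev, source = "simulation ground truth")
  list(movie = TirfMovie(data, pixelSize = params$pixelSizeUm,
                         frameInterval = params$frameIntervalS),
       truth = list(events = evl, docked = docked,
                    cellMask = CellMask(foot), params = params))
}
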