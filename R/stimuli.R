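# Deterministic synthetic panoramic stimuli. Objects are drawn as hard-edged
# filled disks in the panoramic plane at a fixed radial band (mid-annulus);
# the drawn diameter is proportional to the angular size theta(t), scaled so
# that theta = 90 deg spans half the annulus width. The network only needs
# monotone growth, so this fixed monotone mapping stands in for an explicit
# camera projection.

#' Declare a synthetic panoramic stimulus
#'
#' Constructor for [StimulusSpec-class]; see that class for the available
#' kinds and slot meanings. Defaults describe a 128x128 panorama at 30
#' frames/s, a dark object on a light background, and additive Gaussian
#' sensor noise of 2 gray levels.
#'
#' @param kind stimulus kind (see [StimulusSpec-class]).
#' @param azimuthDeg object azimuth (path centre for pass-by), degrees.
#' @param lHalfSize object half-size in metres (l/|v| looms).
#' @param vSpeed approach speed in m/s; the magnitude is used.
#' @param theta0Deg initial (constant-rate looms) or fixed (pass-by) angular
#'   size in degrees.
#' @param omegaDegS angular rate in degrees/s: size growth for
#'   `"loom_const_omega"`, field rotation for `"rotate"`, azimuthal speed for
#'   `"translate_passby"`.
#' @param objectGray,backgroundGray gray levels in 0..255.
#' @param fps frames per second.
#' @param durationS duration in seconds; for `"loom_ltv"` the collision
#'   instant is the end of the sequence.
#' @param noiseSigma additive Gaussian pixel noise SD in gray levels.
#' @param seed integer seed for noise and texture.
#' @param frameDim integer(2) frame rows and columns.
#' @return a [StimulusSpec-class].
#' @export
stimulusSpec <- function(kind, azimuthDeg = 67.5, lHalfSize = 0.05,
                         vSpeed = 0.25, theta0Deg = 5, omegaDegS = 90,
                         objectGray = 0, backgroundGray = 200, fps = 30,
                         durationS = 2, noiseSigma = 2, seed = 1L,
                         frameDim = c(128L, 128L)) {
  new("StimulusSpec",
      kind = kind, azimuthDeg = azimuthDeg, lHalfSize = lHalfSize,
      vSpeed = vSpeed, theta0Deg = theta0Deg, omegaDegS = omegaDegS,
      objectGray = objectGray, backgroundGray = backgroundGray, fps = fps,
      durationS = durationS, noiseSigma = noiseSigma, seed = as.integer(seed),
      frameDim = as.integer(frameDim))
}

#' Angular size of an approaching object
#'
#' For an object of half-size `l` approaching at speed `|v|`, the subtended
#' angle at time-to-collision `ttc = t_collision - t` is
#' `theta(t) = 2 atan(l / (|v| ttc))` (degrees). At or past the collision
#' instant the angle is clipped to `thetaMax` (contact).
#'
#' @param l half-size in metres, `l > 0`.
#' @param v approach speed in m/s (magnitude used), non-zero.
#' @param t time in seconds (vectorised).
#' @param t_collision collision instant in seconds.
#' @param thetaMax clip angle in degrees for `t >= t_collision`.
#' @return angle(s) in degrees, strictly increasing in `t` and in `l`.
#' @examples
#' loomingAngularSize(0.07, 1.4, 0, 1)  # 2*atan(0.05) in degrees
#' @export
loomingAngularSize <- function(l, v, t, t_collision, thetaMax = 170) {
  if (any(l <= 0) || any(v == 0)) stop("need l > 0 and |v| > 0")
  ttc <- t_collision - t
  theta <- ifelse(ttc > 0, 2 * atan(l / (abs(v) * ttc)) * 180 / pi, thetaMax)
  pmin(theta, thetaMax)
}

#' Rotate an image about its centre
#'
#' Nearest-neighbour rotation (counterclockwise, in the on-screen sense with
#' row 1 at the top) about the pixel-grid centre `((H-1)/2, (W-1)/2)`.
#' Destination pixels whose source falls outside the frame take `fill`.
#' At multiples of 90 degrees on a square frame the mapping is an exact
#' permutation of the pixels.
#'
#' @param x numeric matrix.
#' @param deg rotation angle in degrees (counterclockwise).
#' @param fill value for uncovered pixels.
#' @return rotated matrix.
#' @export
rotateImage <- function(x, deg, fill = 0) {
  H <- nrow(x); W <- ncol(x)
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  r <- matrix(0:(H - 1), H, W)
  cl <- matrix(0:(W - 1), H, W, byrow = TRUE)
  xs <- cl - cc
  ys <- -(r - cr)
  a <- deg * pi / 180
  # inverse map: source = R(-deg) %*% destination
  sx <- cos(a) * xs + sin(a) * ys
  sy <- -sin(a) * xs + cos(a) * ys
  srow <- round(cr - sy)
  scol <- round(cc + sx)
  ok <- srow >= 0 & srow < H & scol >= 0 & scol < W
  out <- matrix(fill, H, W)
  out[ok] <- x[cbind(srow[ok] + 1L, scol[ok] + 1L)]
  out
}

# blocky random texture for whole-field rotation stimuli (strong local
# contrast so whole-field motion drives every sector's FFI)
.texture_background <- function(frameDim, block = 8L, lo = 30, hi = 220) {
  nbr <- ceiling(frameDim[1L] / block)
  nbc <- ceiling(frameDim[2L] / block)
  vals <- matrix(runif(nbr * nbc, lo, hi), nbr, nbc)
  big <- vals[rep(seq_len(nbr), each = block), rep(seq_len(nbc), each = block)]
  big[seq_len(frameDim[1L]), seq_len(frameDim[2L])]
}

# draw a filled hard-edged disk; gt bookkeeping done by the caller
.draw_disk <- function(base, rowc, colc, diamPx, gray) {
  if (diamPx <= 0) return(base)
  H <- nrow(base); W <- ncol(base)
  r <- matrix(0:(H - 1), H, W)
  cl <- matrix(0:(W - 1), H, W, byrow = TRUE)
  m <- (r - rowc)^2 + (cl - colc)^2 <= (diamPx / 2)^2
  base[m] <- gray
  base
}

#' Render a synthetic stimulus to frames
#'
#' Renders a [StimulusSpec-class] into a [FrameSequence-class] of 8-bit
#' grayscale frames with per-frame ground truth. Rendering is hard-edged (no
#' antialiasing) and fully reproducible for a fixed seed.
#'
#' @param spec a [StimulusSpec-class].
#' @param geometry optional [SectorGeometry-class] fixing the annulus; built
#'   with defaults for `spec@frameDim` when omitted.
#' @return a [FrameSequence-class].
#' @examples
#' fs <- renderSequence(stimulusSpec("loom_ltv", durationS = 1,
#'                                   frameDim = c(64L, 64L)))
#' dim(fs@frames)
#' @export
renderSequence <- function(spec, geometry = NULL) {
  validObject(spec)
  if (is.null(geometry)) geometry <- buildSectorGeometry(spec@frameDim)
  H <- spec@frameDim[1L]; W <- spec@frameDim[2L]
  nT <- max(1L, round(spec@durationS * spec@fps))
  tS <- (seq_len(nT) - 1) / spec@fps
  inner <- geometry@innerRadius
  outer <- geometry@outerRadius
  rObj <- (inner + outer) / 2
  annW <- outer - inner
  cr <- geometry@center[1L]; cc <- geometry@center[2L]

  if (spec@kind == "recede") {
    loomSpec <- spec
    loomSpec@kind <- "loom_ltv"
    fs <- renderSequence(loomSpec, geometry)
    frames <- fs@frames[, , rev(seq_len(dim(fs@frames)[3L])), drop = FALSE]
    gt <- fs@groundTruth[rev(seq_len(nrow(fs@groundTruth))), ]
    gt$frame <- seq_len(nrow(gt))
    gt$timeS <- tS
    gt$ttcS <- NA_real_  # receding: no collision ahead
    rownames(gt) <- NULL
    return(new("FrameSequence", frames = frames, fps = spec@fps,
               groundTruth = gt))
  }

  az <- rep(spec@azimuthDeg, nT)
  theta <- rep(NA_real_, nT)
  ttc <- rep(NA_real_, nT)
  if (spec@kind == "loom_ltv") {
    tCol <- spec@durationS
    theta <- loomingAngularSize(spec@lHalfSize, spec@vSpeed, tS, tCol)
    ttc <- tCol - tS
  } else if (spec@kind == "loom_const_omega") {
    theta <- pmin(spec@theta0Deg + spec@omegaDegS * tS, 170)
  } else if (spec@kind == "translate_passby") {
    theta <- rep(spec@theta0Deg, nT)
    az <- spec@azimuthDeg + spec@omegaDegS * (tS - spec@durationS / 2)
  }

  withr::with_seed(spec@seed, {
    frames <- array(0L, dim = c(H, W, nT))
    if (spec@kind == "rotate") {
      texture <- .texture_background(c(H, W))
      for (k in seq_len(nT)) {
        img <- rotateImage(texture, spec@omegaDegS * tS[k],
                           fill = spec@backgroundGray)
        if (spec@noiseSigma > 0) {
          img <- img + rnorm(H * W, 0, spec@noiseSigma)
        }
        frames[, , k] <- clamp8(img)
      }
      gt <- data.frame(frame = seq_len(nT), timeS = tS,
                       azimuthDeg = NA_real_, thetaDeg = NA_real_,
                       ttcS = NA_real_, outOfField = FALSE)
    } else {
      outOfField <- logical(nT)
      for (k in seq_len(nT)) {
        img <- matrix(spec@backgroundGray, H, W)
        if (!is.na(theta[k]) && spec@kind != "static") {
          dPx <- theta[k] / 90 * (annW / 2)
          a <- az[k] * pi / 180
          oc <- cc + rObj * cos(a)
          orow <- cr - rObj * sin(a)
          img <- .draw_disk(img, orow, oc, dPx, spec@objectGray)
          # partially rendered: the disk crosses the annulus band, or the
          # angular size hit the contact clip
          outOfField[k] <- (rObj + dPx / 2 > outer) ||
            (rObj - dPx / 2 < inner) || theta[k] >= 170
        }
        if (spec@noiseSigma > 0) {
          img <- img + rnorm(H * W, 0, spec@noiseSigma)
        }
        frames[, , k] <- clamp8(img)
      }
      gt <- data.frame(frame = seq_len(nT), timeS = tS, azimuthDeg = az,
                       thetaDeg = theta, ttcS = ttc, outOfField = outOfField)
      if (spec@kind == "static") {
        gt$azimuthDeg <- NA_real_
      }
    }
    new("FrameSequence", frames = frames, fps = spec@fps, groundTruth = gt)
  })
}

#' Desk-scale fixture suite
#'
#' Renders the named collection of synthetic stimuli used throughout the
#' package's experiments: a direct loom, an angular-deviation set (0, 5, 10
#' and 20 degrees off the direct course, the last a small passing object), a
#' size set (object half-sizes 0.02/0.03/0.04 m), a speed set (0.06-0.30 m/s
#' from a 0.20 m start distance), a six-level contrast set, a loom/recede
#' pair, a whole-field rotation at 90 deg/s, a static control and an
#' adjacent-tie loom placed at the centre of the overlap arc shared by
#' sectors 3 and 4. All members are 128x128 at 30 frames/s and at most 120
#' frames; regeneration from the same seed is exact.
#'
#' @param seed integer; offsets every member's noise seed.
#' @param render logical; if `FALSE`, return the [StimulusSpec-class] objects
#'   instead of rendered [FrameSequence-class]es.
#' @return named list of [FrameSequence-class] (or [StimulusSpec-class])
#'   objects; the `sizes`, `speeds`, `contrasts` and `deviations` entries are
#'   themselves named lists.
#' @export
makeFixtureSuite <- function(seed = 1L, render = TRUE) {
  seed <- as.integer(seed)
  sp <- function(kind, seedOff, ...) {
    stimulusSpec(kind, seed = seed + seedOff, ...)
  }
  specs <- list(
    direct_loom = sp("loom_ltv", 0L, azimuthDeg = 67.5, lHalfSize = 0.05,
                     vSpeed = 0.25, durationS = 2.5),
    static = sp("static", 1L, durationS = 1.5),
    rotate = sp("rotate", 2L, omegaDegS = 90, durationS = 1.5),
    loom = sp("loom_ltv", 3L, azimuthDeg = 67.5, lHalfSize = 0.05,
              vSpeed = 0.25, durationS = 1.5),
    recede = sp("recede", 3L, azimuthDeg = 67.5, lHalfSize = 0.05,
                vSpeed = 0.25, durationS = 1.5),
    adjacent_tie = sp("loom_ltv", 4L, azimuthDeg = 56.25, lHalfSize = 0.06,
                      vSpeed = 0.3, durationS = 2, noiseSigma = 0)
  )
  sizes <- c(0.02, 0.03, 0.04)
  specs$sizes <- lapply(seq_along(sizes), function(i) {
    sp("loom_ltv", 10L + i, azimuthDeg = 67.5, lHalfSize = sizes[i],
       vSpeed = 0.25, durationS = 2.5)
  })
  names(specs$sizes) <- paste0("l_", sizes)
  speeds <- c(0.06, 0.10, 0.15, 0.22, 0.30)
  startDist <- 0.20
  specs$speeds <- lapply(seq_along(speeds), function(i) {
    sp("loom_ltv", 20L + i, azimuthDeg = 67.5, lHalfSize = 0.02,
       vSpeed = speeds[i], durationS = startDist / speeds[i])
  })
  names(specs$speeds) <- paste0("v_", speeds)
  grays <- c(0, 40, 80, 120, 160, 180)
  specs$contrasts <- lapply(seq_along(grays), function(i) {
    sp("loom_ltv", 30L + i, azimuthDeg = 67.5, lHalfSize = 0.05,
       vSpeed = 0.25, durationS = 2.5, objectGray = grays[i],
       backgroundGray = 200)
  })
  names(specs$contrasts) <- paste0("gray_", grays)
  devs <- c(0, 5, 10, 20)
  specs$deviations <- lapply(seq_along(devs), function(i) {
    if (devs[i] < 20) {
      # near-direct courses: looms centred progressively off sector 4's axis
      sp("loom_ltv", 40L + i, azimuthDeg = 67.5 + devs[i], lHalfSize = 0.05,
         vSpeed = 0.25, durationS = 2.5 - 0.3 * i)
    } else {
      # large deviation: a distant passing object - small apparent size,
      # low contrast, slow azimuthal drift
      sp("translate_passby", 40L + i, azimuthDeg = 67.5 + devs[i],
         theta0Deg = 3, omegaDegS = 12, durationS = 2, objectGray = 140)
    }
  })
  names(specs$deviations) <- paste0("dev_", devs)

  if (!render) return(specs)
  rapply(specs, renderSequence, classes = "StimulusSpec", how = "replace")
}

#' @describeIn stimulusSpec compact display.
#' @param object a [StimulusSpec-class].
#' @export
setMethod("show", "StimulusSpec", function(object) {
  cat("StimulusSpec:", object@kind, "at azimuth", object@azimuthDeg, "deg,",
      object@durationS, "s @", object@fps, "fps,",
      paste(object@frameDim, collapse = "x"), "px, seed", object@seed, "\n")
})

#' @describeIn renderSequence compact display of a frame stack.
#' @param object a [FrameSequence-class].
#' @export
setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat("FrameSequence:", d[3L], "frames of", d[1L], "x", d[2L], "px @",
      object@fps, "fps\n")
})
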