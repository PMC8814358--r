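# Panoramic sector geometry: the division of the annular field of view into
# overlapping azimuthal receptive fields, one per MLG1-like unit.

#' Build the panoramic sector decomposition
#'
#' Divides a panoramic frame into `nSectors` equal overlapping azimuthal
#' sectors over an annulus around the image centre. With the defaults
#' (16 sectors, 37.5 degree field of view per sector) each sector shares a
#' 15 degree arc with each neighbour and sees a central 7.5 degree arc alone.
#'
#' Conventions: coordinates are 0-based `(row, col)` with rows increasing
#' downward; azimuth is measured counterclockwise from the +col axis at the
#' image centre, in degrees in `[0, 360)`; sector `j` (1-based) is centred at
#' `(j - 1) * 360 / nSectors` and spans `fovDeg / 2` either side of its
#' centre, half-open at the trailing (lower-azimuth) edge so every annulus
#' azimuth is covered by exactly one or two sectors.
#'
#' @param frameDim integer(2), frame rows and columns (at least 32x32).
#' @param nSectors number of sectors.
#' @param fovDeg per-sector field of view in degrees; must exceed the sector
#'   stride `360 / nSectors` and stay below twice the stride.
#' @param innerRadius,outerRadius annulus radii in pixels; defaults are
#'   `0.15 * min(frameDim) / 2` and `min(frameDim) / 2 - 1`.
#' @return a [SectorGeometry-class] object.
#' @examples
#' geom <- buildSectorGeometry(c(128L, 128L))
#' geom@nSectors
#' geom@fovDeg - geom@strideDeg  # 15 degrees shared with each neighbour
#' @export
buildSectorGeometry <- function(frameDim, nSectors = 16L, fovDeg = 37.5,
                                innerRadius = NULL, outerRadius = NULL) {
  frameDim <- as.integer(frameDim)
  if (length(frameDim) != 2L || any(frameDim < 32L)) {
    stop("frameDim must be two integers, each at least 32")
  }
  nSectors <- as.integer(nSectors)
  strideDeg <- 360 / nSectors
  half <- min(frameDim) / 2
  if (is.null(innerRadius)) innerRadius <- 0.15 * half
  if (is.null(outerRadius)) outerRadius <- half - 1
  if (!(innerRadius < outerRadius && outerRadius <= half)) {
    stop("need innerRadius < outerRadius <= min(frameDim)/2")
  }
  center <- (frameDim - 1) / 2

  H <- frameDim[1L]
  W <- frameDim[2L]
  rows <- matrix(0:(H - 1L), H, W)
  cols <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  dx <- cols - center[2L]
  dy <- -(rows - center[1L])
  az <- (atan2(dy, dx) * 180 / pi) %% 360
  rad <- sqrt(dx^2 + dy^2)
  inAnnulus <- rad >= innerRadius & rad <= outerRadius

  centers <- (seq_len(nSectors) - 1) * strideDeg
  masks <- vector("list", nSectors)
  idx <- vector("list", nSectors)
  nCell <- integer(nSectors)
  for (j in seq_len(nSectors)) {
    d <- ((az - centers[j] + 180) %% 360) - 180  # signed offset in [-180, 180)
    m <- inAnnulus & d > -fovDeg / 2 & d <= fovDeg / 2
    masks[[j]] <- m
    idx[[j]] <- which(m)
    nCell[j] <- length(idx[[j]])
    if (nCell[j] == 0L) {
      stop("degenerate annulus: sector ", j, " has an empty mask")
    }
  }

  new("SectorGeometry",
      frameDim = frameDim, center = center,
      innerRadius = innerRadius, outerRadius = outerRadius,
      nSectors = nSectors, strideDeg = strideDeg, fovDeg = fovDeg,
      sectorMasks = masks, maskIndex = idx, nCell = nCell,
      sectorCenterAzimuth = centers)
}

#' Pixel-to-azimuth mapping
#'
#' Azimuth of a pixel in degrees, measured counterclockwise from the +col
#' axis at the panoramic centre. The exact centre maps to azimuth 0 by
#' convention. Vectorised over `row`/`col`.
#'
#' @param row,col 0-based pixel coordinates (rows increase downward).
#' @param geometry a [SectorGeometry-class].
#' @return numeric azimuths in `[0, 360)`.
#' @examples
#' geom <- buildSectorGeometry(c(64L, 64L))
#' pixelAzimuth(geom@center[1], geom@center[2] + 10, geom)  # 0
#' pixelAzimuth(geom@center[1] - 10, geom@center[2], geom)  # 90
#' @export
pixelAzimuth <- function(row, col, geometry) {
  if (any(row < 0 | row >= geometry@frameDim[1L] |
          col < 0 | col >= geometry@frameDim[2L])) {
    stop("pixel outside the frame")
  }
  dx <- col - geometry@center[2L]
  dy <- -(row - geometry@center[1L])
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Sectors covering an azimuth
#'
#' Indices of the sectors whose angular span contains the given azimuth
#' (ignoring the annulus radii). Every azimuth is covered by one or two
#' sectors.
#'
#' @param azimuthDeg numeric azimuth(s) in degrees.
#' @param geometry a [SectorGeometry-class].
#' @return for a single azimuth, an integer vector of sector indices; for
#'   several, a list of such vectors.
#' @export
sectorsForAzimuth <- function(azimuthDeg, geometry) {
  one <- function(a) {
    d <- ((a - geometry@sectorCenterAzimuth + 180) %% 360) - 180
    which(d > -geometry@fovDeg / 2 & d <= geometry@fovDeg / 2)
  }
  if (length(azimuthDeg) == 1L) one(azimuthDeg) else lapply(azimuthDeg, one)
}

#' Serialise / rebuild a geometry
#'
#' `geometryDescriptor()` reduces a [SectorGeometry-class] to a small plain
#' list (dims, radii, per-sector azimuth ranges) that can be written as JSON;
#' `geometryFromDescriptor()` regenerates the full geometry, masks included,
#' from such a descriptor.
#'
#' @param geometry a [SectorGeometry-class].
#' @return `geometryDescriptor()`: a named list.
#' @examples
#' geom <- buildSectorGeometry(c(64L, 64L))
#' geom2 <- geometryFromDescriptor(geometryDescriptor(geom))
#' identical(geom@sectorMasks, geom2@sectorMasks)
#' @export
geometryDescriptor <- function(geometry) {
  list(
    frameDim = geometry@frameDim,
    innerRadius = geometry@innerRadius,
    outerRadius = geometry@outerRadius,
    nSectors = geometry@nSectors,
    fovDeg = geometry@fovDeg,
    sectorCenterAzimuth = geometry@sectorCenterAzimuth,
    sectorAzimuthRange = lapply(seq_len(geometry@nSectors), function(j) {
      c(geometry@sectorCenterAzimuth[j] - geometry@fovDeg / 2,
        geometry@sectorCenterAzimuth[j] + geometry@fovDeg / 2)
    })
  )
}

#' @rdname geometryDescriptor
#' @param descriptor a list as returned by `geometryDescriptor()` (possibly
#'   round-tripped through JSON).
#' @return `geometryFromDescriptor()`: a [SectorGeometry-class].
#' @export
geometryFromDescriptor <- function(descriptor) {
  buildSectorGeometry(
    frameDim = as.integer(unlist(descriptor$frameDim)),
    nSectors = descriptor$nSectors,
    fovDeg = descriptor$fovDeg,
    innerRadius = descriptor$innerRadius,
    outerRadius = descriptor$outerRadius
  )
}

#' @describeIn buildSectorGeometry compact display.
#' @param object a [SectorGeometry-class].
#' @export
setMethod("show", "SectorGeometry", function(object) {
  cat("SectorGeometry:", object@nSectors, "sectors over a",
      paste(object@frameDim, collapse = "x"), "frame\n")
  cat("  fov", object@fovDeg, "deg, stride", object@strideDeg,
      "deg, overlap", object@fovDeg - object@strideDeg, "deg\n")
  cat("  annulus radii [", format(object@innerRadius), ",",
      format(object@outerRadius), "] px; cells/sector",
      min(object@nCell), "-", max(object@nCell), "\n")
})
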