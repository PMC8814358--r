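# S4 classes for the model: configuration, panoramic geometry, synthetic
# stimulus specifications, rendered frame stacks, and the run container.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MLG1Config: model parameters
#'
#' Holds every tunable scalar of the model. Slot names follow the symbols
#' used throughout the field for this family of looming detectors; see
#' [mlg1Config()] for meanings, units and defaults.
#'
#' @slot N_p integer, luminance persistence window of the photoreceptor layer
#'   (frames).
#' @slot mu numeric, steepness of the logistic persistence coefficients.
#' @slot W_I numeric, weight of the lateral inhibition pathway.
#' @slot inhibition_sign numeric, -1 for subtractive lateral inhibition
#'   (default) or +1 for additive combination.
#' @slot C_w numeric, gain constant of the grouping-layer normaliser.
#' @slot Delta_c numeric, small positive floor used by the grouping
#'   normaliser and the adaptation coefficient.
#' @slot T_g numeric, grouping-layer magnitude threshold (gray-level units).
#' @slot c_i1,c_i2 numeric, adaptation increments applied while excitation
#'   rises (accelerating / decelerating).
#' @slot c_a numeric, adaptation decrement applied while excitation falls.
#' @slot tau numeric, inter-frame time constant in seconds.
#' @slot T_s numeric, spike threshold on the sigmoidal activation.
#' @slot n_sp integer, number of spikes within the alarm window required to
#'   raise a collision alarm.
#' @slot N_t integer, length of the spike buffer inspected by the alarm rule.
#' @slot N_a integer, persistence window of the feed-forward inhibition.
#' @slot T_F0 numeric, base value of the adaptive FFI threshold.
#' @slot a_ffi numeric in (0,1), persistence of the adaptive FFI threshold.
#' @slot wta_window integer, length of the alarm history window scored by the
#'   winner-take-all layer.
#' @slot rotation_veto_count integer, number of sectors whose FFI must be
#'   active before the whole ensemble is vetoed as self-rotation.
#' @slot warmup_frames integer, initial frames during which spikes and alarms
#'   are suppressed while delay buffers fill.
#' @slot sfa_enabled logical, whether spike-frequency adaptation is active.
#' @slot sfa_fixed_c numeric, constant gain used when `sfa_enabled` is FALSE.
#' @seealso [mlg1Config()], [urbanConfig()]
#' @export
setClass("MLG1Config",
  representation(
    N_p = "integer", mu = "numeric", W_I = "numeric",
    inhibition_sign = "numeric", C_w = "numeric", Delta_c = "numeric",
    T_g = "numeric", c_i1 = "numeric", c_i2 = "numeric", c_a = "numeric",
    tau = "numeric", T_s = "numeric", n_sp = "integer", N_t = "integer",
    N_a = "integer", T_F0 = "numeric", a_ffi = "numeric",
    wta_window = "integer", rotation_veto_count = "integer",
    warmup_frames = "integer", sfa_enabled = "logical",
    sfa_fixed_c = "numeric"
  )
)

setValidity("MLG1Config", function(object) {
  msg <- character(0)
  pos <- c(
    N_p = object@N_p, W_I = object@W_I, C_w = object@C_w,
    Delta_c = object@Delta_c, T_g = object@T_g, c_i1 = object@c_i1,
    c_i2 = object@c_i2, c_a = object@c_a, tau = object@tau, T_s = object@T_s,
    n_sp = object@n_sp, N_t = object@N_t, N_a = object@N_a,
    T_F0 = object@T_F0, sfa_fixed_c = object@sfa_fixed_c
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    msg <- c(msg, paste0("parameters must be strictly positive: ",
                         paste(bad, collapse = ", ")))
  }
  if (!(object@inhibition_sign %in% c(-1, 1))) {
    msg <- c(msg, "inhibition_sign must be -1 or +1")
  }
  if (!(object@a_ffi > 0 && object@a_ffi < 1)) {
    msg <- c(msg, "a_ffi must lie in (0, 1)")
  }
  if (object@n_sp > object@N_t) msg <- c(msg, "n_sp must not exceed N_t")
  if (object@wta_window < 1L) msg <- c(msg, "wta_window must be >= 1")
  if (object@rotation_veto_count < 1L) {
    msg <- c(msg, "rotation_veto_count must be >= 1")
  }
  if (object@warmup_frames < 0L) msg <- c(msg, "warmup_frames must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SectorGeometry: panoramic sector decomposition
#'
#' The division of a panoramic frame into `nSectors` overlapping azimuthal
#' receptive fields over an annulus centred on the image centre (the image
#' centre is the sky above the camera; approaching objects travel outward
#' through the annulus).
#'
#' @slot frameDim integer(2), frame rows and columns.
#' @slot center numeric(2), 0-based (row, col) of the panoramic centre.
#' @slot innerRadius,outerRadius numeric, annulus radii in pixels.
#' @slot nSectors integer, number of sectors (16 by default).
#' @slot strideDeg numeric, angular spacing of sector centres (360/nSectors).
#' @slot fovDeg numeric, angular width of each sector's receptive field.
#' @slot sectorMasks list of logical matrices, one per sector.
#' @slot maskIndex list of integer vectors, `which()` of each mask (kept for
#'   fast masked sums).
#' @slot nCell integer, pixels inside each sector mask.
#' @slot sectorCenterAzimuth numeric, sector centre azimuths in degrees.
#' @seealso [buildSectorGeometry()]
#' @export
setClass("SectorGeometry",
  representation(
    frameDim = "integer", center = "numeric",
    innerRadius = "numeric", outerRadius = "numeric",
    nSectors = "integer", strideDeg = "numeric", fovDeg = "numeric",
    sectorMasks = "list", maskIndex = "list", nCell = "integer",
    sectorCenterAzimuth = "numeric"
  )
)

setValidity("SectorGeometry", function(object) {
  msg <- character(0)
  if (abs(object@nSectors * object@strideDeg - 360) > 1e-9) {
    msg <- c(msg, "nSectors * strideDeg must equal 360 exactly")
  }
  if (object@fovDeg <= object@strideDeg) {
    msg <- c(msg, "fovDeg must exceed strideDeg (sectors must overlap)")
  }
  if (object@fovDeg >= 2 * object@strideDeg) {
    msg <- c(msg, "fovDeg must be below 2*strideDeg (at most two-fold coverage)")
  }
  if (!(object@innerRadius < object@outerRadius)) {
    msg <- c(msg, "innerRadius must be below outerRadius")
  }
  if (length(object@sectorMasks) != object@nSectors ||
      length(object@nCell) != object@nSectors) {
    msg <- c(msg, "one mask and cell count per sector required")
  }
  if (any(object@nCell <= 0L)) {
    bad <- which(object@nCell <= 0L)
    msg <- c(msg, paste0("empty sector mask (degenerate annulus) for sector ",
                         paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' StimulusSpec: declarative synthetic panoramic stimulus
#'
#' Describes one synthetic stimulus for [renderSequence()]. Kinds:
#' `"loom_ltv"` (approach with l/|v| kinematics, collision at the end of the
#' sequence), `"loom_const_omega"` (angular size grows at a constant rate),
#' `"recede"` (exact frame-reversal of the paired loom), `"rotate"`
#' (whole-field rotation of a textured background), `"translate_passby"`
#' (constant-size object crossing the field at constant angular rate) and
#' `"static"`.
#'
#' @slot kind character, one of the stimulus kinds above.
#' @slot azimuthDeg numeric, object azimuth (path centre for pass-by) in
#'   degrees.
#' @slot lHalfSize numeric, physical half-size of the object in metres.
#' @slot vSpeed numeric, approach speed in m/s (its magnitude is used;
#'   negative values point toward the observer).
#' @slot theta0Deg numeric, initial (or constant) angular size in degrees.
#' @slot omegaDegS numeric, constant angular-size growth rate, rotation rate,
#'   or pass-by azimuthal rate (degrees per second, by kind).
#' @slot objectGray,backgroundGray numeric in [0, 255].
#' @slot fps numeric, frames per second.
#' @slot durationS numeric, sequence duration in seconds.
#' @slot noiseSigma numeric, standard deviation of additive Gaussian pixel
#'   noise (gray levels).
#' @slot seed integer, seed for the noise and texture streams.
#' @slot frameDim integer(2), frame rows and columns.
#' @seealso [stimulusSpec()], [renderSequence()]
#' @export
setClass("StimulusSpec",
  representation(
    kind = "character", azimuthDeg = "numeric", lHalfSize = "numeric",
    vSpeed = "numeric", theta0Deg = "numeric", omegaDegS = "numeric",
    objectGray = "numeric", backgroundGray = "numeric", fps = "numeric",
    durationS = "numeric", noiseSigma = "numeric", seed = "integer",
    frameDim = "integer"
  )
)

.stimulus_kinds <- c("loom_ltv", "loom_const_omega", "recede", "rotate",
                     "translate_passby", "static")

setValidity("StimulusSpec", function(object) {
  msg <- character(0)
  if (!(object@kind %in% .stimulus_kinds)) {
    msg <- c(msg, paste0("kind must be one of: ",
                         paste(.stimulus_kinds, collapse = ", ")))
  }
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  moving <- !(object@kind %in% c("static", "rotate"))
  if (moving && object@objectGray == object@backgroundGray) {
    msg <- c(msg, "objectGray must differ from backgroundGray for motion stimuli")
  }
  if (any(object@frameDim < 32L)) msg <- c(msg, "frames must be at least 32x32")
  if (object@theta0Deg < 0 || object@theta0Deg >= 180) {
    msg <- c(msg, "theta0Deg must lie in [0, 180)")
  }
  if (length(msg)) msg else TRUE
})

#' FrameSequence: rendered 8-bit grayscale frame stack
#'
#' @slot frames integer array (rows x cols x frames), values in 0..255.
#' @slot fps numeric, frames per second.
#' @slot groundTruth data.frame with one row per frame: `frame`, `timeS`,
#'   `azimuthDeg`, `thetaDeg`, `ttcS` (time to collision, NA when undefined)
#'   and `outOfField`.
#' @seealso [renderSequence()], [readFrames()]
#' @export
setClass("FrameSequence",
  representation(frames = "array", fps = "numeric", groundTruth = "data.frame")
)

setValidity("FrameSequence", function(object) {
  msg <- character(0)
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a rows x cols x time array")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (length(d) == 3L && nrow(object@groundTruth) > 0 &&
      nrow(object@groundTruth) != d[3L]) {
    msg <- c(msg, "groundTruth must have one row per frame")
  }
  rng <- range(object@frames)
  if (rng[1] < 0 || rng[2] > 255) msg <- c(msg, "pixel values must lie in 0..255")
  if (length(msg)) msg else TRUE
})

#' MLG1Run: results of a network run
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the full
#' per-sector, per-frame output of [runMLG1s()]. Rows are the 16 sectors
#' (rowData: `sector`, `centerAzimuthDeg`, `nCell`), columns are frames
#' (colData: `frame`, `timeS`, `warmup`, `veto`, `lsl`, `lslLabel`). Assays:
#' `m` (membrane potential), `M` (sigmoidal activation), `F` (feed-forward
#' inhibition), `T_FFI` (its adaptive threshold), `spike`, `alarm` and `Chat`
#' (winner-take-all score). `metadata()` carries the configuration, the
#' geometry descriptor and the event summary.
#'
#' @seealso [runMLG1s()], [lslTrace()], [eventSummary()]
#' @export
setClass("MLG1Run", contains = "SummarizedExperiment")
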