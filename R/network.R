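# Network-level machinery: the ensemble frame loop, the self-rotation veto,
# and the winner-take-all looming spatial localization (LSL) layer.

#' Winner-take-all weights
#'
#' The alarm-history weights of the localization layer: strictly increasing
#' toward older frames and summing to one. Linear weights are used:
#' `alpha_k = 2 k / (n (n + 1))`, with `alpha_1` applied to the current frame
#' and `alpha_n` to the oldest frame in the window, so earlier alarms carry
#' more weight.
#'
#' @param n window length.
#' @return numeric vector of length `n`, strictly increasing, summing to 1.
#' @export
alphaWeights <- function(n) {
  if (n < 1) stop("window length must be >= 1")
  2 * seq_len(n) / (n * (n + 1))
}

#' Self-rotation veto
#'
#' The ensemble treats the scene as self-rotation when the feed-forward
#' inhibition of at least `rotation_veto_count` sectors (10 of 16 by default)
#' meets its threshold; all spikes are then suppressed for the frame.
#'
#' @param F_values per-sector FFI values.
#' @param T_values per-sector FFI thresholds.
#' @param config an [MLG1Config-class].
#' @return integer 0/1.
#' @export
rotationVeto <- function(F_values, T_values, config) {
  if (length(F_values) != length(T_values)) {
    stop("F and threshold vectors must have equal length")
  }
  as.integer(sum(F_values >= T_values) >= config@rotation_veto_count)
}

#' Fresh localization-layer state
#'
#' @param nSectors number of sectors.
#' @param window alarm-history window length (`wta_window`).
#' @return a list with the alarm history matrix (sectors x window, current
#'   frame in column 1), the lock bookkeeping and per-sector first-alarm
#'   frames.
#' @export
newLSLState <- function(nSectors, window) {
  list(
    alarmHist = matrix(0L, nrow = nSectors, ncol = window),
    locked = FALSE,
    winnerSectors = integer(0),
    report = NA_real_,
    label = NA_character_,
    firstAlarmFrame = rep(NA_integer_, nSectors)
  )
}

# numeric report and label for a locked winner (single sector or an
# adjacent pair reported as the midpoint between them)
.lsl_report <- function(winnerSectors, nSectors) {
  if (length(winnerSectors) == 1L) {
    list(report = as.numeric(winnerSectors), label = as.character(winnerSectors))
  } else {
    a <- winnerSectors[1L]
    b <- winnerSectors[2L]
    if (a == 1L && b == nSectors) {
      # pair straddling the azimuth origin
      list(report = nSectors + 0.5, label = paste0(nSectors, "|", 1L))
    } else {
      list(report = a + 0.5, label = paste0(a, "|", b))
    }
  }
}

#' One winner-take-all update
#'
#' Pushes the current alarm bits into the history window, scores each sector
#' as `Chat_j = sum_k alpha_k * alarm_j(t - k + 1)` with weights increasing
#' toward older frames, and maintains the latched localization report:
#'
#' * while a locked winner's alarm persists the report does not change;
#' * when its alarm drops the lock releases and the currently alarming
#'   sectors re-compete;
#' * the winner is the alarming sector with the largest `Chat`; an exact tie
#'   between two adjacent sectors is reported as the midpoint between them
#'   (e.g. 3.5, labelled `"3|4"`); other exact ties fall back to the earliest
#'   first-alarm frame, then the lowest index;
#' * no new lock is taken on a frame under the self-rotation veto.
#'
#' @param alarms integer 0/1 vector, one bit per sector.
#' @param state localization state from [newLSLState()] (or a previous call).
#' @param config an [MLG1Config-class] (uses `wta_window`).
#' @param vetoed integer 0/1, the frame's self-rotation veto.
#' @param frameIndex current frame number (for first-alarm bookkeeping).
#' @return list with the updated `state`, the numeric `lsl` report (sector
#'   index, half-index midpoint, or `NA`), its character `label`, and the
#'   `Chat` scores.
#' @export
wtaStep <- function(alarms, state, config, vetoed = 0L, frameIndex = NA_integer_) {
  n <- nrow(state$alarmHist)
  window <- ncol(state$alarmHist)
  alarms <- as.integer(alarms)
  if (length(alarms) != n) stop("one alarm bit per sector required")

  state$alarmHist <- cbind(alarms, state$alarmHist[, -window, drop = FALSE])
  newly <- which(alarms == 1L & is.na(state$firstAlarmFrame))
  state$firstAlarmFrame[newly] <- frameIndex

  alpha <- alphaWeights(window)
  Chat <- as.numeric(state$alarmHist %*% alpha)

  if (state$locked) {
    if (all(alarms[state$winnerSectors] == 1L)) {
      return(list(state = state, lsl = state$report, label = state$label,
                  Chat = Chat))
    }
    state$locked <- FALSE
    state$winnerSectors <- integer(0)
    state$report <- NA_real_
    state$label <- NA_character_
  }

  active <- which(alarms == 1L)
  if (length(active) == 0L || vetoed == 1L) {
    return(list(state = state, lsl = NA_real_, label = NA_character_,
                Chat = Chat))
  }

  cb <- Chat[active]
  cand <- active[cb == max(cb)]
  adjacent <- length(cand) == 2L &&
    (cand[2L] - cand[1L] == 1L || (cand[1L] == 1L && cand[2L] == n))
  if (length(cand) == 1L || adjacent) {
    winner <- cand
  } else {
    ord <- order(state$firstAlarmFrame[cand], cand)
    winner <- cand[ord[1L]]
  }
  rep <- .lsl_report(winner, n)
  state$locked <- TRUE
  state$winnerSectors <- winner
  state$report <- rep$report
  state$label <- rep$label
  list(state = state, lsl = rep$report, label = rep$label, Chat = Chat)
}

#' Run the MLG1 ensemble over a frame stack
#'
#' Executes the full model: for every frame, the shared photoreceptor,
#' lateral-inhibition, summation and grouping layers are computed over the
#' whole panorama; each sector then derives its membrane potential,
#' adaptation coefficient, activation, feed-forward inhibition and spike and
#' alarm bits over its own mask, the self-rotation veto is applied before
#' spike decisions, and the winner-take-all layer updates the localization
#' report. The run is fully deterministic: identical inputs and
#' configuration give bit-identical results.
#'
#' @param frames a [FrameSequence-class] or a rows x cols x time numeric
#'   array of gray levels in 0..255.
#' @param config an [MLG1Config-class]; when `frames` is a
#'   [FrameSequence-class] and `config` is omitted, `tau` is taken from the
#'   sequence frame rate.
#' @param geometry a [SectorGeometry-class]; built with defaults for the
#'   frame size when omitted.
#' @return an [MLG1Run-class] (a `SummarizedExperiment`: sectors x frames,
#'   assays `m`, `M`, `F`, `T_FFI`, `spike`, `alarm`, `Chat`).
#' @examples
#' seq <- renderSequence(stimulusSpec("static", durationS = 0.3,
#'                                    frameDim = c(64L, 64L), noiseSigma = 0))
#' run <- runMLG1s(seq)
#' all(assay(run, "spike") == 0)
#' @export
runMLG1s <- function(frames, config = NULL, geometry = NULL) {
  fps <- NULL
  if (is(frames, "FrameSequence")) {
    fps <- frames@fps
    arr <- frames@frames
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    arr <- frames
  } else {
    stop("frames must be a FrameSequence or a 3-d array")
  }
  if (is.null(config)) {
    config <- if (is.null(fps)) mlg1Config() else mlg1Config(fps = fps)
  }
  validObject(config)
  d <- dim(arr)
  H <- d[1L]; W <- d[2L]; nT <- d[3L]
  if (is.null(geometry)) geometry <- buildSectorGeometry(c(H, W))
  if (!all(geometry@frameDim == c(H, W))) {
    stop("frame dimensions do not match the geometry")
  }
  nS <- geometry@nSectors
  idx <- geometry@maskIndex
  nCell <- geometry@nCell

  # per-sector recurrent state
  zero <- matrix(0, H, W)
  P_hist <- list()              # photoreceptor outputs, most recent first
  L_prev <- NULL
  m_hist <- matrix(NA_real_, nS, 2)   # columns: m(t-1), m(t-2)
  c_cur <- rep(if (config@sfa_enabled) config@Delta_c else config@sfa_fixed_c, nS)
  F_hist <- matrix(numeric(0), nrow = nS, ncol = 0)
  T_prev <- config@T_F0
  spike_buf <- matrix(0L, nS, config@N_t)
  lsl <- newLSLState(nS, config@wta_window)

  m_out <- matrix(0, nS, nT)
  M_out <- matrix(0, nS, nT)
  F_out <- matrix(0, nS, nT)
  T_out <- matrix(0, nS, nT)
  s_out <- matrix(0L, nS, nT)
  a_out <- matrix(0L, nS, nT)
  C_out <- matrix(0, nS, nT)
  c_out <- matrix(0, nS, nT)
  veto_out <- integer(nT)
  lsl_out <- rep(NA_real_, nT)
  lab_out <- rep(NA_character_, nT)

  for (t in seq_len(nT)) {
    L_t <- arr[, , t]
    P_prev <- if (length(P_hist)) P_hist[[1L]] else zero
    P <- if (t == 1L) zero else photoreceptorUpdate(L_t, L_prev, P_hist, config)

    path <- lateralPathways(P, P_prev)
    S <- summationLayer(path$E, path$I, config)
    G <- groupingLayer(S, config)$G
    absG <- abs(G)

    T_cur <- ffiThreshold(T_prev, config)
    m_vec <- vapply(idx, function(ii) sum(absG[ii]), numeric(1))
    F_vec <- vapply(seq_len(nS), function(j) {
      ffiUpdate(P_prev, idx[[j]], nCell[j], F_hist[j, ], config)
    }, numeric(1))

    for (j in seq_len(nS)) {
      der <- discreteDerivatives(m_vec[j], m_hist[j, 1L], m_hist[j, 2L],
                                 config@tau)
      c_cur[j] <- sfaUpdate(c_cur[j], der$d1, der$d2, config)
    }
    M_vec <- activationLevel(m_vec, c_cur, nCell)

    veto <- rotationVeto(F_vec, rep(T_cur, nS), config)
    warm <- t <= config@warmup_frames
    spikes <- integer(nS)
    if (!warm && veto == 0L) {
      for (j in seq_len(nS)) {
        spikes[j] <- spikeDecision(M_vec[j], F_vec[j], T_cur, config)
      }
    }
    spike_buf <- cbind(spikes, spike_buf[, -config@N_t, drop = FALSE])
    alarms <- integer(nS)
    if (!warm) {
      for (j in seq_len(nS)) {
        alarms[j] <- collisionAlarm(spike_buf[j, ], config)
      }
    }

    step <- wtaStep(alarms, lsl, config, vetoed = veto, frameIndex = t)
    lsl <- step$state

    m_out[, t] <- m_vec
    M_out[, t] <- M_vec
    F_out[, t] <- F_vec
    T_out[, t] <- T_cur
    s_out[, t] <- spikes
    a_out[, t] <- alarms
    C_out[, t] <- step$Chat
    c_out[, t] <- c_cur
    veto_out[t] <- veto
    lsl_out[t] <- step$lsl
    lab_out[t] <- step$label

    # roll state
    m_hist[, 2L] <- m_hist[, 1L]
    m_hist[, 1L] <- m_vec
    F_hist <- cbind(F_vec, if (ncol(F_hist) >= config@N_a)
      F_hist[, seq_len(config@N_a - 1L), drop = FALSE] else F_hist)
    T_prev <- T_cur
    P_hist <- c(list(P), P_hist)
    if (length(P_hist) > max(config@N_p, 1L)) {
      P_hist <- P_hist[seq_len(max(config@N_p, 1L))]
    }
    L_prev <- L_t
  }

  tau_fps <- if (is.null(fps)) 1 / config@tau else fps
  cd <- S4Vectors::DataFrame(
    frame = seq_len(nT),
    timeS = (seq_len(nT) - 1) / tau_fps,
    warmup = seq_len(nT) <= config@warmup_frames,
    veto = veto_out,
    lsl = lsl_out,
    lslLabel = lab_out
  )
  rd <- S4Vectors::DataFrame(
    sector = seq_len(nS),
    centerAzimuthDeg = geometry@sectorCenterAzimuth,
    nCell = nCell
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(m = m_out, M = M_out, F = F_out, T_FFI = T_out,
                  spike = s_out, alarm = a_out, Chat = C_out, sfa = c_out),
    rowData = rd, colData = cd,
    metadata = list(
      config = configAsList(config),
      geometry = geometryDescriptor(geometry),
      events = .run_events(s_out, a_out, lsl_out, lab_out)
    )
  )
  rownames(se) <- paste0("sector", seq_len(nS))
  colnames(se) <- paste0("frame", seq_len(nT))
  new("MLG1Run", se)
}

# first spike/alarm frame per sector and the sequence of distinct LSL reports
.run_events <- function(spikes, alarms, lsl, labels) {
  firstOf <- function(mat) {
    apply(mat, 1L, function(v) {
      w <- which(v == 1L)
      if (length(w)) w[1L] else NA_integer_
    })
  }
  keep <- which(!is.na(lsl))
  chg <- keep[c(TRUE, diff(lsl[keep]) != 0)]
  list(
    firstSpikeFrame = firstOf(spikes),
    firstAlarmFrame = firstOf(alarms),
    lslTrace = data.frame(frame = chg, lsl = lsl[chg], label = labels[chg],
                          stringsAsFactors = FALSE)
  )
}

#' Localization trace of a run
#'
#' @param run an [MLG1Run-class].
#' @return data.frame with `frame`, `lsl` (numeric report, `NA` when silent),
#'   `lslLabel`, `veto` and `warmup` for every frame.
#' @export
lslTrace <- function(run) {
  cd <- SummarizedExperiment::colData(run)
  data.frame(frame = cd$frame, lsl = cd$lsl, lslLabel = cd$lslLabel,
             veto = cd$veto, warmup = cd$warmup, stringsAsFactors = FALSE)
}

#' First spike / first alarm frame per sector
#'
#' @param run an [MLG1Run-class].
#' @return integer vector, one entry per sector (`NA` if the sector never
#'   spiked / alarmed).
#' @export
firstSpikeFrame <- function(run) {
  S4Vectors::metadata(run)$events$firstSpikeFrame
}

#' @rdname firstSpikeFrame
#' @export
firstAlarmFrame <- function(run) {
  S4Vectors::metadata(run)$events$firstAlarmFrame
}

#' @describeIn runMLG1s compact display of a run.
#' @param object an [MLG1Run-class].
#' @export
setMethod("show", "MLG1Run", function(object) {
  cat("MLG1Run:", nrow(object), "sectors x", ncol(object), "frames\n")
  ev <- S4Vectors::metadata(object)$events
  fa <- ev$firstAlarmFrame
  if (any(!is.na(fa))) {
    al <- which(!is.na(fa))
    cat("  alarms in sector(s)", paste(al, collapse = ", "),
        "(first at frame", min(fa, na.rm = TRUE), ")\n")
  } else {
    cat("  no alarms\n")
  }
  if (nrow(ev$lslTrace)) {
    cat("  LSL reports:", paste(unique(ev$lslTrace$label), collapse = " -> "),
        "\n")
  } else {
    cat("  no localization report\n")
  }
})
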