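# Frame readers/writers, tidy time-series output, run manifests and a small
# base-graphics report plot.

#' Read a frame stack
#'
#' Reads an ordered directory of PNG images (sorted by file name) into a
#' [FrameSequence-class]. Colour images are converted to 8-bit grayscale
#' with the standard luma weighting 0.299 R + 0.587 G + 0.114 B. If a
#' `ground_truth.json` sidecar (as written by [writeFrames()]) is present it
#' is attached.
#'
#' @param path directory containing `.png` frames.
#' @param fps frames per second to attach (sidecar value wins if present).
#' @return a [FrameSequence-class].
#' @export
readFrames <- function(path, fps = 30) {
  if (!dir.exists(path)) stop("input not readable: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png frames found in ", path)
  mats <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) {
      ch <- dim(img)[3L]
      img <- if (ch >= 3L) {
        0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
      } else {
        img[, , 1L]
      }
    }
    clamp8(img * 255)
  })
  d1 <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == d1), logical(1)))) {
    stop("mixed frame dimensions in ", path)
  }
  frames <- array(unlist(mats), dim = c(d1, length(mats)))
  gt <- data.frame()
  sidecar <- file.path(path, "ground_truth.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$fps)) fps <- meta$fps
    if (!is.null(meta$groundTruth)) gt <- as.data.frame(meta$groundTruth)
  }
  new("FrameSequence", frames = frames, fps = fps, groundTruth = gt)
}

#' Write a frame stack
#'
#' Writes each frame as an 8-bit grayscale PNG (`frame_0001.png`, ...) plus a
#' `ground_truth.json` sidecar with the frame rate and per-frame ground
#' truth. [readFrames()] restores the pixel data exactly.
#'
#' @param frameSeq a [FrameSequence-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeFrames <- function(frameSeq, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nT <- dim(frameSeq@frames)[3L]
  for (k in seq_len(nT)) {
    png::writePNG(frameSeq@frames[, , k] / 255,
                  file.path(path, sprintf("frame_%04d.png", k)))
  }
  jsonlite::write_json(
    list(fps = frameSeq@fps, groundTruth = frameSeq@groundTruth),
    file.path(path, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

.run_variables <- c("m", "M", "F", "T_FFI", "spike", "alarm", "Chat")

#' Write run time series
#'
#' Writes the per-frame, per-sector time series of a run as a tidy CSV
#' (columns `frame`, `sector`, `variable`, `value`; network-level rows use an
#' empty sector) and as JSON lines (one object per frame). Doubles are
#' serialised at full precision so re-reading reproduces the run's values
#' exactly. A localization midpoint is serialised both as the numeric
#' half-index (e.g. 3.5) and as the label `"3|4"`.
#'
#' @param run an [MLG1Run-class].
#' @param csvPath path of the CSV to write (`NULL` to skip).
#' @param jsonlPath path of the JSON-lines file to write (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeTimeSeries <- function(run, csvPath = NULL, jsonlPath = NULL) {
  cd <- SummarizedExperiment::colData(run)
  nS <- nrow(run)
  nT <- ncol(run)
  if (nT == 0L) stop("empty run")
  if (!is.null(csvPath)) {
    con <- file(csvPath, "w")
    on.exit(close(con), add = TRUE)
    writeLines("frame,sector,variable,value", con)
    for (v in .run_variables) {
      a <- SummarizedExperiment::assay(run, v)
      lines <- sprintf("%d,%d,%s,%s",
                       rep(seq_len(nT), each = nS),
                       rep(seq_len(nS), times = nT),
                       v, fmt_full(as.numeric(a)))
      writeLines(lines, con)
    }
    writeLines(sprintf("%d,,veto,%s", seq_len(nT), fmt_full(cd$veto)), con)
    writeLines(sprintf("%d,,lsl,%s", seq_len(nT), fmt_full(cd$lsl)), con)
    labs <- ifelse(is.na(cd$lslLabel), "NA", cd$lslLabel)
    writeLines(sprintf("%d,,lsl_label,%s", seq_len(nT), labs), con)
  }
  if (!is.null(jsonlPath)) {
    conj <- file(jsonlPath, "w")
    on.exit(close(conj), add = TRUE)
    assays <- lapply(.run_variables, function(v)
      SummarizedExperiment::assay(run, v))
    names(assays) <- .run_variables
    for (t in seq_len(nT)) {
      obj <- list(frame = t, warmup = cd$warmup[t], veto = cd$veto[t],
                  lsl = cd$lsl[t], lsl_label = cd$lslLabel[t],
                  sectors = lapply(assays, function(a) a[, t]))
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  na = "null"), conj)
    }
  }
  invisible(list(csv = csvPath, jsonl = jsonlPath))
}

#' Read run time series back from CSV
#'
#' Inverse of the CSV written by [writeTimeSeries()].
#'
#' @param csvPath path of a tidy time-series CSV.
#' @return list with one sectors x frames matrix per variable plus the
#'   network-level `veto`, `lsl` and `lsl_label` vectors.
#' @export
readTimeSeries <- function(csvPath) {
  df <- read.csv(csvPath, colClasses = c("integer", "integer", "character",
                                         "character"))
  nT <- max(df$frame)
  out <- list()
  for (v in .run_variables) {
    sub <- df[df$variable == v & !is.na(df$sector), ]
    mat <- matrix(as.numeric(sub$value), nrow = max(sub$sector), ncol = nT)
    mat[cbind(sub$sector, sub$frame)] <- as.numeric(sub$value)
    out[[v]] <- mat
  }
  net <- function(v) df[df$variable == v & is.na(df$sector), ]
  out$veto <- as.integer(net("veto")$value)
  suppressWarnings(out$lsl <- as.numeric(net("lsl")$value))
  out$lsl_label <- ifelse(net("lsl_label")$value == "NA", NA_character_,
                          net("lsl_label")$value)
  out
}

#' Event summary of a run
#'
#' @param run an [MLG1Run-class].
#' @return list with `firstSpikeFrame` and `firstAlarmFrame` (one entry per
#'   sector) and the `lslTrace` data.frame of distinct localization reports.
#' @export
eventSummary <- function(run) {
  S4Vectors::metadata(run)$events
}

#' Write a run manifest
#'
#' A JSON manifest capturing everything needed to reproduce a run: the full
#' configuration snapshot, the input identifier (path, or fixture name plus
#' seed), the package version, the event summary and the list of output
#' files written alongside.
#'
#' @param run an [MLG1Run-class].
#' @param path manifest path.
#' @param input character identifier of the input (file path or
#'   `"fixture:<name>:<seed>"`).
#' @param outputs character vector of output files the manifest refers to.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(run, path, input = "unknown",
                             outputs = character(0)) {
  md <- S4Vectors::metadata(run)
  ev <- md$events
  jsonlite::write_json(
    list(
      software = list(package = "crabloom",
                      version = as.character(packageVersion("crabloom"))),
      input = input,
      config = md$config,
      geometry = md$geometry,
      events = list(firstSpikeFrame = ev$firstSpikeFrame,
                    firstAlarmFrame = ev$firstAlarmFrame,
                    lslTrace = ev$lslTrace),
      outputs = outputs
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Per-sector activation panel plot
#'
#' Draws the 16 sector activation traces (with spike frames shaded) in a
#' 4x4 panel layout, mirroring how this family of models is usually
#' inspected.
#'
#' @param run an [MLG1Run-class].
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, `NULL` (or `file`).
#' @importFrom graphics abline axis lines mtext par plot rect
#' @importFrom grDevices dev.off png
#' @export
plotSectorActivation <- function(run, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  M <- SummarizedExperiment::assay(run, "M")
  sp <- SummarizedExperiment::assay(run, "spike")
  Ts <- S4Vectors::metadata(run)$config$T_s
  nS <- nrow(M)
  op <- graphics::par(mfrow = c(4, ceiling(nS / 4)), mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  for (j in seq_len(nS)) {
    graphics::plot(M[j, ], type = "l", col = "blue", ylim = c(0.45, 1),
                   xlab = "", ylab = "", main = paste0("MLG1_", j),
                   cex.main = 0.9)
    w <- which(sp[j, ] == 1L)
    if (length(w)) {
      graphics::rect(w - 0.5, 0.45, w + 0.5, 1, col = grDevices::rgb(1, 0, 0, 0.2),
                     border = NA)
    }
    graphics::abline(h = Ts, lty = 3, col = "gray40")
  }
  invisible(file)
}
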