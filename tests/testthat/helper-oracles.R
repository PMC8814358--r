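# Independent brute-force references used by the unit and acceptance tests.
suppressPackageStartupMessages(library(SummarizedExperiment))

# direct-summation 3x3 convolution with zero padding (nested loops)
convBrute <- function(x, kernel) {
  H <- nrow(x)
  W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di
          jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            acc <- acc + kernel[di + 2, dj + 2] * x[ii, jj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# counting oracle for the alarm rule
alarmOracle <- function(buf, n_sp) {
  cnt <- 0L
  for (b in buf) cnt <- cnt + as.integer(b == 1L)
  as.integer(cnt >= n_sp)
}

# all binary vectors of length n as rows
allBits <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# run a rendered stimulus through the network with defaults
runStimulus <- function(spec, config = mlg1Config()) {
  runMLG1s(renderSequence(spec), config)
}

# does a numeric LSL report (sector index or half-index) cover an azimuth?
lslCoversAzimuth <- function(report, azimuthDeg, nSectors = 16, fovDeg = 37.5) {
  if (is.na(report)) return(FALSE)
  sectors <- if (report %% 1 == 0) {
    report
  } else {
    lo <- floor(report)
    c(lo, lo %% nSectors + 1)
  }
  any(vapply(sectors, function(s) {
    d <- ((azimuthDeg - (s - 1) * 360 / nSectors + 180) %% 360) - 180
    abs(d) <= fovDeg / 2
  }, logical(1)))
}
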