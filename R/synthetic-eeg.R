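#' Generate a synthetic epileptiform-discharge epoch
#'
#' Emulates the statistical structure of a multichannel EEG epoch around a
#' spontaneous epileptiform discharge (ED): the pre-ED and post-ED
#' background segments follow a sparse stationary VAR(1) on a random
#' coupling network; the ED segment follows a denser, more strongly coupled
#' network and carries a superposed high-amplitude slow oscillation
#' (3 Hz by convention, spike-wave-like in rate only). Segments are
#' cross-faded, and the realized ED boundaries are recorded.
#'
#' @param nChannels channel count (default 44, as in the clinical montage).
#' @param fs sampling rate in Hz.
#' @param preDur,postDur background durations in seconds (10 s each by
#'   convention).
#' @param edDurRange range the ED duration is drawn from, in seconds.
#' @param edFreq frequency of the superposed ED oscillation (Hz).
#' @param edAmplitude oscillation amplitude relative to the background
#'   standard deviation.
#' @param bgDensity,edDensity wiring probabilities of the background and ED
#'   coupling networks.
#' @param crossfade cross-fade duration at the segment boundaries (s).
#' @param seed RNG seed; the epoch is reproducible under it.
#' @return an \linkS4class{EdEpoch}.
#' @export
generateEdEpoch <- function(nChannels = 44, fs = 200, preDur = 10,
                            postDur = 10, edDurRange = c(2, 6), edFreq = 3,
                            edAmplitude = 4, bgDensity = 0.05,
                            edDensity = 0.15, crossfade = 0.1, seed = NULL) {
  labels <- head(tenTenMontage()$label, nChannels)
  if (length(labels) < nChannels) stop("not enough montage labels for the requested channel count")
  withSeed(seed, {
    edDur <- runif(1, edDurRange[1], edDurRange[2])
    nPre <- round(preDur * fs); nPost <- round(postDur * fs)
    nEd <- round(edDur * fs)
    bgNet <- generateNetwork("RAND", nChannels, params = list(p = bgDensity))
    edNet <- generateNetwork("RAND", nChannels, params = list(p = edDensity))
    bgProc <- stabilizeVar(bgNet)
    edProc <- stabilizeVar(edNet, margin = 0.02)   # closer to instability: stronger coupling
    pad <- round(crossfade * fs)
    pre  <- values(simulateVar(bgProc, nPre + pad, transient = 200))
    ed   <- values(simulateVar(edProc, nEd + 2 * pad, transient = 200))
    post <- values(simulateVar(bgProc, nPost + pad, transient = 200))
    bgSd <- stats::sd(pre)
    tEd <- (seq_len(nEd + 2 * pad) - 1) / fs
    osc <- edAmplitude * bgSd *
      sin(2 * pi * edFreq * tEd + runif(1, 0, 2 * pi)) %o%
      runif(nChannels, 0.5, 1.5)
    ed <- ed + osc
    X <- matrix(0, nPre + nEd + nPost, nChannels)
    X[seq_len(nPre), ] <- pre[seq_len(nPre), ]
    X[nPre + seq_len(nEd), ] <- ed[pad + seq_len(nEd), ]
    X[nPre + nEd + seq_len(nPost), ] <- post[pad + seq_len(nPost), ]
    if (pad > 0) {
      # cross-fade the pads centred on each boundary
      w <- seq(0, 1, length.out = 2 * pad)
      i1 <- nPre - pad + seq_len(2 * pad)
      X[i1, ] <- pre[nPre - pad + seq_len(2 * pad), ] * (1 - w) +
        ed[seq_len(2 * pad), ] * w
      i2 <- nPre + nEd - pad + seq_len(2 * pad)
      X[i2, ] <- ed[nEd + seq_len(2 * pad), ] * (1 - w) +
        post[seq_len(2 * pad), ] * w
    }
    colnames(X) <- labels
    sig <- new("MultiTS", values = X, samplingInterval = 1 / fs,
               space = "sensor")
    new("EdEpoch", signal = sig, edStart = nPre / fs,
        edEnd = (nPre + nEd) / fs, background = bgNet, edNetwork = edNet)
  })
}

#' Band-pass filter and downsample a multichannel series
#'
#' Zero-phase Butterworth filtering (applied forward-backward) followed by
#' integer-factor decimation with anti-alias filtering: the low-pass edge is
#' applied at the input rate, the series is decimated to \code{fsTarget},
#' and the (very low) high-pass edge is applied at the output rate where it
#' is numerically well conditioned. The whole chain is linear.
#'
#' @param ts a \linkS4class{MultiTS} (samplingInterval = 1/fs seconds).
#' @param band c(low, high) pass band in Hz.
#' @param fsTarget output rate; must divide the input rate.
#' @return the filtered, downsampled \linkS4class{MultiTS}.
#' @export
preprocessTS <- function(ts, band = c(0.01, 70), fsTarget = 200) {
  stopifnot(is(ts, "MultiTS"))
  fs <- 1 / ts@samplingInterval
  if (band[2] >= fs / 2) stop("upper band edge must lie below the input Nyquist frequency")
  if (band[2] >= fsTarget / 2) stop("upper band edge must lie below the output Nyquist frequency")
  if (fsTarget > fs) stop("fsTarget must not exceed the input rate")
  q <- fs / fsTarget
  if (abs(q - round(q)) > 1e-9) stop("fsTarget must divide the input rate")
  q <- round(q)
  X <- ts@values
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  Y <- apply(X, 2, function(col) signal::filtfilt(lp, col))
  if (q > 1)
    Y <- apply(Y, 2, function(col)
      signal::decimate(col, q, ftype = "fir"))
  hp <- signal::butter(2, band[1] / (fsTarget / 2), type = "high")
  Y <- apply(Y, 2, function(col) signal::filtfilt(hp, col))
  colnames(Y) <- colnames(X)
  new("MultiTS", values = Y, samplingInterval = 1 / fsTarget,
      space = ts@space)
}

#' Sliding windows over an ED epoch
#'
#' Windows of \code{width} seconds at every \code{step} from the epoch
#' start while fully inside the epoch. Each window is labelled preED, ED or
#' postED by the period holding the majority of its extent; an exact 50/50
#' split goes to the later period.
#'
#' @param epoch an \linkS4class{EdEpoch}.
#' @param width,step window width and sliding step in seconds (reference
#'   convention: 2 s and 0.5 s).
#' @return a \linkS4class{WindowSet}.
#' @export
makeWindows <- function(epoch, width = 2, step = 0.5) {
  stopifnot(is(epoch, "EdEpoch"))
  dur <- nrow(epoch@signal@values) * epoch@signal@samplingInterval
  if (width > dur) stop("window width exceeds the epoch duration")
  starts <- seq(0, dur - width, by = step)
  b1 <- epoch@edStart; b2 <- epoch@edEnd
  lab <- vapply(starts, function(s) {
    e <- s + width
    ov <- c(preED  = max(0, min(e, b1) - s),
            ED     = max(0, min(e, b2) - max(s, b1)),
            postED = max(0, e - max(s, b2)))
    # majority overlap; ties go to the later period
    names(ov)[max(which(ov == max(ov)))]
  }, "")
  new("WindowSet",
      windows = data.frame(start = starts, end = starts + width, label = lab,
                           stringsAsFactors = FALSE),
      width = width, step = step)
}

#' Extract one window of a series
#'
#' @param ts a \linkS4class{MultiTS}.
#' @param start,end window boundaries in the series' time units.
#' @return the windowed \linkS4class{MultiTS}.
#' @export
windowSlice <- function(ts, start, end) {
  dt <- ts@samplingInterval
  i0 <- floor(start / dt) + 1
  i1 <- min(nrow(ts@values), ceiling(end / dt))
  new("MultiTS", values = ts@values[i0:i1, , drop = FALSE],
      samplingInterval = dt, space = ts@space)
}

#' Write / read a multichannel series as CSV with a JSON sidecar
#'
#' Rows are time points, the header holds channel labels; the sidecar
#' records the sampling interval and space tag (and any extra metadata
#' supplied). This is also the ingestion point for external recordings
#' exported as CSV.
#'
#' @param ts a \linkS4class{MultiTS}.
#' @param path file path without extension (\code{.csv} / \code{.json}
#'   appended).
#' @param meta extra metadata stored in the sidecar.
#' @return \code{writeTimeSeries} returns \code{path} invisibly;
#'   \code{readTimeSeries} the reconstructed \linkS4class{MultiTS}.
#' @export
writeTimeSeries <- function(ts, path, meta = list()) {
  utils::write.csv(as.data.frame(ts@values), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(list(samplingInterval = ts@samplingInterval, space = ts@space), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @param samplingInterval,space fallbacks when no sidecar is present.
#' @export
readTimeSeries <- function(path, samplingInterval = 1, space = "sensor") {
  X <- as.matrix(utils::read.csv(paste0(path, ".csv"), check.names = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    samplingInterval <- meta$samplingInterval
    space <- meta$space
  }
  new("MultiTS", values = X, samplingInterval = samplingInterval,
      space = space)
}
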