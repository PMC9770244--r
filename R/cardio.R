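# Heart-rate estimation from intensity-trace videos: ROI mean trace,
# [-1, 1] normalisation, power-of-two zero padding, FFT fundamental.

#' Read a video as a frame list
#'
#' Multi-page TIFF, one page per frame, each returned as a `[y, x]` matrix.
#'
#' @param path TIFF file.
#' @return list of matrices.
#' @export
readVideo <- function(path) {
  if (!file.exists(path)) stop("cannot read video: ", path)
  frames <- readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) if (length(dim(f)) == 3L) f[, , 1L] else f)
}

#' Mean-intensity ROI trace of a video
#'
#' @param video list of `[y, x]` frame matrices (or a `[y, x, t]` array),
#'   at least 2 frames.
#' @param roi `(x, y, w, h)` rectangle in pixels, 1-based corner, fully
#'   inside the frames.
#' @param frameRate frames per second.
#' @return A [HeartRateTrace-class].
#' @export
roiTrace <- function(video, roi, frameRate) {
  if (is.array(video) && length(dim(video)) == 3L)
    video <- lapply(seq_len(dim(video)[3]), function(t) video[, , t])
  if (length(video) < 2L) stop("video needs >= 2 frames")
  d <- dim(video[[1L]])
  x <- roi[1L]; y <- roi[2L]; w <- roi[3L]; h <- roi[4L]
  if (w < 1L || h < 1L || x < 1L || y < 1L ||
      x + w - 1L > d[2L] || y + h - 1L > d[1L])
    stop("roi out of frame bounds")
  vals <- vapply(video, function(f)
    mean(f[y:(y + h - 1L), x:(x + w - 1L)]), numeric(1))
  HeartRateTrace(vals, frameRate, roi)
}

#' Normalise a trace to the range -1 to 1
#'
#' Affine map `x -> 2 (x - min) / (max - min) - 1`; the minimum maps to -1
#' and the maximum to +1, absorbing camera gain and offset.  A constant
#' trace carries no pulsatile signal and is an error.
#'
#' @param trace a [HeartRateTrace-class].
#' @return a normalised [HeartRateTrace-class].
#' @export
normalizeTrace <- function(trace) {
  stopifnot(is(trace, "HeartRateTrace"))
  v <- trace@values
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("no pulsatile signal: constant intensity trace")
  HeartRateTrace(2 * (v - rng[1L]) / (rng[2L] - rng[1L]) - 1,
                 trace@frameRate, trace@roi)
}

#' Zero-pad a trace to the next power of two
#'
#' Appends zeros until the length is the smallest power of two at or above
#' the original length, as the FFT step expects; the leading values are
#' untouched.
#'
#' @param trace a [HeartRateTrace-class] or numeric vector.
#' @return same type as the input, padded.
#' @export
padPow2 <- function(trace) {
  v <- if (is(trace, "HeartRateTrace")) trace@values else as.numeric(trace)
  if (length(v) < 1L) stop("empty trace")
  n2 <- 2^ceiling(log2(length(v)))
  out <- c(v, rep(0, n2 - length(v)))
  if (is(trace, "HeartRateTrace"))
    HeartRateTrace(out, trace@frameRate, trace@roi)
  else out
}

#' Heart rate from the FFT of a prepared trace
#'
#' Discrete Fourier transform of the (normalised, padded) trace; the
#' fundamental frequency is the power argmax over the bins inside the
#' physiological search band (which excludes the DC bin and low-frequency
#' drift by construction), and BPM = 60 times that frequency.  No peak
#' interpolation is applied; the spectral resolution
#' `frameRate / length(trace)` is reported alongside.
#'
#' @param trace a [HeartRateTrace-class] (normalised, padded) or numeric
#'   vector.
#' @param frameRate frames per second (taken from the trace when omitted).
#' @param band `(lo, hi)` Hz with `0 < lo < hi < frameRate / 2`; default
#'   `(0.5, 5)` Hz = 30-300 BPM.
#' @return A [HeartRateResult-class].
#' @export
bpmFromFft <- function(trace, frameRate = NULL, band = c(0.5, 5)) {
  v <- if (is(trace, "HeartRateTrace")) trace@values else as.numeric(trace)
  if (is.null(frameRate)) {
    stopifnot(is(trace, "HeartRateTrace"))
    frameRate <- trace@frameRate
  }
  stopifnot(length(band) == 2L, band[1L] > 0, band[2L] > band[1L])
  if (band[2L] >= frameRate / 2)
    stop("band upper edge must be below the Nyquist frequency")
  n <- length(v)
  pw <- Mod(stats::fft(v))^2
  freq <- (seq_len(n) - 1L) * frameRate / n
  keep <- freq <= frameRate / 2
  spectrum <- data.frame(freq_hz = freq[keep], power = pw[keep])
  inBand <- spectrum$freq_hz >= band[1L] & spectrum$freq_hz <= band[2L]
  if (!any(inBand)) stop("search band is empty after discretization")
  sub <- spectrum[inBand, ]
  peak <- sub$freq_hz[which.max(sub$power)]
  new("HeartRateResult", bpm = 60 * peak, peakHz = peak,
      resolutionHz = frameRate / n, spectrum = spectrum,
      band = as.numeric(band))
}

#' Estimate heart rate from a video
#'
#' Composition [roiTrace()] -> [normalizeTrace()] -> [padPow2()] ->
#' [bpmFromFft()].
#'
#' @inheritParams roiTrace
#' @inheritParams bpmFromFft
#' @return A [HeartRateResult-class].
#' @examples
#' vid <- genHeartVideo(bpm = 120, fps = 24, seconds = 12, noiseSd = 0,
#'                      seed = 1)
#' bpm(estimateHeartRate(vid, roi = c(17, 17, 32, 32), frameRate = 24))
#' @export
estimateHeartRate <- function(video, roi, frameRate, band = c(0.5, 5)) {
  tr <- roiTrace(video, roi, frameRate)
  bpmFromFft(padPow2(normalizeTrace(tr)), band = band)
}
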