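# Audio rendering of contour stimuli (harmonic complex with odd partials) and
# autocorrelation F0 estimation. Validation/demo only: the analysis pipeline
# consumes breakpoint shifts, never audio.

#' Waveform container
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"waveform"` with `samples`, `sample_rate` and
#'   `duration` (ms).
#' @export
waveform <- function(samples, sample_rate) {
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = 1000 * length(samples) / sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), peak %.3f\n",
              length(x$samples), x$sample_rate, x$duration,
              max(abs(x$samples))))
  invisible(x)
}

# Additive synthesis of a harmonic complex following a cents contour.
# Instantaneous F0 f(t) = base_f0 * 2^(c(t)/1200); partial m runs at m*f(t)
# with sine phase at onset; phase accumulated by integrating frequency so the
# contour glides continuously.
synthesize_harmonic <- function(shifts, config, sample_rate, partials,
                                peak_dbfs, ramp_ms) {
  n <- round(config$duration / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  cents <- contour_at(shifts, config, t)
  f0 <- config$base_f0 * 2^(cents / 1200)
  phase <- 2 * pi * cumsum(f0) / sample_rate   # fundamental phase (radians)
  x <- rep(0, n)
  for (m in partials) x <- x + sin(m * phase)
  # raised-cosine onset/offset ramps
  nr <- min(round(ramp_ms / 1000 * sample_rate), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  x <- x / max(abs(x)) * 10^(peak_dbfs / 20)
  w <- waveform(x, sample_rate)
  w$peak_dbfs <- peak_dbfs
  w
}

#' Render a contour stimulus as a harmonic complex tone
#'
#' Additive synthesis of the fundamental plus its seven odd harmonics
#' (partials 1, 3, 5, ..., 15 times F0) at equal amplitude with sine phase,
#' giving a clarinet-like quality. The instantaneous fundamental follows the
#' pitch contour, `f(t) = base_f0 * 2^(c(t)/1200)`.
#'
#' @param stimulus A `"contour_stimulus"` or numeric shift vector (cents).
#' @param config The matching [noise_config()].
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param partials Harmonic numbers to include (default the fundamental and
#'   its seven odd harmonics). A single-element vector gives a pure tone, a
#'   convenient test hook.
#' @param peak_dbfs Peak level after normalization, in dBFS (default -3).
#' @param ramp_ms Raised-cosine onset/offset ramp in ms (default 5).
#' @return A `"waveform"`.
#' @export
render_harmonic_tone <- function(stimulus, config, sample_rate = 44100,
                                 partials = c(1, 3, 5, 7, 9, 11, 13, 15),
                                 peak_dbfs = -3, ramp_ms = 5) {
  if (config$base_f0 <= 0) stop("base_f0 must be > 0", call. = FALSE)
  shifts <- if (inherits(stimulus, "contour_stimulus")) stimulus$shifts
            else as.numeric(stimulus)
  if (length(shifts) != config$n_breakpoints)
    stop("shift vector length does not match config$n_breakpoints",
         call. = FALSE)
  synthesize_harmonic(shifts, config, sample_rate, partials, peak_dbfs,
                      ramp_ms)
}

#' Render a melody stimulus
#'
#' Renders a 3-note melody contour (square breakpoint function with 0.1 s
#' transitions) as a harmonic complex on the melody base (260 Hz, 1380 ms).
#'
#' @inheritParams render_harmonic_tone
#' @return A `"waveform"`.
#' @export
render_melody <- function(stimulus, config, sample_rate = 44100,
                          partials = c(1, 3, 5, 7, 9, 11, 13, 15),
                          peak_dbfs = -3, ramp_ms = 5) {
  shifts <- if (inherits(stimulus, "contour_stimulus")) stimulus$shifts
            else as.numeric(stimulus)
  if (length(shifts) != config$n_breakpoints ||
      config$interpolation != "square_bpf")
    stop("render_melody needs a square-BPF config with matching breakpoints",
         call. = FALSE)
  render_harmonic_tone(shifts, config, sample_rate, partials, peak_dbfs,
                       ramp_ms)
}

# Autocorrelation F0 of one frame; parabolic interpolation of the peak lag.
frame_f0 <- function(x, sample_rate, fmin, fmax) {
  x <- x - mean(x)
  if (max(abs(x)) < 1e-6) return(NA_real_)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  s <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(s)^2, inverse = TRUE))[seq_len(n)]
  ac <- ac / ac[1L]
  lo <- max(2L, floor(sample_rate / fmax))
  hi <- min(n - 1L, ceiling(sample_rate / fmin))
  if (hi <= lo) return(NA_real_)
  lags <- lo:hi
  k <- lags[which.max(ac[lags + 1L])]
  # parabolic refinement around the peak
  y1 <- ac[k]; y2 <- ac[k + 1L]; y3 <- ac[k + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  sample_rate / (k + delta)
}

#' Estimate the fundamental frequency of a waveform
#'
#' Frame-based autocorrelation pitch tracking: each analysis frame's F0 is the
#' lag of the autocorrelation peak within the search band, refined by
#' parabolic interpolation; the whole-stimulus estimate is the median over
#' frames.
#'
#' @param wave A `"waveform"`.
#' @param frame Optional `c(start, end)` analysis window in seconds; default
#'   the whole waveform.
#' @param fmin,fmax F0 search band in Hz.
#' @param frame_ms Analysis frame length in ms.
#' @param hop_ms Hop between frames in ms.
#' @return Estimated F0 in Hz (median over frames).
#' @export
estimate_f0 <- function(wave, frame = NULL, fmin = 60, fmax = 600,
                        frame_ms = 50, hop_ms = 25) {
  x <- wave$samples
  fs <- wave$sample_rate
  if (!is.null(frame)) {
    i0 <- max(1L, floor(frame[1] * fs) + 1L)
    i1 <- min(length(x), ceiling(frame[2] * fs))
    x <- x[i0:i1]
  }
  if (length(x) == 0 || max(abs(x)) < 1e-6)
    stop("cannot estimate F0 of silent input", call. = FALSE)
  flen <- round(frame_ms / 1000 * fs)
  hop <- max(1L, round(hop_ms / 1000 * fs))
  if (length(x) <= flen)
    return(frame_f0(x, fs, fmin, fmax))
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  f0s <- vapply(starts, function(s) frame_f0(x[s:(s + flen - 1L)], fs,
                                             fmin, fmax), numeric(1))
  f0s <- f0s[is.finite(f0s)]
  if (length(f0s) == 0) stop("no voiced frames found", call. = FALSE)
  stats::median(f0s)
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE I/O for mono PCM16, sufficient to export rendered
#' stimuli and reload them bit-faithfully.
#'
#' @param wave A `"waveform"`.
#' @param path Output file path.
#' @return `read_wav()` returns a `"waveform"`.
#' @export
write_wav <- function(wave, path) {
  x <- pmin(1, pmax(-1, wave$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 2L), con, size = 4,
           endian = "little")                              # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file", call. = FALSE)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk", call. = FALSE)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8L))
      if (fmt[1L] != 1L || fmt[2L] != 1L)
        stop("only mono PCM supported", call. = FALSE)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2,
                     endian = "little")
      return(waveform(pcm / 32767, sample_rate))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
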