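#' Two-channel sampled audio signal
#'
#' The basic container for all stimulus construction: a left and a right
#' amplitude sequence sampled at a common rate. Amplitudes are dimensionless
#' with nominal full scale at +/- 1.
#'
#' @param left,right Numeric vectors of equal length; all samples finite.
#' @param rate Sampling rate in samples per second.
#' @return An object of class `stereo_waveform` (a list with elements
#'   `left`, `right`, `rate`).
#' @examples
#' w <- stereo_waveform(sin(2 * pi * 440 * (0:999) / 8000),
#'                      sin(2 * pi * 440 * (0:999) / 8000), rate = 8000)
#' n_samples(w)
#' @export
stereo_waveform <- function(left, right, rate) {
  if (!is.numeric(left) || !is.numeric(right)) {
    stop("`left` and `right` must be numeric vectors", call. = FALSE)
  }
  if (length(left) != length(right)) {
    stop("`left` and `right` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(left)) || !all(is.finite(right))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 rate = rate),
            class = "stereo_waveform")
}

#' @export
print.stereo_waveform <- function(x, ...) {
  cat(sprintf("<stereo_waveform: %d samples @ %g Hz (%.3f s), peak %.4f>\n",
              length(x$left), x$rate, length(x$left) / x$rate,
              max(abs(c(x$left, x$right)))))
  invisible(x)
}

#' Number of samples in a stereo waveform
#' @param w A `stereo_waveform`.
#' @return Integer number of samples per channel.
#' @export
n_samples <- function(w) length(w$left)

#' Is a waveform diotic?
#'
#' A diotic waveform delivers the identical signal to both ears
#' (left == right sample for sample).
#' @param w A `stereo_waveform`.
#' @param tol Absolute tolerance; 0 demands exact equality.
#' @return Logical scalar.
#' @export
is_diotic <- function(w, tol = 0) {
  if (tol == 0) identical(w$left, w$right) else max(abs(w$left - w$right)) <= tol
}

#' Root-mean-square amplitude
#' @param x Numeric vector.
#' @return RMS of `x`.
#' @export
rms <- function(x) sqrt(mean(x^2))

## ---- seeded randomness -----------------------------------------------------

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' One master seed drives a whole pool or cohort; per-trial (or per-subject)
#' seeds are derived by a fixed multiplicative scheme so that any single
#' trial can be regenerated in isolation. The derivation is
#' `(seed * 48271 + index) mod (2^31 - 1)` (exact in double precision).
#'
#' @param seed Master seed (non-negative integer below 2^31).
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), all(index >= 0))
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647)
}

## ---- primitive generators --------------------------------------------------

#' Generate Gaussian white noise
#'
#' Draws a zero-mean Gaussian time sequence (flat spectrum out to Nyquist)
#' and normalizes it to a fixed RMS level. This is the raw material for the
#' Huggins Pitch stimulus.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param rate Sampling rate in samples/second (default 44100).
#' @param seed Optional integer seed; the same seed always reproduces the
#'   same sequence.
#' @param rms_level Target RMS amplitude re full scale (default 0.05).
#' @return Numeric vector of `round(duration_s * rate)` samples.
#' @examples
#' x <- generate_white_noise(0.5, rate = 8000, seed = 1)
#' length(x)
#' @export
generate_white_noise <- function(duration_s, rate = 44100, seed = NULL,
                                 rms_level = 0.05) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) {
    stop("`rate` must be positive", call. = FALSE)
  }
  n <- round(duration_s * rate)
  x <- with_seed(seed, stats::rnorm(n))
  x * (rms_level / rms(x))
}

#' Apply raised-cosine onset and offset ramps
#'
#' Multiplies the first and last `ramp_s` seconds by half-cosine gates
#' (gain 0.5 * (1 - cos(pi * t / ramp_s))), leaving the interior untouched.
#' Works on mono vectors or `stereo_waveform`s (both channels gated
#' identically).
#'
#' @param x Numeric vector or `stereo_waveform`.
#' @param ramp_s Ramp duration in seconds; `2 * ramp_s` must not exceed the
#'   waveform duration. A zero ramp is a no-op.
#' @param rate Sampling rate (ignored for `stereo_waveform`, which carries
#'   its own).
#' @return Object of the same type as `x`.
#' @export
apply_ramp <- function(x, ramp_s, rate = 44100) {
  if (inherits(x, "stereo_waveform")) {
    return(stereo_waveform(apply_ramp(x$left, ramp_s, x$rate),
                           apply_ramp(x$right, ramp_s, x$rate),
                           x$rate))
  }
  if (ramp_s < 0) stop("`ramp_s` must be non-negative", call. = FALSE)
  if (ramp_s == 0) return(x)
  n <- length(x)
  nr <- round(ramp_s * rate)
  if (2 * nr > n) {
    stop("ramp longer than half the waveform duration", call. = FALSE)
  }
  if (nr == 0) return(x)
  g <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  x[1:nr] <- x[1:nr] * g
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(g)
  x
}

## Scale both channels so the target interval RMS is met; no-op guard keeps
## the peak under full scale.
normalize_rms <- function(w, rms_level = 0.05) {
  r <- rms(c(w$left, w$right))
  if (r == 0) return(w)
  s <- rms_level / r
  peak <- max(abs(c(w$left, w$right))) * s
  if (peak > 1) s <- s / peak
  stereo_waveform(w$left * s, w$right * s, w$rate)
}

## ---- spectral helpers ------------------------------------------------------

## Indices (1-based, full FFT length) of bins whose center frequency, folded
## to [0, rate/2], lies inside [lo, hi]; DC excluded.
band_bins <- function(n, rate, lo, hi) {
  freq <- (0:(n - 1)) * rate / n
  folded <- pmin(freq, rate - freq)
  which(folded >= lo & folded <= hi & seq_len(n) > 1L)
}

## Mean-square power of `x` restricted to a frequency band, via Parseval.
band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  sum(Mod(X[band_bins(n, rate, lo, hi)])^2) / n^2
}

## Envelope of the analytic signal (Hilbert magnitude), via the one-sided
## spectrum construction.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

## Modulation depth of an envelope at `mod_hz`: 2 |single-bin DFT| / mean.
## The window is truncated to a whole number of modulation periods and the
## mean is removed first, so the DC component cannot leak into the bin.
envelope_depth_at <- function(env, rate, mod_hz) {
  period <- rate / mod_hz
  n <- floor(length(env) / period) * period
  if (n < period) n <- length(env)
  env <- env[seq_len(floor(n))]
  t <- (seq_along(env) - 1) / rate
  m <- mean(env)
  if (m <= 0) return(0)
  2 * Mod(mean((env - m) * exp(-2i * pi * mod_hz * t))) / m
}

## ---- trial assembly and WAV output ----------------------------------------

#' Concatenate a trial's intervals into one stereo waveform
#'
#' Joins the three intervals with `gap_s` seconds of silence between them,
#' as presented to a participant.
#'
#' @param trial A `trial_spec`.
#' @return A `stereo_waveform`.
#' @export
assemble_trial_waveform <- function(trial) {
  stopifnot(inherits(trial, "trial_spec"))
  rate <- trial$intervals[[1]]$rate
  gap <- numeric(round(trial$gap_s * rate))
  left <- right <- numeric(0)
  for (i in seq_along(trial$intervals)) {
    w <- trial$intervals[[i]]
    left <- c(left, w$left, if (i < length(trial$intervals)) gap)
    right <- c(right, w$right, if (i < length(trial$intervals)) gap)
  }
  stereo_waveform(left, right, rate)
}

#' Write a stereo waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit little-endian PCM, channel 0 = left).
#' Samples are clipped to `[-1, 1]` before quantization.
#'
#' @param w A `stereo_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "stereo_waveform"))
  n <- n_samples(w)
  interleaved <- as.vector(rbind(pmax(pmin(w$left, 1), -1),
                                 pmax(pmin(w$right, 1), -1)))
  pcm <- as.integer(round(interleaved * 32767))
  data_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(2L, con, size = 2, endian = "little")           # channels
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM stereo WAV file
#'
#' Companion reader for [write_wav()]; supports only the format that writer
#' emits (stereo, 16-bit PCM).
#'
#' @param path WAV file path.
#' @return A `stereo_waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk", call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 2L) {
        stop("only stereo PCM supported", call. = FALSE)
      }
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      ba <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit PCM supported", call. = FALSE)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      x <- pcm / 32767
      idx <- seq(1, length(x), by = 2)
      return(stereo_waveform(x[idx], x[idx + 1], rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}
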