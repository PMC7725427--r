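## Stimulus recipes for the three screening tests.
##
## HP: three intervals of white noise; the target interval carries a 180
## degree interaural phase shift in a narrow band around 600 Hz (Huggins
## Pitch), audible only under dichotic presentation.
## AP: three 200-Hz tones; target at -6 dB, foil in interaural anti-phase.
## BT: three tone pairs 30 Hz apart; standards beat monaurally, the target
## splits the pair across ears and sounds smooth over headphones.

#' Configuration for the Huggins Pitch test stimulus
#'
#' @param center_hz Center frequency of the phase-shifted band (Hz).
#' @param band_fraction Half-width of the band as a fraction of
#'   `center_hz`; the shifted band is
#'   `[center_hz * (1 - band_fraction), center_hz * (1 + band_fraction)]`.
#' @param phase_shift Interaural phase shift in radians. Only `pi`
#'   (exact polarity inversion of the in-band components) is supported;
#'   it is implemented as multiplication by -1, which is numerically exact.
#' @param duration_s Interval duration in seconds.
#' @param onset_ramp_s Raised-cosine on/off ramp for the noise intervals,
#'   in seconds. Applied to the noise before the dichotic transform so
#'   that left and right keep identical magnitude spectra; set to 0 to
#'   disable.
#' @param rate Sampling rate (samples/second).
#' @param gap_s Silent gap between intervals in seconds.
#' @param rms_level Per-interval RMS normalization target re full scale.
#' @return A validated list of class `hp_config`.
#' @export
hp_config <- function(center_hz = 600, band_fraction = 0.06,
                      phase_shift = pi, duration_s = 1.0,
                      onset_ramp_s = 0.005, rate = 44100,
                      gap_s = 0.5, rms_level = 0.05) {
  cfg <- structure(list(center_hz = center_hz, band_fraction = band_fraction,
                        phase_shift = phase_shift, duration_s = duration_s,
                        onset_ramp_s = onset_ramp_s, rate = rate,
                        gap_s = gap_s, rms_level = rms_level),
                   class = c("hp_config", "stim_config"))
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (band_fraction < 0 || band_fraction >= 1) {
    stop("`band_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (center_hz * (1 + band_fraction) >= rate / 2) {
    stop("phase-shifted band exceeds the Nyquist frequency", call. = FALSE)
  }
  if (!isTRUE(all.equal(phase_shift, pi))) {
    stop("only a 180-degree (`pi`) phase shift is supported", call. = FALSE)
  }
  cfg
}

#' Configuration for the anti-phase tone test stimulus
#'
#' @param tone_hz Tone frequency (Hz).
#' @param target_level_db Target level relative to the standard, in dB
#'   (must be negative: the target is the quieter tone).
#' @param duration_s Tone duration in seconds, ramps included.
#' @param ramp_s Raised-cosine onset/offset ramp duration (seconds).
#' @param rate Sampling rate.
#' @param gap_s Silent gap between intervals (seconds).
#' @param rms_level Standard-tone RMS normalization target.
#' @return A validated list of class `ap_config`.
#' @export
ap_config <- function(tone_hz = 200, target_level_db = -6, duration_s = 1.0,
                      ramp_s = 0.1, rate = 44100, gap_s = 0.5,
                      rms_level = 0.05) {
  if (target_level_db == 0) {
    stop("degenerate target: `target_level_db` must be nonzero", call. = FALSE)
  }
  if (target_level_db > 0) {
    stop("`target_level_db` must be negative", call. = FALSE)
  }
  if (2 * ramp_s > duration_s) {
    stop("ramps longer than the tone", call. = FALSE)
  }
  structure(list(tone_hz = tone_hz, target_level_db = target_level_db,
                 duration_s = duration_s, ramp_s = ramp_s, rate = rate,
                 gap_s = gap_s, rms_level = rms_level),
            class = c("ap_config", "stim_config"))
}

#' Configuration for the beat test stimulus
#'
#' @param f1_min_hz,f1_max_hz Range the lower tone frequency f1 is drawn
#'   from, uniformly per trial (Hz).
#' @param beat_hz Frequency separation; the upper tone is `f1 + beat_hz`.
#' @param duration_s Interval duration (seconds).
#' @param ramp_s Raised-cosine ramp duration (seconds; 5 ms default).
#' @param rove_db_max Per-interval level rove: each interval is attenuated
#'   by an independent uniform draw from `[0, rove_db_max]` dB, so relative
#'   interval levels differ by 0 to `rove_db_max` dB.
#' @param rate Sampling rate.
#' @param gap_s Silent gap between intervals (seconds).
#' @param rms_level Per-channel RMS normalization target before the rove.
#' @return A validated list of class `bt_config`.
#' @export
bt_config <- function(f1_min_hz = 1800, f1_max_hz = 2500, beat_hz = 30,
                      duration_s = 1.0, ramp_s = 0.005, rove_db_max = 4,
                      rate = 44100, gap_s = 0.5, rms_level = 0.05) {
  if (f1_max_hz + beat_hz >= rate / 2) {
    stop("upper tone exceeds the Nyquist frequency", call. = FALSE)
  }
  if (rove_db_max < 0) stop("`rove_db_max` must be >= 0", call. = FALSE)
  if (f1_min_hz > f1_max_hz) stop("`f1_min_hz` > `f1_max_hz`", call. = FALSE)
  structure(list(f1_min_hz = f1_min_hz, f1_max_hz = f1_max_hz,
                 beat_hz = beat_hz, duration_s = duration_s, ramp_s = ramp_s,
                 rove_db_max = rove_db_max, rate = rate, gap_s = gap_s,
                 rms_level = rms_level),
            class = c("bt_config", "stim_config"))
}

#' Default configuration for a test kind
#' @param test_kind One of `"HP"`, `"AP"`, `"BT"`.
#' @return The corresponding config object with default parameters.
#' @export
default_config <- function(test_kind) {
  switch(match.arg(test_kind, c("HP", "AP", "BT")),
         HP = hp_config(), AP = ap_config(), BT = bt_config())
}

## ---- Huggins Pitch ---------------------------------------------------------

#' Turn a mono noise into a Huggins Pitch dichotic pair
#'
#' Transforms the noise to the frequency domain, inverts the sign (exact
#' 180-degree phase shift) of every component whose bin center frequency
#' lies inside the configured band (inclusive band edges), mirrors the
#' conjugate bins so the output stays real, and leaves all magnitudes
#' unchanged. The original noise is the left channel; the phase-shifted
#' version is the right channel.
#'
#' @param noise Mono numeric vector (finite).
#' @param cfg An [hp_config()].
#' @return A `stereo_waveform`; left is `noise` unchanged, right has the
#'   identical magnitude spectrum with the in-band components negated.
#' @export
make_huggins_pair <- function(noise, cfg = hp_config()) {
  stopifnot(inherits(cfg, "hp_config"))
  if (!all(is.finite(noise))) stop("noise must be finite", call. = FALSE)
  n <- length(noise)
  lo <- cfg$center_hz * (1 - cfg$band_fraction)
  hi <- cfg$center_hz * (1 + cfg$band_fraction)
  if (hi >= cfg$rate / 2) {
    stop("phase-shifted band exceeds the Nyquist frequency", call. = FALSE)
  }
  # a zero-width band carries no spectral mass: no-op
  bins <- if (cfg$band_fraction == 0) integer(0) else
    band_bins(n, cfg$rate, lo, hi)         # both conjugate halves, DC excluded
  if (length(bins) == 0L) {
    return(stereo_waveform(noise, noise, cfg$rate))
  }
  X <- stats::fft(noise)
  X[bins] <- -X[bins]
  right <- Re(stats::fft(X, inverse = TRUE) / n)
  stereo_waveform(noise, right, cfg$rate)
}

## ---- trial construction ----------------------------------------------------

new_trial_spec <- function(test_kind, target_position, intervals, gap_s,
                           metadata = list()) {
  stopifnot(length(intervals) == 3L, target_position %in% 1:3)
  rates <- vapply(intervals, function(w) w$rate, numeric(1))
  stopifnot(length(unique(rates)) == 1L)
  structure(list(test_kind = test_kind,
                 target_position = as.integer(target_position),
                 intervals = intervals, gap_s = gap_s, metadata = metadata),
            class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("<%s trial: target at position %d, %d intervals of %.0f ms>\n",
              x$test_kind, x$target_position, length(x$intervals),
              1000 * n_samples(x$intervals[[1]]) / x$intervals[[1]]$rate))
  invisible(x)
}

check_target_position <- function(target_position) {
  if (!(length(target_position) == 1L && target_position %in% 1:3)) {
    stop("`target_position` must be 1, 2, or 3", call. = FALSE)
  }
}

#' Build one Huggins Pitch 3AFC trial
#'
#' Three 1000-ms intervals of independent white noise; two are diotic and
#' the target interval carries the dichotic phase-shifted band. Ramps and
#' RMS normalization are applied to the noise before the dichotic
#' transform, so the left/right magnitude-spectrum identity is exact.
#'
#' @param cfg An [hp_config()].
#' @param target_position Which interval (1-3) carries the Huggins pair.
#' @param seed Optional seed; per-interval noise uses child seeds
#'   ([child_seed()]) so the trial is reproducible.
#' @return A `trial_spec`.
#' @export
make_hp_trial <- function(cfg = hp_config(), target_position = sample(3, 1),
                          seed = NULL) {
  check_target_position(target_position)
  seeds <- if (is.null(seed)) rep(list(NULL), 3) else
    as.list(child_seed(seed, 1:3))
  intervals <- lapply(1:3, function(i) {
    noise <- generate_white_noise(cfg$duration_s, cfg$rate, seeds[[i]],
                                  rms_level = cfg$rms_level)
    noise <- apply_ramp(noise, cfg$onset_ramp_s, cfg$rate)
    if (i == target_position) {
      make_huggins_pair(noise, cfg)
    } else {
      stereo_waveform(noise, noise, cfg$rate)
    }
  })
  new_trial_spec("HP", target_position, intervals, cfg$gap_s,
                 metadata = list(seed = seed))
}

#' Build one anti-phase tone 3AFC trial
#'
#' A diotic standard, a diotic target at `target_level_db` (default -6 dB)
#' relative to the standard, and a foil with the standard's per-channel
#' amplitude but opposite polarity across ears. The foil and standard are
#' assigned uniformly at random to the two non-target slots.
#'
#' @param cfg An [ap_config()].
#' @param target_position Which interval (1-3) is the quiet target.
#' @param seed Optional seed (drives the foil/standard slot assignment).
#' @return A `trial_spec`; metadata records the foil position.
#' @export
make_ap_trial <- function(cfg = ap_config(), target_position = sample(3, 1),
                          seed = NULL) {
  check_target_position(target_position)
  n <- round(cfg$duration_s * cfg$rate)
  t <- (0:(n - 1)) / cfg$rate
  tone <- cfg$rms_level * sqrt(2) * sin(2 * pi * cfg$tone_hz * t)
  tone <- apply_ramp(tone, cfg$ramp_s, cfg$rate)
  gain <- 10^(cfg$target_level_db / 20)
  others <- setdiff(1:3, target_position)
  foil_pos <- with_seed(seed, sample(others, 1))
  intervals <- lapply(1:3, function(i) {
    if (i == target_position) {
      stereo_waveform(tone * gain, tone * gain, cfg$rate)
    } else if (i == foil_pos) {
      stereo_waveform(tone, -tone, cfg$rate)
    } else {
      stereo_waveform(tone, tone, cfg$rate)
    }
  })
  new_trial_spec("AP", target_position, intervals, cfg$gap_s,
                 metadata = list(seed = seed, foil_position = foil_pos))
}

#' Build one beat test 3AFC trial
#'
#' One f1 is drawn per trial from `[f1_min_hz, f1_max_hz]`; f2 = f1 +
#' `beat_hz`. The two standards carry both tones diotically (a monaural
#' 30-Hz beat); the target carries one tone per ear (which ear gets f1 is
#' randomized), so it beats only if the channels mix. Each interval gets an
#' independent level rove of 0-`rove_db_max` dB; per-channel RMS is
#' equalized across intervals before the rove so interval level is not a
#' reliable cue.
#'
#' @param cfg A [bt_config()].
#' @param target_position Which interval (1-3) is the dichotic pair.
#' @param seed Optional seed (f1 draw, rove gains, ear assignment).
#' @return A `trial_spec`; metadata records `f1`, `rove_db`, the target's
#'   f1 ear, and per-interval per-channel tone amplitudes (used by the
#'   listener simulator's fast path).
#' @export
make_bt_trial <- function(cfg = bt_config(), target_position = sample(3, 1),
                          seed = NULL) {
  check_target_position(target_position)
  draws <- with_seed(seed, list(
    f1 = stats::runif(1, cfg$f1_min_hz, cfg$f1_max_hz),
    rove_db = stats::runif(3, 0, cfg$rove_db_max),
    f1_left = stats::runif(1) < 0.5
  ))
  f1 <- draws$f1
  f2 <- f1 + cfg$beat_hz
  n <- round(cfg$duration_s * cfg$rate)
  t <- (0:(n - 1)) / cfg$rate
  s1 <- sin(2 * pi * f1 * t)
  s2 <- sin(2 * pi * f2 * t)
  a_pair <- cfg$rms_level            # per-tone amp in a two-tone channel
  a_solo <- cfg$rms_level * sqrt(2)  # single-tone channel, same channel RMS
  gains <- 10^(-draws$rove_db / 20)
  amps <- vector("list", 3)
  intervals <- lapply(1:3, function(i) {
    g <- gains[i]
    if (i == target_position) {
      left <- if (draws$f1_left) a_solo * s1 else a_solo * s2
      right <- if (draws$f1_left) a_solo * s2 else a_solo * s1
      amps[[i]] <<- list(
        left = if (draws$f1_left) c(g * a_solo, 0) else c(0, g * a_solo),
        right = if (draws$f1_left) c(0, g * a_solo) else c(g * a_solo, 0))
    } else {
      left <- right <- a_pair * (s1 + s2)
      amps[[i]] <<- list(left = c(g * a_pair, g * a_pair),
                         right = c(g * a_pair, g * a_pair))
    }
    apply_ramp(stereo_waveform(g * left, g * right, cfg$rate), cfg$ramp_s)
  })
  new_trial_spec("BT", target_position, intervals, cfg$gap_s,
                 metadata = list(seed = seed, f1 = f1, f2 = f2,
                                 rove_db = draws$rove_db,
                                 f1_ear = if (draws$f1_left) "left" else "right",
                                 interval_amps = amps))
}

#' Build the fully diotic example trial for a test
#'
#' The example that precedes each screening block must sound the same over
#' any equipment, so it contains no dichotic content: for HP, a diotic
#' 600-Hz tone added to one noise interval; for AP, two equal standards and
#' a softer diotic target; for BT, two diotic beating pairs and one diotic
#' single tone. Failing the example flags a participant for exclusion.
#'
#' @param test_kind One of `"HP"`, `"AP"`, `"BT"`.
#' @param cfg Optional config (defaults per test kind).
#' @param target_position Interval holding the example target (default 2).
#' @param seed Optional seed for the noise/f1 draws.
#' @param hp_tone_db HP example only: tone level relative to the noise RMS,
#'   in dB (default -6, clearly audible within the noise).
#' @return A `trial_spec` with `metadata$example = TRUE`; every interval is
#'   exactly diotic.
#' @export
make_example_trial <- function(test_kind, cfg = default_config(test_kind),
                               target_position = 2, seed = NULL,
                               hp_tone_db = -6) {
  test_kind <- match.arg(test_kind, c("HP", "AP", "BT"))
  check_target_position(target_position)
  if (test_kind == "HP") {
    seeds <- if (is.null(seed)) rep(list(NULL), 3) else
      as.list(child_seed(seed, 1:3))
    n <- round(cfg$duration_s * cfg$rate)
    t <- (0:(n - 1)) / cfg$rate
    tone <- cfg$rms_level * 10^(hp_tone_db / 20) * sqrt(2) *
      sin(2 * pi * cfg$center_hz * t)
    intervals <- lapply(1:3, function(i) {
      x <- generate_white_noise(cfg$duration_s, cfg$rate, seeds[[i]],
                                rms_level = cfg$rms_level)
      if (i == target_position) x <- x + tone
      x <- apply_ramp(x, cfg$onset_ramp_s, cfg$rate)
      stereo_waveform(x, x, cfg$rate)
    })
    trial <- new_trial_spec("HP", target_position, intervals, cfg$gap_s)
  } else if (test_kind == "AP") {
    n <- round(cfg$duration_s * cfg$rate)
    t <- (0:(n - 1)) / cfg$rate
    tone <- apply_ramp(cfg$rms_level * sqrt(2) * sin(2 * pi * cfg$tone_hz * t),
                       cfg$ramp_s, cfg$rate)
    gain <- 10^(cfg$target_level_db / 20)
    intervals <- lapply(1:3, function(i) {
      x <- if (i == target_position) tone * gain else tone
      stereo_waveform(x, x, cfg$rate)
    })
    trial <- new_trial_spec("AP", target_position, intervals, cfg$gap_s)
  } else {
    f1 <- with_seed(seed, stats::runif(1, cfg$f1_min_hz, cfg$f1_max_hz))
    f2 <- f1 + cfg$beat_hz
    n <- round(cfg$duration_s * cfg$rate)
    t <- (0:(n - 1)) / cfg$rate
    intervals <- lapply(1:3, function(i) {
      x <- if (i == target_position) {
        cfg$rms_level * sqrt(2) * sin(2 * pi * f1 * t)
      } else {
        cfg$rms_level * (sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t))
      }
      x <- apply_ramp(x, cfg$ramp_s, cfg$rate)
      stereo_waveform(x, x, cfg$rate)
    })
    trial <- new_trial_spec("BT", target_position, intervals, cfg$gap_s,
                            metadata = list(f1 = f1))
  }
  trial$metadata$example <- TRUE
  trial$metadata$seed <- seed
  trial
}

## ---- trial pools -----------------------------------------------------------

#' Pre-generate a pool of 12 trials for one test
#'
#' Mirrors the pre-generated offline pools used in deployment: 12 trials,
#' each from fresh stochastic draws, with the target position uniformly
#' distributed (each position exactly 4 times, in seeded random order).
#'
#' @param test_kind One of `"HP"`, `"AP"`, `"BT"`.
#' @param cfg Optional stimulus config (defaults per test kind).
#' @param seed Master seed; trial `i` uses `child_seed(seed, i)` and the
#'   position permutation uses `child_seed(seed, 0)`.
#' @param n_trials Pool size (default 12; must be divisible by 3).
#' @return An object of class `trial_pool`.
#' @export
build_trial_pool <- function(test_kind, cfg = default_config(test_kind),
                             seed = 1L, n_trials = 12L) {
  test_kind <- match.arg(test_kind, c("HP", "AP", "BT"))
  if (n_trials %% 3 != 0) {
    stop("`n_trials` must be divisible by 3", call. = FALSE)
  }
  positions <- with_seed(child_seed(seed, 0),
                         sample(rep(1:3, n_trials / 3)))
  maker <- switch(test_kind, HP = make_hp_trial, AP = make_ap_trial,
                  BT = make_bt_trial)
  trials <- lapply(seq_len(n_trials), function(i) {
    maker(cfg, target_position = positions[i], seed = child_seed(seed, i))
  })
  structure(list(trials = trials, test_kind = test_kind, seed = seed,
                 cfg = cfg),
            class = "trial_pool")
}

#' @export
print.trial_pool <- function(x, ...) {
  cat(sprintf("<trial_pool: %d %s trials, seed %s, targets %s>\n",
              length(x$trials), x$test_kind, format(x$seed),
              paste(vapply(x$trials, function(tr) tr$target_position,
                           integer(1)), collapse = "")))
  invisible(x)
}

#' Target positions of a pool's trials
#' @param pool A `trial_pool`.
#' @return Integer vector of target positions.
#' @export
pool_positions <- function(pool) {
  vapply(pool$trials, function(tr) tr$target_position, integer(1))
}

#' Write a trial pool to WAV files with a JSON manifest
#'
#' One stereo WAV per trial (intervals concatenated with silent gaps),
#' named `<test>_<poolindex>_<targetpos>.wav`, plus `manifest.json` -- the
#' machine-readable answer key (test kind, config echo, per-trial seed,
#' target position, f1 and rove gains for BT).
#'
#' @param pool A `trial_pool`.
#' @param dir Output directory (created if missing).
#' @param write_intervals Also write each interval as its own WAV.
#' @return The manifest path, invisibly.
#' @export
write_trial_pool <- function(pool, dir, write_intervals = FALSE) {
  stopifnot(inherits(pool, "trial_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- tolower(pool$test_kind)
  entries <- vector("list", length(pool$trials))
  for (i in seq_along(pool$trials)) {
    trial <- pool$trials[[i]]
    fname <- sprintf("%s_%02d_%d.wav", prefix, i, trial$target_position)
    write_wav(assemble_trial_waveform(trial), file.path(dir, fname))
    if (write_intervals) {
      for (j in 1:3) {
        write_wav(trial$intervals[[j]],
                  file.path(dir, sprintf("%s_%02d_interval%d.wav",
                                         prefix, i, j)))
      }
    }
    meta <- trial$metadata
    meta$interval_amps <- NULL
    entries[[i]] <- c(list(index = i, file = fname,
                           target_position = trial$target_position),
                      meta)
  }
  manifest <- list(test_kind = pool$test_kind, seed = pool$seed,
                   config = unclass(pool$cfg), trials = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
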