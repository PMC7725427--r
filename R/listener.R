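## Virtual listener: an explicit playback-mixing model (how channel signals
## reach the two ears) plus per-test decision statistics. The decision rules
## are deliberately the simplest physics-faithful detectors of each cue --
## interaural band power for Huggins Pitch, mean ear loudness for the
## anti-phase test, envelope-modulation depth for the beat test. Their
## purpose is pipeline validation, not auditory modeling.

#' Playback mixing model
#'
#' A 2x2 matrix mapping the (left, right) channel signals to the (left,
#' right) ear signals, with an optional delay (in samples) on the
#' cross-ear paths to emulate off-center loudspeaker geometries.
#'
#' @param m Numeric 2x2 mixing matrix `[[a_LL, a_LR], [a_RL, a_RR]]`.
#' @param delay Non-negative integer delay (samples) applied to the cross
#'   terms (`a_LR`, `a_RL`).
#' @param label Optional descriptive label.
#' @return An object of class `playback_model`.
#' @seealso [headphone_model()], [full_mix_model()], [crosstalk_model()],
#'   [delayed_mix_model()]
#' @export
playback_model <- function(m, delay = 0L, label = "custom") {
  m <- matrix(as.numeric(m), 2, 2)
  if (!all(is.finite(m))) stop("mixing matrix must be finite", call. = FALSE)
  if (delay < 0 || delay != round(delay)) {
    stop("`delay` must be a non-negative integer", call. = FALSE)
  }
  structure(list(m = m, delay = as.integer(delay), label = label),
            class = "playback_model")
}

#' @export
print.playback_model <- function(x, ...) {
  cat(sprintf("<playback_model '%s': [[%.3g, %.3g], [%.3g, %.3g]], delay %d>\n",
              x$label, x$m[1, 1], x$m[1, 2], x$m[2, 1], x$m[2, 2], x$delay))
  invisible(x)
}

#' @rdname playback_model
#' @details `headphone_model()` is the identity: each channel reaches its
#'   own ear only.
#' @export
headphone_model <- function() {
  playback_model(diag(2), label = "headphones")
}

#' @rdname playback_model
#' @details `full_mix_model()` sends the average of both channels to both
#'   ears -- the idealized listener centered between loudspeakers, where
#'   anti-phase signals cancel completely.
#' @export
full_mix_model <- function() {
  playback_model(matrix(0.5, 2, 2), label = "full_mix")
}

#' @rdname playback_model
#' @param crosstalk Leakage proportion `c` in `[0, 0.5]`: each ear receives
#'   `(1 - c)` of its own channel and `c` of the other.
#' @export
crosstalk_model <- function(crosstalk) {
  if (crosstalk < 0 || crosstalk > 0.5) {
    stop("`crosstalk` must be in [0, 0.5]", call. = FALSE)
  }
  playback_model(matrix(c(1 - crosstalk, crosstalk,
                          crosstalk, 1 - crosstalk), 2, 2, byrow = TRUE),
                 label = sprintf("crosstalk(%.3g)", crosstalk))
}

#' @rdname playback_model
#' @param delay_samples Cross-path delay in samples for `delayed_mix_model`
#'   (an off-center listening position).
#' @export
delayed_mix_model <- function(crosstalk, delay_samples) {
  mod <- crosstalk_model(crosstalk)
  playback_model(mod$m, delay = delay_samples,
                 label = sprintf("delayed_mix(%.3g, %d)", crosstalk,
                                 as.integer(delay_samples)))
}

delay_samples <- function(x, d) {
  if (d == 0) return(x)
  c(numeric(d), x[seq_len(length(x) - d)])
}

#' Pass a trial through a playback model
#'
#' Applies the mixing matrix sample-wise to every interval, turning channel
#' signals into ear signals. With a nonzero delay, the cross-ear paths are
#' delayed by that many samples.
#'
#' @param trial A `trial_spec`.
#' @param model A `playback_model`.
#' @return A `trial_spec` whose intervals are ear signals;
#'   `metadata$playback` records the model label.
#' @export
apply_playback <- function(trial, model) {
  stopifnot(inherits(trial, "trial_spec"), inherits(model, "playback_model"))
  m <- model$m
  d <- model$delay
  trial$intervals <- lapply(trial$intervals, function(w) {
    ear_l <- m[1, 1] * w$left + m[1, 2] * delay_samples(w$right, d)
    ear_r <- m[2, 1] * delay_samples(w$left, d) + m[2, 2] * w$right
    stereo_waveform(ear_l, ear_r, w$rate)
  })
  trial$metadata$playback <- model$label
  trial
}

## ---- per-interval decision statistics (waveform route) ---------------------

#' Decision statistics for the intervals of an ear-signal trial
#'
#' The deterministic part of the virtual listener's evidence, one number
#' per interval:
#' * HP: power of (left ear - right ear) inside the phase-shifted band,
#'   divided by the broadband power of the left ear (larger = stronger
#'   dichotic pitch cue; the listener picks the maximum).
#' * AP: mean of the two per-ear RMS levels (a loudness estimate; the
#'   listener picks the minimum, the "quietest" interval).
#' * BT: envelope-modulation depth at the beat frequency (magnitude of the
#'   analytic-signal envelope's spectrum at `beat_hz`, normalized by the
#'   envelope mean, averaged over ears, ramps trimmed before the envelope
#'   spectrum); the listener picks the minimum, the "smoothest" interval.
#'
#' @param ear_trial A `trial_spec` of ear signals (see [apply_playback()]).
#' @param cfg The matching stimulus config (band edges for HP, beat
#'   frequency and ramp for BT); ignored for AP.
#' @return Numeric vector of 3 statistics.
#' @export
decision_statistics <- function(ear_trial,
                                cfg = default_config(ear_trial$test_kind)) {
  stopifnot(inherits(ear_trial, "trial_spec"))
  switch(ear_trial$test_kind,
         HP = vapply(ear_trial$intervals, hp_interval_statistic,
                     numeric(1), cfg = cfg),
         AP = vapply(ear_trial$intervals, ap_interval_statistic, numeric(1)),
         BT = vapply(ear_trial$intervals, bt_interval_statistic,
                     numeric(1), cfg = cfg))
}

hp_interval_statistic <- function(w, cfg) {
  lo <- cfg$center_hz * (1 - cfg$band_fraction)
  hi <- cfg$center_hz * (1 + cfg$band_fraction)
  broad <- mean(w$left^2)
  if (broad <= 0) return(0)
  band_power(w$left - w$right, w$rate, lo, hi) / broad
}

ap_interval_statistic <- function(w) {
  (rms(w$left) + rms(w$right)) / 2
}

bt_interval_statistic <- function(w, cfg) {
  nr <- round(cfg$ramp_s * w$rate)
  n <- n_samples(w)
  keep <- (nr + 1):(n - nr)
  depth_one <- function(x) {
    env <- analytic_envelope(x)[keep]
    envelope_depth_at(env, w$rate, cfg$beat_hz)
  }
  (depth_one(w$left) + depth_one(w$right)) / 2
}

## ---- choice rule -----------------------------------------------------------

#' Listener configuration
#'
#' @param internal_noise_sd Standard deviation of zero-mean Gaussian noise
#'   added to each interval's decision statistic, in the statistic's own
#'   units. 0 gives the ideal (noise-free) listener.
#' @param seed Optional seed making a single decision reproducible; when
#'   `NULL`, draws come from the current RNG stream (the usual mode inside
#'   seeded simulations).
#' @return An object of class `listener_config`.
#' @export
listener_config <- function(internal_noise_sd = 0, seed = NULL) {
  if (internal_noise_sd < 0) {
    stop("`internal_noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(internal_noise_sd = internal_noise_sd, seed = seed),
            class = "listener_config")
}

## Pick the extreme statistic; exact (and numerically near-exact) ties are
## broken uniformly at random. The tie window is 1e-9 relative to the
## largest statistic magnitude, which separates genuine cues from
## floating-point residue.
choose_extreme <- function(stats, maximize = TRUE) {
  s <- if (maximize) stats else -stats
  tol <- 1e-9 * max(abs(stats), 1e-12)
  cand <- which(s >= max(s) - tol)
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

decide <- function(stats, listener, maximize) {
  with_seed(listener$seed, {
    noisy <- stats + stats::rnorm(length(stats), 0,
                                  listener$internal_noise_sd)
    choose_extreme(noisy, maximize = maximize)
  })
}

#' Virtual-listener decisions for one trial
#'
#' Each decision computes the per-interval statistic (see
#' [decision_statistics()]), adds the listener's internal noise, and picks
#' the extreme interval (maximum dichotic-cue power for HP; minimum
#' loudness for AP; minimum beat depth for BT). Exact ties are broken
#' uniformly at random.
#'
#' @param ear_trial A `trial_spec` of ear signals.
#' @param listener A [listener_config()].
#' @param cfg The matching stimulus config.
#' @return The chosen interval, an integer in 1-3.
#' @export
hp_decision <- function(ear_trial, listener = listener_config(),
                        cfg = hp_config()) {
  decide(decision_statistics(ear_trial, cfg), listener, maximize = TRUE)
}

#' @rdname hp_decision
#' @export
ap_decision <- function(ear_trial, listener = listener_config()) {
  decide(decision_statistics(ear_trial), listener, maximize = FALSE)
}

#' @rdname hp_decision
#' @export
bt_decision <- function(ear_trial, listener = listener_config(),
                        cfg = bt_config()) {
  decide(decision_statistics(ear_trial, cfg), listener, maximize = FALSE)
}

## ---- fast statistics from cached quadratic moments -------------------------
##
## For delay-free mixing the HP and AP statistics are quadratic forms in the
## mixing coefficients, so a pool's waveforms reduce to a handful of scalar
## moments per interval; the BT statistic reduces to per-frequency tone
## amplitudes. This makes whole-cohort simulation arithmetic rather than
## signal processing. Equivalence with the waveform route is covered by
## tests.

pool_moments <- function(pool) {
  cfg <- pool$cfg
  test <- pool$test_kind
  per_interval <- function(w) {
    out <- list(P_LL = mean(w$left^2), P_RR = mean(w$right^2),
                P_LR = mean(w$left * w$right))
    if (test == "HP") {
      n <- n_samples(w)
      lo <- cfg$center_hz * (1 - cfg$band_fraction)
      hi <- cfg$center_hz * (1 + cfg$band_fraction)
      b <- band_bins(n, w$rate, lo, hi)
      XL <- stats::fft(w$left)[b]
      XR <- stats::fft(w$right)[b]
      out$B_LL <- sum(Mod(XL)^2) / n^2
      out$B_RR <- sum(Mod(XR)^2) / n^2
      out$B_LR <- sum(Re(XL * Conj(XR))) / n^2
    }
    out
  }
  moments <- lapply(pool$trials, function(tr) lapply(tr$intervals,
                                                     per_interval))
  amps <- if (test == "BT") {
    lapply(pool$trials, function(tr) tr$metadata$interval_amps)
  }
  list(test = test, cfg = cfg, moments = moments, amps = amps,
       targets = pool_positions(pool))
}

## 12x3 statistic matrix for one playback model from cached moments.
## Falls back to the waveform route when the model has a cross-path delay
## (HP/AP) since the quadratic forms assume sample-aligned mixing.
pool_statistics <- function(pm, model, pool = NULL) {
  m <- model$m
  if (model$delay > 0 && pm$test != "BT") {
    stopifnot(!is.null(pool))
    return(t(vapply(pool$trials, function(tr) {
      decision_statistics(apply_playback(tr, model), pm$cfg)
    }, numeric(3))))
  }
  n_tr <- length(pm$moments)
  out <- matrix(0, n_tr, 3)
  if (pm$test == "BT") {
    phase <- exp(-2i * pi * c(0, pm$cfg$beat_hz) / pm$cfg$rate * model$delay)
    for (i in seq_len(n_tr)) {
      for (j in 1:3) {
        a <- pm$amps[[i]][[j]]
        # cross-path delay shifts tone phase but leaves two-tone envelope
        # depth unchanged; amplitudes add coherently (common sine phase)
        ear_l <- Mod(m[1, 1] * a$left + m[1, 2] * a$right * phase)
        ear_r <- Mod(m[2, 1] * a$left * phase + m[2, 2] * a$right)
        out[i, j] <- (bt_pair_depth(ear_l, pm$cfg) +
                        bt_pair_depth(ear_r, pm$cfg)) / 2
      }
    }
    return(out)
  }
  a11 <- m[1, 1]; a12 <- m[1, 2]; a21 <- m[2, 1]; a22 <- m[2, 2]
  alpha <- a11 - a21
  beta <- a12 - a22
  for (i in seq_len(n_tr)) {
    for (j in 1:3) {
      mo <- pm$moments[[i]][[j]]
      if (pm$test == "HP") {
        band <- alpha^2 * mo$B_LL + beta^2 * mo$B_RR +
          2 * alpha * beta * mo$B_LR
        broad <- a11^2 * mo$P_LL + a12^2 * mo$P_RR + 2 * a11 * a12 * mo$P_LR
        out[i, j] <- if (broad <= 0) 0 else max(band, 0) / broad
      } else {
        p_l <- a11^2 * mo$P_LL + a12^2 * mo$P_RR + 2 * a11 * a12 * mo$P_LR
        p_r <- a21^2 * mo$P_LL + a22^2 * mo$P_RR + 2 * a21 * a22 * mo$P_LR
        out[i, j] <- (sqrt(max(p_l, 0)) + sqrt(max(p_r, 0))) / 2
      }
    }
  }
  out
}

## Beat-envelope modulation depth of a two-tone ear signal with amplitudes
## (a1, a2): env(t) = sqrt(a1^2 + a2^2 + 2 a1 a2 cos(2 pi beat t)). Depth
## depends only on the amplitude ratio; values are interpolated from a
## cached ratio grid.
bt_pair_depth <- function(a, cfg) {
  a1 <- max(a); a2 <- min(a)
  if (a1 <= 0) return(0)
  r <- a2 / a1
  tab <- bt_depth_table(cfg)
  stats::approx(tab$r, tab$depth, xout = r, rule = 2)$y
}

.bt_depth_cache <- new.env(parent = emptyenv())

bt_depth_table <- function(cfg, n_grid = 201L, env_rate = 1000) {
  key <- sprintf("%g_%g_%g", cfg$beat_hz, cfg$duration_s, cfg$ramp_s)
  if (!is.null(.bt_depth_cache[[key]])) return(.bt_depth_cache[[key]])
  dur <- cfg$duration_s - 2 * cfg$ramp_s
  t <- seq(0, dur, by = 1 / env_rate)
  r <- seq(0, 1, length.out = n_grid)
  depth <- vapply(r, function(ri) {
    env <- sqrt(1 + ri^2 + 2 * ri * cos(2 * pi * cfg$beat_hz * t))
    envelope_depth_at(env, env_rate, cfg$beat_hz)
  }, numeric(1))
  .bt_depth_cache[[key]] <- list(r = r, depth = depth)
  .bt_depth_cache[[key]]
}

## ---- cohort simulation -----------------------------------------------------

#' Specification of a simulated screening cohort
#'
#' Describes a virtual cohort taking the screening battery over both
#' headphones and loudspeakers. Equipment variability is expressed through
#' playback models: each subject's headphones leak a subject-specific
#' crosstalk proportion (channel bleed being the main real-world
#' degradation of dichotic stimuli), and their loudspeaker setup is a
#' full-mix (or configurable crosstalk/delayed) geometry. Internal noise
#' scales with each test's nominal cue magnitude through a per-subject
#' sensitivity factor.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param tests Character vector of tests to run (subset of HP, AP, BT).
#' @param trials_per_block Trials drawn per block (default 6).
#' @param headphone_crosstalk Length-2 range; each subject's headphone
#'   crosstalk is drawn uniformly from it.
#' @param loudspeaker_model `"full_mix"`, `"crosstalk"`, or
#'   `"delayed_mix"`.
#' @param loudspeaker_crosstalk Range for the loudspeaker crosstalk draw
#'   (used by the `"crosstalk"` and `"delayed_mix"` presets).
#' @param loudspeaker_delay Cross-path delay in samples for
#'   `"delayed_mix"`.
#' @param noise_factor Length-2 range; each subject's internal-noise SD is
#'   `factor x` the test's cue scale, with the factor drawn uniformly.
#' @param configs Named list of stimulus configs (defaults per test).
#' @param pool_seed Optional fixed seed for the trial pools; by default
#'   pools are derived from the cohort seed.
#' @param n_pool Pool size (default 12).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L, tests = c("HP", "AP"),
                        trials_per_block = 6L,
                        headphone_crosstalk = c(0, 0.35),
                        loudspeaker_model = c("full_mix", "crosstalk",
                                              "delayed_mix"),
                        loudspeaker_crosstalk = c(0.3, 0.5),
                        loudspeaker_delay = 0L,
                        noise_factor = c(0.02, 0.2),
                        configs = NULL, pool_seed = NULL, n_pool = 12L) {
  tests <- match.arg(tests, c("HP", "AP", "BT"), several.ok = TRUE)
  loudspeaker_model <- match.arg(loudspeaker_model)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (is.null(configs)) {
    configs <- stats::setNames(lapply(tests, default_config), tests)
  }
  structure(list(n_subjects = as.integer(n_subjects), tests = tests,
                 trials_per_block = as.integer(trials_per_block),
                 headphone_crosstalk = headphone_crosstalk,
                 loudspeaker_model = loudspeaker_model,
                 loudspeaker_crosstalk = loudspeaker_crosstalk,
                 loudspeaker_delay = as.integer(loudspeaker_delay),
                 noise_factor = noise_factor, configs = configs,
                 pool_seed = pool_seed, n_pool = as.integer(n_pool)),
            class = "cohort_spec")
}

## Nominal cue magnitude of a pool under identity playback: mean margin
## between the target's statistic and its closest competitor.
pool_cue_scale <- function(pm, maximize) {
  stats <- pool_statistics(pm, headphone_model())
  margins <- vapply(seq_len(nrow(stats)), function(i) {
    tgt <- stats[i, pm$targets[i]]
    others <- stats[i, -pm$targets[i]]
    if (maximize) tgt - max(others) else min(others) - tgt
  }, numeric(1))
  mean(margins)
}

#' Simulate a screening cohort
#'
#' Generates trial pools, draws each subject's equipment and sensitivity,
#' runs every block (each test over headphones and over loudspeakers)
#' through the virtual listener, and records block scores. Fully
#' reproducible from `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A subject table (see [subject_table()]): a long data.frame with
#'   columns `subject_id`, `test`, `equipment`, `n_correct`. Attribute
#'   `"subjects"` holds the per-subject equipment and noise draws.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    pools <- lapply(seq_along(spec$tests), function(k) {
      ps <- if (is.null(spec$pool_seed)) child_seed(seed, 1000 + k) else
        child_seed(spec$pool_seed, k)
      build_trial_pool(spec$tests[k], spec$configs[[spec$tests[k]]],
                       seed = ps, n_trials = spec$n_pool)
    })
    names(pools) <- spec$tests
    pm <- lapply(pools, pool_moments)
    maximize <- stats::setNames(spec$tests == "HP", spec$tests)
    cue <- stats::setNames(
      vapply(spec$tests, function(tk) pool_cue_scale(pm[[tk]],
                                                     maximize[[tk]]),
             numeric(1)), spec$tests)
    ns <- spec$n_subjects
    c_head <- stats::runif(ns, spec$headphone_crosstalk[1],
                           spec$headphone_crosstalk[2])
    c_spk <- stats::runif(ns, spec$loudspeaker_crosstalk[1],
                          spec$loudspeaker_crosstalk[2])
    s_noise <- stats::runif(ns, spec$noise_factor[1], spec$noise_factor[2])
    rows <- vector("list", ns * length(spec$tests) * 2L)
    ri <- 0L
    for (s in seq_len(ns)) {
      models <- list(
        headphones = crosstalk_model(c_head[s]),
        loudspeakers = switch(spec$loudspeaker_model,
                              full_mix = full_mix_model(),
                              crosstalk = crosstalk_model(c_spk[s]),
                              delayed_mix = delayed_mix_model(
                                c_spk[s], spec$loudspeaker_delay)))
      for (tk in spec$tests) {
        stat_mats <- lapply(models, function(mod) {
          pool_statistics(pm[[tk]], mod, pool = pools[[tk]])
        })
        for (eq in names(models)) {
          stats_mat <- stat_mats[[eq]]
          idx <- sample(spec$n_pool, spec$trials_per_block)
          sd_i <- s_noise[s] * cue[[tk]]
          correct <- vapply(idx, function(i) {
            noisy <- stats_mat[i, ] + stats::rnorm(3, 0, sd_i)
            choose_extreme(noisy, maximize = maximize[[tk]]) ==
              pm[[tk]]$targets[i]
          }, logical(1))
          ri <- ri + 1L
          rows[[ri]] <- data.frame(subject_id = sprintf("S%03d", s),
                                   test = tk, equipment = eq,
                                   n_correct = sum(correct))
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "subjects") <- data.frame(
      subject_id = sprintf("S%03d", seq_len(ns)),
      headphone_crosstalk = c_head, loudspeaker_crosstalk = c_spk,
      noise_factor = s_noise)
    subject_table(out)
  })
}

#' Long-run accuracy of a virtual listener on one test
#'
#' Repeatedly samples trials from a pool, runs the decision rule under a
#' given playback model and internal noise level, and returns the
#' proportion of correct choices. Used to characterize the simulator
#' (e.g. chance performance under full channel mixing).
#'
#' @param test_kind `"HP"`, `"AP"`, or `"BT"`.
#' @param model A [playback_model()].
#' @param n_trials Number of simulated trials.
#' @param internal_noise_sd Internal noise SD in statistic units.
#' @param cfg Stimulus config.
#' @param pool_seed Seed for the trial pool.
#' @param seed Seed for the trial draws, noise, and tie-breaks.
#' @return Proportion correct in `[0, 1]`.
#' @export
simulate_accuracy <- function(test_kind, model, n_trials = 1000L,
                              internal_noise_sd = 0,
                              cfg = default_config(test_kind),
                              pool_seed = 1L, seed = 1L) {
  pool <- build_trial_pool(test_kind, cfg, seed = pool_seed)
  pm <- pool_moments(pool)
  stats_mat <- pool_statistics(pm, model, pool = pool)
  maximize <- test_kind == "HP"
  with_seed(seed, {
    idx <- sample(length(pool$trials), n_trials, replace = TRUE)
    mean(vapply(idx, function(i) {
      noisy <- stats_mat[i, ] + stats::rnorm(3, 0, internal_noise_sd)
      choose_extreme(noisy, maximize = maximize) == pm$targets[i]
    }, logical(1)))
  })
}
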