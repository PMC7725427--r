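test_that("Huggins pair negates exactly the 564-636 Hz bins and preserves magnitudes", {
  cfg <- hp_config()                     # 600 Hz +/- 6% at 44.1 kHz
  noise <- generate_white_noise(1.0, cfg$rate, seed = 11)
  pair <- make_huggins_pair(noise, cfg)
  expect_identical(pair$left, noise)
  n <- length(noise)
  XL <- fft(pair$left)
  XR <- fft(pair$right)
  freq <- (0:(n - 1)) * cfg$rate / n
  folded <- pmin(freq, cfg$rate - freq)
  in_band <- folded >= 564 & folded <= 636 & seq_len(n) > 1
  # shifted band spans 564-636 Hz: in-band bins are negated ...
  expect_lt(max(Mod(XR[in_band] + XL[in_band])) / max(Mod(XL)), 1e-9)
  # ... and out-of-band bins are untouched
  expect_lt(max(Mod(XR[!in_band] - XL[!in_band])) / max(Mod(XL)), 1e-9)
  # magnitude spectra agree everywhere
  expect_lt(max(abs(Mod(XR) - Mod(XL))) / max(Mod(XL)), 1e-9)
})

test_that("a zero-width band leaves the pair diotic", {
  cfg <- fast_hp(band_fraction = 0)
  noise <- generate_white_noise(cfg$duration_s, cfg$rate, seed = 1)
  pair <- make_huggins_pair(noise, cfg)
  expect_identical(pair$left, pair$right)
})

test_that("summing the Huggins channels cancels the shifted band (anti-phase oracle)", {
  cfg <- hp_config()
  noise <- generate_white_noise(1.0, cfg$rate, seed = 3)
  pair <- make_huggins_pair(noise, cfg)
  s <- pair$left + pair$right
  in_sum <- headscreen:::band_power(s, cfg$rate, 564, 636)
  in_left <- headscreen:::band_power(pair$left, cfg$rate, 564, 636)
  expect_lt(in_sum, 1e-6 * in_left)
  out_sum <- mean(s^2) - in_sum
  out_left <- mean(pair$left^2) - in_left
  expect_equal(out_sum / out_left, 4, tolerance = 1e-9)
})

test_that("an HP trial is dichotic only in the target interval, 1000 ms each", {
  cfg <- hp_config()
  trial <- make_hp_trial(cfg, target_position = 2, seed = 5)
  expect_s3_class(trial, "trial_spec")
  expect_true(is_diotic(trial$intervals[[1]]))
  expect_true(is_diotic(trial$intervals[[3]]))
  expect_false(is_diotic(trial$intervals[[2]]))
  diff_energy <- vapply(trial$intervals,
                        function(w) sum((w$left - w$right)^2), numeric(1))
  expect_identical(which(diff_energy > 1e-12), 2L)
  expect_true(all(vapply(trial$intervals, n_samples, numeric(1)) == 44100))
  expect_error(make_hp_trial(cfg, target_position = 4), "1, 2, or 3")
})

test_that("AP trial: -6 dB target, exactly anti-phase foil with the standard's amplitude", {
  cfg <- ap_config()
  trial <- make_ap_trial(cfg, target_position = 2, seed = 7)
  foil <- trial$metadata$foil_position
  std <- setdiff(1:3, c(2, foil))
  # target at 10^(-6/20) ~ 0.5012 of the standard, per channel
  expect_equal(rms(trial$intervals[[2]]$left) /
                 rms(trial$intervals[[std]]$left),
               10^(-6 / 20), tolerance = 1e-9)
  # foil: left + right identically zero
  fw <- trial$intervals[[foil]]
  expect_identical(fw$left + fw$right, rep(0, n_samples(fw)))
  # each foil channel matches the standard's channel RMS
  expect_equal(rms(fw$left) / rms(trial$intervals[[std]]$left), 1,
               tolerance = 1e-9)
  expect_equal(rms(fw$right) / rms(trial$intervals[[std]]$right), 1,
               tolerance = 1e-9)
  # target and standard are diotic
  expect_true(is_diotic(trial$intervals[[2]]))
  expect_true(is_diotic(trial$intervals[[std]]))
  expect_error(ap_config(target_level_db = 0), "degenerate")
})

test_that("the AP foil slot is randomized over the two non-target positions", {
  slots <- vapply(1:40, function(s) {
    make_ap_trial(fast_ap(), target_position = 2, seed = s)$
      metadata$foil_position
  }, integer(1))
  expect_setequal(unique(slots), c(1L, 3L))
})

test_that("BT trial: f2 - f1 = 30 Hz, f1 in range, rove within 4 dB", {
  cfg <- bt_config()
  for (s in 1:5) {
    trial <- make_bt_trial(cfg, target_position = 1 + s %% 3, seed = s)
    expect_identical(trial$metadata$f2 - trial$metadata$f1, 30)
    expect_gte(trial$metadata$f1, 1800)
    expect_lte(trial$metadata$f1, 2500)
    levels_db <- vapply(trial$intervals,
                        function(w) 20 * log10(rms(w$left)), numeric(1))
    expect_lte(max(levels_db) - min(levels_db), 4 + 1e-6)
  }
})

test_that("BT envelope oracle: standards beat at 30 Hz, target channels are flat", {
  cfg <- bt_config()
  trial <- make_bt_trial(cfg, target_position = 3, seed = 2)
  keep <- (round(cfg$ramp_s * cfg$rate) + 1):
    (n_samples(trial$intervals[[1]]) - round(cfg$ramp_s * cfg$rate))
  depth <- function(x, hz) {
    env <- headscreen:::analytic_envelope(x)[keep]
    headscreen:::envelope_depth_at(env, cfg$rate, hz)
  }
  std <- trial$intervals[[1]]$left
  # the standard's envelope modulation spectrum peaks at the 30 Hz beat
  d30 <- depth(std, 30)
  expect_gt(d30, 0.5)
  for (hz in c(10, 20, 45, 60)) expect_gt(d30, 2 * depth(std, hz))
  # the dichotic target's single-tone channels are unmodulated
  expect_lt(depth(trial$intervals[[3]]$left, 30), 0.01)
  expect_lt(depth(trial$intervals[[3]]$right, 30), 0.01)
})

test_that("example trials are fully diotic with the advertised targets", {
  for (tk in c("HP", "AP", "BT")) {
    cfg <- switch(tk, HP = fast_hp(), AP = fast_ap(), BT = fast_bt())
    ex <- make_example_trial(tk, cfg, target_position = 2, seed = 4)
    expect_true(all(vapply(ex$intervals, is_diotic, logical(1))),
                label = paste(tk, "example diotic"))
    expect_true(ex$metadata$example)
  }
  # HP example: spectral peak at the pitch frequency above the noise floor
  cfg <- hp_config()
  ex <- make_example_trial("HP", cfg, target_position = 2, seed = 4)
  tgt <- ex$intervals[[2]]$left
  peak <- headscreen:::band_power(tgt, cfg$rate, 595, 605)
  floor_band <- headscreen:::band_power(tgt, cfg$rate, 700, 710)
  expect_gt(peak, 10 * floor_band)
  # AP example: target softer than both standards by the configured level
  exa <- make_example_trial("AP", ap_config(), target_position = 2)
  r <- vapply(exa$intervals, function(w) rms(w$left), numeric(1))
  expect_equal(r[2] / r[1], 10^(-6 / 20), tolerance = 1e-9)
  expect_equal(r[1], r[3], tolerance = 1e-12)
})

test_that("trial pools hold 12 trials with each target position exactly 4 times", {
  pool <- build_trial_pool("AP", fast_ap(), seed = 9)
  expect_length(pool$trials, 12)
  expect_identical(as.vector(table(pool_positions(pool))), rep(4L, 3))
  # deterministic from the seed
  pool2 <- build_trial_pool("AP", fast_ap(), seed = 9)
  expect_identical(pool_positions(pool), pool_positions(pool2))
  expect_identical(pool$trials[[5]]$intervals[[1]]$left,
                   pool2$trials[[5]]$intervals[[1]]$left)
})

test_that("pools from different seeds share no noise interval", {
  p1 <- build_trial_pool("HP", fast_hp(), seed = 1)
  p2 <- build_trial_pool("HP", fast_hp(), seed = 2)
  firsts1 <- lapply(p1$trials, function(tr) tr$intervals[[1]]$left[1:16])
  firsts2 <- lapply(p2$trials, function(tr) tr$intervals[[1]]$left[1:16])
  for (a in firsts1) for (b in firsts2) expect_false(identical(a, b))
  # and noise differs across trials within a pool
  for (i in 1:11) expect_false(identical(firsts1[[i]], firsts1[[i + 1]]))
})

test_that("pool export writes WAVs and a machine-readable answer key", {
  pool <- build_trial_pool("BT", fast_bt(), seed = 3)
  dir <- withr::local_tempdir()
  manifest_path <- write_trial_pool(pool, dir)
  manifest <- jsonlite::read_json(manifest_path)
  expect_identical(manifest$test_kind, "BT")
  expect_length(manifest$trials, 12)
  entry <- manifest$trials[[1]]
  expect_identical(entry$target_position,
                   pool$trials[[1]]$target_position)
  expect_true(file.exists(file.path(dir, entry$file)))
  w <- read_wav(file.path(dir, entry$file))
  gap <- round(fast_bt()$gap_s * fast_bt()$rate)
  expect_equal(n_samples(w), 3 * n_samples(pool$trials[[1]]$intervals[[1]]) +
                 2 * gap)
  expect_false(is.null(entry$f1))
})
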