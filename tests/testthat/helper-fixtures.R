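# Reduced-rate configs for tests whose assertions do not concern the
# default 44.1 kHz / 1 s deployment parameters; keeps FFT sizes small.
fast_hp <- function(...) hp_config(rate = 8820, duration_s = 0.5, ...)
fast_ap <- function(...) ap_config(rate = 8820, duration_s = 0.5,
                                   ramp_s = 0.05, ...)
fast_bt <- function(...) bt_config(rate = 8820, duration_s = 0.5, ...)

# Long-format subject table from per-test score vectors.
make_table <- function(..., n = NULL) {
  tests <- list(...)
  rows <- lapply(names(tests), function(tk) {
    sc <- tests[[tk]]
    n_sub <- length(sc$phones)
    rbind(
      data.frame(subject_id = sprintf("S%03d", seq_len(n_sub)), test = tk,
                 equipment = "headphones", n_correct = sc$phones),
      data.frame(subject_id = sprintf("S%03d", seq_len(n_sub)), test = tk,
                 equipment = "loudspeakers", n_correct = sc$speakers))
  })
  subject_table(do.call(rbind, rows))
}

# Shoelace (polygon) area under a monotone ROC: close the polygon along
# the bottom-right edge and take half the absolute cross-product sum.
shoelace_auc <- function(fa, hit) {
  x <- c(fa, 1, 0)
  y <- c(hit, 0, 0)
  n <- length(x)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Random monotone ROC curve object (anchors included).
random_roc <- function() {
  fa <- sort(stats::runif(4))
  hit <- sort(stats::runif(4))
  headscreen:::new_roc_curve(c(NA, 6:3, NA), c(0, fa, 1), c(0, hit, 1))
}
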