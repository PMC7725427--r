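## Screening protocol: block assembly from pre-generated pools, scoring of
## 3AFC responses, pass thresholds, and the "Both" combination rule.

#' Draw a screening block from a trial pool
#'
#' Six trials (by default) are drawn from the pool of 12 without
#' replacement, in randomized order.
#'
#' @param pool A `trial_pool`.
#' @param n Number of trials in the block (default 6).
#' @param seed Optional seed for the draw.
#' @return A list of `trial_spec`s with attribute `"indices"` giving their
#'   positions in the pool.
#' @export
sample_block <- function(pool, n = 6L, seed = NULL) {
  stopifnot(inherits(pool, "trial_pool"))
  if (n > length(pool$trials)) {
    stop("cannot draw more trials than the pool holds", call. = FALSE)
  }
  idx <- with_seed(seed, sample(length(pool$trials), n))
  structure(pool$trials[idx], indices = idx)
}

## Accept either a list of trial_specs or a bare integer vector of target
## positions.
target_positions <- function(trials) {
  if (is.numeric(trials)) return(as.integer(trials))
  vapply(trials, function(tr) tr$target_position, integer(1))
}

#' Score a block of 3AFC responses
#'
#' A response is correct when it names the target interval. Responses are
#' 1-based interval indices, matching the on-screen buttons 1/2/3.
#'
#' @param trials A list of `trial_spec`s (or an integer vector of target
#'   positions).
#' @param responses Integer vector of the same length with values in 1-3.
#' @return An object of class `block_result` with fields `targets`,
#'   `responses`, `correct` (logical), and `n_correct`.
#' @export
score_block <- function(trials, responses) {
  targets <- target_positions(trials)
  responses <- as.integer(responses)
  if (length(responses) != length(targets)) {
    stop("one response per trial is required", call. = FALSE)
  }
  if (!all(responses %in% 1:3)) {
    stop("responses must be 1, 2, or 3", call. = FALSE)
  }
  correct <- responses == targets
  structure(list(targets = targets, responses = responses, correct = correct,
                 n_correct = sum(correct)),
            class = "block_result")
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result: %d/%d correct>\n", x$n_correct,
              length(x$targets)))
  invisible(x)
}

#' Apply a pass threshold to a block score
#'
#' A participant passes a test at threshold `t` when they got at least `t`
#' of the block's 6 trials correct. The recommended deployment threshold
#' is 6/6; 5/6 matches earlier practice for the anti-phase test.
#'
#' @param n_correct Integer score(s), 0-6.
#' @param threshold Required number of correct responses, 0-6.
#' @return Logical: pass (`TRUE`) or fail, vectorized over `n_correct`.
#' @export
classify_pass <- function(n_correct, threshold) {
  stopifnot(all(n_correct >= 0), all(threshold >= 0))
  n_correct >= threshold
}

#' Combine two tests under the "Both" rule
#'
#' A participant passes the combined screen only when they pass both
#' component tests; the conjunction trades hit rate for a lower
#' false-alarm rate.
#'
#' @param pass_a,pass_b Logical pass indicators (vectorized).
#' @return Logical conjunction.
#' @export
combine_both <- function(pass_a, pass_b) {
  as.logical(pass_a) & as.logical(pass_b)
}

#' Block presentation order from a cyclic Latin square
#'
#' The four blocks (HP/headphones, HP/loudspeakers, AP/headphones,
#' AP/loudspeakers, or their BT equivalents) are counterbalanced with a
#' cyclic Latin square: participant `p` receives row `p mod n_blocks`, so
#' across any `n_blocks` consecutive participants every block occupies
#' every serial position exactly once.
#'
#' @param participant_index Non-negative integer participant counter.
#' @param n_blocks Number of blocks (default 4).
#' @return Integer permutation of `1:n_blocks`.
#' @export
latin_square_order <- function(participant_index, n_blocks = 4L) {
  if (participant_index < 0) {
    stop("`participant_index` must be non-negative", call. = FALSE)
  }
  r <- participant_index %% n_blocks
  ((r + 0:(n_blocks - 1)) %% n_blocks) + 1L
}

#' Tabulate block results across subjects and conditions
#'
#' Builds the long-format results table consumed by the signal-detection
#' analysis: one row per trial with pass indicators at every threshold.
#'
#' @param subject_id Subject identifier.
#' @param test_kind Test label (e.g. `"HP"`).
#' @param equipment_label Equipment label (e.g. `"headphones"`).
#' @param result A `block_result`.
#' @return A data.frame with columns `subject_id`, `test`,
#'   `equipment_label`, `trial_index`, `target_position`, `response`,
#'   `correct`, `n_correct`, and `pass_at_6` ... `pass_at_3`.
#' @export
block_result_df <- function(subject_id, test_kind, equipment_label, result) {
  stopifnot(inherits(result, "block_result"))
  k <- length(result$targets)
  df <- data.frame(subject_id = subject_id, test = test_kind,
                   equipment_label = equipment_label, trial_index = seq_len(k),
                   target_position = result$targets,
                   response = result$responses, correct = result$correct,
                   n_correct = result$n_correct)
  for (thr in 6:3) {
    df[[paste0("pass_at_", thr)]] <- classify_pass(result$n_correct, thr)
  }
  df
}
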