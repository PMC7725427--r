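## Signal-detection evaluation of the screening tests. "Hit" and "false
## alarm" are properties of a *test*, not of a listener: passing a subject
## who really used headphones is a hit; passing the same subject when they
## used loudspeakers is a false alarm. Sweeping the pass threshold over the
## above-chance values 6, 5, 4, 3 traces an ROC whose area summarizes how
## well the test discriminates equipment.

#' Subject score table
#'
#' The input to all statistics: one row per subject x test x equipment
#' with the block score (number of trials correct out of 6). Long format
#' with columns `subject_id`, `test`, `equipment`, `n_correct`; equipment
#' must include both `"headphones"` and `"loudspeakers"` for ROC analysis.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `subject_table` prepended.
#' @export
subject_table <- function(df) {
  required <- c("subject_id", "test", "equipment", "n_correct")
  if (!all(required %in% names(df))) {
    stop("subject table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("subject table is empty", call. = FALSE)
  if (!all(df$n_correct == round(df$n_correct)) ||
      any(df$n_correct < 0) || any(df$n_correct > 6)) {
    stop("`n_correct` must be integers in 0-6", call. = FALSE)
  }
  if (anyDuplicated(df[c("subject_id", "test", "equipment")])) {
    stop("duplicate subject x test x equipment cells", call. = FALSE)
  }
  class(df) <- unique(c("subject_table", class(df)))
  df
}

#' Read / write a subject table as CSV
#' @param path CSV file path.
#' @return `read_subject_table()` returns a `subject_table`;
#'   `write_subject_table()` returns `path` invisibly.
#' @export
read_subject_table <- function(path) {
  subject_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_subject_table
#' @param table A `subject_table`.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

## Aligned per-subject score vectors for one test: headphone and
## loudspeaker scores in a common subject order.
score_pair <- function(table, test) {
  sub <- table[table$test == test, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("test '%s' not present in the table", test), call. = FALSE)
  }
  ph <- sub[sub$equipment == "headphones", ]
  sp <- sub[sub$equipment == "loudspeakers", ]
  if (nrow(ph) == 0 || nrow(sp) == 0) {
    stop("both headphone and loudspeaker scores are required", call. = FALSE)
  }
  ids <- sort(intersect(ph$subject_id, sp$subject_id))
  if (length(ids) == 0) {
    stop("no subjects with both equipment conditions", call. = FALSE)
  }
  list(subject_id = ids,
       phones = ph$n_correct[match(ids, ph$subject_id)],
       speakers = sp$n_correct[match(ids, sp$subject_id)])
}

#' Hit and false-alarm rates of a test at one pass threshold
#'
#' @param table A [subject_table()].
#' @param test Test label present in the table (e.g. `"HP"`).
#' @param threshold Pass threshold (number correct out of 6), normally in
#'   3-6.
#' @return Named numeric vector `c(hit = ..., false_alarm = ...)`: the
#'   proportions of subjects passing at `threshold` over headphones and
#'   over loudspeakers respectively.
#' @export
pass_rates <- function(table, test, threshold) {
  sp <- score_pair(table, test)
  c(hit = mean(classify_pass(sp$phones, threshold)),
    false_alarm = mean(classify_pass(sp$speakers, threshold)))
}

new_roc_curve <- function(threshold, fa, hit, test = NA_character_) {
  pts <- data.frame(threshold = threshold, false_alarm = fa, hit = hit)
  pts <- pts[order(pts$false_alarm, pts$hit), ]
  structure(list(points = pts, test = test), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve%s: AUC %.3f>\n",
              if (is.na(x$test)) "" else paste0(" ", x$test), auc(x)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' ROC curve of a screening test over pass thresholds
#'
#' Computes (false alarm, hit) at each above-chance threshold (6, 5, 4, 3
#' out of 6) and adds the degenerate accept-none (0, 0) and accept-all
#' (1, 1) anchor policies. Hit and false-alarm rates are non-decreasing as
#' the threshold drops, so the curve is monotone by construction.
#'
#' @param table A [subject_table()].
#' @param test Test label.
#' @param thresholds Thresholds to sweep (default `6:3`).
#' @return An object of class `roc_curve` (points data.frame + test
#'   label).
#' @export
roc_curve <- function(table, test, thresholds = 6:3) {
  rates <- vapply(thresholds, function(th) pass_rates(table, test, th),
                  numeric(2))
  new_roc_curve(c(NA, thresholds, NA),
                c(0, rates["false_alarm", ], 1),
                c(0, rates["hit", ], 1), test = test)
}

#' Area under an ROC curve
#'
#' Trapezoidal integration over the curve's points sorted by false-alarm
#' rate, anchors included.
#'
#' @param curve An object of class `roc_curve`.
#' @return The area, in `[0, 1]`; 0.5 is chance, 1 a perfect
#'   discriminator.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fa <- curve$points$false_alarm
  hit <- curve$points$hit
  if (any(fa < 0 | fa > 1 | hit < 0 | hit > 1)) {
    stop("ROC coordinates must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(fa) || is.unsorted(hit)) {
    stop("ROC points must be monotone in both coordinates", call. = FALSE)
  }
  sum(diff(fa) * (utils::head(hit, -1) + utils::tail(hit, -1)) / 2)
}

#' Sensitivity index d-prime of a screening test
#'
#' `d' = qnorm(hit) - qnorm(false_alarm)`, the separation between the
#' equipment classes in standard-normal units. Extreme rates of 0 or 1
#' are clipped to `1/(2N)` and `1 - 1/(2N)` before quantile inversion when
#' the number of subjects `n` is supplied.
#'
#' @param hit,false_alarm Rates in `[0, 1]`.
#' @param n Number of subjects behind the rates (enables clipping of 0/1
#'   rates; without it, extreme rates are an error).
#' @return d-prime (vectorized).
#' @export
dprime <- function(hit, false_alarm, n = NULL) {
  clip <- function(p) {
    if (any(p < 0 | p > 1)) stop("rates must be in [0, 1]", call. = FALSE)
    if (is.null(n)) {
      if (any(p %in% c(0, 1))) {
        stop("rate of 0 or 1: supply `n` to enable clipping", call. = FALSE)
      }
      p
    } else {
      pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
  }
  stats::qnorm(clip(hit)) - stats::qnorm(clip(false_alarm))
}

#' Per-subject pass indicators for a combined ("Both") test
#'
#' A subject passes the combined test at a threshold only if they meet it
#' on both component tests; the conjunction is evaluated separately for
#' each equipment condition.
#'
#' @param table A [subject_table()].
#' @param test_a,test_b Component test labels.
#' @param threshold Pass threshold.
#' @return A data.frame with columns `subject_id`, `equipment`, `pass`.
#' @export
both_scores <- function(table, test_a, test_b, threshold) {
  a <- score_pair(table, test_a)
  b <- score_pair(table, test_b)
  ids <- intersect(a$subject_id, b$subject_id)
  if (length(ids) == 0) stop("no common subjects", call. = FALSE)
  ia <- match(ids, a$subject_id)
  ib <- match(ids, b$subject_id)
  rbind(
    data.frame(subject_id = ids, equipment = "headphones",
               pass = combine_both(classify_pass(a$phones[ia], threshold),
                                   classify_pass(b$phones[ib], threshold))),
    data.frame(subject_id = ids, equipment = "loudspeakers",
               pass = combine_both(classify_pass(a$speakers[ia], threshold),
                                   classify_pass(b$speakers[ib], threshold))))
}

#' ROC curve of the combined ("Both") test
#'
#' @inheritParams both_scores
#' @param thresholds Thresholds to sweep (default `6:3`).
#' @return An object of class `roc_curve`.
#' @export
roc_curve_both <- function(table, test_a, test_b, thresholds = 6:3) {
  rates <- vapply(thresholds, function(th) {
    bs <- both_scores(table, test_a, test_b, th)
    c(fa = mean(bs$pass[bs$equipment == "loudspeakers"]),
      hit = mean(bs$pass[bs$equipment == "headphones"]))
  }, numeric(2))
  new_roc_curve(c(NA, thresholds, NA), c(0, rates["fa", ], 1),
                c(0, rates["hit", ], 1),
                test = paste0("Both(", test_a, "+", test_b, ")"))
}

## ---- fast AUC kernels for resampling --------------------------------------

## AUC from aligned phone/speaker score vectors, thresholds 6:3 + anchors.
auc_from_scores <- function(phones, speakers, thresholds = 6:3) {
  hit <- vapply(thresholds, function(th) mean(phones >= th), numeric(1))
  fa <- vapply(thresholds, function(th) mean(speakers >= th), numeric(1))
  fa_all <- c(0, fa, 1)
  hit_all <- c(0, hit, 1)
  sum(diff(fa_all) * (utils::head(hit_all, -1) + utils::tail(hit_all, -1)) / 2)
}

## Matrix version: columns of `phones` / `speakers` are resamples.
auc_from_score_mats <- function(phones, speakers, thresholds = 6:3) {
  k <- length(thresholds)
  hit <- matrix(0, ncol(phones), k + 2)
  fa <- matrix(0, ncol(phones), k + 2)
  hit[, k + 2] <- 1
  fa[, k + 2] <- 1
  for (j in seq_len(k)) {
    hit[, j + 1] <- colMeans(phones >= thresholds[j])
    fa[, j + 1] <- colMeans(speakers >= thresholds[j])
  }
  rowSums((fa[, -1, drop = FALSE] - fa[, -(k + 2), drop = FALSE]) *
            (hit[, -1, drop = FALSE] + hit[, -(k + 2), drop = FALSE]) / 2)
}

## Two-tailed p from the two directional support proportions (each the
## strict proportion of resamples/permutations favoring that direction):
## the result is significant at alpha when one direction's support exceeds
## 1 - alpha/2, so p = 2 * (1 - max(support)). Ties at the boundary count
## toward neither direction's support, making the p conservative.
two_sided_p <- function(support_a, support_b, n) {
  p <- min(1, 2 * (1 - max(support_a, support_b)))
  list(p_value = max(p, 1 / n), floored = p < 1 / n)
}

#' Bootstrap test of an AUC difference between two screening tests
#'
#' Resamples whole subjects (all four condition scores together) with
#' replacement, recomputes the AUC difference per resample, and reports
#' the proportion of resampled differences falling on each side of zero.
#' The difference is significant (two-tailed, alpha = 0.05) when one
#' direction exceeds 97.5%. Ties at exactly zero count in neither
#' direction.
#'
#' @param table A [subject_table()] containing both tests in both
#'   equipment conditions.
#' @param test_a,test_b Test labels; the difference is
#'   `AUC(test_a) - AUC(test_b)`.
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Optional seed.
#' @param thresholds Thresholds to sweep (default `6:3`).
#' @return A list: `observed` (AUC difference on the original table),
#'   `auc_a`, `auc_b`, `prop_greater`/`prop_less` (resampled difference
#'   > 0 / < 0), `p_value` (two-tailed, floored at `1/n_resamples` with
#'   `p_floored` flag), `mean`, `sd`, and `quantiles` of the resampled
#'   differences.
#' @export
bootstrap_auc_diff <- function(table, test_a, test_b, n_resamples = 10000L,
                               seed = NULL, thresholds = 6:3) {
  a <- score_pair(table, test_a)
  b <- score_pair(table, test_b)
  ids <- sort(intersect(a$subject_id, b$subject_id))
  n <- length(ids)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  ia <- match(ids, a$subject_id)
  ib <- match(ids, b$subject_id)
  ph_a <- a$phones[ia]; sp_a <- a$speakers[ia]
  ph_b <- b$phones[ib]; sp_b <- b$speakers[ib]
  auc_a <- auc_from_scores(ph_a, sp_a, thresholds)
  auc_b <- auc_from_scores(ph_b, sp_b, thresholds)
  observed <- auc_a - auc_b
  diffs <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), n)
    auc_from_score_mats(matrix(ph_a[idx], n), matrix(sp_a[idx], n),
                        thresholds) -
      auc_from_score_mats(matrix(ph_b[idx], n), matrix(sp_b[idx], n),
                          thresholds)
  })
  p <- two_sided_p(mean(diffs > 0), mean(diffs < 0), n_resamples)
  list(observed = observed, auc_a = auc_a, auc_b = auc_b,
       prop_greater = mean(diffs > 0), prop_less = mean(diffs < 0),
       p_value = p$p_value, p_floored = p$floored,
       mean = mean(diffs), sd = stats::sd(diffs),
       quantiles = stats::quantile(diffs, c(0.025, 0.5, 0.975)),
       n_resamples = n_resamples, n_subjects = n)
}

#' Permutation test of an AUC difference between two screening tests
#'
#' Builds the null by relabeling: for each permutation and each subject
#' independently, the two tests' headphone scores are swapped or kept with
#' equal probability, and likewise (independently) the two loudspeaker
#' scores. The AUC difference is recomputed on each relabeled table and
#' the observed difference is compared against this null distribution
#' (strict exceedance in each direction, two-tailed).
#'
#' @inheritParams bootstrap_auc_diff
#' @param n_perms Number of permutations (default 10000).
#' @return A list: `observed`, `auc_a`, `auc_b`, `p_greater`/`p_less`
#'   (proportion of null differences above / below the observed),
#'   `p_value` (two-tailed, floored at `1/n_perms` with `p_floored`
#'   flag), and `null_sd`.
#' @export
permutation_auc_diff <- function(table, test_a, test_b, n_perms = 10000L,
                                 seed = NULL, thresholds = 6:3) {
  a <- score_pair(table, test_a)
  b <- score_pair(table, test_b)
  ids <- sort(intersect(a$subject_id, b$subject_id))
  n <- length(ids)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  ia <- match(ids, a$subject_id)
  ib <- match(ids, b$subject_id)
  ph_a <- a$phones[ia]; sp_a <- a$speakers[ia]
  ph_b <- b$phones[ib]; sp_b <- b$speakers[ib]
  observed <- auc_from_scores(ph_a, sp_a, thresholds) -
    auc_from_scores(ph_b, sp_b, thresholds)
  null_diffs <- with_seed(seed, {
    swap_h <- matrix(stats::runif(n * n_perms) < 0.5, n)
    swap_s <- matrix(stats::runif(n * n_perms) < 0.5, n)
    ph_a_m <- matrix(ph_a, n, n_perms); ph_b_m <- matrix(ph_b, n, n_perms)
    sp_a_m <- matrix(sp_a, n, n_perms); sp_b_m <- matrix(sp_b, n, n_perms)
    ph_a_p <- ifelse(swap_h, ph_b_m, ph_a_m)
    ph_b_p <- ifelse(swap_h, ph_a_m, ph_b_m)
    sp_a_p <- ifelse(swap_s, sp_b_m, sp_a_m)
    sp_b_p <- ifelse(swap_s, sp_a_m, sp_b_m)
    auc_from_score_mats(ph_a_p, sp_a_p, thresholds) -
      auc_from_score_mats(ph_b_p, sp_b_p, thresholds)
  })
  # support for the positive direction: null mass strictly below the
  # observed difference (and symmetrically for the negative direction)
  p <- two_sided_p(mean(null_diffs < observed), mean(null_diffs > observed),
                   n_perms)
  list(observed = observed,
       auc_a = auc_from_scores(ph_a, sp_a, thresholds),
       auc_b = auc_from_scores(ph_b, sp_b, thresholds),
       p_greater = mean(null_diffs > observed),
       p_less = mean(null_diffs < observed),
       p_value = p$p_value, p_floored = p$floored,
       null_sd = stats::sd(null_diffs), n_perms = n_perms, n_subjects = n)
}

#' Full signal-detection evaluation report
#'
#' Convenience wrapper producing, for each test (and optionally their
#' "Both" combination), the ROC points, AUC, and d-prime at each
#' threshold, plus inference on the AUC difference between the first two
#' tests.
#'
#' @param table A [subject_table()].
#' @param tests Tests to evaluate (default all present).
#' @param thresholds Pass thresholds (default `6:3`).
#' @param include_both Add the combined test of the first two `tests`.
#' @param n_resamples Bootstrap/permutation iterations (0 skips
#'   inference).
#' @param seed Optional seed for the inference resampling.
#' @return A list with elements `roc` (per test), `auc` (named vector),
#'   `dprime` (matrix test x threshold), and, when computed, `bootstrap`
#'   and `permutation`.
#' @export
evaluate_tests <- function(table, tests = unique(table$test),
                           thresholds = 6:3, include_both = length(tests) >= 2,
                           n_resamples = 0L, seed = NULL) {
  n <- length(unique(table$subject_id))
  rocs <- lapply(tests, function(tk) roc_curve(table, tk, thresholds))
  names(rocs) <- tests
  if (include_both) {
    rocs[["Both"]] <- roc_curve_both(table, tests[1], tests[2], thresholds)
  }
  aucs <- vapply(rocs, auc, numeric(1))
  dp <- vapply(rocs, function(rc) {
    pts <- rc$points[!is.na(rc$points$threshold), ]
    pts <- pts[order(-pts$threshold), ]
    dprime(pts$hit, pts$false_alarm, n = n)
  }, numeric(length(thresholds)))
  dp <- t(dp)
  colnames(dp) <- paste0("t", sort(thresholds, decreasing = TRUE))
  out <- list(roc = rocs, auc = aucs, dprime = dp)
  if (n_resamples > 0 && length(tests) >= 2) {
    out$bootstrap <- bootstrap_auc_diff(table, tests[1], tests[2],
                                        n_resamples, seed = seed,
                                        thresholds = thresholds)
    out$permutation <- permutation_auc_diff(table, tests[1], tests[2],
                                            n_resamples, seed = seed,
                                            thresholds = thresholds)
  }
  out
}
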