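## Headphone-proportion estimation: the score distribution of an
## unscreened cohort is modeled as a one-parameter convex mixture of a
## reference cohort's headphone and loudspeaker score distributions, with
## the mixing weight propH (the proportion of headphone users) shared
## across tests and fit by least-squares grid search.

#' Score histogram over 0-6 correct
#'
#' @param x Either a vector of block scores (integers 0-6) to tabulate, or
#'   7 proportions over the bins 0-6.
#' @param proportions Set `TRUE` when `x` already holds the 7 bin
#'   proportions.
#' @return A named numeric vector of class `score_histogram` (bins
#'   `"0"`-`"6"`, non-negative, summing to 1).
#' @export
score_histogram <- function(x, proportions = FALSE) {
  if (proportions) {
    if (length(x) != 7) stop("need 7 bin proportions", call. = FALSE)
    h <- as.numeric(x)
  } else {
    if (length(x) == 0) stop("no scores to tabulate", call. = FALSE)
    if (!all(x == round(x)) || any(x < 0) || any(x > 6)) {
      stop("scores must be integers in 0-6", call. = FALSE)
    }
    h <- as.numeric(table(factor(x, levels = 0:6))) / length(x)
  }
  if (any(h < 0) || abs(sum(h) - 1) > 1e-12) {
    stop("histogram bins must be non-negative and sum to 1", call. = FALSE)
  }
  structure(stats::setNames(h, 0:6), class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat("<score_histogram>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Score histogram of one condition in a subject table
#'
#' @param table A [subject_table()].
#' @param test,equipment Condition selectors.
#' @return A [score_histogram()].
#' @export
condition_histogram <- function(table, test, equipment) {
  sub <- table[table$test == test & table$equipment == equipment, ]
  if (nrow(sub) == 0) stop("condition not present in table", call. = FALSE)
  score_histogram(sub$n_correct)
}

#' Reference score distributions for mixture fitting
#'
#' Bundles, for each test, the headphone and loudspeaker score histograms
#' of a reference ("trusted") cohort that completed the battery over both
#' kinds of equipment.
#'
#' @param ... Named per-test lists, each `list(phones = , speakers = )` of
#'   [score_histogram()]s, e.g.
#'   `mixture_reference(HP = list(phones = h1, speakers = h2), ...)`.
#' @return An object of class `mixture_reference`.
#' @export
mixture_reference <- function(...) {
  ref <- list(...)
  if (length(ref) == 0 || is.null(names(ref)) || any(names(ref) == "")) {
    stop("supply named per-test components", call. = FALSE)
  }
  for (nm in names(ref)) {
    cmp <- ref[[nm]]
    if (!is.list(cmp) || !all(c("phones", "speakers") %in% names(cmp))) {
      stop(sprintf("component '%s' needs `phones` and `speakers`", nm),
           call. = FALSE)
    }
    for (part in c("phones", "speakers")) {
      if (!inherits(cmp[[part]], "score_histogram")) {
        stop(sprintf("'%s$%s' must be a score_histogram", nm, part),
             call. = FALSE)
      }
    }
  }
  structure(ref, class = "mixture_reference")
}

#' Reference distributions extracted from a subject table
#'
#' @param table A [subject_table()] with both equipment conditions.
#' @param tests Tests to include (default all present).
#' @return A [mixture_reference()].
#' @export
reference_from_table <- function(table, tests = unique(table$test)) {
  args <- lapply(tests, function(tk) {
    list(phones = condition_histogram(table, tk, "headphones"),
         speakers = condition_histogram(table, tk, "loudspeakers"))
  })
  names(args) <- tests
  do.call(mixture_reference, args)
}

#' Convex mixture of headphone and loudspeaker score distributions
#'
#' The modeled distribution of an unknown cohort:
#' `propH * phones + (1 - propH) * speakers`, bin-wise.
#'
#' @param hist_phones,hist_speakers [score_histogram()]s of the reference
#'   headphone and loudspeaker conditions.
#' @param prop_h Mixing proportion of headphone users, in `[0, 1]`.
#' @return A [score_histogram()].
#' @export
mix_distributions <- function(hist_phones, hist_speakers, prop_h) {
  if (!inherits(hist_phones, "score_histogram") ||
      !inherits(hist_speakers, "score_histogram")) {
    stop("inputs must be score_histograms", call. = FALSE)
  }
  if (prop_h < 0 || prop_h > 1) {
    stop("`prop_h` must be in [0, 1]", call. = FALSE)
  }
  score_histogram(prop_h * unclass(hist_phones) +
                    (1 - prop_h) * unclass(hist_speakers),
                  proportions = TRUE)
}

#' Estimate the proportion of headphone users in an unknown cohort
#'
#' Grid search over propH in 0, 0.01, ..., 1: for each candidate the
#' observed score distributions are compared against the modeled mixtures
#' of the reference distributions, and the value minimizing the sum of
#' squared errors across all tests and all 7 bins is returned (one shared
#' propH across tests; exact ties break toward the smaller propH, with a
#' flag).
#'
#' @param unknown Named list of [score_histogram()]s observed in the
#'   unknown cohort; names must match components of `reference`.
#' @param reference A [mixture_reference()].
#' @param grid_step Grid increment (default 0.01).
#' @param n_boot Optional parametric-bootstrap interval: number of
#'   multinomial resamples of the unknown histograms (0 = off).
#' @param n_unknown Cohort size behind the unknown histograms, used only
#'   for the bootstrap resampling (default 100).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `mixture_fit`: `prop_h`, `sse`,
#'   `sse_profile` (named by grid value), `modeled` (per-test mixed
#'   histograms at the optimum), `tie` flag, and `ci` when `n_boot > 0`.
#' @export
estimate_prop_h <- function(unknown, reference, grid_step = 0.01,
                            n_boot = 0L, n_unknown = 100L, seed = NULL) {
  stopifnot(inherits(reference, "mixture_reference"))
  if (is.null(names(unknown)) ||
      !all(names(unknown) %in% names(reference))) {
    stop("`unknown` names must match reference components", call. = FALSE)
  }
  for (h in unknown) {
    if (!inherits(h, "score_histogram")) {
      stop("`unknown` must hold score_histograms", call. = FALSE)
    }
  }
  grid <- seq(0, 1, by = grid_step)
  sse_for <- function(unk) {
    vapply(grid, function(p) {
      sum(vapply(names(unk), function(nm) {
        modeled <- p * unclass(reference[[nm]]$phones) +
          (1 - p) * unclass(reference[[nm]]$speakers)
        sum((unclass(unk[[nm]]) - modeled)^2)
      }, numeric(1)))
    }, numeric(1))
  }
  profile <- sse_for(unknown)
  best <- which(profile == min(profile))
  fit_p <- grid[best[1]]
  modeled <- lapply(names(unknown), function(nm) {
    mix_distributions(reference[[nm]]$phones, reference[[nm]]$speakers,
                      fit_p)
  })
  names(modeled) <- names(unknown)
  out <- structure(list(prop_h = fit_p, sse = profile[best[1]],
                        sse_profile = stats::setNames(profile, grid),
                        modeled = modeled, tie = length(best) > 1),
                   class = "mixture_fit")
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      res <- lapply(unknown, function(h) {
        score_histogram(stats::rmultinom(1, n_unknown, unclass(h))[, 1] /
                          n_unknown, proportions = TRUE)
      })
      pr <- sse_for(res)
      grid[which.min(pr)]
    }, numeric(1)))
    out$ci <- stats::quantile(boots, c(0.025, 0.975))
    out$boot_prop_h <- boots
  }
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: propH = %.2f (SSE %.5g)%s>\n", x$prop_h, x$sse,
              if (x$tie) ", tied grid minimum" else ""))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: [%.2f, %.2f]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Write a mixture fit as JSON
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mixture_fit <- function(fit, path) {
  jsonlite::write_json(
    list(prop_h = fit$prop_h, sse = fit$sse, tie = fit$tie,
         sse_profile = as.list(fit$sse_profile)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
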