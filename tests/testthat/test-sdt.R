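test_that("subject tables validate their schema", {
  expect_error(subject_table(data.frame(x = 1)), "columns")
  df <- data.frame(subject_id = "A", test = "HP", equipment = "headphones",
                   n_correct = 7)
  expect_error(subject_table(df), "0-6")
  df$n_correct <- 5
  expect_error(subject_table(rbind(df, df)), "duplicate")
  expect_s3_class(subject_table(df), "subject_table")
})

test_that("hit and false-alarm rates come from the equipment conditions", {
  tab <- make_table(HP = list(phones = c(6, 6, 4), speakers = c(6, 2, 1)))
  expect_equal(pass_rates(tab, "HP", 6),
               c(hit = 2 / 3, false_alarm = 1 / 3))
  # saturation
  sat <- make_table(HP = list(phones = rep(6, 5), speakers = rep(6, 5)))
  expect_equal(pass_rates(sat, "HP", 6), c(hit = 1, false_alarm = 1))
  expect_error(pass_rates(tab, "XX", 6), "not present")
})

test_that("ROC curves are anchored, monotone, and reflect separation", {
  perfect <- make_table(HP = list(phones = rep(6, 10), speakers = rep(0, 10)))
  rc <- roc_curve(perfect, "HP")
  expect_true(any(rc$points$false_alarm == 0 & rc$points$hit == 1))
  expect_equal(auc(rc), 1)
  # identical scores per subject in both conditions: points on the diagonal
  sc <- c(0:6, 3, 4, 5)
  same <- make_table(HP = list(phones = sc, speakers = sc))
  rc2 <- roc_curve(same, "HP")
  expect_equal(rc2$points$hit, rc2$points$false_alarm)
  expect_equal(auc(rc2), 0.5)
})

test_that("hit and false-alarm rates never decrease as the threshold drops", {
  set.seed(11)
  for (i in 1:1000) {
    tab <- make_table(T1 = list(phones = sample(0:6, 15, TRUE),
                                speakers = sample(0:6, 15, TRUE)))
    pts <- roc_curve(tab, "T1")$points
    expect_false(is.unsorted(pts$false_alarm))
    expect_false(is.unsorted(pts$hit))
  }
})

test_that("trapezoidal AUC agrees with the shoelace polygon oracle", {
  set.seed(12)
  for (i in 1:1000) {
    rc <- random_roc()
    expect_lt(abs(auc(rc) - shoelace_auc(rc$points$false_alarm,
                                         rc$points$hit)), 1e-12)
  }
})

test_that("AUC of a curve and its hit/FA reflection sum to one", {
  set.seed(13)
  for (i in 1:200) {
    rc <- random_roc()
    flipped <- headscreen:::new_roc_curve(rc$points$threshold,
                                          rc$points$hit,
                                          rc$points$false_alarm)
    expect_lt(abs(auc(rc) + auc(flipped) - 1), 1e-12)
  }
})

test_that("d-prime matches the normal-quantile definition", {
  expect_equal(round(dprime(0.81, 0.20), 2), 1.72)
  expect_equal(dprime(0.81, 0.20),
               qnorm(0.81) - qnorm(0.20), tolerance = 1e-12)
  expect_equal(dprime(0.4, 0.4), 0)
  # antisymmetry
  expect_equal(dprime(0.9, 0.3), -dprime(0.3, 0.9))
  # strictly increasing in hit, decreasing in FA
  expect_gt(dprime(0.85, 0.2), dprime(0.8, 0.2))
  expect_lt(dprime(0.8, 0.25), dprime(0.8, 0.2))
  # extreme rates clip to 1/(2N) when N is known, error otherwise
  expect_error(dprime(1, 0.2), "clipping")
  expect_equal(dprime(1, 0.2, n = 50), qnorm(1 - 1 / 100) - qnorm(0.2))
})

test_that("the Both combination bounds hold on arbitrary tables", {
  tab <- make_table(HP = list(phones = c(6, 6, 5, 4), speakers = c(6, 1, 2, 0)),
                    AP = list(phones = c(5, 6, 6, 3), speakers = c(2, 6, 0, 1)))
  bs <- both_scores(tab, "HP", "AP", 6)
  # subject 3: HP 6 but AP 6? no -> fail
  expect_false(bs$pass[bs$subject_id == "S001" &
                         bs$equipment == "headphones"])  # HP 6, AP 5
  set.seed(14)
  for (i in 1:50) {
    tab <- make_table(A = list(phones = sample(0:6, 20, TRUE),
                               speakers = sample(0:6, 20, TRUE)),
                      B = list(phones = sample(0:6, 20, TRUE),
                               speakers = sample(0:6, 20, TRUE)))
    for (th in 3:6) {
      ra <- pass_rates(tab, "A", th)
      rb <- pass_rates(tab, "B", th)
      bs <- both_scores(tab, "A", "B", th)
      hit_both <- mean(bs$pass[bs$equipment == "headphones"])
      fa_both <- mean(bs$pass[bs$equipment == "loudspeakers"])
      expect_lte(hit_both, min(ra["hit"], rb["hit"]))
      expect_lte(fa_both, min(ra["false_alarm"], rb["false_alarm"]))
    }
  }
})

planted_table <- function(n = 100, seed = 15) {
  headscreen:::with_seed(seed, make_table(
    A = list(phones = rep(6, n), speakers = rep(0, n)),
    B = list(phones = rbinom(n, 6, 1 / 3), speakers = rbinom(n, 6, 1 / 3))))
}

test_that("bootstrap inference detects planted separation and is deterministic", {
  tab <- planted_table()
  res <- bootstrap_auc_diff(tab, "A", "B", n_resamples = 10000, seed = 5)
  expect_gt(res$observed, 0.3)
  expect_lt(res$p_value, 0.001)
  res2 <- bootstrap_auc_diff(tab, "A", "B", n_resamples = 10000, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$mean, res2$mean)
})

test_that("identical tests give a maximal bootstrap p and zero exceedances", {
  sc <- rep(c(6, 3, 5, 2), 10)
  tab <- make_table(A = list(phones = sc, speakers = rep(1, 40)),
                    B = list(phones = sc, speakers = rep(1, 40)))
  res <- bootstrap_auc_diff(tab, "A", "B", n_resamples = 2000, seed = 1)
  expect_identical(res$observed, 0)
  expect_identical(res$prop_greater, 0)
  expect_identical(res$prop_less, 0)
  expect_identical(res$p_value, 1)
})

test_that("permutation inference detects planted separation; degenerate case is null", {
  tab <- planted_table()
  res <- permutation_auc_diff(tab, "A", "B", n_perms = 10000, seed = 6)
  expect_lt(res$p_value, 0.01)
  sc <- rep(c(6, 3, 5, 2), 10)
  same <- make_table(A = list(phones = sc, speakers = rep(1, 40)),
                     B = list(phones = sc, speakers = rep(1, 40)))
  res2 <- permutation_auc_diff(same, "A", "B", n_perms = 1000, seed = 6)
  expect_identical(res2$observed, 0)
  expect_identical(res2$p_value, 1)
})

test_that("inference p-values ignore subject row order", {
  tab <- planted_table(n = 40)
  shuffled <- headscreen:::with_seed(7, tab[sample(nrow(tab)), ])
  b1 <- bootstrap_auc_diff(tab, "A", "B", 2000, seed = 8)
  b2 <- bootstrap_auc_diff(subject_table(shuffled), "A", "B", 2000, seed = 8)
  expect_identical(b1$p_value, b2$p_value)
  p1 <- permutation_auc_diff(tab, "A", "B", 2000, seed = 8)
  p2 <- permutation_auc_diff(subject_table(shuffled), "A", "B", 2000, seed = 8)
  expect_identical(p1$p_value, p2$p_value)
})

test_that("the evaluation report bundles ROC, AUC, and d-prime per test", {
  tab <- planted_table(n = 50)
  ev <- evaluate_tests(tab, c("A", "B"), n_resamples = 500, seed = 9)
  expect_named(ev$auc, c("A", "B", "Both"))
  expect_equal(unname(ev$auc["A"]), 1)
  expect_identical(dim(ev$dprime), c(3L, 4L))
  expect_identical(colnames(ev$dprime), c("t6", "t5", "t4", "t3"))
  expect_lt(ev$bootstrap$p_value, 0.01)
  # subject-table CSV round trip feeds the same analysis
  path <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(tab, path)
  back <- read_subject_table(path)
  expect_equal(auc(roc_curve(back, "A")), 1)
})
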