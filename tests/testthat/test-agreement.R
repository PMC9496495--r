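test_that("paired-t TOST matches one-sided t tests computed independently", {
  cases <- list(c(1, 2, 3, 4, 5), c(-12, 4, 7, -3, 0, 9, 2),
                rnorm(20, 5, 10), c(29, 31, 30, 28, 33, 27))
  set.seed(31)
  for (d in cases) {
    for (margin in c(5, 10, 30)) {
      r <- tost_paired_t(d, margin)
      p_lo <- t.test(d, mu = -margin, alternative = "greater")$p.value
      p_hi <- t.test(d, mu = margin, alternative = "less")$p.value
      expect_equal(r$p_lower, p_lo, tolerance = 1e-12)
      expect_equal(r$p_upper, p_hi, tolerance = 1e-12)
      expect_equal(r$p_tost, max(p_lo, p_hi), tolerance = 1e-12)
    }
  }
  # small differences well inside a wide margin are clearly equivalent
  r <- tost_paired_t(c(1, 2, 3, 4, 5), 10)
  expect_lt(r$p_tost, 0.001)
  expect_true(r$equivalent)
})

test_that("paired-t TOST degenerate and boundary branches", {
  r0 <- tost_paired_t(rep(0, 6), 30)
  expect_true(r0$equivalent)
  expect_equal(r0$p_tost, 0)
  expect_true(r0$degenerate)
  # constant difference outside the margin is never equivalent
  r1 <- tost_paired_t(rep(45, 6), 30)
  expect_equal(r1$p_tost, 1)
  expect_false(r1$equivalent)
  # mean exactly at the margin: upper-sided t statistic is 0, p = 0.5
  d <- c(8, 10, 12)  # mean 10
  r2 <- tost_paired_t(d, 10)
  expect_equal(r2$p_upper, 0.5)
  expect_false(r2$equivalent)
})

test_that("TOST p-values respond correctly to the margin", {
  set.seed(77)
  d <- rnorm(15, 2, 5)
  # as the margin grows, equivalence becomes certain
  expect_lt(tost_paired_t(d, 1e4)$p_tost, 1e-10)
  expect_lt(tost_wilcoxon(d, 1e6)$p_tost, 0.01)
  # as the margin shrinks toward zero, equivalence is never declared
  expect_false(tost_paired_t(d, 1e-6)$equivalent)
  expect_false(tost_wilcoxon(d, 1e-6)$equivalent)
})

test_that("Wilcoxon TOST uses the exact signed-rank distribution for n <= 10", {
  # all shifted upper-test values positive: cannot be equivalent
  d <- c(12, 11, 13, 12, 12)
  r <- tost_wilcoxon(d, 10)
  expect_false(r$equivalent)
  expect_equal(r$p_upper, enum_signed_rank_p(d - 10, "less"), tolerance = 1e-12)

  # symmetric small differences inside a generous margin are equivalent
  r2 <- tost_wilcoxon(c(-2, -1, 0, 1, 2, -1, 1, 2), 20)
  expect_true(r2$equivalent)

  # a fixed n = 8 case matches full enumeration on both sides
  d8 <- c(3, -5, 8, 1, -2, 7, 4, -6)
  r8 <- tost_wilcoxon(d8, 10)
  expect_equal(r8$p_lower, enum_signed_rank_p(d8 + 10, "greater"),
               tolerance = 1e-12)
  expect_equal(r8$p_upper, enum_signed_rank_p(d8 - 10, "less"),
               tolerance = 1e-12)

  # random n <= 10 cases, including ties and zeros after shifting
  set.seed(88)
  for (i in 1:60) {
    n <- sample(5:10, 1)
    d <- sample(-15:15, n, replace = TRUE)
    margin <- sample(c(4, 10), 1)
    r <- tost_wilcoxon(d, margin)
    expect_equal(r$p_lower, enum_signed_rank_p(d + margin, "greater"),
                 tolerance = 1e-12, info = paste("case", i, "lower"))
    expect_equal(r$p_upper, enum_signed_rank_p(d - margin, "less"),
                 tolerance = 1e-12, info = paste("case", i, "upper"))
  }
})

test_that("large-sample Wilcoxon path matches the standard normal approximation", {
  set.seed(99)
  d <- round(rnorm(40, 3, 8), 1)
  margin <- 10
  ref_lo <- wilcox.test(d + margin, alternative = "greater", mu = 0,
                        exact = FALSE, correct = TRUE)$p.value
  ref_hi <- wilcox.test(d - margin, alternative = "less", mu = 0,
                        exact = FALSE, correct = TRUE)$p.value
  r <- tost_wilcoxon(d, margin)
  expect_equal(r$p_lower, ref_lo, tolerance = 1e-9)
  expect_equal(r$p_upper, ref_hi, tolerance = 1e-9)
})

test_that("repeated-measures Bland-Altman matches the hand-worked layout", {
  # two subjects, three days each, constant within-subject differences 1 and 3
  subj <- rep(c("p1", "p2"), each = 3)
  b <- c(400, 410, 420, 430, 440, 450)
  a <- b + rep(c(1, 3), each = 3)
  r <- bland_altman_rm(subj, a, b)
  # hand ANOVA on the 2x3 layout: MSB = 6, MSW = 0, n0 = 3
  expect_equal(r$bias, 2)
  expect_equal(r$var_within, 0)
  expect_equal(r$var_between, 2)
  expect_equal(r$sd_total, sqrt(2))
  expect_equal(r$loa_low, 2 - 1.96 * sqrt(2))
  expect_equal(r$loa_high, 2 + 1.96 * sqrt(2))
})

test_that("Bland-Altman degenerate and error branches", {
  subj <- rep(c("p1", "p2", "p3"), each = 2)
  a <- c(400, 410, 420, 430, 440, 450)
  r <- bland_altman_rm(subj, a, a)
  expect_equal(r$bias, 0)
  expect_equal(r$loa_low, 0)
  expect_equal(r$loa_high, 0)
  expect_equal(r$slope, 0)
  expect_error(bland_altman_rm(rep("p1", 5), rnorm(5), rnorm(5)),
               ">= 2 subjects")
})

test_that("Bland-Altman slope recovers a known proportional bias", {
  # true slope 0.14 between difference and pair mean, with subject effects;
  # the cluster-robust 95% CI should cover the truth in most replicates
  set.seed(1234)
  reps <- 200
  covered <- 0
  for (i in 1:reps) {
    subj <- rep(sprintf("p%02d", 1:30), each = 7)
    m <- rnorm(210, 420, 40)
    d <- 0.14 * m + rep(rnorm(30, 0, 3), each = 7) + rnorm(210, 0, 4)
    a <- m + d / 2
    b <- m - d / 2
    r <- bland_altman_rm(subj, a, b)
    if (r$slope_ci[1] <= 0.14 && 0.14 <= r$slope_ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.93)
})

test_that("ICCs follow the Shrout-Fleiss mean-squares arithmetic", {
  # identical raters: perfect agreement and consistency
  x <- c(400, 380, 455, 395, 430, 362)
  r <- icc_shrout_fleiss(cbind(x, x))
  expect_equal(r$icc_2_1, 1)
  expect_equal(r$icc_3_1, 1)

  # constant offset: consistency perfect, absolute agreement penalised
  r5 <- icc_shrout_fleiss(cbind(x, x + 5))
  expect_equal(r5$icc_3_1, 1)
  expect_lt(r5$icc_2_1, 1)

  # hand-worked 6x2 table, frozen from spreadsheet-style sums of squares
  a <- c(410, 380, 455, 395, 430, 362)
  b <- c(425, 370, 450, 415, 446, 375)
  rh <- icc_shrout_fleiss(cbind(a, b))
  expect_equal(rh$msr, 2246.6833333333, tolerance = 1e-10)
  expect_equal(rh$msc, 200.0833333333, tolerance = 1e-10)
  expect_equal(rh$mse, 77.4833333333, tolerance = 1e-10)
  expect_equal(rh$icc_2_1, 0.917196374963, tolerance = 1e-10)
  expect_equal(rh$icc_3_1, 0.933323771961, tolerance = 1e-10)

  # independent route: mean squares from aov()
  long <- data.frame(y = c(a, b), subj = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- as.data.frame(summary(aov(y ~ subj + rater, data = long))[[1]])
  expect_equal(rh$msr, ms["subj", "Mean Sq"], tolerance = 1e-9)
  expect_equal(rh$msc, ms["rater", "Mean Sq"], tolerance = 1e-9)
  expect_equal(rh$mse, ms["Residuals", "Mean Sq"], tolerance = 1e-9)
})

test_that("agreement and consistency ICCs coincide as rater bias vanishes", {
  # the two ICCs differ only through the rater mean square: they are equal
  # exactly when MSC = MSE, and with equal rater means the finite-sample
  # gap is O(1/n) and vanishes with the number of subjects
  set.seed(42)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    m <- matrix(rnorm(2 * n, 400, 50), ncol = 2)
    m[, 2] <- m[, 2] - mean(m[, 2]) + mean(m[, 1])  # equalise rater means
    r <- icc_shrout_fleiss(m)
    # algebraic identity: denominators differ by k (MSC - MSE) / n
    gap <- (r$msr - r$mse) * r$k * (r$msc - r$mse) / r$n
    denom31 <- r$msr + (r$k - 1) * r$mse
    expect_equal(r$icc_2_1 * (denom31 + r$k * (r$msc - r$mse) / r$n),
                 r$icc_3_1 * denom31, tolerance = 1e-9)
    expect_lte(r$icc_2_1, 1)
    expect_lte(r$icc_3_1, 1)
  }
  # shrinking gap under equal rater means as n grows
  gap_at <- function(n) {
    m <- matrix(rnorm(2 * n, 400, 50), ncol = 2)
    m[, 2] <- 0.9 * m[, 1] + rnorm(n, 0, 15)
    m[, 2] <- m[, 2] - mean(m[, 2]) + mean(m[, 1])
    r <- icc_shrout_fleiss(m)
    abs(r$icc_2_1 - r$icc_3_1)
  }
  set.seed(43)
  expect_lt(mean(replicate(30, gap_at(400))), mean(replicate(30, gap_at(25))))
  expect_lt(mean(replicate(30, gap_at(400))), 0.01)
  # a positive rater variance component makes consistency exceed agreement
  x <- rnorm(12, 400, 50)
  r_off <- icc_shrout_fleiss(cbind(x, x + 20))
  expect_gt(r_off$icc_3_1, r_off$icc_2_1)
})

test_that("degenerate ICC inputs are flagged, not NaN", {
  r <- icc_shrout_fleiss(matrix(5, nrow = 4, ncol = 2))
  expect_equal(r$icc_2_1, 0)
  expect_true(r$degenerate)
  expect_error(icc_shrout_fleiss(matrix(1:4, ncol = 2)), ">= 3")
})

make_paired <- function(subject, ref, tst, start = "2023-01-03 23:00:00") {
  n <- length(ref)
  out <- data.frame(subject_id = subject,
                    timestamp = minute_seq(start, n),
                    lying_a = 1L, lying_b = 1L,
                    sleeping_a = as.integer(ref),
                    sleeping_b = as.integer(tst),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_epochs", "data.frame")
  out
}

test_that("epoch confusion metrics match direct counting", {
  # identical devices: perfect everything
  set.seed(3)
  x <- rbinom(200, 1, 0.7)
  cm <- epoch_confusion(make_paired("s1", x, x))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$accuracy, 1)

  # 10 reference sleep minutes (9 matched), 10 wake (8 matched)
  ref <- rep(c(1, 0), each = 10)
  tst <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  cm2 <- epoch_confusion(make_paired("s1", ref, tst))
  expect_equal(cm2$sensitivity, 0.9)
  expect_equal(cm2$specificity, 0.8)
  expect_equal(cm2$lr_pos, 4.5)
  expect_equal(cm2$lr_neg, 0.125)
  expect_equal(cm2$accuracy, 17 / 20)
})

test_that("pooled and per-subject confusion differ under unequal minutes", {
  # subject 1: many epochs, modest accuracy; subject 2: few epochs, perfect
  ref1 <- rep(c(1, 0), each = 100)
  tst1 <- c(rep(1, 80), rep(0, 20), rep(0, 60), rep(1, 40))
  ref2 <- rep(c(1, 0), each = 5)
  tst2 <- ref2
  pe <- rbind(make_paired("s1", ref1, tst1),
              make_paired("s2", ref2, tst2, start = "2023-01-04 23:00:00"))
  class(pe) <- c("paired_epochs", "data.frame")
  cm <- epoch_confusion(pe)
  # brute-force counting oracle, per subject then pooled
  sens1 <- 80 / 100; sens2 <- 1
  expect_equal(cm$sensitivity, (80 + 5) / 105)  # pooled
  expect_equal(sort(cm$per_subject$sensitivity), sort(c(sens1, sens2)))
  expect_equal(unname(cm$subject_mean$sensitivity["mean"]),
               mean(c(sens1, sens2)))
  expect_false(isTRUE(all.equal(cm$sensitivity,
                                unname(cm$subject_mean$sensitivity["mean"]))))
  # identities
  expect_equal(cm$accuracy,
               (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn))
  expect_equal(cm$lr_pos * (1 - cm$specificity), cm$sensitivity)
})

test_that("confusion metrics respect the night window and the reference", {
  ref <- c(1, 1, 0, 0)
  tst <- c(1, 0, 0, 1)
  # two epochs at 15:00 (daytime) and two at 23:00 (night)
  pe <- rbind(make_paired("s1", ref[1:2], tst[1:2], start = "2023-01-03 15:00:00"),
              make_paired("s1", ref[3:4], tst[3:4], start = "2023-01-03 23:00:00"))
  class(pe) <- c("paired_epochs", "data.frame")
  # only the two night epochs count (their reference minutes are all wake,
  # so the per-subject sensitivity warning is expected here)
  cm <- suppressWarnings(epoch_confusion(pe))
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 2)
  cm_all <- epoch_confusion(pe, night_only = FALSE)
  expect_equal(cm_all$tp + cm_all$tn + cm_all$fp + cm_all$fn, 4)
  # swapping the reference transposes the roles
  cm_b <- suppressWarnings(epoch_confusion(pe, reference = "b",
                                           night_only = FALSE))
  expect_equal(cm_b$fp, cm_all$fn)
  expect_equal(cm_b$fn, cm_all$fp)
})

test_that("a subject with no reference wake minutes is excluded with warning", {
  pe <- rbind(make_paired("s1", rep(1, 10), rep(1, 10)),
              make_paired("s2", c(1, 1, 0, 0), c(1, 1, 0, 1),
                          start = "2023-01-04 23:00:00"))
  class(pe) <- c("paired_epochs", "data.frame")
  expect_warning(cm <- epoch_confusion(pe), "no reference wake")
  expect_equal(unname(cm$subject_mean$specificity["n"]), 1)
})
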