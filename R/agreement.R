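#' Paired-t two one-sided tests (TOST) for equivalence
#'
#' Tests whether the mean of paired differences lies inside the a-priori
#' equivalence margin `(-margin, +margin)`: one one-sided t test of
#' H0: mean <= -margin and one of H0: mean >= +margin, on n - 1 degrees of
#' freedom. Equivalence is declared when the larger of the two one-sided
#' p-values is below `alpha`.
#'
#' With zero variance the t statistic is undefined; the degenerate branch
#' declares equivalence (p = 0) when the common difference is strictly inside
#' the margin and non-equivalence (p = 1) otherwise.
#'
#' @param diffs numeric vector of per-subject paired differences.
#' @param margin positive equivalence margin, in the units of `diffs`.
#' @param alpha significance level.
#' @param variable optional label carried into the result.
#' @return a `tost_result` list: `variable`, `method`, `n`, `estimate` (mean
#'   difference), `margin`, `p_lower`, `p_upper`, `p_tost`, `equivalent`,
#'   `alpha`, `degenerate`.
#' @export
tost_paired_t <- function(diffs, margin, alpha = 0.05, variable = NA_character_) {
  stopifnot(margin > 0, length(diffs) >= 2)
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    p <- if (abs(m) < margin) 0 else 1
    return(tost_result(variable, "paired-t", n, m, margin, p, p, alpha,
                       degenerate = TRUE))
  }
  se <- s / sqrt(n)
  p_lower <- stats::pt((m + margin) / se, df = n - 1, lower.tail = FALSE)
  p_upper <- stats::pt((m - margin) / se, df = n - 1, lower.tail = TRUE)
  tost_result(variable, "paired-t", n, m, margin, p_lower, p_upper, alpha)
}

#' Wilcoxon signed-rank TOST for equivalence
#'
#' Nonparametric analogue of [tost_paired_t()]: one-sided signed-rank tests
#' of location against `-margin` (alternative: greater) and `+margin`
#' (alternative: less), with `p_tost` the larger one-sided p-value. For 10 or
#' fewer nonzero shifted differences the null distribution is enumerated
#' exactly over all sign assignments (ties handled by mid-ranks); larger
#' samples use the normal approximation with tie correction and continuity
#' correction. Zeros are dropped, as is conventional for the signed-rank
#' statistic.
#'
#' @inheritParams tost_paired_t
#' @param exact_max largest sample size for exact enumeration.
#' @return a `tost_result` (estimate is the median difference).
#' @export
tost_wilcoxon <- function(diffs, margin, alpha = 0.05,
                          variable = NA_character_, exact_max = 10) {
  stopifnot(margin > 0, length(diffs) >= 2)
  n <- length(diffs)
  med <- stats::median(diffs)
  p_lower <- signed_rank_p(diffs + margin, alternative = "greater",
                           exact_max = exact_max)
  p_upper <- signed_rank_p(diffs - margin, alternative = "less",
                           exact_max = exact_max)
  degen <- is.na(p_lower) || is.na(p_upper)
  if (degen) {
    p <- if (abs(med) < margin) 0 else 1
    if (is.na(p_lower)) p_lower <- p
    if (is.na(p_upper)) p_upper <- p
  }
  tost_result(variable, "wilcoxon", n, med, margin, p_lower, p_upper, alpha,
              degenerate = degen)
}

# one-sided signed-rank p-value; NA when no nonzero values remain
signed_rank_p <- function(x, alternative = c("greater", "less"),
                          exact_max = 10) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(NA_real_)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    # exact: all 2^n sign assignments of the realised ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.vector(signs %*% r)
    if (alternative == "greater") mean(wdist >= w - 1e-9) else mean(wdist <= w + 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (alternative == "greater") {
      stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      stats::pnorm((w - mu + 0.5) / sqrt(sigma2), lower.tail = TRUE)
    }
  }
}

tost_result <- function(variable, method, n, estimate, margin,
                        p_lower, p_upper, alpha, degenerate = FALSE) {
  p_tost <- max(p_lower, p_upper)
  structure(list(variable = variable, method = method, n = n,
                 estimate = estimate, margin = margin,
                 p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
                 equivalent = p_tost < alpha, alpha = alpha,
                 degenerate = degenerate),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST (%s)%s: n=%d, estimate=%.3f, margin=%.3f, p=%.4g -> %s\n",
              x$method,
              if (!is.na(x$variable)) paste0(" for ", x$variable) else "",
              x$n, x$estimate, x$margin, x$p_tost,
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Repeated-measures Bland-Altman agreement
#'
#' Bland-Altman analysis for person-day data where each subject contributes
#' several paired measurements. The bias is the grand mean of the differences
#' `d = A - B`. The SD of a single difference combines the between-subject
#' and within-subject components estimated from a one-way ANOVA of `d` on
#' subject (method of moments, with the unbalanced-design coefficient
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`); limits of agreement are
#' `bias +/- 1.96 * sd_total`. Proportional bias is the slope of `d` on the
#' pair mean `(A + B)/2`, fitted by ordinary least squares (equivalently a
#' working-independence estimating equation) with a cluster-robust sandwich
#' variance by subject.
#'
#' @param subject subject identifier per pair.
#' @param a,b paired measurements from devices A and B.
#' @param conf_q quantile for the limits of agreement (1.96 for 95%).
#' @return a `ba_result` list: `bias`, `sd_total`, `loa_low`, `loa_high`,
#'   `var_between`, `var_within`, `slope`, `slope_se`, `slope_ci`, `slope_p`,
#'   `n_subjects`, `n_pairs`, and `points` (a plot-ready data.frame of
#'   subject, mean, difference).
#' @export
bland_altman_rm <- function(subject, a, b, conf_q = 1.96) {
  stopifnot(length(a) == length(b), length(subject) == length(a))
  keep <- !(is.na(a) | is.na(b))
  subject <- as.character(subject)[keep]
  a <- a[keep]; b <- b[keep]
  d <- a - b
  m <- (a + b) / 2
  k <- length(unique(subject))
  if (k < 2) {
    stop("bland_altman_rm needs >= 2 subjects; for a single subject use a ",
         "simple Bland-Altman on independent differences", call. = FALSE)
  }
  N <- length(d)
  bias <- mean(d)
  ni <- tapply(d, subject, length)
  mi <- tapply(d, subject, mean)
  msb <- sum(ni * (mi - bias)^2) / (k - 1)
  ssw <- sum((d - mi[subject])^2)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_between <- max(0, (msb - msw) / n0)
  sd_total <- sqrt(var_between + msw)

  if (stats::var(d) == 0) {
    # constant difference: no proportional bias by construction
    slope <- 0; slope_se <- 0; slope_ci <- c(0, 0); slope_p <- NA_real_
  } else if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    vc <- sandwich::vcovCL(fit, cluster = subject)
    slope <- unname(stats::coef(fit)["m"])
    slope_se <- sqrt(vc["m", "m"])
    slope_ci <- slope + c(-1, 1) * stats::qnorm(0.975) * slope_se
    slope_p <- 2 * stats::pnorm(-abs(slope / slope_se))
  } else {
    slope <- 0; slope_se <- NA_real_; slope_ci <- c(NA_real_, NA_real_)
    slope_p <- NA_real_
  }

  structure(list(bias = bias, sd_total = sd_total,
                 loa_low = bias - conf_q * sd_total,
                 loa_high = bias + conf_q * sd_total,
                 var_between = var_between, var_within = msw,
                 slope = slope, slope_se = slope_se, slope_ci = slope_ci,
                 slope_p = slope_p, n_subjects = k, n_pairs = N,
                 points = data.frame(subject = subject, mean = m,
                                     difference = d,
                                     stringsAsFactors = FALSE)),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (repeated measures): bias=%.3f, LoA=(%.3f, %.3f)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  %d subjects, %d pairs; slope=%.3f (95%% CI %.3f, %.3f)\n",
              x$n_subjects, x$n_pairs, x$slope, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Shrout-Fleiss intraclass correlations for two raters
#'
#' Single-rater ICCs from the two-way ANOVA decomposition of an n x k matrix
#' (subjects by raters/devices): ICC(2,1), absolute agreement, treats raters
#' as random and is penalised by a systematic rater offset; ICC(3,1),
#' consistency, is not. Rows with missing cells are dropped (complete-case).
#'
#' @param mat numeric matrix or data.frame, subjects in rows, raters in
#'   columns (k = 2 in the device-comparison use).
#' @return an `icc_result` list: `icc_2_1`, `icc_3_1`, mean squares `msr`
#'   (subjects), `msc` (raters), `mse`, `n`, `k`, `degenerate`.
#' @export
icc_shrout_fleiss <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("icc_shrout_fleiss needs >= 3 complete subjects", call. = FALSE)
  if (k < 2) stop("icc_shrout_fleiss needs >= 2 raters", call. = FALSE)
  gm <- mean(mat)
  rm_ <- rowMeans(mat)
  cm <- colMeans(mat)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom21 <- msr + (k - 1) * mse + k * (msc - mse) / n
  denom31 <- msr + (k - 1) * mse
  degenerate <- denom21 <= 0 || denom31 <= 0 || msr == 0
  icc21 <- if (degenerate) 0 else (msr - mse) / denom21
  icc31 <- if (degenerate) 0 else (msr - mse) / denom31
  structure(list(icc_2_1 = icc21, icc_3_1 = icc31,
                 msr = msr, msc = msc, mse = mse, n = n, k = k,
                 degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1)=%.3f (absolute agreement), ICC(3,1)=%.3f (consistency), n=%d\n",
              x$icc_2_1, x$icc_3_1, x$n))
  invisible(x)
}

#' Epoch-level confusion metrics against a reference device
#'
#' Sensitivity is the proportion of reference sleep minutes the test device
#' also classifies as sleep; specificity is the proportion of reference wake
#' minutes the test device classifies as wake. Likelihood ratios are
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, always computed
#' from unrounded proportions. Metrics are reported pooled over all epochs
#' and per subject, with a t-based 95% CI on the per-subject means. By
#' default only nighttime minutes (the scoring night window) enter.
#'
#' @param paired a `paired_epochs` table from [align_two_devices()].
#' @param reference `"a"` or `"b"`: which device is the criterion. Metrics
#'   are asymmetric in this choice.
#' @param night_only restrict to minutes inside `[night_start, night_end]`.
#' @param config a [scoring_config()] supplying the night window.
#' @return a `confusion_metrics` list with pooled `sensitivity`,
#'   `specificity`, `accuracy`, `lr_pos`, `lr_neg`, counts, a `per_subject`
#'   data.frame, and `subject_mean` summaries (mean, 95% CI, n).
#' @export
epoch_confusion <- function(paired, reference = c("a", "b"),
                            night_only = TRUE, config = scoring_config()) {
  reference <- match.arg(reference)
  ref <- if (reference == "a") paired$sleeping_a else paired$sleeping_b
  tst <- if (reference == "a") paired$sleeping_b else paired$sleeping_a
  subj <- as.character(paired$subject_id)
  if (night_only) {
    msn <- timestamp_msn(paired$timestamp)
    keep <- msn >= config$night_start_msn & msn <= config$night_end_msn
    ref <- ref[keep]; tst <- tst[keep]; subj <- subj[keep]
  }
  if (!length(ref)) stop("no epochs left after night-window restriction", call. = FALSE)

  pooled <- confusion_counts(ref, tst)
  per <- do.call(rbind, lapply(split(seq_along(ref), subj), function(idx) {
    cc <- confusion_counts(ref[idx], tst[idx])
    data.frame(subject_id = subj[idx[1]], n_epochs = length(idx),
               sensitivity = cc$sensitivity, specificity = cc$specificity,
               accuracy = cc$accuracy, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  if (any(is.na(per$specificity))) {
    warning(sum(is.na(per$specificity)),
            " subject(s) with no reference wake minutes: specificity ",
            "undefined, excluded from the per-subject mean", call. = FALSE)
  }
  if (any(is.na(per$sensitivity))) {
    warning(sum(is.na(per$sensitivity)),
            " subject(s) with no reference sleep minutes: sensitivity ",
            "undefined, excluded from the per-subject mean", call. = FALSE)
  }
  t_ci <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    m <- mean(x)
    half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else NA_real_
    c(mean = m, lo = m - half, hi = m + half, n = n)
  }
  structure(c(pooled,
              list(reference = reference, per_subject = per,
                   subject_mean = list(sensitivity = t_ci(per$sensitivity),
                                       specificity = t_ci(per$specificity),
                                       accuracy = t_ci(per$accuracy)))),
            class = "confusion_metrics")
}

confusion_counts <- function(ref, tst) {
  tp <- sum(ref == 1L & tst == 1L)
  fn <- sum(ref == 1L & tst == 0L)
  tn <- sum(ref == 0L & tst == 0L)
  fp <- sum(ref == 0L & tst == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       lr_pos = if (!is.na(sens) && !is.na(spec)) sens / (1 - spec) else NA_real_,
       lr_neg = if (!is.na(sens) && !is.na(spec)) (1 - sens) / spec else NA_real_)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Epoch confusion vs reference '%s' (pooled over %d epochs):\n",
              x$reference, x$tp + x$fn + x$tn + x$fp))
  cat(sprintf("  sensitivity=%.3f specificity=%.3f accuracy=%.3f LR+=%.2f LR-=%.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$lr_pos, x$lr_neg))
  sm <- x$subject_mean
  cat(sprintf("  per-subject means: sens %.3f (%.3f, %.3f), spec %.3f (%.3f, %.3f), n=%d\n",
              sm$sensitivity["mean"], sm$sensitivity["lo"], sm$sensitivity["hi"],
              sm$specificity["mean"], sm$specificity["lo"], sm$specificity["hi"],
              as.integer(sm$sensitivity["n"])))
  invisible(x)
}

#' Default a-priori equivalence margins
#'
#' 30 minutes for bedtime, sleep onset, sleep offset, waketime, midpoint,
#' TIB, and TST; 10 minutes for sleep regularity, SOL, and WASO; 5 events
#' for SF; 3 percentage points for SE.
#'
#' @return named numeric vector of margins keyed by variable.
#' @export
default_margins <- function() {
  c(bedtime = 30, sleep_onset = 30, sleep_offset = 30, waketime = 30,
    midpoint = 30, tib = 30, tst = 30,
    regularity = 10, sol = 10, waso = 10,
    sf = 5, se = 3)
}

#' Full two-device agreement battery
#'
#' Reproduces the validation battery for two devices observing the same
#' subjects: per-variable equivalence tests (both paired-t and Wilcoxon
#' TOST) on weekly per-subject summaries, Shrout-Fleiss ICCs and
#' repeated-measures Bland-Altman on person-day data, and epoch-level
#' confusion metrics when a paired epoch table is supplied.
#'
#' The paired-t and Wilcoxon TOST are both reported for every variable; the
#' `method` column marks which one a Shapiro-Wilk normality check on the
#' differences (rejection at 0.05 selects Wilcoxon) would choose, and
#' `p_tost` / `equivalent` follow that choice.
#'
#' @param nightly_a,nightly_b nightly tables from [score_epochs()] for the
#'   two devices (device A is conventionally the criterion).
#' @param paired optional `paired_epochs` table for confusion metrics.
#' @param margins named margins as in [default_margins()].
#' @param reference reference device for confusion metrics, `"a"` or `"b"`.
#' @param alpha significance level.
#' @param config a [scoring_config()].
#' @return an `agreement_report` list: `equivalence` (Table-2-style
#'   data.frame), `icc` (Table-3-style data.frame), `bland_altman` (named
#'   list of `ba_result`), `ba_points` (long plot-ready data.frame), and
#'   `confusion` (or `NULL`).
#' @export
compare_devices <- function(nightly_a, nightly_b, paired = NULL,
                            margins = default_margins(),
                            reference = "a", alpha = 0.05,
                            config = scoring_config()) {
  wa <- weekly_summary(nightly_a, config$min_weekdays, config$min_weekend_days)
  wb <- weekly_summary(nightly_b, config$min_weekdays, config$min_weekend_days)
  shared <- intersect(wa$subject_id, wb$subject_id)
  if (!length(shared)) {
    stop("no subjects with valid weeks on both devices; missing from one ",
         "device: ",
         paste(union(setdiff(wa$subject_id, wb$subject_id),
                     setdiff(wb$subject_id, wa$subject_id)), collapse = ", "),
         call. = FALSE)
  }
  wa <- wa[match(shared, wa$subject_id), ]
  wb <- wb[match(shared, wb$subject_id), ]

  vars <- names(default_margins())
  weekly_col <- function(v) if (v == "regularity") "regularity_min" else paste0(v, "_mean")

  eq <- do.call(rbind, lapply(vars, function(v) {
    xa <- wa[[weekly_col(v)]]
    xb <- wb[[weekly_col(v)]]
    d <- xb - xa
    marg <- margins[[v]]
    tt <- tost_paired_t(d, marg, alpha, variable = v)
    tw <- tost_wilcoxon(d, marg, alpha, variable = v)
    sw_p <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
    method <- if (!is.na(sw_p) && sw_p < 0.05) "wilcoxon" else "paired-t"
    sel <- if (method == "wilcoxon") tw else tt
    data.frame(variable = v, n = length(d),
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               mean_diff = mean(d), margin = marg,
               p_t = tt$p_tost, p_wilcoxon = tw$p_tost,
               method = method, p_tost = sel$p_tost,
               equivalent = sel$equivalent, stringsAsFactors = FALSE)
  }))

  # person-day joins for ICC / Bland-Altman
  ka <- paste(nightly_a$subject_id, nightly_a$anchor_date)
  kb <- paste(nightly_b$subject_id, nightly_b$anchor_date)
  ia <- match(intersect(ka, kb), ka)
  ib <- match(ka[ia], kb)
  day_vars <- setdiff(vars, "regularity")
  nightly_col <- function(v) {
    switch(v, se = "se_pct", sf = "sf_n", paste0(v, "_min"))
  }
  icc <- do.call(rbind, lapply(day_vars, function(v) {
    m <- cbind(a = nightly_a[[nightly_col(v)]][ia],
               b = nightly_b[[nightly_col(v)]][ib])
    r <- icc_shrout_fleiss(m)
    data.frame(variable = v, icc_2_1 = r$icc_2_1, icc_3_1 = r$icc_3_1,
               n_person_days = r$n, stringsAsFactors = FALSE)
  }))
  ba <- lapply(day_vars, function(v) {
    bland_altman_rm(nightly_a$subject_id[ia],
                    a = nightly_b[[nightly_col(v)]][ib],
                    b = nightly_a[[nightly_col(v)]][ia])
  })
  names(ba) <- day_vars
  ba_points <- do.call(rbind, lapply(day_vars, function(v) {
    p <- ba[[v]]$points
    p$variable <- v
    p
  }))

  conf <- if (!is.null(paired)) {
    epoch_confusion(paired, reference = reference, config = config)
  }
  structure(list(equivalence = eq, icc = icc, bland_altman = ba,
                 ba_points = ba_points, confusion = conf,
                 subjects = shared),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report over", length(x$subjects), "subjects\n\n")
  cat("Equivalence (TOST on weekly summaries):\n")
  print(x$equivalence[, c("variable", "mean_a", "mean_b", "margin",
                          "method", "p_tost", "equivalent")],
        row.names = FALSE, digits = 4)
  cat("\nICC (person-days):\n")
  print(x$icc, row.names = FALSE, digits = 3)
  if (!is.null(x$confusion)) {
    cat("\n")
    print(x$confusion)
  }
  invisible(x)
}
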