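---
title: "Scoring nightly sleep from wearable epoch data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring nightly sleep from wearable epoch data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A research-grade armband or wrist actigraph reduces each minute of wear to
two binary judgements: *is the wearer lying down?* and *is the wearer
asleep?* Manufacturer software typically reports only total sleep time.
For sleep epidemiology one wants the full nightly picture — when the
subject went to bed, fell asleep, woke, and got up; how efficient and how
fragmented the night was; and how regular waketimes are across a week.
`actisleep` computes these indices from the minute-level stream, and
provides the agreement statistics needed to validate one epoch-level
device against another.

Everything operates on a **minutes-since-noon** axis: analysis days run
12:00 to 11:59 the next calendar day, so slot 0 is noon, slot 720 is
midnight, and slot 1439 is 11:59 the next morning. On this axis an
ordinary night is a monotone interval, so means, SDs, and midpoints of
clock times are plain arithmetic — no circular statistics — and a night's
sleep is never split across two analysis days. Clock means are reported
back modulo 24 h (`msn_to_clock()`).

## The night-window algorithm

Scoring one noon-to-noon day proceeds in four steps
(`detect_sleep_window()`), searching only the configurable night window
(default 19:00–11:59):

1. **Candidate onset** — the first minute classified both lying down and
   asleep inside the night window. If no such minute exists the night is
   unscored (`NULL`), never an error.
2. **Evening resets** — scanning forward from the candidate, every wake
   bout of at least `wake_reset_minutes` (default 10) that starts before
   midnight moves the onset to the next lying-and-asleep minute. The rule
   applies iteratively to every qualifying bout, not just the first: its
   purpose is to skip evening periods of extended wakefulness (reading,
   television) that follow a brief initial doze. Nights where it fires are
   flagged `onset_reset` so they can be audited.
3. **Awake at midnight** — if the subject is awake at 24:00, the onset
   becomes the first lying-and-asleep minute after midnight (flag
   `awake_at_midnight`). This rule only ever moves the onset later, and it
   also covers short (< 10 min) wake bouts that happen to straddle
   midnight.
4. **Offset** — the window extends across lying-and-asleep bouts and ends
   one past the last such minute that is followed, before any further
   lying-and-asleep minute, by at least `upright_terminate_minutes`
   (default 90) *consecutive* not-lying minutes; otherwise it ends at the
   night window's edge (flag `truncated_at_night_end`).

Two interpretation choices in step 4 deserve emphasis. First, *upright*
means the lying indicator is 0, regardless of the sleep bit, and the 90
minutes must be consecutive — "followed by 90 minutes of upright time"
is read strictly, which is the conservative reading. Second, the window is
anchored on minutes that are **lying and asleep**, not merely asleep.
Epoch-level classifiers occasionally emit isolated "sleep" minutes while
the wearer is upright and active in the morning; if bare sleep minutes
could extend the window, a device with imperfect wake specificity would
have its offset dragged toward the end of the night window by a chain of
spurious minutes spaced closer than 90 minutes apart, inflating WASO by
hours. Anchoring on the posture-confirmed minutes makes the offset robust
to exactly the noise such devices produce. Sleep minutes inside the window
still count toward TST whether or not the posture bit agrees.

The bed window (`detect_bed_window()`) extends the contiguous lying run
backward from onset (bedtime) and forward from offset (waketime). When no
lying minute precedes the onset, bedtime equals onset and SOL is 0.

All intervals are half-open — `[onset, offset)`, `[bedtime, waketime)` —
which makes the arithmetic exact: TST + WASO = offset − onset on every
night, TIB = waketime − bedtime, and slot counting is unambiguous. The
midpoint is onset + (offset − onset)/2, reported to half-minute precision.
SF counts every maximal wake run inside the window, with no minimum bout
length: a single wake minute is one fragmentation.

### Degenerate inputs and flags

- Nonwear minutes (absent rows, or `wearing = 0`) are masked: both
  indicators are treated as 0. Nonwear inside the bed window is scored as
  wake and the night is flagged `nonwear_in_tib`.
- A day below the wear-time threshold (default 1361 min = 95% of 1440) is
  not scored at all.
- Timestamps are wall clock; duplicated minutes are an error naming the
  offending stream and minute. Clock shifts therefore surface as
  duplicates (rejected) or gaps (nonwear), and a day distorted enough to
  matter fails the 95% wear rule.
- A noon-to-noon day is a weekend day iff its anchor (noon start) date is
  Saturday or Sunday: the night the day mostly covers begins on the anchor
  date.

## Weekly summaries

`weekly_summary()` aggregates one device's nightly table per subject,
keeping subjects with at least 2 valid weekday and 1 valid weekend nights.
Means and SDs use the sample (n − 1) denominator — the natural choice for
a 3-to-7-night sample — and clock variables are averaged in minutes since
noon. Sleep regularity is the sample SD of waketime in minutes, computed
on the same weekly-valid subset as every other weekly variable.

## The agreement battery

`compare_devices()` reproduces a standard device-validation analysis:

- **Equivalence (TOST)** on weekly per-subject summaries, at a-priori
  margins: 30 min for bedtime, onset, offset, waketime, midpoint, TIB,
  TST; 10 min for regularity, SOL, WASO; 5 events for SF; 3% for SE. Both
  the paired-*t* and the Wilcoxon signed-rank TOST are always reported;
  the headline `p_tost` follows a Shapiro–Wilk normality check on the
  differences (rejection at 0.05 selects the rank test). With zero
  variance the t statistic is undefined, so the degenerate branch declares
  p = 0 when the constant difference is strictly inside the margin and
  p = 1 otherwise. The Wilcoxon path drops zeros, uses mid-ranks for ties,
  enumerates the exact null over all 2^n sign assignments for n ≤ 10
  nonzero values, and otherwise uses the normal approximation with tie and
  continuity corrections.
- **Repeated-measures Bland–Altman** on person-days. The SD of a single
  difference combines between- and within-subject components from a
  one-way ANOVA of the differences on subject, by method of moments with
  the unbalanced-design coefficient n0 = (N − Σn²ᵢ/N)/(k − 1). Method of
  moments (not REML) is deliberate: it is the classical repeated-measures
  Bland–Altman estimator, closed-form, and testable against hand-worked
  tables. Negative between-subject estimates are truncated at zero.
  Proportional bias is the OLS slope of difference on pair mean —
  identical to a working-independence estimating equation — with a
  cluster-by-subject sandwich variance (`sandwich::vcovCL`). A single
  subject is an error: the between component is inestimable and a simple
  Bland–Altman should be used instead.
- **Shrout–Fleiss ICCs** from the two-way mean squares, on person-day
  pairs (complete cases): ICC(2,1) treats devices as random raters and is
  penalised by systematic offsets; ICC(3,1) measures consistency. With
  zero subject variance both are defined as 0 and flagged. Note the two
  estimators coincide exactly only when MSC = MSE; under equal device
  means the finite-sample gap is O(1/n).
- **Epoch confusion** against a designated criterion device, restricted to
  nighttime minutes (19:00–11:59), pooled and per subject (t-based 95% CI
  across subjects). Likelihood ratios are always computed from unrounded
  proportions. Subjects without reference wake (or sleep) minutes have
  undefined specificity (sensitivity) and are excluded from the
  per-subject mean with a warning. The metrics are intentionally
  asymmetric: the reference device is a required choice.

## The synthetic study generator

`simulate_study()` emulates the design such devices are validated on: 30
subjects wearing two devices for 7 consecutive nights (first anchor a
Monday, so a week contains 5 weekdays and 2 weekend days). Per night,
bedtime and waketime are truncated-normal draws centred on 22:44 ± 60 min
and 06:46 ± 62 min — typical self-reported values for free-living adults —
with geometric sleep-onset latency (mean 14 min) and a geometric
lying-awake tail after the final awakening (mean 5 min). Wake bouts inside
the sleep window have a Poisson count (mean 10/night) and shifted-geometric
lengths (mean 5 min), giving roughly 50 min of WASO. A 20-minute daytime
nonwear block emulates showering without invalidating the day.

Device error is **independent-Bernoulli epoch misclassification**: a true
sleep minute is recorded as sleep with probability `sleep_detect_prob` and
a true wake minute as wake with probability `wake_detect_prob`, plus a
uniform integer jitter on lying-run boundaries. The defaults (0.94/0.88
for the armband-like device B, 0.97/0.95 for the criterion-grade device A)
are in the range reported for wearable sleep classifiers. The Bernoulli
mechanism is the simplest whose confusion metrics are analytically known,
so observed-vs-truth sensitivity and specificity must converge to the set
probabilities — a property the tests exploit. A correlated (Markov) error
overlay was considered and rejected as default: it adds parameters the
validation battery cannot identify from binary streams.

Two generator constraints keep *noiseless truth recovery exact*: wake
bouts are placed only after midnight and never touch the window's first or
last minute, so none of the onset-reset rules can fire on a truth stream;
and waketimes are truncated at 10:29 so the ≥ 90-minute upright tail fits
inside the day. Scoring a truth stream therefore reproduces the
generator's bookkeeping night by night, exactly — which is what makes the
generator a usable oracle for the scorer.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: correlated (bursty) misclassification,
naps and daytime sleep (the scorer cannot detect them by design), shift
work or split sleep, circadian drift across the week, posture
misclassification beyond boundary jitter, and device clock skew. Results
on simulated studies validate the *arithmetic and the statistics*, not any
physiological claim.

## Verification strategy and problem sizes

The test suite validates the scorer against an independently written
brute-force reference: a literal minute-by-minute forward scan of the
window rules, sharing no code with the production (run-length-based)
implementation. The two are compared on 10,000 random nights mixing
realistic and adversarial structures (bout-level generation with mixed
geometric lengths, sleep bouts near window edges and midnight, nonwear
blocks); any disagreement fails with the first differing index. Further
property checks: conservation identities on every scored night;
monotonicity (flipping an in-window wake minute to sleep never decreases
TST or SE, never increases WASO); determinism; exact truth recovery on a
30 × 7 simulated cohort; epoch-error recovery within ±0.01 over > 200,000
nighttime epochs; TOST p-values against closed-form and full-enumeration
oracles (500 random small-sample cases); Bland–Altman limits containing
~95% of exchangeable differences over 500 replicates of a 30 × 7 design;
and hand-worked ICC and variance-component tables frozen to 10 decimal
places. These sizes were chosen to make binomial/Monte-Carlo noise small
relative to the tolerances while keeping the default suite around a
minute.

## Known limitations

- The scorer finds at most one sleep window per noon-to-noon day; naps and
  daytime sleep are out of scope, and nighttime shift workers will be
  scored incorrectly.
- The upright-termination lookahead does not cross the end of the night
  window; sleep running into 11:59 is truncated and flagged.
- SF has no minimum bout length, so devices with low wake specificity
  report systematically higher SF; compare SF across devices only with the
  epoch-level metrics alongside.
- The equivalence battery operates on weekly summaries; with very few
  qualifying subjects the Shapiro–Wilk-based method selection is
  essentially arbitrary, and both TOST variants should be inspected.
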