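---
title: "Models, parameters and design choices in kiosksim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in kiosksim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiosksim)
```

`kiosksim` simulates the software side of a cage-mounted touchscreen kiosk
used to train and profile nonhuman primates. This vignette is the package's
own account of its models and the choices behind them: what is simulated,
which parameters matter and why they default as they do, what the synthetic
agents do and do not emulate, and where the design was genuinely open.

## 1. The stimulus model

A *feature space* is an ordered list of dimensions, each with an ordered
list of value labels and one **neutral** (never-rewarded) value. The
canonical space (`default_feature_space()`) has 9 body shapes, 8 colors,
11 arm types and 9 surface patterns — 7,128 unique objects — with neutrals
spherical / gray / straight-blunt / uniform. Descriptors are purely
symbolic: no meshes or textures are generated, because every piece of task
logic (reward rules, similarity, the abort rule) depends only on the value
labels. Value labels beyond the neutral four are package-chosen mnemonics.

Enumeration is lexicographic in declared dimension order with the last
dimension varying fastest; this fixes a canonical object index for
reproducible sampling and logging.

**Colors.** The only stated constraint on task colors is perceptual
equidistance in CIELAB. `make_color_palette(n, L, C, hue0)` realizes it as
`n` points at equal hue increments on the circle of radius `C` (chroma) at
lightness `L`: on such a circle all adjacent-pair Euclidean Lab distances
are equal by symmetry. Defaults `L = 70`, `C = 40`, `hue0 = 0` are
documented constants chosen to keep all eight hues inside the sRGB gamut at
a mid-high lightness typical of stimuli on a bright display; they are
configurable and carry no perceptual-validation claim (no display
calibration is modeled). sRGB columns in the palette export come from
`grDevices::convertColor` with gamut clipping.

**Sampling.** `sample_target()` draws targets with an exact number of
non-neutral dimensions (conjunction-search targets default to three
non-neutral features on a neutral spherical body).
`sample_search_array()` draws distractors sharing *exactly* `n_shared`
feature values with the target — shared means equal value in the same
dimension, not merely the same dimension varied. Distractors are mutually
distinct and never the fully neutral object; neither is stated in the source
protocol, but distinctness avoids degenerate arrays and the neutrality
exclusion mirrors the abort rule's intent (the abort object is a *choice*
cost, not a search item). Feasibility is checked combinatorially (the count
of descriptors at exact sharing level is computed in closed form) before
rejection sampling, so infeasible requests fail fast rather than spinning.

`sample_learning_array()` builds learning displays: objects neutral in all
non-varied dimensions, pairwise-distinct non-neutral values within each
varied dimension, and exactly one object carrying the rewarded value, at a
uniformly random position.

## 2. The task engine

Trials run as a discrete-event state machine; time is simulated, not wall
clock. A trial's timing parameters — 0.2 s initiation hold, a delay drawn
from Uniform(0.3, 0.5) s, a 5 s response window, 0.2 s choice hold — are the
protocol's stated values and live in `trial_timing()`. Outcomes are
`correct` (rewarded), `incorrect`, `timeout` (no choice in the window; RT
logged as the window length and excluded from RT statistics downstream),
and `abort_neutral` (the all-neutral object was chosen). `broken_hold` is
reserved in the log schema for initiation failures; whether initiation
touches can fail is unstated in the protocol, so the simulator models
initiation as always eventually succeeding and keeps the label for log
compatibility.

**Search sessions** default to 2 runs x (10 initialization + 100 test
trials) with set sizes from {3, 6, 9, 12}. "Varied randomly" is ambiguous
between stratification and iid draws; both policies are provided and
`stratified` (exactly 25 trials per set size per 100) is the default
because it removes between-session variance in the regression design
matrix. Each test trial draws its sharing level uniformly from {1, 2, 3}.

**Learning sessions** default to 40 blocks with lengths uniform on
[45, 60]. The source protocol states the block range three ways (45–55,
45–60, 40–60) in different places; the range is a parameter and the task
section's [45, 60] is the default. The rewarded feature switch rule is read
as: the new (dimension, value) pair must differ from the previous pair —
a new value within the same dimension is allowed. Difficulty is the number
of varied dimensions (1 easy, 2–3 difficult), default 1.

**Geometry.** Stimuli land on intersections of a virtual grid. The real
grid is never specified, so the default is 5 x 3 intersections spanning a
17" x 9.5" usable area (a 19.5" 16:9 panel) with 1" margins. Learning
displays instead use 8 equally spaced slots on a ring of radius 4.1" — the
stated eccentricity; the slot count is a package choice (8 slots keep >3"
between neighbors, comfortably above the ~1.1" object size).

**Seeds.** Sessions are reproducible from (config, master seed). Child
seeds per run/block come from `derive_seed(master, k)`, a Lehmer-style
mix `(master * 48271 + k) mod (2^31 - 1)`; the constant is the classic
MINSTD multiplier, used only to decorrelate nearby indices, and keeps all
seeds in 32-bit integer range. Block *k* can thus be regenerated in
isolation.

**THR ladder.** The shaping task is modeled as a monotone lattice walk over
ordered difficulty levels (shrinking square, tightening hold/release
windows, position randomization), promoting at >= 80% and demoting at
< 50% rolling accuracy over 10 trials; thresholds are operator-set in the
real system, so these defaults are conventional shaping values. The final
level enforces the stated 200–300 ms hold and 500 ms release endpoint and
sets the `touch_ready` flag. `classify_touch()` names the undesired contact
strategies (tap, overlong hold, late release, swipe, off-target); a swipe
is a contact path leaving the object bounds by more than a 0.1" tolerance
before release.

## 3. The synthetic agents

The agents are fixture generators: they produce behavior with the
statistical structure the analyses assume, standing in for the animals.
They are *not* models of macaque cognition, and the package deliberately
excludes parameter fitting to real data.

**RT agent.** On each search trial it lapses (times out) with probability
`lapse_rate`, otherwise picks the target with probability `p_correct`
(uniform distractor otherwise) and reports
`RT = b0 + b1 * set_size + N(0, sigma)`, clamped to (choice hold, response
window]. Clamping (rather than resampling a truncated normal) keeps the
closed form exact at the defaults: with `sigma = 0.15` s around means
>= 0.9 s the clamp probability is below 1e-5, so sample means track
`b0 + b1 * n` to Monte-Carlo precision. Defaults (`p_correct = 0.9`,
`b0 = 0.9`, `b1 = 0.06`, `sigma = 0.15`, `lapse = 0.02`) sit mid-range of
the published per-subject values for trained macaques (slopes
0.049–0.072 s/distractor, intercepts 0.77–0.91 s, accuracies 81–90%);
`agent_presets()` ships the four subject-like corner cases.

**RL agent.** A delta-rule learner over (dimension, value) features:
object value is the **mean** of its feature values (so the value scale is
invariant to the number of dimensions — a sum would inflate values in
3-varied-dimension blocks), choice is softmax with inverse temperature
`beta`, and after feedback only the chosen object's features update,
`V <- V + alpha * (reward - V)`. No fictive updates: this is the simplest
learner sufficient to exercise the criterion statistics. Values carry
across blocks by default (`reset_between_blocks = FALSE`): the residual
value on the previously rewarded feature produces the proactive
interference that makes reversals and multi-dimension blocks slower, which
is the phenomenon the flexibility statistics are built to detect. Defaults
`alpha = 0.3`, `beta = 5` put trials-to-criterion around 20 with plateau
accuracy ~0.6 in 1-dimension blocks.

**What a green test does not establish.** The agents are stationary within
their parameterization: no motivation drift, no session-length effects, no
spatial biases, no win-stay/lose-shift structure, no RT-accuracy trade-off,
and the RT agent's errors are uniform over distractors rather than
similarity-weighted. Tests green against these agents certify the task
machinery and the statistics, not any claim about animal behavior.

## 4. The analyses

* `search_summary()` computes per-set-size mean RT over **correct test
  trials only**; timeouts/aborts/errors stay in the accuracy denominator,
  initialization trials are excluded from both. Restricting RT means to
  correct trials is not stated in the source analysis but is required for
  the slope to measure search time rather than giving-up time.
* `fit_set_size_regression()` fits OLS to the per-set-size means (the
  literal reading of "average reaction times ... were fit"), not to
  per-trial RTs; with stratified set sizes the two differ only in SE scale.
  Standard errors come from `stats::lm`, verified in the tests against an
  independent normal-equations solver at 1e-10.
* `trials_to_criterion()` uses trailing inclusive windows and returns the
  window's **last** trial (1-based); the index convention is unstated in
  the field and this is the conservative choice (criterion can never
  precede the evidence for it). The default is 70% over 10 trials; 75% also
  appears in published use, so the threshold is a named parameter.
  Sequences shorter than the window are censored.
* `plateau_performance()` averages trials strictly after the criterion
  trial; a criterion on the final trial yields `NA` (empty plateau), and
  censored blocks are an error — callers decide the censoring policy.
  `block_learning_summary()` excludes censored blocks from means (the
  default convention; imputing the block length would bias learning speed
  toward the block length for slow learners).
* `weekly_aggregate()` pools consecutive non-overlapping groups of five
  sessions (one testing week), keeping a trailing partial group with its
  own n. SEM uses the sample SD (n − 1).

## 5. Logging and the CLI

Trial logs are append-only JSON-Lines, one schema-stamped record per trial,
flushed after every write: interrupting a session after trial *k* leaves
exactly *k* complete records, and a truncated final line (a crash
mid-write) is skipped with a warning on read. CSV export is provided for
spreadsheet use. The CLI (`inst/cli/kiosksim`, plus the exported
`cli_simulate()` / `cli_analyze()` / `cli_report()`) maps validation
failures to distinct non-zero exit codes and guarantees bit-identical logs
for a fixed (config, seed).

## 6. Numerical and degenerate-input choices

* Exactly-at-threshold windows count (>= semantics) in the criterion.
* A perfectly linear RT profile (a noise-free agent) is a legitimate
  regression input; the "essentially perfect fit" warning from
  `summary.lm` is muffled for that case only.
* `set_size = 0` trials (initialization) never enter the regression.
* Feasibility of distractor requests is decided by exact counting before
  sampling; the sampler itself additionally caps rejection attempts.
* All RNG flows through R's global generator under an explicit seed
  discipline; no randomness escapes the (config, seed) contract.

## 7. Known limitations

Event-level (not frame-level) logging; no rendering, touch input, video,
or reward-pump hardware; no husbandry modeling (reward volume is a logged
constant); agents are deliberately minimal (no Bayesian feature inference
or WSLS strategies); and no inferential statistics across subjects — the
package profiles single synthetic subjects and leaves population inference
out of scope.
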