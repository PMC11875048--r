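---
title: "Simulating a cross-modal set-shifting task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a cross-modal set-shifting task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setshiftr)
```

`setshiftr` is a hardware-free re-implementation of the control logic of a
head-fixed, two-alternative forced-choice attentional set-shifting task:
trial scheduling, reward delivery, the staged training curriculum,
performance-triggered rule switches, and the behavioral analytics, all
driven by simulated mouse agents on a millisecond-resolution simulated
clock. This vignette is the package's own account of the models, the
parameters that matter, and the design decisions taken where the protocol
left room.

## The trial state machine

A trial unfolds as: `trial_start` → a bilateral white-noise onset tone
(`tone_ms`, default 500 ms) → stimulus onset at tone offset → response
window opening `stim_ms` (default 2,500 ms) after stimulus onset, lasting
`response_window_ms` (default 1,500 ms) → reward or omission →
`trial_end`, followed by a uniformly drawn intertrial interval (8,000 to
10,000 ms in the task stages, 3,000 to 4,500 ms during shaping). The tone
and stimulus are sequential rather than overlapping — so the response
window opens exactly 2.5 s after stimulus onset — and this is a
configurable choice. The odorant's command signal is logged separately
from its arrival at the nose, `odor_onset_latency_ms` (default 120 ms,
the upper end of the measured 115–120 ms plumbing latency) later.

Time is integer milliseconds from session start; every scheduled interval
is drawn uniformly and inclusively over its configured range as an
integer. This matches microcontroller-grade timing and makes logs exactly
reproducible — there is no floating-point time anywhere in the engine or
its files.

Licks during the stimulus epoch (anticipatory licking) are recorded but
can never earn reward; only response-window licks enter the reward rule.
Two reward semantics exist: in habituation and the first shaping stage
(`SH4`) *any* lick to the rewarded side triggers reward, even after a
wrong-side lick, with reward delivered at the moment of the qualifying
lick; from `SH5` onward the *first* response-window lick must be correct.
Licks the agent emits after the trial has ended (post-reward licking runs
into the intertrial interval) are not part of the trial record. The
odorant-clearing bookkeeping event is likewise clamped to the trial span.

Sessions terminate at the first of: ten consecutive no-response trials
(the satiety rule, from the first shaping stage onward), the
consumed-volume target (500 µl in habituation/shaping), a two-minute run
without any reward in the earliest habituation stages (recorded as
`"manual"` — the experimenter ends such sessions), or a configurable
trial cap (default 2,000) that exists only as an infinite-loop guard. The
volume target is checked first when conditions coincide.

## The curriculum

Stages run HB1 → HB2 → HB3 → HB3B → SH4 → SH5 → SD → CD; a failed stage
repeats. Habituation arms the spouts (alternating in HB1/HB2; in HB3,
blocked in incrementally increasing runs realized as 5, 10, 15, then
repeating 20 — the protocol names only the ceiling of 20, so the ramp is
configurable). HB1–HB3 trials are modeled through the same engine with
`tone_ms = 0` and `stim_ms = 0`: an armed-spout lick opportunity followed
by the 0.5–1.5 s timeout. Free exploration is modeled by the agent
sampling both spouts within the window, which is why habituation sessions
reliably reach the 500 µl target in 125 droplets. HB3B inserts a brief
(150–300 ms) whisker flash between the qualifying lick and water
delivery; it is an event in the log with no effect on outcomes.

Pass criteria: habituation and `SH4` pass on 500 µl consumed; `SH5` on
reaching 80% accuracy within a 100-trial moving window; `SD` and `CD` on
the fourfold criterion — (1) more than 100 trials, (2) 80% in a 30-trial
window, (3) one 10-trial window with both left-trial and right-trial
accuracy simultaneously above 50%, and (4) responses on more than 80% of
trials. Two conventions are fixed package-wide and configurable nowhere
else: accuracy windows count **response trials only** (omissions count
toward the response-rate criterion instead), and thresholds phrased as
"reach 80%" are **inclusive** — 24/30 triggers.

## Reward-side scheduling and bias correction

From simple discrimination onward the reward side is either randomized
trial-by-trial or drawn with lick-bias correction: the probability of
arming the left spout equals the fraction of *right* responses in the
recent window, clamped. Window and clamp are explicit configuration
(defaults: 20 response trials, clamp [0.1, 0.9]) since the protocol
states only the inverse-relation principle; an empty history counts as
balanced. Against a non-learning, hard-left agent the drawn sides
converge to the clamp bound opposing the bias — the package's acceptance
checks verify that fixed point to binomial precision.

## The set-shifting controller

A **block** is the run of trials between consecutive covert rule switches
(plus the terminal partial block). In serial set-shifting sessions the
controller evaluates, after every trial, the trailing 30-response-trial
accuracy of the current block; at ≥ 80% it applies the next shift in the
sequence (default: alternating EDS between the whisker and odor rules;
arbitrary mixes of EDS/Rev/IDS are accepted and recycled). Evaluating
only the trailing window is equivalent to detecting the first attainment
and cheaper. Whether the trigger window should count no-response trials
is unstated in the protocol; they are excluded, consistent with the
accuracy convention everywhere else. Intradimensional shifts may only
introduce never-before-used exemplars, so a four-exemplar pool supports
exactly one IDS per modality before erroring.

Congruency is defined against the two latent maps — congruent iff both
send their presented exemplars to the same side — and is therefore
deliberately independent of which modality is currently relevant:
congruency labels are invariant under EDS and flip under Rev.

## The agent

The agent is an artifact construct (no claim of biological fidelity); it
is the simplest mechanism producing every phenomenon the analytics must
detect. Parameters, units and defaults:

| parameter | meaning | default |
|---|---|---|
| `attn_whisker0` | initial whisker attention weight (odor = complement) | 0.5 |
| `assoc_lr` | association learning rate per response trial | 0.2 |
| `attn_lr` | attention reallocation rate | 0.1 |
| `inv_temp` | logistic choice sharpness (1/log-odds units) | 3 |
| `lapse` | probability of a uniformly random choice | 0.1 |
| `side_bias` | additive right-bias, log-odds units | 0 |
| `p_respond` | per-trial response probability before satiety | 0.95 |
| `satiety_trials` | mean trials to satiety (per-session draw, SD 50) | 450 |
| `lick_rate_hz` | anticipatory lick rate | 8 |

Choice: evidence is the attention-weighted sum of the presented
exemplars' signed strengths (an absent stimulus contributes nothing; its
weight renormalizes away), passed through a lapse-mixture logistic.
Learning is full-information: after any response, each presented
exemplar's strength moves toward the signed rewarded side, and attention
moves toward the modality whose prediction agreed with the outcome when
the other's disagreed. Bounds (strengths in [−1, 1], weights summing to
one) are preserved by construction.

Anticipatory licking runs from stimulus onset to the response at
`lick_rate_hz` with ±10% interval jitter; the first lick inside the
response window is the response. The default of 8 Hz sits at the
intersection of the two ranges reported for such tasks (6–8 Hz in one
account, 8–10 Hz in another). Satiety is a per-session normal draw
(mean `satiety_trials`, SD 50, truncated at one trial) after which the
response probability drops to zero, which produces the ten-omission
termination naturally; the session-start re-arm models overnight
re-motivation under water restriction.

Default cohort parameter ranges are chosen so simulated set-shifting
sessions land near 450 ± 75 trials with roughly a dozen switches — inside
the few-hundred-trials-per-session envelope such experiments report. What
the generator emulates: graded acquisition, perseveration confined to
incongruent trials after covert switches, lapses, side bias, ~8 Hz lick
trains, satiety. What it does not: sensory noise and psychometric
detectability limits, motivation drifts within a session, running-speed
or arousal covariates, inter-animal correlations. Passing tests therefore
certify the *task logic and analytics*, not any claim about real mouse
cognition.

## Analytics

Moving-window accuracy at trial *i* is the fraction correct among the
trailing *w* response trials ending at *i*, `NA` until the first full
window. Trials-to-criterion is the 1-based response-trial index of first
attainment. Both are verified against exhaustive brute-force scans on a
thousand random sequences — exactly, not approximately.

Switch-aligned analysis takes the 10 trials before each switch (offsets
−10…−1) and the 10 after (offset 0 is the first trial under the new
rule), and fills the modality-rule × congruency × timing cell table. The
factorial ANOVA models per-trial correctness (0/1) with the three main
effects and pairwise interactions. Periswitch cells are inherently
unbalanced, so marginal (type III) sums of squares with sum-to-zero
contrasts are the default, with sequential (type I) available; the two
coincide on balanced data, which the tests exploit against a
hand-computed table. The linear-model F test on a Bernoulli response is
an approximation; its type-I error is verified by simulation to be at
the nominal 5% within Monte-Carlo error at the cell sizes used
(50 trials/cell). Post-hoc pairwise cell comparisons use Bonferroni
correction across group pairs. Rank-sum (Wilcoxon) comparisons of
trials-to-criterion across modalities apply unchanged via
`stats::wilcox.test` on `trials_to_criterion` outputs per block.

Parameter fitting is a deterministic-replay grid search: for each
candidate initial attention weight the learning trajectory is replayed
through the logged trials, and the Bernoulli likelihood of the observed
choices is maximized over the lapse × attention × temperature grid. With
attention reallocation active, the initial weight only influences early
trials and its likelihood surface is nearly flat; the package's recovery
experiment therefore uses a fixed-attention agent (`attn_lr = 0`, a known
parameter of the generating model), for which both lapse and the
attention weight are recovered to within one grid step from ~2,000
trials.

## Determinism, seeds and problem sizes

Every session is a pure function of (config, rule, agent parameters,
seed): the engine seeds R's RNG per session and all draws flow from it,
so identical seeds give byte-identical log bundles. Curriculum sessions
and cohort agents derive child seeds as `(seed + 7919 k) mod (2^31 − 1)`,
keeping any single session reproducible in isolation. Files serialize
sides as `L`/`R`, timestamps as integers, and JSON keys in fixed order.

Validation sizes, chosen as a balance of statistical resolution and
desk-scale runtime: 1,000 random sequences for the windowed-statistic
oracles; 100 simulated set-shifting sessions for the switch audit;
10,000 Bernoulli trials for each closed-form accuracy check (three
binomial standard errors); 1,000 null datasets and 100 effect replicates
for ANOVA calibration and power; ~2,100 trials for parameter recovery.

## Known limitations

The engine is not real-time and synthesizes no stimuli — whisker
waveforms, odorant flows and audio exist only as named events. The
incorrect-response path in `SH5`+ imposes no penalty timeout beyond the
ordinary intertrial interval, as none is specified. The agent's
full-information learning makes relearning after reversals faster than
real animals exhibit; perseveration durations should not be read
quantitatively. Congruency requires both maps defined, which the engine
guarantees even when one modality is absent from the stimulus set.
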