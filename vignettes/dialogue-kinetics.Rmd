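---
title: "Topological and kinetic analysis of task dialogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological and kinetic analysis of task dialogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialtk)
```

## The model

`dialtk` analyses two-party task dialogues annotated at the speech-act
level. A dialogue is a hierarchy: *planes* (thematic plans) contain
*concatenations* (themes, indexed by `x`), which contain *speech acts* —
utterances or nonverbal actions, each stamped with its dialogical time
`epsilon` (the integer rank of the act in the exchange), a topological
address `(x, y)` (`y` is depth of elaboration within the theme), and one
of five act types: `DO` (action), `MK` (inform), `DMK` (ask), `DC`
(offer/invite), `DM` (directive without alternative).

Two binary annotations drive the kinetic metrics:

* **Polarity** $\delta \in \{0, 1\}$, per *object of analysis*: whether
  the act substantiates the dialogue's orientation toward that object.
  Polarity is stored as one column per object (`delta_task`,
  `delta_interlocutor`, and any further `delta_<object>` columns),
  because the same act can align with the task while ignoring the
  interlocutor, or vice versa. Objects without an annotation default to
  $\delta = 0$.
* **Decisivity** $d \in \{0, 1\}$: whether the act directly advances
  task resolution.

From these, for any act set (a concatenation, a trailing window, a whole
dialogue):

$$V = \frac{\#\{\delta = 1\}}{\#\text{acts}}, \qquad
  C = \frac{\#\{d = 1\}}{\#\text{acts}}.$$

*Vergence* $V$ measures cooperation (above 0.5 is read as effective
cooperation, below 0.5 as divergence; the threshold is reported, never
hard-coded into logic), *celerity* $C$ efficiency; $(1 - C) \times 100$
is the percentage slowdown relative to an exchange containing only
decisive acts. The **primacy inequality** $C \le V$ holds on every
validated act set because validation enforces its premise per act:
$d = 1 \Rightarrow \delta_{task} = 1$ (a decisive act must be positively
task-polarized). The literature names this theorem inconsistently —
once after celerity, once after vergence, with the prose direction
flipped in one place — but the worked example and the per-act premise
fix the inequality unambiguously as $C \le V$, which is what
`primacy_check()` tests. We treat a violation as a data error to be
reported, not silently corrected.

A dialogue-level *interaction function* of the address, the time and
the per-act state annotations is sometimes posited as the model's
foundation; no evaluable form exists, so the package houses its
arguments in the data model and computes nothing from it.

## Reading, validating, measuring

The canonical format is TSV (utterance text routinely contains commas,
so CSV is ruled out; embedded tabs/newlines are escaped), one act per
row, fixed leading columns. `epsilon` may be zero or negative on input
— pre-task talk is conventionally numbered backwards — and is shifted
to a 1-based internal index that preserves order and gaps, with the
original values retained.

```{r}
mc <- read_transcript(system.file("extdata", "monte_cristo.tsv",
                                  package = "dialtk"))
vergence(mc)
celerity(mc)
per_concatenation_metrics(mc)
```

The packaged eight-act literary dialogue is the standard worked
example: two themes, all acts task-polarized ($V = 1$), two redundant
question/answer acts coded non-decisive ($C = 6/8 = 0.75$, a 25%
slowdown). Its topological matrix places themes on columns and depth on
rows; a theme may start at `y > 1` when it emerges as an elaboration of
an earlier one, leaving the cells above empty — exactly as in the
source encoding:

```{r}
encode_matrix(mc)[6, 1]
```

`running_vergence()` produces per-act trajectories. The smoothing used
for published per-act curves is never stated, so both a trailing
window and a cumulative variant are exposed. The default window of 20
acts was chosen once, to make regime changes visible at typical task
dialogue lengths (roughly 300–650 acts): much shorter windows are
dominated by Bernoulli noise ($\mathrm{SD} \approx 0.5/\sqrt{w}$), much
longer ones smear a change point over a hundred acts. "Vergence toward
the interlocutor" for one party is the same trajectory restricted to
that speaker's acts with `object = "interlocutor"`.

`vc_correlation()` tests the vergence–celerity association across
concatenations (Pearson, two-tailed p from the exact t transform with
$n - 2$ degrees of freedom). Constant series are an error, not an
`NA`: a degenerate correlation almost always signals an annotation
problem, and silently propagating `NaN` buries it.

## The recurrent vergence forecaster

The forecaster is a single-layer Elman recurrence

$$h_\varepsilon = \tanh(W_{xh} x_\varepsilon + W_{hh} h_{\varepsilon-1} + b_h),
\qquad \hat V_\varepsilon = \sigma(W_{hy} h_\varepsilon + b_y),$$

with a logistic output so predictions are valid vergence values by
construction. Loss, optimizer and architecture are design choices:
mean squared error, full-batch gradient descent with exact
backpropagation through time, $H = 8$ hidden units, learning rate
0.01, 2000 epochs, weights initialized uniformly in $[-0.5, 0.5]$
scaled by $1/\sqrt{H}$ under a fixed default seed. All are arguments
to `vergence_rnn()`.

The input features are the design decision that matters. The published
description pairs each dialogical time index with its vergence value;
its forecast protocol, however, *re-conditions on observed values
every three speech acts* and runs a counterfactual *conditioned on a
positively polarized act* — neither of which can influence a network
whose only input is the time index. We therefore feed two inputs per
step: `epsilon` normalized by the training-window length, and the
previous conditioning vergence value (teacher forcing during training
and at stride boundaries; the model's own prediction inside free-run
blocks). This is the standard autoregressive reading and the minimal
one under which the protocol is well defined; it is an interpretation,
and is flagged as such.

`rolling_forecast()` implements the stride-3 protocol: free-run three
steps, re-condition the hidden state on the observed values of those
steps, repeat. `stride = 1` degenerates to one-step-ahead prediction
(and coincides with the teacher-forced fit); `stride = n` is a single
free run. `counterfactual_forecast()` modifies the conditioning series
as if one extra positively polarized act occurred at the intervention:
a phantom $\delta = 1$ flag is attached at that position and every
window covering it averages one extra positive act,
$(S + 1)/(n + 1)$. Under this semantics the counterfactual
conditioning value is raised exactly when the factual window contains
any null-polarity act, is never lowered, and an intervention on an
all-positive stream is a no-op.

Numerical notes. Training is deterministic given the seed (pure
gradient descent, no stochastic batching), so refits are bit-identical.
The bounded activations mean the loss cannot overflow to `NaN` —
extreme learning rates saturate and stall rather than diverge — so the
divergence guard in the trainer is defensive only. Weight recovery is
not claimed (recurrent weights are not identifiable); what the tests
pin down is behavioral: the step recurrence agrees with an independent
brute-force evaluation to $10^{-10}$, trend-following forecasts slope
the right way, and the factual forecast sits below the counterfactual
one on divergence scenarios.

## Graded-prompting cooperation scoring

The three-subtask ecological protocol (basket / door / syllogism)
probes cooperation under a three-level prompt ladder: initial indirect
prompt, indirect reformulation, direct request. A subject's *response
level* (0–3) records how far down the ladder compliance occurred,
level 3 meaning never. Levels map to canonical trajectories over a
4 × 6 grid:

| level | path |
|---|---|
| 0 | (1,1) → (1,2) |
| 1 | (1,1) → (2,2) → (2,3) → (1,2) |
| 2 | (1,1) → (2,2) → (2,3) → (3,4) → (3,5) → (1,2) |
| 3 | (1,1) → (2,2) → (2,3) → (3,4) → (3,5) → (4,6) |

(1,2) is task success, (4,6) failure; (2,2)/(2,3) the
indirect-reformulation stage, (3,4)/(3,5) the
clarification/direct-reformulation stage. The grid extent and the
paths are a package convention: the source names these positions but
prints no full per-level paths, so we chose the minimal automaton in
which every named position is reachable, intermediate positions are
visited in sequence, and the quoted group fractions (20%, 40%, 60%,
80%, 100% of five subjects) are expressible. A clarification request
inserts (3,4) before compliance at levels whose path does not already
pass through it. `occupancy()` then aggregates a group into the
probability of visiting each cell at least once; repeat visits count
once, so occupancy is invariant to within-trajectory repeats and to
trajectory order.

The packaged response fixture encodes the described group patterns.
One published figure for the control syllogism group ("only 60%
reached the success position") is arithmetically incompatible with the
same paragraph's explicit counts (one failure among five forces 80% at
the success terminal); the fixture follows the counts, and we read the
60% as a timing remark the terminal-state automaton does not model.

## The synthetic generator

`generate_dialogue()` draws dialogues with known parameters so every
pipeline stage is testable without clinical transcripts. Defaults are
the study conditions where stated, and fixed realistic choices where
not: 15 concatenations of 20 acts (≈300 acts, the order of the
analysed sessions); per-speaker act-type distributions taken from the
published experimenter/subject usage profiles; task-polarity
probability 0.9 (cooperative phase) dropping to 0.2 after the change
point in divergence scenarios; `p(d = 1 | delta_task = 1)` = 0.75,
matching the worked example's celerity/vergence ratio; floor-holding
probability 0.3, loosely matching printed multi-act turns. Content
strings are placeholders — no pipeline stage inspects text. Decisivity
is drawn only for task-polarized acts, so everything generated passes
validation and satisfies $C \le V$ by construction.

What the generator does *not* emulate: real act-type/polarity
dependence (a directive is more likely decisive than a laugh),
autocorrelated polarity runs, content semantics, or per-subject
heterogeneity. Passing tests therefore demonstrate that the machinery
computes the intended quantities under known conditions — not that the
clinical effect sizes would be recovered from real transcripts.

## Group comparison from summary statistics

`summary_ttest()` computes pooled or Welch two-sample t-tests from
printed `(mean, SD, n)` summaries; with two groups a one-way ANOVA is
the same test ($F = t^2$), so one operation serves both reporting
styles. Pooled equal-variance is the default because it reproduces the
reproducible entries of the published demographics table (age
$p = 0.69$, visuo-spatial index $p = 0.003$); Welch does not. Several
printed p-values (verbal comprehension, general ability, IQ, theory of
mind) are *not* recoverable from their printed summaries under either
variant — recomputation gives $p \approx 0.02$–$0.05$ where
$\le 0.002$ is printed — presumably because the original test used raw
data or a different procedure. These entries are excluded from
reproduction claims. No multiple-testing correction is applied because
none is reported.

## Problem sizes and limitations

The property suites run on deliberately small cases: hundreds of
random dialogues of 2–40 acts for validation/primacy properties, one
10,000-act dialogue for binomial recovery of the polarity probability,
100 random parameter draws for the recurrence oracle, and 20 seeded
replicates of the 300-act divergence scenario for the counterfactual
ordering check. These sizes make every distributional claim testable
in seconds while keeping the binomial error bounds meaningful.

Known limitations: the clinical trajectories behind the published
per-item figures and the $r(7) = 0.87$ vergence–celerity correlation
rest on unpublished transcripts and are not reproduction targets; the
forecaster's counterfactual mechanism is an interpretation (see
above); binary polarity is adopted as defined — mentions of
"negatively polarized" acts notwithstanding, no third level is
invented; and the package consumes annotations, it does not produce
them — automatic speech-act classification from raw text is out of
scope.
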