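---
title: "Segmenting maternal-behavior ethograms with hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting maternal-behavior ethograms with hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethohmm)
```

## The problem

Rodent maternal care is scored as a stream of discrete behaviors — one
ethogram code per minute, one hour per observation block. Simple frequency
tables of those codes miss the *organization* of care: which behaviors
cluster in time, how long the resulting modes persist, and which routes the
animal takes between them. `ethohmm` models each hour-long sequence with a
discrete-emission hidden Markov model (HMM): a latent first-order Markov
chain over behavioral *states*, each state emitting observed codes from its
own categorical distribution. The canonical configuration uses seven states
— blanket nursing (BLN), arched-back nursing (ABN), licking/grooming pups
(LG), self-grooming (GRO), eating (EAT), activity (ACT) and sleeping (SLP)
— over a 21-behavior maternal ethogram.

The model is parameterized by a row-stochastic transition matrix $A$
($N \times N$), an emission matrix $B$ ($N \times M$) and an initial-state
vector $\pi$. The package trains one model jointly on all mothers' hours,
labels every minute with its Viterbi state, and compares groups on the
frequency, bout duration, composition and transition statistics of those
labels.

## Numerical core

* **Likelihood.** The scaled (normalized-$\alpha$) forward recursion is
  used throughout: at each minute the forward vector is renormalized and
  the log of the normalizer accumulated. This is $O(N^2 T)$ and underflow
  free for sequences far longer than any observation hour; a sequence that
  is impossible under a model reports $-\infty$ with an explicit flag
  rather than an arbitrary small number.
* **Posteriors.** The backward pass reuses the forward normalizers, so
  per-minute state posteriors $\gamma$ and transition posteriors $\xi$
  normalize exactly by construction; the suite checks both to $10^{-10}$
  and checks all three recursions against exhaustive path enumeration on
  small models.
* **Training.** Baum-Welch pools expected transition, emission and
  initial-state counts over all sequences; $\pi$ is re-estimated because
  hour-long sequences are short ($T = 60$) and numerous, so position-1
  posteriors carry real information. Convergence is declared when the
  relative log-likelihood improvement drops below `tol` (default $10^{-6}$)
  or after `max_iter` (default 500) iterations. EM monotonicity is asserted
  (tolerance $10^{-8}$) on every fit in the test suite.
* **Zeros.** An exact zero appearing in a re-estimated emission row would
  be absorbing for the rest of the run, so such entries are floored at
  $\varepsilon = 10^{-12}$ and the row renormalized; the fit reports how
  many entries were floored. At this magnitude the perturbation is far
  below every tolerance used anywhere in the package.
* **Ties.** Viterbi backtracking breaks exact ties toward the lower state
  index, making labeling bit-reproducible.

## Model selection

The number of states is audited two ways.

*BIC.* The score is $-2 \ln L + d \ln p$, with $p$ the total number of
observations over all sequences and $d = N(N-1) + N(M-1) + (N-1)$ the count
of free probabilities (each row of $A$, each row of $B$ and $\pi$ lose one
degree of freedom to normalization). Alternative models merge the state
pairs whose separation is scientifically in question — ABN/BLN (two nursing
postures) and LG/GRO (pup-directed versus self-directed grooming). A merge
combines the two emission rows and outgoing transition rows weighted by the
states' expected occupancy, sums incoming probabilities and initial
probabilities, and then retrains all parameters by Baum-Welch — the merged
model is given every chance to fit before being compared. When the two
merged states are exactly interchangeable (identical rows), the merge
provably preserves every sequence likelihood, which the suite checks.

*Restart robustness.* Because EM only finds local optima, the trained model
is re-derived from uniform-random initial models and the fits landing on
the top log-likelihood plateau are compared state-by-state. The plateau
window defaults to 0.02 nats per observation — about a 2000-nat band on a
study of $10^5$ observations — and is a reporting construct: it selects
which restarts are worth profiling, not an inference. States of two plateau
fits are paired by minimizing total variation distance between emission
rows under an optimal assignment (exact branch-and-bound; for seven states
the search is trivial). In synthetic studies the nursing, grooming, eating,
activity and sleeping states reappear with nearly identical profiles across
restarts, while the deliberately heterogeneous GRO state is the least
stable — the expected behavior for a "leftover" transition state.

## Group statistics

Viterbi labels feed three families of hypotheses per group pair:

* **Frequencies** — per-subject fraction of minutes in each state, compared
  with a pooled-variance two-sample t test (one value per mother; Welch's
  form available via `welch = TRUE`).
* **Compositions** — for each (state, behavior) cell, counts of that
  behavior within minutes labeled with that state, pooled over a group's
  subjects, compared with the pooled two-proportion z statistic
  $z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}$,
  $\hat p = (x_1 + x_2)/(n_1 + n_2)$. The normal approximation is trusted
  only when $x_1$, $x_2$, $n_1 - x_1$ and $n_2 - x_2$ all exceed 5; tests
  failing the rule are reported but marked invalid.
* **Transitions** — each ordered cross-state pair, with the transition
  count as successes and total observed minutes as trials, tested with the
  same z statistic. The package reports both the conditional
  (row-normalized) transition matrix and absolute rates
  (cross-state transitions per observed minute); bouts and transitions are
  always computed within an hour block, never across blocks, days or
  subjects.

Benjamini-Hochberg correction at $q = 0.05$ is applied separately within
each family (each family is its own series of tests); invalid z tests are
excluded from the correction rather than silently dropped. The z statistic
satisfies $z^2 = \chi^2$ of the corresponding 2×2 table, which the suite
verifies to $10^{-10}$, and its empirical type-I error at $n = 500$ per
side is checked to sit in $[0.04, 0.06]$.

## The synthetic-study generator

No raw observation dataset ships with the package, so the generator builds
study-shaped data from a hand-specified 7-state ground truth
(`base_ground_truth()`), and every end-to-end claim in the test suite is a
claim about recovery of that known truth. Its design targets:

* **Design.** Four groups of 26, 26, 36 and 39 subjects (127 total), two
  hour blocks per day, 60 minutes per hour, postnatal days 1–7 — 1778
  sequences and 106,680 observations at full scale. Each subject draws its
  sequences from its own RNG stream derived from the master seed, so
  datasets are reproducible even under subject-parallel generation.
* **States.** Emission rows put most of their mass on the state's namesake
  behavior (0.93 for EAT down to 0.66 for LG) with the remainder on that
  state's typical interruptions; GRO is deliberately diverse (0.34 on
  self-grooming out of nest, the rest spread over nest-maintenance and
  sniffing behaviors), making it the hardest state to pin down — a
  realistic stress case for restart matching.
* **Durations.** Self-transitions are set through the geometric
  mean-duration identity (mean bout $= 1/(1 - A_{ss})$): ~12.5 min for the
  nursing states, ~4 min for LG, EAT and ACT, ~3.3 min for GRO, 5 min for
  SLP. Observed mean bouts in 60-minute windows are shorter than these
  nominal values because bouts are truncated at block boundaries (about
  16% shortening at a 12.5-min mean); tests compare against
  truncation-corrected bounds rather than the naive identity.
* **Topology.** LG is the dominant gateway between nursing and everything
  else; ACT and EAT interchange rapidly; GRO sits between nest and
  non-nest behavior.
* **Contrasts.** `default_contrasts()` injects strain-style differences:
  the BALB/c-like group gets ABN decaying into BLN more often, frequent
  direct GRO→BLN transitions bypassing LG, more self-grooming inside LG
  and more out-of-nest sleeping; the reciprocal-hybrid pair differs only
  in a small LG→ABN contrast. Each contrast perturbs one named row entry
  and rescales the rest of the row, and the contrast table doubles as a
  perturbation log from which every group model can be reconstructed
  exactly.

What the generator does *not* emulate: postnatal-day trends, circadian
structure across observation windows, litter-size effects, non-geometric
(semi-Markov) bout durations, and inter-observer noise. Passing the suite
therefore demonstrates that the pipeline recovers a first-order-Markov
truth of realistic size and separation — not that real maternal behavior
is first-order Markov.

## Problem sizes and tolerances used in validation

The validation suite runs, at a fixed seed: exhaustive-enumeration
equivalence on 100 random small models ($N \le 3$, $M \le 4$, $T \le 6$,
agreement to $10^{-9}$); full-scale parameter recovery (127 subjects,
106,680 observations; maximum entrywise error of $A$ and $B$ below 0.05
after optimal state alignment); BIC preference for the 7-state model over
both merged alternatives in at least 9 of 10 replicate studies of 30
subjects × 5 days (the merged-state comparison needs enough minutes in the
rarer states for the likelihood loss to dominate the ~320-nat penalty
difference, so this family uses a larger reduction than the others); 20-restart sweeps on 25 subjects × 4 days with plateau
fits agreeing on at least 6 of 7 matched states at TV < 0.1; z-test
calibration on 10,000 null tables and BH-versus-definition identity on
1,000 random p-vectors; and a two-group study (26 vs 26 subjects, days
1–7) where a single injected GRO→BLN transition contrast of +0.12 must be
BH-significant in at least 80% of 20 replicates while fully null studies
reject at most 5% of hypotheses per family. The replicate counts and
reduced designs were chosen once as the smallest sizes at which each
property is comfortably identified.

## Design choices and limitations

* Training pools all groups into a single model (as when strains are
  assumed to share gross behavioral structure); group differences are then
  assessed on labels, not on per-group models. Fitting per-group HMMs is
  possible with the same functions but is not the packaged workflow.
* Composition and transition z tests pool counts over a group's subjects,
  so minutes — not mothers — are the exchangeable unit; the per-subject t
  tests on frequencies are the mother-level complement. Pooled counts
  overstate certainty when subjects are heterogeneous; this is inherent to
  count-pooling and is why both families are reported.
* The reader accepts any day range but the canonical analysis window is
  postnatal days 1–7 (`filter_sequences(ss, days = 1:7)`).
* Merged alternative models re-estimate *all* parameters, including $\pi$.
* `hour_block` is an opaque label: blocks are never concatenated, and no
  time-of-day structure is modeled.
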