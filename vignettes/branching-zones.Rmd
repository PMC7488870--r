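---
title: "Branching-zone analysis of apple shoots with hidden semi-Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching-zone analysis of apple shoots with hidden semi-Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchzones)
```

## The problem

An apple shoot carries one axillary bud per node, and each bud takes one of a
small set of fates in the following season: it stays latent, grows into a
short (< 5 cm) or long (>= 5 cm) vegetative shoot, or flowers as a bourse
bearing a short or a long bourse shoot.  Reading these fates from the base to
the tip of a parent shoot gives a categorical sequence, and such sequences
are strongly zoned: stretches of nodes with a homogeneous mixture of fates
(an unbranched basal zone, a diffuse floral zone, an acrotonic zone of long
laterals near the tip) succeed one another in a fixed order.  How that
zonation depends on the parent shoot's own growth — whether it paused within
the season (monocyclic vs bicyclic shoots), how long it grew (growth
duration, GD), and when it started (growth period, GP) — is the scientific
question this package operationalises.

`branchzones` provides the full chain of analysis:

1. **Shoot categorization** from weekly length records
   (`detect_cessations()`, `compute_start_date()`, `classify_shoot()`).
2. **Hidden semi-Markov chain (HSMM) estimation** on bud-fate sequences
   under structural constraints (`fit_em()`), with explicit-duration
   likelihood (`log_likelihood()`) and restoration of the most probable
   state path (`viterbi_decode()`).
3. **Zone-level comparison** across shoot categories: occurrence
   probabilities, zone-length GLMs, lateral-type mixtures, correlations
   (`occurrence_probabilities()`, `compare_zone_lengths()`,
   `compare_lateral_distributions()`, `correlate_zone_vs_total()`).
4. **Category-level comparisons** of node numbers and lateral counts
   (`compare_node_numbers()`, `compare_lateral_counts()`,
   `compare_lateral_proportions()`).
5. A **synthetic-data generator** (`default_ground_truth()`,
   `simulate_study()`) producing growth tables and zone-structured
   sequences with known ground truth, so every stage can be validated by
   parameter recovery without any field data.

## Shoot categorization

Weekly cumulative lengths drive three rules:

* **Start date** — the first observation at which the shoot reaches 5 cm
  (`start_length_cm`).  For a second growth unit (GU), the first
  observation after the previous cessation at which the length exceeds the
  cessation-date length by another 5 cm.
* **Cessation** — the first observation whose gain over a trailing two-week
  window falls below 0.5 cm (`cessation_delta_cm`,
  `cessation_window_days`).  The window is realized as "the nearest
  observation at least 14 days earlier", which tolerates irregular visit
  spacing.
* **Classes** — one GU vs two GUs; GD classes split at 30 and 90 days
  (monocyclic) or 30 days (each GU of a bicyclic shoot), with both printed
  boundaries, 30 and 90 days, assigned to the *medium* class; GP is early
  or late relative to June 3 (one-GU shoots and first GUs) or July 18
  (second GUs), with a start exactly on the threshold counted as early.

Two conventions deserve comment.  A cessation is dated at the *earliest*
observation of a stagnation episode: that is the first date at which the
stop is detectable, and it is reproducible under subsampling.  And two
qualifying runs are treated as the *same* episode unless the later one
starts at a length at least 5 cm above the earlier one's start — i.e. the
intervening regrowth would itself qualify as a new GU start.  Without this
merge, measurement noise on a plateau (where the true two-week gain is
essentially zero) would fragment one biological cessation into several
statistical ones; with it, "number of episodes" coincides with "number of
growth units", which is the quantity the categorization actually uses.

Shoots that never reach 5 cm, or whose series is shorter than the
assessment window, are excluded with a logged reason rather than forced
into a category (`categorize_shoots()` returns the reason per shoot).

## The model

Each cohort of sequences is described by a hidden semi-Markov chain with
`K` transient states and one absorbing, non-emitting end state.  A state
`j` carries

* an **occupancy distribution** `d_j(u)` on zone lengths `u >= 1` (nodes):
  shifted Poisson, shifted negative binomial, shifted binomial, or a point
  mass;
* an **emission distribution** `b_j(y)` over the six bud fates, constrained
  by a symbol mask (forced states — the basal latent zone, the second-GU
  latent zone, the bud-scar zone — emit a single symbol with probability
  one);
* a row of **transition probabilities** restricted to strictly higher
  state indices (left-to-right, transient: no state can be revisited) plus
  the end state.

The likelihood of a sequence is the probability of emitting exactly its
`T` nodes *and* entering the end state at `T`; the final zone is treated
as complete (no right-censoring).  Two published structures are built in:
a 3+1-state chain for monocyclic shoots with short or medium GD (basal
latent S0, diffuse floral S1, acrotonic vegetative S2), and a 7+1-state
chain for monocyclic long-GD plus bicyclic shoots (L0 basal latent, L1
diffuse floral, L2 bud scars, L3 second-GU latent, L4 short shoots, L5
floral, L6 acrotonic), in which monocyclic shoots bypass the scar zone L2
through a skip transition.  `model_a_template()` and `model_b_template()`
expose these structures for estimation; the initial probability is fixed
on the first state (every decoded shoot starts in the basal latent zone),
though the API supports free initial vectors.

### Estimation

`fit_em()` runs explicit-duration forward–backward EM:

* **Initialization** — transitions uniform over the allowed cells;
  emissions proportional to global symbol frequencies renormalized under
  each state's mask with a 1e-3 floor; occupancies set to mean sequence
  length / number of states.  Restart 1 is unjittered; later restarts
  multiply probabilities by `exp(U(-0.5, 0.5))` and occupancy means by
  `U(0.7, 1.3)` (10 restarts by default, per-restart seeds derived from
  `em_settings(seed=)`).
* **M-step** — closed-form weighted ML for transitions, masked emissions
  and shifted-Poisson/point-mass occupancies; profile likelihood over the
  dispersion (shifted negative binomial) or size (shifted binomial)
  parameter.  Free emission cells are floored at 1e-6 during iterations to
  avoid absorbing zeros; cells still at or below the floor are removed
  from the final reported model.
* **Convergence** — relative log-likelihood change below 1e-6 or 500
  iterations.  The per-iteration log-likelihood is non-decreasing (checked
  to 1e-8 in the tests).  `bic = -2 loglik + k log(total nodes)` with `k`
  the free-parameter count under the masks.

The inner recursions run in compiled code; a sequence of length `T` costs
`O(T^2 K + T K^2)`.  One numerical detail matters: cumulative emission
log-sums are kept as a finite part plus a *count of masked positions*, so
that a zone spanning a symbol its state cannot emit is recognised as
impossible rather than silently absorbed by floating point.

### Decoding and tie-breaks

`viterbi_decode()` maximises the joint probability of states and
observations with explicit durations.  Candidates are scanned with state
indices and durations ascending and replaced only on strict improvement,
so ties resolve toward the lowest state index and then the shorter zone —
decoding is deterministic, which the pipeline's reproducibility contract
relies on.  An impossible sequence raises an error carrying the first
node index (0-based) at which no partial state path remains feasible.

## Zone statistics

"Occurrence" of a zone in a shoot group is the fraction of decoded shoots
whose restored path visits the state — presence in the most probable path,
not a posterior probability, matching how segmentations are read in
practice.  Zone lengths between two groups are compared with a negative
binomial GLM (log link, Wald test on the group coefficient; Poisson
fallback with a flag if the NB fit does not converge; no test when either
group has fewer than 3 zones — the rule used for the dashes in the
published-style summary tables).  Lateral-type mixtures within a state are
compared with Fisher's exact test, switching to a Monte-Carlo exact
version (100,000 draws, fixed internal seed) above a table total of 200;
bud-scar zones are segmented but excluded from mixture comparisons.
Significance codes are `*` for p < 0.05 and `**` for p < 0.01.

For node-number and lateral-count comparisons across categories, the count
family (Poisson vs negative binomial) is chosen by a Pearson chi-square
goodness-of-fit test of the Poisson fit on pooled bins (expected count >= 5
per bin); group effects use the GLM with single-step Tukey-style contrasts
(`multcomp`) and a compact letter display.  "Tukey after chi-square" for
proportions is statistically ambiguous as a recipe, so proportions use
Holm-adjusted pairwise chi-square sub-tables after a significant omnibus
test, with the exact route taken (and flagged) whenever an expected cell is
below 5.  Dunn's rank-based post hoc after Kruskal–Wallis uses Holm
adjustment; the z-statistics with tie correction are computed in-package.

## The synthetic generator

`default_ground_truth()` fixes the study conditions: 71% monocyclic / 29%
bicyclic shoots; within monocyclic, 65/28/7% short/medium/long GD with GP
mixes per class; spring starts centred on April 30 and post-pruning starts
on June 26 (truncated normals, sd 8 days); GD windows per class that keep a
margin to the 30/90-day boundaries; and one generating HSMM per category.
Zone visit probabilities come from the published occurrence tables (e.g.
0.26/0.09 for the mutually exclusive S1/S2 of short-GD shoots, 0.65 for L1
of bicyclic shoots, implemented via `routing_transitions()`, which realises
independent per-zone visits), and the diffuse-floral occupancy means (3.9,
13.4, 16.1 nodes) come from the published zone-length summaries.  Emission
mixtures are package defaults: each zone puts weight 0.7 on its
name-giving lateral type (short bourse for floral zones, short/long
vegetative for the short-shoot and acrotonic zones) with the remainder
mostly latent.  This convention makes zones identifiable from their
emissions, which is what the recovery tolerances (+-0.07 on transitions)
require of a generator; the real data's mixtures are latent-heavier, so
recovery results here certify the estimator, not field effect sizes.

Growth trajectories are piecewise linear with an engineered geometry: a
10-day rise to the 5 cm criterion on the target start date, extension at
0.3–0.5 cm/day, then an abrupt switch to a 0.01 cm/day creep exactly one
trailing window before the target cessation observation, so the 0.5 cm
rule fires on schedule; bicyclic shoots add a second rise of 5 cm above
the first plateau.  Measurement noise is Gaussian with sd 0.15 cm (clamped
so no observation shrinks by more than the reader's 1 cm tolerance).  The
noise level is chosen so that the two-week-gain statistic — whose noise is
sqrt(2) times the per-observation sd — stays clearly below the 0.5 cm
threshold on plateaus: at sd 0.3 the rule misfires on 12–16% of plateau
observations, quantising detected GD upward by a week at a time and
pushing reclassification consistency below 95%; at sd 0.15 consistency is
~98%.  What the generator does *not* emulate: within-tree correlation
between shoots, weather forcing of growth, irregular visit dates, or the
latent-dominant emission mixtures of real orchards — so a green test suite
validates the machinery and the recovery properties, not field
conclusions.

A drawn "early" second GU whose first GU only stops after mid-July cannot
exist; the generator re-labels it late before recording the truth (the
analogous field shoots were rare and excluded from the published
analyses), and early second GUs of the short-GD class have weight zero for
the same reason.

## Problem sizes and determinism

The validation suite runs at deliberate desk scale: enumeration
equivalence on chains with up to 3 states and sequences up to 8 nodes
(tolerance 1e-10); parameter recovery on 500 sequences per generator
(transitions within +-0.07, visited-zone mean lengths within 15%); type-I
error of the zone-length test over 1,000 null replicates of 50 + 50 zones
(within [0.03, 0.07] at alpha 0.05); Fisher agreement with full
enumeration on tables with totals up to 15 (tolerance 1e-9); pipeline runs
on simulated studies of 60–250 shoots.  All stochastic checks fix their
seeds; EM restarts, Monte-Carlo p-values and the pipeline are
deterministic given a seed, and identical seeds reproduce output files
byte for byte.

## Known limitations

* No right-censoring of the final zone: shoots whose last zone was cut
  short (e.g. by pruning) are modelled as complete.
* No macrostates, bidirectional transitions, covariate-dependent
  transitions or tree-level random effects; shoots are independent.
* The occupancy family set (shifted Poisson / negative binomial / binomial
  / point mass) is a convention; `select_occupancy_family()` chooses by
  BIC with ties to the simpler family.
* Transition probabilities of never-visited states are unidentifiable and
  simply retain their initialization; downstream summaries only use
  visited states.
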