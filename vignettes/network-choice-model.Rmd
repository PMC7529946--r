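---
title: "A network model of probabilistic choice: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A network model of probabilistic choice: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netchoice)
```

## The model

A choice problem is represented as a network. Nodes are either *cues*
(the framing of the choice — "choose a recording") or *alternatives*
(the options). Each node `i` is binary, active or inactive, and carries a
*general appeal* `b_i`; each pair carries a symmetric *coupling* `a_ij`
(negative couplings implement mutual inhibition). A configuration
`x` of node states has energy

    H(x) = -beta * [ sum_{i<j} a_ij x_i x_j + mu * sum_i b_i x_i ]

and the network at rest follows the quadratic exponential (Ising)
distribution `p(x) = exp(-H(x)) / Z`. The scaling constants enter as an
inverse temperature `beta >= 0` (attention, inverse time-pressure) that
scales the whole structure, and `mu`, which weighs the appeals against
the couplings. Multiplying `beta` by a constant while dividing `A` and
`b` by the same constant leaves all state probabilities unchanged, so
`beta = mu = 1` is the canonical parameterisation and the pair
`(beta, mu)` spans choice-setting variations (the phase scan below).

When a choice is posed, all cues are clamped active and the alternatives
are evaluated by Metropolis single spin-flip dynamics: sample one
mutable alternative uniformly, flip it, keep the flip if it lowers the
energy, otherwise keep it with probability `exp(H - H*)`. Two *trigger*
rules convert the evaluation into a decision:

* **converged** — run to stationarity and sample from the invariant
  distribution restricted to the *choice conditions* (configurations
  with exactly one active alternative). This yields the softmax of the
  cue-adjusted appeals `u_i = beta * (sum_k a_ik + mu * b_i)`, the
  classical Boltzmann / Bradley–Terry–Luce form, which satisfies Luce's
  choice axiom; couplings between alternatives cancel out of it.
* **first passage** — stop the first time a choice condition holds.
  This implements bounded rationality: the start distribution and the
  between-alternative couplings now matter, which is precisely what
  produces the endowment effect and the similarity, attraction,
  repulsion, compromise and phantom context effects.

The start distribution is the *resting state*: the Boltzmann
distribution of the whole free network — cues included — marginalised
over the cue states. We marginalise rather than condition on active cues
because the network rests *before* the choice is posed; the
weak-rationality diagnostic (`weak_rationality_diagnostic()`) depends on
exactly this: with a strongly unappealing cue, resting cue states are
almost always inactive, and the start mass follows the raw appeals even
when the cue-adjusted appeals order the other way.

Offering a subset of alternatives is modelled by restricting the network
to the cues plus that subset (`restrict_structure()`); an absent node is
equivalent to one clamped inactive and contributes nothing to any
energy.

## Exact solver

For `m` offered alternatives the dynamics are a Markov chain on the
`2^m` alternative configurations (canonical enumeration: node 1 is the
least-significant bit). Choice conditions are absorbing; splitting the
transition matrix into its canonical blocks `Q` (transient to transient)
and `R` (transient to absorbing) gives

    p(y)    = z_a 1_y + z_t (I - Q)^{-1} R_y
    E(t | y) = z_t (I - Q)^{-2} R_y / p(y)

where `z` is the start distribution split into absorbing and transient
mass and `t` counts Metropolis proposals, rejected ones included. Both
formulas are evaluated by LU solves, never by explicit inversion; the
reciprocal condition number of `I - Q` is estimated, and below `1e-12`
the result carries a `condition_warning` (deep in the rational regime
the exit probabilities underflow and the solve degrades — the
"precision limit" region of the phase diagram). Alternatives with
essentially zero choice probability (below `1e-300`) report `NA`
expected iterations instead of propagating a division by zero.

For two alternatives the first-passage probability has a closed form
(`binary_first_passage()`): start mass on a choice condition triggers
immediately, and from the empty or full configuration the decision is a
race between two accepted flips, a logistic in the *clipped* appeals
(`min(0, u)` terms). The suite checks this form against the matrix
solver on a thousand random problems to `1e-10`.

Exact enumeration is guarded at 20 free nodes / alternatives; beyond
that the Monte-Carlo simulator is the intended tool (dense `2^m`
matrices stop being practical well before the guard).

## Simulator

`estimate_choice_outcome()` runs independent trials of the chosen
trigger. The batch engine is vectorised over trials on canonical state
indices, with per-(state, flip) acceptance probabilities precomputed;
one seeded R random stream drives a whole run, so summaries are exactly
reproducible given `seed` (two runs with the same seed are identical; we
do not maintain per-trial substreams). A per-trial iteration guard
(default `1e7`) converts the nearly non-absorbing regimes into a
diagnosable error rather than a hang. Single trials
(`run_first_passage_trial()`, `run_k_visit_trial()`) use the same
engine with `n = 1` and consume the current RNG state.

The k-visit triggers model deliberation: `proportional` stops after the
choice conditions have been occupied `k` iterations in total and samples
the choice proportional to the per-alternative counts — as `k` grows the
occupation fractions converge to the invariant distribution, i.e. to the
converged probabilities; `first_to_k` stops when one alternative has
accumulated `k` visits, which concentrates on the alternative with the
largest effective appeal.

The simulator is validated against the exact solver (probabilities and
mean iteration counts within three standard errors at `1e5` trials on
randomized structures with `|a|, |b| <= 2` and up to four alternatives)
and, free-running without absorption, against the conditional Boltzmann
distribution (chi-square goodness of fit). These are the study
conditions of the test suite; they exercise every regime the worked
fixtures use, but small dense networks are not evidence about behaviour
on large or sparse structures.

## Fixtures and calibration

The worked phenomena ship as calibrated fixtures (`build_fixture()`).
All of them couple the cue to every alternative with weight 1 — the
effects should not depend on biased framing — and put the sign pattern
that explains the effect on a single alternative–alternative edge.
Appeals are never hard-coded to reproduce a prediction; they are
*calibrated* to the classical anchor values by root finding on the exact
solver (`calibrate_general_appeal()`), so every headline number is
recomputed from the model at build time:

* **similarity** — recordings `D_C` vs two interchangeable `B_F`, `B_K`
  with a strong negative edge between the latter; `D_C`'s appeal is
  calibrated so each pairwise probability against a `B` is 3/5. The
  first-passage triple then stays at (3/5, 1/5, 1/5) — the intuitive
  split — while the converged limit would give 3/7.
* **attraction (a)** — money / nice pen / plain pen with a negative
  money–plain edge. Money's appeal is calibrated to the pairwise 64/36
  split; the plain pen's appeal and the edge weight are then jointly
  calibrated (nested root finds) to the observed triple (52, 46, 2)%.
  The regularity violation — the nice pen rising from 36% to 46% when a
  worse pen is added — is therefore reproduced exactly.
* **attraction (b)** — the same boost explained by a *positive* edge
  (+2) between the pens; only the plain pen's 2% share is calibrated
  (the positive-edge mechanism cannot reach the full 46% under these
  baselines, so this variant is anchored qualitatively).
* **repulsion** — attraction (a) with the money–plain edge sign flipped,
  everything else identical: the boost now goes to the money.
* **compromise** — cameras low/mid/high with a strong negative low–high
  edge; the high camera's appeal is calibrated so it takes 1/4 of the
  triple, leaving approximately (1/4, 1/2, 1/4).
* **phantom** — target/rival/decoy paperclips, the decoy superior
  (appeal 4 vs 3) and negatively coupled to the rival; the edge is
  calibrated so that after the decoy is revealed unavailable the target
  is re-chosen with probability 4/5. With the unavailability known
  upfront the decoy's lone-active states are merely transient
  ("sample and flip, but not terminate"); reaching the same target boost
  then demands a substantially stronger edge, which the suite checks by
  comparing the minimal edge magnitudes across the two modes.
* **endowment** — two equally appealing alternatives, known initial
  configuration (the endowed one active), and a *forced first step*:
  the start already satisfies a choice condition, so one Metropolis step
  is always executed and staying put counts as keeping the endowment.
  The switch probability is `(1/4) [min(1, e^u) + min(1, e^{-u})]`,
  equal to 1/2 only at `u = 0` — loss aversion emerging from the
  process, not from re-valued payoffs.

Two baseline regimes recur. Where the anchor is a race between
*deactivation* flips (similarity, compromise) the non-calibrated
alternatives carry baseline appeal 5: the resting state then
concentrates on the nearly-all-active configurations and the pairwise
and triple anchors become consistent; at this baseline the similarity
triple is within `6e-4` of (3/5, 1/5, 1/5) (at baseline 3 the residual
is `4.5e-3`, at baseline 1 `2.8e-2`). "Strong" negative couplings
default to −30 rather than a token large value, because forbidding
co-activation requires the edge to dominate the *effective* appeals
(~6 at baseline 5); at −10 a leakage path through the forbidden
configuration still contributes `~2e-3`. The attraction family and the
phantom use baseline 3, where the printed triples are attainable
exactly. These choices are fixed by the anchors, not tunable knobs.

Re-choice protocols (`rechoice_probabilities()`) clamp the owned
alternative active — it becomes an extra cue, feeding its couplings into
the remaining alternatives' effective appeals — and by default restart
from the known configuration with the remaining alternatives inactive.
A known all-inactive start cannot transmit a relation *between two
remaining* alternatives (from the empty configuration the first accepted
flip already decides), so the function also offers `initial = "resting"`,
which lets the reduced network re-equilibrate before the second choice
and does transmit such relations. The default follows the stricter
known-state reading; both are exposed because they make divergent,
testable predictions.

## The beta/mu phase scan

`phase_scan()` re-solves a fixture over a log-spaced grid of
`(beta, mu)`, recomputing the resting start in every cell, and
classifies each cell by `classify_phase()` against the converged
reference at `beta = mu = 1`. The six labels (random; strong and normal
attraction; choice-axiom; increasingly rational; rational) follow fixed
thresholds — probabilities within 10 points of each other; target above
rival; rival below 62%; within 0.01 of the reference; rival above 66%;
rival above 90% — applied in the precedence order RND, AE+, RA+, RA,
CA, AE. The definitions overlap, so *some* precedence is required; this
order resolves ties toward the more specific phase and treats the 0.01
band as the operationalisation of "differs only marginally". Cells whose
solve fails or is ill-conditioned are `UNCLASSIFIED` — the white
precision-limit corner at large `beta * mu`.

On the attraction fixture the 20 × 20 grid over `[e^-4, e^2]^2`
reproduces the qualitative geography: random behaviour at small
scalings, the attraction phases strongest at large `beta` with small
`mu`, increasing rationality as both grow, and the precision limit in
the far corner. Decision times (log overall expected iterations) grow
explosively toward that corner. Along the `beta = mu` diagonal they are
*not* globally monotone for this fixture: the exact solver shows a
shallow dip (about 2.7%, from 1.2302 at `e^-4` to 1.1972 near 0.08,
with closed-form value 10/8 at zero) before the steep rise — weak energy
gradients at first *accelerate* absorption slightly. The test suite
records this as a known deviation from the idealised
"non-decreasing along the diagonal" expectation.

## Numerical choices

* All Boltzmann weights are computed after subtracting the extremal
  energy, so huge `beta * mu` degrades gracefully instead of
  overflowing.
* Linear systems in `I - Q` are solved by LU factorisation with a
  reciprocal-condition estimate; `1e-12` is the warning threshold.
* Calibration root finds use bracketed `uniroot` with tolerance
  `1e-10` and verify the achieved residual against `1e-8`; targets of
  exactly 0 or 1 are rejected as infeasible.
* Identity checks run at `1e-8` (utility classes), simplex and axiom
  identities at `1e-10`; both are exposed as `tol` arguments.
* Configuration enumeration order (node 1 = least-significant bit) is
  fixed and shared across the solver, the simulator and the state
  distributions, so indices are stable between modules.

## Limitations

* Exact solving is dense in `2^m`; beyond roughly a dozen alternatives
  only the simulator is practical.
* Iteration counts are a proxy for response times, not a chronometric
  model; only orderings and qualitative shapes are meaningful.
* Binary node states only; no attribute-node layer, no per-individual
  parameters — the model describes a single shared choice structure.
* The strong-utility checker tests necessary conditions only; existence
  of a distribution-function representation is not decidable from
  finite data.
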