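---
title: "Propagation models, triggering scores and cotreatment interference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation models, triggering scores and cotreatment interference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triggernet)
```

## The problem

Kinase inhibitors bind many proteins besides their intended target. When a
drug class such as the BTK inhibitors shows a reproducible adverse-event
signal — atrial fibrillation and hypertension in the motivating case — a
mechanistic question follows: *which* of the drug's targets and off-targets,
when inhibited, can evoke the molecular processes behind the event, and
through which network paths? `triggernet` answers this in silico, by
propagating target perturbations over a signed, directed protein-interaction
network and scoring how the propagated signal aligns with molecular
definitions of the pathophysiological processes.

The package implements the full chain: a trainable propagation model over
the interactome, an ensemble ("universe of solutions") sampled by repeated
stochastic training, a distance-weighted triggering score with a
classification rule, mechanism-of-action (MoA) models with pathway
extraction, and a tSignal-based cotreatment-interference screen with
rank-sum/FDR statistics. A synthetic-benchmark generator with planted ground
truth makes every stage testable end to end without any proprietary input.

## The propagation model

The interactome is treated like a multilayer perceptron unrolled over the
network itself: proteins are units, curated signed edges are connections.
Each edge $(i \to j)$ carries a weight $w_{ij} \in [-1, 1]$ whose sign is
pinned to the curated edge sign — an inhibiting interaction can only
transmit inhibition. Given a stimulus (a set of proteins clamped at
$\pm 1$), activities start at zero elsewhere and are updated synchronously
for $T$ rounds:

$$ y_j^{(t+1)} = \tanh\!\Big(\sum_{i \to j} w_{ij}\, y_i^{(t)}\Big), $$

with clamped proteins held fixed. Choices behind this form, none of which
is dictated by the modelling framework itself:

* **Squashing** is `tanh`: odd (negating every clamp negates every
  activity), maps 0 to 0, bounded in $(-1, 1)$.
* **Synchronous updates**, not asynchronous: results are independent of an
  arbitrary node ordering and bit-reproducible.
* **Step count** `n_steps = 5` by default. Signal relevant to the analyses
  travels at most a handful of interactions (the triggering score only
  looks three steps out); five rounds let a clamp reach everything that
  matters on networks of the size used here while keeping propagation cheap.
* **Activity threshold** `tau_act = 0.05`: a protein counts as "stimulated"
  only when its activity magnitude reaches this value. The cut avoids
  reading numerical dust as signal; it is deliberately small relative to
  the activities planted paths produce (≥ 0.6).

A stimulus-response **truth table** defines training: each constraint clamps
a stimulus and requires a response protein to end with a given sign at
magnitude ≥ `tau_act`. **Accuracy** (training compliance) is the fraction of
constraints satisfied.

## Training and the solution ensemble

Weight magnitudes are trained by simulated annealing (`train_solution()`),
signs staying pinned. Each proposal perturbs one edge magnitude with a
Gaussian step (reflected into `[min_weight, 1]`); acceptance follows the
Metropolis rule under geometric cooling. The objective is the accuracy plus
a margin bonus bounded by half the value of one constraint, which smooths
the otherwise step-shaped landscape without ever trading away a satisfied
constraint.

Defaults (`sa_control()`): 4000 proposals, `t_start = 0.02`,
`t_end = 0.001`, `step_sd = 0.4`. The proposal budget is roughly ten
proposals per edge at the reference benchmark size; substantially fewer
leaves the search short of its accuracy plateau. The starting temperature
sits well below the objective's constraint step (1/30 ≈ 0.033 on the
reference truth table), so early exploration comes from the margin term
rather than from accepting outright constraint losses. On the reference
benchmark these settings reach 97–100% compliance per solution.

`sample_ensemble()` repeats training under seeds `base_seed + 0, 1, …` and
retains solutions at or above an acceptance threshold (default 0.9, in line
with training compliance around 93% being the expected quality of a usable
solution). All downstream quantities — triggering scores, MoA activities,
pathway supports, tSignals — are summaries over this universe of retained
solutions, weighted uniformly: no density over solutions is available, so
no reweighting is attempted.

## Triggering analysis

For a protein under evaluation, the clamp (−1 "inhibited" or +1
"activated") is propagated through every solution. Effectors of a process
at directed distance 1, 2 or 3 (following edge direction — signal flows
downstream; an undirected fallback exists behind `distance_mode`) whose
activity carries the expected sign at magnitude ≥ `tau_act` contribute a
proximity weight; the per-solution sums are averaged over the ensemble.
Proximity weights default to $w_d = 1/d$ = (1, 1/2, 1/3): proximity is
rewarded, with no tier dominating absolutely.

Raw scores are normalized per process by the maximum observed across all
evaluated proteins and both modes, so normalized scores live in $[0, 1]$
and each process's best cell is exactly 1. The classification rule flags a
(protein, process) pair when

$$ \mathrm{score}(\text{inhibited}) - \mathrm{score}(\text{activated}) > 0.2, $$

a strict inequality. Under this package's normalization the difference can
never leave $[-1, 1]$; externally reported difference matrices include
magnitudes up to 2.88, so whatever normalization produced them is not
recoverable from their description and no attempt is made to regenerate
reported score *values*. What is reproduced — exactly — is the
classification rule applied to reported difference matrices; the bundled
`btki_difference_table()` fixtures demonstrate this on the two inhibitors'
atrial-fibrillation and hypertension tables.

## MoA models and pathways

`build_moa()` simulates the drug context: every target of the drug is
clamped at −1, the triggering-flagged off-targets being the stimulus of
interest while the remaining targets are kept inhibited. Pathway extraction
enumerates simple directed paths (≤ `max_len = 4` steps) from flagged
proteins to process effectors; a path is active in a solution when all its
nodes are above `tau_act` and every step is sign-consistent (child sign =
edge sign × parent sign). Support is the fraction of solutions in which the
path is active; paths at `min_support = 0.5` or more are reported ("most
frequent" has no published cutoff; majority support is the natural
default). Ties are broken by path length, then lexicographically, so output
is deterministic.

Agreement with literature response sets counts only proteins *predicted* by
at least one model (mean activity ≥ `tau_act`), excludes clamped proteins
(their sign is imposed), and by default requires the predicted sign to
match in every model where the protein is present — the conservative
reading; `consistency = "any"` gives the permissive one. When no literature
protein is present at all, agreement is undefined and returned as `NA`,
never as 0.

## tSignal, Diff Effect and the statistical layer

For a process with effectors $i = 1..n$, expected signs $v_i$ and predicted
activities $y_i$:

$$ \mathrm{tSignal} = -\frac{1}{n} \sum_{i=1}^n v_i y_i . $$

The leading minus is implemented verbatim, so full concordance gives −1.
Because a stimulus that *drives* the process therefore scores negatively,
the package also reports the negated value (`induction_signal()`), on which
"signal over the process" reads positively. The cotreatment **Diff Effect**
is the change in induction signal when the cotreatment's clamps join the
drug's: negative when the cotreatment counteracts the drug-evoked
mechanism. Both raw tSignal means are printed alongside, so either
convention can be read off the output.

The screen tests, per (cotreatment class, process), combined-vs-alone
tSignal samples across solutions with the two-sided Wilcoxon rank-sum test
(exact for small untied samples, normal approximation with tie correction
otherwise; a paired signed-rank alternative sits behind `paired = TRUE`),
corrects with Benjamini–Hochberg across the whole screen, and flags when
`q ≤ 0.05` **and** `|Diff Effect| > 0.05`.

A practical power note: with $n$ solutions per arm the smallest achievable
two-sided rank-sum p-value is $2/\binom{2n}{n}$. Five solutions
($p_{\min} = 2/252$) is the smallest ensemble for which a completely
separated comparison can stay significant after BH across a 12-test screen
at $\alpha = 0.05$; four cannot, whatever the data. Screens on small
ensembles should be read with this floor in mind, and the package's own
recovery tests use ensembles of at least five.

## The synthetic benchmark

`generate_benchmark()` builds the study conditions every test runs under:

* a scale-free backbone (preferential attachment, `m = 2`), randomly
  oriented, with inhibiting edges at probability 0.3 — interactomes are
  heavy-tailed and sign-mixed, and the triggering analysis is
  distance-sensitive, so topology matters more than biochemical realism;
* two inhibitor profiles: one primary target plus shared off-targets (both
  drugs) and drug-A-specific off-targets — the superset/subset asymmetry of
  the motivating drug pair;
* per process, designated inducer off-targets wired to dedicated effectors
  at distance 1 and (through a relay) distance 2, expected signs chosen so
  inhibition of the inducer produces them. Targets are placed pairwise at
  directed distance ≥ 3, so non-inducer targets have *no* path of length
  ≤ 3 to any effector: under the planted parameterization the triggering
  classification recovers the designated inducers exactly, with specificity
  guaranteed by construction rather than by luck;
* one antagonist cotreatment class per process, wired to push the planted
  effectors against their expected signs, and a null class drawn from
  proteins with no directed path to any effector (its Diff Effect is zero
  per solution, under any parameters);
* a truth table recording planted-model propagation outcomes: constraints
  pinning every inducer→effector and antagonist→effector response, plus
  random stimulus–response pairs (responses with planted activity ≥ 0.1,
  twice the activity threshold, so satisfiability is robust). A
  100%-compliant solution exists by construction; pinning the planted paths
  is also what makes *trained* ensembles — not just the planted model —
  recover the planted structure.

The reference spec is 200 proteins and 30 constraints; the recovery suite
uses 100-protein benchmarks across ten seeds with five-solution ensembles,
and most unit fixtures use a 60-protein single-process benchmark. These
sizes keep a full pipeline run in minutes on one CPU while leaving the
scale-free tail and the 3-step distance structure intact.

What the generator does *not* emulate: curation noise and literature bias
in edge signs, node-degree correlations of the real interactome, multiple
primary targets, incomplete effector definitions, and feedback between
processes. Passing recovery tests therefore show the pipeline's inference
machinery is sound under conditions where truth is known — not that its
conclusions on a real curated interactome are correct, which depends
entirely on input quality.

## Two-drug asymmetry, precisely

"The superset drug modulates a superset of proteins" is almost — but not
exactly — true: a protein can receive opposing signal from a drug-A-specific
target and cancel below threshold (one to five proteins out of ~140 on
benchmark runs). The invariant the package tests is the provable version:
outside the `n_steps`-downstream cone of the A-specific targets, the two
drugs' MoA activity vectors are *identical* (nothing else differs), so
subset containment holds exactly there; and A's suprathreshold count is at
least B's.

## Numerical and degenerate-input choices

* Duplicate edges with conflicting signs are a hard load error; conflicting
  curation must be resolved upstream, not silently overwritten.
* Self-edges are rejected; sign tokens `±1`, `+`/`-`,
  `activation`/`inhibition`, `activates`/`inhibits` are normalized to ±1.
* Off-target potency filtering keeps IC50 strictly below threshold *or*
  regulatory-document-sourced targets without an IC50 (an explicit flag);
  it is idempotent and monotone in the threshold.
* Empty effector sets and empty truth tables are errors; an empty
  *cotreatment* clamp set is legal and yields Diff Effect exactly 0.
* Identical constant samples in the rank-sum test return p = 1 (no
  evidence), not an error.
* All stochastic operations take explicit seeds; training seeds are
  `base_seed + solution index`. Same seed, same bytes.

## Known limitations

* The propagation model is a design choice, not an identified system:
  transfer function, step count and optimizer are not recoverable from any
  published description of the modelling framework this emulates, and
  different choices would yield different trained weights (though the
  sign-constrained structure pins much of the qualitative behaviour).
* Solutions are weighted uniformly; "most probable solutions according to
  the distribution" is not implementable without a density over solutions,
  which is not available.
* Reported triggering score values from external analyses are not
  regenerable (see above); only the classification rule is.
* Simple-path enumeration is exponential in the worst case; `max_len = 4`
  keeps it tractable on interactome-like graphs but dense subgraphs with
  larger `max_len` will be slow.
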