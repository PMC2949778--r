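---
title: "Methods: evolutionary variable selection, neural classification and connectivity mapping for folate-pathway case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary variable selection, neural classification and connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Mothers of children with Down syndrome (MDS) differ, on average, from
mothers of healthy children in two kinds of measurements: the frequency of
micronucleated binucleated lymphocytes (BNMN, per 1000 binucleated cells — a
chromosome-damage biomarker) and the genotype distribution of common
polymorphisms in folate-metabolizing genes (MTHFR 677C>T and 1298A>C, MTRR
66A>G, MTR 2756A>G, RFC1 80G>A, and the TYMS 28bp-repeat and 1494 6bp-deletion
variants). Individually these associations are weak and cohort sizes in this
field are small (tens of subjects), so single-variant statistics are
underpowered. `twistmap` implements a non-linear analysis strategy for this
setting:

1. **Encoding** — each locus expands to three binary genotype-class
   indicators (major homozygote, heterozygote, minor homozygote); BNMN is
   min-max scaled to [0, 1]; case status is the binary target (case = 1).
2. **Evolutionary wrapper selection (the "TWIST" stage)** — a genetic
   algorithm evolves, simultaneously, a train/test split of the records and
   a mask over the input variables, scored by how well a small perceptron
   trained on one half classifies the other half *in both directions*.
3. **5x2 cross-validated classification** — five stratified random halvings,
   each used in both train/test directions, give ten held-out estimates of
   sensitivity, specificity, global accuracy and ROC AUC for
   back-propagation networks restricted to the selected variables.
4. **Semantic connectivity map** — an Auto-Contractive Map (Auto-CM) is
   trained on all encoded variables plus two condition indicator nodes; its
   learned pairwise weights are converted to distances, filtered by a
   minimum spanning tree, and scaled to [0, 1] edge strengths. Nodes of
   maximal tree degree are reported as hubs.

A calibrated synthetic-cohort generator makes every stage testable without
subject-level data.

## The synthetic-cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions: 29 cases and 32 controls, per-(group, locus) genotype-class
probabilities equal to the published per-group counts divided by the group
size, and BNMN drawn from a normal with the published group parameters
(16.5 ± 7.6 per-mille in cases, 9.3 ± 3.1 in controls), truncated at zero by
rejection because a per-mille frequency cannot be negative. The truncation
shifts the control mean by well under 1% of its SD, which the recovery
tolerances absorb.

Design choices a user should know about:

* **Genotype-level sampling, no Hardy–Weinberg assumption.** Uncoupled loci
  are sampled directly from the genotype-class frequencies, because the
  study conditions are genotype counts, not allele counts.
* **Couplings are haplotype-level.** Linkage disequilibrium between two loci
  (the rare MTHFR 677T–1298C haplotype; the rare TYMS 2R–deletion haplotype)
  is planted by drawing two two-locus haplotypes per subject (random union)
  from a 2×2 haplotype table in which the named rare haplotype gets a chosen
  frequency (default 0) and the other three cells are solved to preserve the
  single-locus allele marginals. Infeasible requests (a rare-haplotype
  frequency above an allele marginal) are rejected with the violated
  constraint. This is the minimal model that realizes "strong linkage".
* **Noise loci** are drawn once per configuration from Hardy–Weinberg
  proportions with a uniform allele frequency and are identical in both
  groups, so they carry no case-status signal by construction.
* **No extra effect-size knob.** The group signal is carried by the
  calibrated group-specific frequencies themselves (e.g. RFC1 80 AA: 1 case
  vs 10 controls) and by the BNMN shift; both are freely overridable for
  power experiments.
* `table1_reference_cohort()` builds a deterministic 61-subject cohort whose
  genotype counts equal the published ones *exactly* and whose per-group
  BNMN values realize the published mean and sample SD *exactly* (an equally
  spaced grid, standardized and rescaled). It is the fixture for
  summary-level checks such as the univariate BNMN/case-status correlation,
  which on any such cohort equals 0.54 to two decimals.

What the generator does **not** emulate: the real joint genotype
distribution across loci (unknown from published marginals), age structure,
missing data, genotyping error, or population stratification. Passing
recovery tests on synthetic cohorts therefore demonstrates that the pipeline
recovers structure *of the kinds planted*, not that it would behave
identically on the original subject-level file.

## The back-propagation perceptron

The classifier is deliberately small and era-faithful: one hidden layer of 4
logistic units, a single logistic output, squared-error loss, online
(per-pattern) gradient descent with momentum. Defaults: learning rate 0.1,
momentum 0.9, 500 epochs, uniform(−0.5, 0.5) seeded weight initialization,
per-epoch reshuffling. None of these are dictated by the problem; they are
standard for small bounded tabular inputs and are all exposed in
`train_config()`. Squared error (not cross-entropy) keeps the loss the plain
"error function" minimized by classic back-propagation. The decision
threshold is 0.5 on the sigmoid output, with ties classified as positive —
a deterministic tie rule. Training is bit-reproducible given the seed (a
self-contained splitmix64 stream drives initialization and shuffling,
independent of R's RNG state).

ROC AUC is computed by the rank-sum (Mann–Whitney) formulation with
midranks, so ties count one half; it equals brute-force pairwise counting to
1e-12, which the tests assert.

## The TWIST stage

The genome concatenates one bit per record (subset a vs b) and one bit per
feature (selected vs not). A genome is *valid* when at least one feature is
selected and each subset contains both classes; invalid genomes score 0
rather than being repaired, which keeps the operator simple and unbiased.
Fitness of a valid genome is the mean of the two directions' held-out global
accuracy (train a → test b and train b → test a) using a reduced-budget
inner perceptron (100 epochs) for tractability; the final reported networks
are retrained at full budget inside the 5x2 stage.

Two details make fitness a pure function of the genome:

* the inner networks use a fixed seed from the configuration, and
* training rows are put into a canonical lexicographic order first, so the
  fitness depends only on the *partition* of records, not on the order they
  happen to be stored in (online back-propagation is otherwise
  order-sensitive).

The evolutionary operators are: tournament selection (size 2), uniform
crossover (rate 0.9), per-bit mutation (rate 1/genome-length), elitism (2),
and "doping" — `floor(0.1 × population)` random immigrant genomes injected
each generation in place of the worst-bred offspring, which maintains
diversity in the small population (30 genomes, 100 generations by default).
Within a run, fitness values are memoized, which matters as the population
converges. The exact operator suite of the original evolutionary system is
not public; this implementation keeps its documented essence (a doped
genetic algorithm jointly optimizing split and mask) behind a configurable
interface.

The train/test-split half of the genome realizes the "similar distributions"
objective implicitly: splits on which both halves generalize to each other
score higher. No separate density-similarity term is added.

**A caution that follows from the design.** Because the GA maximizes
*held-out* accuracy over the split bits, its final fitness is an optimistic,
winner's-curse-biased estimate: on cohorts with no group signal at all the
evolved fitness still reaches roughly 0.75–0.85, even though the fitness of
*random* genomes is correctly centered near 0.5 (both behaviors are
measured in the test suite). Reported performance should therefore always
come from the 5x2 stage, whose test halves never influence the weights that
score them, and not from the GA's internal fitness.

## The 5x2 validation stage

Halvings are stratified by class. The published test-half compositions are
near-balanced and, with ~30 records per half, unstratified halvings
frequently produce degenerate class ratios, so stratification is the
defensible reading of "random subdivision". 61 records split as 31/30 with
per-class counts differing by at most one. Each halving gets one fresh
weight initialization (derived from the master seed) shared by both
directions, so relabeling the halves permutes the ten rows without changing
the mean row; the mean row is the exact arithmetic mean of the ten rows.
The features fed to this stage are normally the TWIST-selected set, but any
subset can be passed to run selection-free baselines.

## The Auto-Contractive Map and the connectivity graph

For each input record the map contracts the signal twice — once through a
mono-connection weight per variable, once through the pairwise weight
matrix:

* hidden signal: `m_s(i) = m_in(i) · (1 − v(i)/C)`
* net input: `Net(i) = Σ_j m_s(j) · (1 − W(j,i)/C)`
* output: `m_out(i) = m_s(i) · (1 − Net(i)/C)`
* updates: `Δv(i) = α (m_in(i) − m_s(i)) (1 − v(i)/C)` and
  `Δw(j,i) = α (m_s(i) − m_out(i)) (1 − W(j,i)/C) m_s(j)`

with zero-initialized weights, fixed record order (fully deterministic), and
stopping when the epoch-mean absolute weight change falls below `tol`
(1e-6) or at the epoch cap (1000). Pairwise weights grow with co-activation
and stay strictly below the contraction constant `C`, which defaults to the
number of nodes — the value that guarantees the output contraction can never
go negative. The learning rate α defaults to 0.1. The exact update rules of
the original system are not published in the main literature; these
equations realize every documented contract (co-activation growth, the
`[0, C)` bound, determinism) and sit behind the training interface so they
can be swapped if a different variant is preferred.

The directed weight matrix is symmetrized by averaging before any downstream
use, because the spanning tree needs an undirected graph. Distances are
`d = C − w`; edge strengths are `w / C`, an order-preserving bijection from
`[0, C)` to `[0, 1)` — the scale used on the exported graph labels. The
minimum spanning tree uses sort-based greedy construction with cycle
detection (Kruskal); distance ties are broken lexicographically on the
(smaller, larger) node-name pair so the tree is reproducible. Hubs are all
nodes of maximal tree degree, reported with ties.

The two condition labels (MDS, control) enter the map as two binary
indicator nodes, since the connectivity graph is read through the variables'
positions relative to the conditions. BNMN enters as its continuous [0, 1]
encoding; discretizing it first is possible by modifying the encoded matrix,
but is not the default.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full defaults on
61-subject cohorts: one complete pipeline run (GA of 30×100 genomes with a
100-epoch inner perceptron, then ten 500-epoch networks, then the Auto-CM on
24 nodes), plus ten-seed stability loops for selection frequency, linkage
adjacency and hub recovery, and 10,000-subject-per-group draws for marginal
recovery. These sizes were chosen so that each property is measured under
the study conditions themselves rather than on scaled-down surrogates, while
single runs stay interactive (tens of seconds). Degenerate inputs are
handled explicitly rather than silently: a degenerate BNMN range encodes as
0.5 with a warning, zero-variance features are flagged with r = 0 in the
correlation screen, single-class metric denominators report `NA` (missing)
rather than 0, and single-record groups report SD 0 with a flag.

## Known limitations

* The GA's internal fitness is not a performance estimate (see above); use
  the 5x2 table.
* With ~60 subjects, 5x2 metrics have wide sampling variability; the mean
  row summarizes ten correlated estimates, not ten independent ones.
* The synthetic joint genotype distribution is a modeling choice; only
  marginals and planted couplings are faithful to the published summary.
* The selected variable set is a stochastic output of the GA; across seeds
  the dominant biomarker is stable, the weaker genotype indicators are not,
  and set sizes vary. Agreement with any particular published 6-variable
  set should be treated as an expectation, not an identity.
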