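---
title: "Multi-objective virtual screening with desirability aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective virtual screening with desirability aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moscreen)
```

## The screening problem

Ligand-based drug repurposing often starts from two lists of proteins: the
*targets*, whose modulation is desirable for a disease, and the
*off-targets*, whose modulation must be avoided (for example because the
drugs hitting them are contraindicated in the patient population). Given a
probabilistic activity classifier per protein, every library compound can be
scored against every protein, and the question becomes: **which combination
of per-target models, aggregated how, ranks the known good drugs highest
while pushing risky chemistry down?**

moscreen implements one complete answer:

1. curate raw replicated bioactivity records into per-protein
   active/inactive training labels;
2. balance each protein's training classes by clustered undersampling of
   circular fingerprints (classifier training itself is outside the package
   boundary — any probabilistic classifier can plug in);
3. aggregate the per-protein activity probabilities into a single
   *desirability* per compound over a selected subset of proteins;
4. search the subset space with a genetic algorithm (GA) maximizing the
   BEDROC early-recognition metric of the resulting ranking;
5. cluster the well-performing subsets, read off per-cluster target
   relevance, and rank a drug library by cluster-consensus desirability.

## The desirability model

Let $P_{i,j}$ be the predicted probability that compound $i$ is active on
protein $j$, and let a *model mask* select $N^P$ target columns and $N^O$
off-target columns. The desirability of compound $i$ is

$$
D_i \;=\; P_i^P \, P_i^O, \qquad
P_i^P = \frac{1}{N^P}\sum_{j \in \text{targets}} P_{i,j}, \qquad
P_i^O = \frac{1}{N^O}\sum_{j \in \text{off-targets}} \bigl(1 - P_{i,j}\bigr).
$$

Both factors live in $[0,1]$: $P_i^P$ rewards predicted activity on the
selected targets and $P_i^O$ rewards predicted *inactivity* on the selected
off-targets, so $D_i$ is the unweighted two-objective compromise. A mask
selecting zero targets or zero off-targets leaves one factor undefined; such
masks are *invalid screening models* and receive a $-\infty$ fitness
sentinel in the GA rather than silently dropping a factor — this keeps the
multi-objective intent intact while letting the GA traverse the invalid
region. (Each role's mean is normalized by its own count of selected
columns; that is the only reading under which both factors are means of
their respective summands.)

```{r desirability}
compound_desirability(c(0.9, 0.7, 0.2), mask = c(1, 1, 1),
                      roles = c("target", "target", "off_target"))
```

## Early-recognition metrics

For a ranking of $N$ compounds containing $n$ known desirables at ranks
$r_i$ (relative ranks $x_i = r_i/N$):

* **AUAC** $= 1 - \frac{1}{n}\sum_i x_i$ — one minus the mean relative rank;
  insensitive to *where* in the list the actives sit.
* **EF** at fraction $\chi$: actives retrieved in the top
  $\lceil \chi N\rceil$ positions relative to the random expectation. We use
  the ceiling cutoff with effective fraction
  $\chi_\mathrm{eff} = \lceil\chi N\rceil / N$ as normalizer, so the maximum
  is exactly $1/\chi_\mathrm{eff}$ when all actives fit in the top set and
  $N/n$ otherwise. A consistency check that motivated this convention: for a
  screen of $N = 14{,}686$ with $n = 19$ desirables and 6 of them inside the
  top-1% cutoff of $\lceil 0.01 N \rceil = 147$, the ceiling convention
  gives $\mathrm{EF}_{1\%} = 31.55$ (two decimals), whereas the naive
  $\chi = 0.01$ normalizer gives 31.58.
* **RIE** $=\frac{\frac1n\sum_i e^{-\alpha x_i}}
  {\frac1N\,(1-e^{-\alpha})/(e^{\alpha/N}-1)}$ — exponentially
  rank-weighted retrieval relative to a uniform ranking.
* **BEDROC** $=\dfrac{\mathrm{RIE}-\mathrm{RIE}_{\min}}
  {\mathrm{RIE}_{\max}-\mathrm{RIE}_{\min}} \in [0,1]$, the min–max
  normalization over all possible placements.

The weight $\alpha$ is calibrated by solving
$\theta(1-e^{-\alpha}) - 1 + e^{-\alpha z} = 0$: the $\alpha$ at which a
fraction $\theta$ of the BEDROC weight falls in the top fraction $z$ of the
list. The default is $\theta = 0.8$, $z = 0.01$:

```{r alpha}
solve_alpha(theta = 0.8, z = 0.01)
```

about $160.9$ — 80% of the weight in the top 1%, an aggressive
early-recognition regime appropriate when only the top tens of compounds
out of thousands will ever be inspected.

### Numerical choices

* All exponential expressions use `expm1` and non-positive exponents only,
  so $\alpha \approx 161$ (or far larger) cannot overflow:
  $\mathrm{RIE}_{\min}$ is evaluated as
  $(e^{\alpha(R_a-1)} - e^{-\alpha}) / (R_a(1 - e^{-\alpha}))$.
* BEDROC is clamped to $[0,1]$ against floating-point overshoot of order
  $10^{-16}$ at the extremes.
* Score ties are broken deterministically by compound id before ranking;
  BEDROC needs a total order and reproducibility matters more than any
  particular tie policy.
* The calibration root is found by bracketed bisection (`uniroot`) plus one
  Newton polish; the residual is verified below $10^{-10}$.

## Curation rules

* A record is **active** iff its potency (IC50, Ki, EC50 or GI50, in µM) is
  *strictly* below 10 µM — "lower than" is read literally, so exactly
  10 µM is inactive.
* Replicated reports for one (compound, target) pair are resolved by
  **modal-label share**: the pair is kept iff the majority label covers at
  least 75% of the reports, otherwise discarded. Shares are computed on
  report counts; at 75% a tie (50/50) can never be kept. Single reports
  pass through.
* Targets keep their classifier only with at least 100 actives **and** 100
  inactives (inclusive bounds).
* Proteins appearing in both the target-derived and off-target-derived sets
  stay in the **target** group (flagged `was_common`) and leave the
  off-target set.
* Units are the caller's duty beyond the provided nM/µM/mM/M helper;
  censored values ("> 10 µM" qualifiers) are not modeled and must be
  resolved upstream.

## Class balancing

Compounds are featurized as 1024-bit circular fingerprints of radius 4
(OpenBabel's ECFP8 via ChemmineOB, OR-folded from 4096 to 1024 bits — the
descriptor family matches the usual Morgan/ECFP setup; the hash positions
are OpenBabel's). Balancing then:

1. computes PCA on the **pooled** fingerprint matrix (both classes), keeping
   the smallest number of components with cumulative explained variance
   above 90% (`nPCA`) — pooling keeps the projection class-independent;
2. k-means-clusters the **majority class** in that PCA space for every
   $k \in \{3, \dots, n_\mathrm{PCA}+1\}$, choosing $k$ by maximum mean
   silhouette width (computed in PCA space; ties to smaller $k$; 10 seeded
   restarts per $k$);
3. samples from each cluster proportionally to its size until the majority
   count equals the minority count. Proportional quotas use
   **largest-remainder apportionment** so they sum exactly to the minority
   count — the natural deterministic rounding when a sum constraint must
   hold.

A 25% external validation split (stratified by class, so external metrics
remain meaningful on balanced data) is drawn afterwards. Both steps are
bit-reproducible under their seeds. When $n_\mathrm{PCA}+1 < 3$ the
clustered scheme is infeasible and plain seeded undersampling is used (and
recorded in the metadata).

## GA model selection

Individuals are bit strings, one bit per probability-matrix column. The
reference configuration is population 4000, 3000 generations, mutation
probability 0.4, crossover probability 0.6. Operators not pinned down by the
method description use standard bit-string GA choices, all exposed in
`ga_config()`:

* tournament selection of size 3;
* two-point crossover;
* mutation probability interpreted **per individual** (0.4 per bit would be
  near-random search); inside a mutated individual each bit flips with
  probability $1/T$;
* one elite copied unchanged per generation, making the best-fitness trace
  non-decreasing;
* initial individuals are repaired to select both roles; during evolution
  invalid individuals simply carry $-\infty$;
* fitness values are memoized by mask — the fitness is a pure function, and
  the cache provably returns identical results (tested).

Multiple restarts run from distinct seeded initial populations and
concatenate their final populations.

## Cluster consensus

Models at BEDROC $\ge$ 0.15 (inclusive) are kept, duplicates retained —
their multiplicity is information about GA convergence and weights the
relevance profile. The kept masks are clustered agglomeratively under
Euclidean distance; linkage is not dictated by the method description, so
Ward (`ward.D2`) is the default as the natural partner of Euclidean
distance on binary fingerprints, with `average` available for reproducing
externally clustered model sets. Per cluster:

* **target relevance** $S_i$ = fraction of the cluster's models selecting
  target $i$;
* **global desirability** $GD_i$ = mean desirability of compound $i$ over
  the cluster's masks — the consensus repurposing score;
* top-$n$ lists (default 50) are compared across clusters by union,
  all-cluster intersection and full Venn pattern counts;
* cross-cluster agreement is summarized by Pearson correlation of the $GD$
  vectors (Spearman available by flag, since rankings are the object of
  interest).

## The synthetic benchmark

Real inputs for this pipeline are per-target classifier probabilities over
a screening library — large, externally produced, and unavailable in a
self-contained test run. The generator emulates their *shape* at reduced
scale with recoverable ground truth. The reference testbed
(`synthetic_spec()` defaults) has $M = 2000$ compounds, 14 targets and 6
off-targets of which 12 and 4 are informative, and 20 planted desirable
compounds with signal level $p_\mathrm{signal} = 0.9$.

Cells are Beta draws parameterized by mean and concentration:

* **actives**: mean $p_\mathrm{signal}$ on informative targets,
  $1-p_\mathrm{signal}$ on informative off-targets, concentration 10
  (moderate classifier noise);
* **background** compounds on informative columns: mean
  $p_\mathrm{noise} = 0.5$, concentration 0.5 — a heavy-tailed (bathtub)
  distribution emulating the overconfident probabilities classifiers
  assign to decoys, independent per cell, so averaging over *all*
  informative columns is what suppresses decoy intrusion into the top
  ranks;
* **uninformative columns**: the same heavy-tailed noise for every
  compound (a classifier with no signal is confidently wrong at random), so
  selecting them only dilutes the actives' margin;
* **selective decoys**: 3 compounds per informative column carry an
  active-like profile *except* on that one column, where they behave like
  the opposite class — single-target activity cliffs, a well-known feature
  of real libraries. A ranking separates them from the true actives only
  while their discriminating column stays in the model.

The last two ingredients shape the fitness landscape: dropping any
informative column releases that column's decoys into the active band, and
adding any uninformative column shrinks the margin, so the planted mask is
the early-recognition optimum and a GA of modest budget (population 200,
100 generations) recovers it. Without the decoys the landscape is flat
across subsets of the informative columns and the planted set is not
identifiable — an instructive failure mode for feature selection on
early-recognition objectives generally. In the degenerate noiseless
setting ($p_\mathrm{signal}=1$, $p_\mathrm{noise}=0$, infinite
concentrations, no decoys) the planted mask provably attains the global
BEDROC maximum, which the tests verify by exhaustive mask enumeration.

What the generator does **not** emulate: correlated classifier errors
across related proteins, compound-series structure, class imbalance of real
screening decks, or any molecular structure (a tiny fixed SMILES panel
serves the fingerprint tests). Passing the recovery tests therefore shows
the optimizer and metrics behave as designed, not that any particular real
screen will reach a given BEDROC.

Replicated activity-record fixtures draw a truth label per pair, then emit
`replicate_count` potency values on the matching side of the 10 µM cutoff,
each flipping side with probability `disagreement_rate` — at rate 0 the
curation stage recovers truth exactly; at rate 0.5 with 4 replicates the
expected discard fraction is the binomial $P(2{:}2) = 0.375$.

## Problem sizes used by the test suite

The packaged tests run the full stack at deliberately reduced scale: the
GA recovery experiment uses the reference testbed above (2000 × 20, ten
seeds, population 200 × 100 generations, about half a minute in total);
unit fixtures use 5–400 compounds and 6–10 columns; the exhaustive metric
oracle enumerates all active placements for $N \le 8$. These sizes were
chosen so the whole suite exercises every code path in well under a minute
of compute while leaving the reference GA configuration (4000 × 3000)
available for real runs.

## Known limitations

* Desirability is the unweighted product of two means; Derringer-style
  power weights per target are deliberately out of scope.
* The 75% agreement rule counts reports, not unique assays; deduplication
  of identical reports is the caller's choice upstream.
* The EF ceiling-cutoff convention is one of two defensible readings (see
  above); both differ only in the third decimal at screening scale.
* Hierarchical-clustering membership depends on the linkage choice;
  reproduction of externally produced cluster files is best-effort via the
  `average` option.
* `featurize()` requires ChemmineOB; the rest of the package has no
  cheminformatics dependency and accepts externally computed bit matrices.
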