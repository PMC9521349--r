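---
title: "Methods: co-mutation networks from binary alteration calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-mutation networks from binary alteration calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The data and the model

The unit of analysis is a binary patient × gene matrix: entry 1 means the
patient carries at least one retained pathogenic alteration in the gene.
Retention applies two rules to the incoming call table: variants of
unknown significance and benign calls are excluded, while frameshift and
nonsense alterations are treated as pathogenic whatever their annotation.
Copy-number amplifications and fusions do not confer mutation-positive
status by default (`binarize(includeCopyNumber = TRUE)` reverses this),
because gene-level "mutation" in this setting conventionally means a
sequence variant; the flag exposes the alternative reading. Gene symbols
are upper-cased and whitespace-stripped; no alias resolution is
attempted — symbol harmonization belongs upstream.

Two model layers sit on that matrix:

* **Pairwise layer.** For an anchor gene and each candidate, a 2×2 table
  and a two-sided Fisher exact test (minimum-likelihood convention: the
  p-value sums hypergeometric point probabilities no larger than the
  observed one, with a `1e-7` relative tolerance for floating-point
  ties). Adjustment is Benjamini–Hochberg, applied within the candidate
  family of each anchor separately, because the anchors are screened
  independently. Significance uses `p_adj <= alpha` (the threshold is
  inclusive). Odds ratios are reported as the raw cross-product ratio,
  `Inf` when only the off-diagonal is empty; no continuity correction
  ever enters the test itself.

* **Network layer.** A discrete Bayesian network over the binary
  indicators. The network factorizes the joint as
  $P(x) = \prod_v P(x_v \mid x_{\mathrm{pa}(v)})$; every conditional is a
  Bernoulli table over parent configurations. The assumptions are those
  of any discrete BN: patients independent and identically distributed,
  no latent confounders inside the modeled gene set, and dependence
  expressible with at most `maxParents` parents per gene.

# Structure learning

Scores are decomposable: BDeu (Bayesian Dirichlet equivalent uniform,
equivalent sample size `ess = 1`, uniform structure prior) by default,
BIC by option. BDeu with a modest ESS is the common default for binary
panels and assigns equal scores to Markov-equivalent structures, which
the test suite asserts to `1e-9`.

Learning is two-stage, reflecting the cost asymmetry:

1. `approximateNeighbors()` hill-climbs over the full panel
   (add/delete/reverse moves, strictly improving steps, 10 restarts of at
   most 500 moves; restart *r* seeds the RNG with `seed + r - 1`, the
   first restart starts from the empty graph). The union of the anchors'
   Markov blankets is extracted; if it exceeds `k` (default 15), the
   genes with the largest single-gene score gain when linked to an anchor
   are kept. The same `maxParents` cap (default 4) applies during the
   climb; an uncapped climb would make move evaluation exponential in
   in-degree without changing the blanket in practice.
2. `exactSearch()` solves the candidate subnetwork optimally: A\* on the
   lattice of variable subsets, where appending node *v* to placed set
   *S* costs the best stored score of *v* with parents inside *S*
   (computed by subset-lattice dynamic programming over the
   `localScores()` table). The heuristic — the sum of each unplaced
   node's unconstrained best score — is admissible, so the first
   expansion of the full set is globally optimal. Determinism: equal-`f`
   states expand in ascending subset order, and among tied parent sets
   the smallest, then lexicographically first, is reconstructed. The
   search is guarded at 25 nodes; the subset arrays grow as $2^m$ and the
   intended use is the ≤ 17-node candidate set from stage 1.

`maxParents = 4` bounds the stored table (≈ 2,500 parent sets per node at
17 nodes) while allowing richer families than the hub-and-spoke truth
needs; raising it is a memory/time decision, not a correctness one.

# Parameter fitting and inference

CPTs are Dirichlet-smoothed frequencies:
$\hat p = (n_1 + c) / (n + 2c)$ with pseudo-count `c = 1` per cell, so no
factor is exactly 0 or 1 and belief propagation cannot divide by zero;
never-observed parent configurations fall back to the prior 0.5. The
smoothing matters for rare events: a configuration with expected count
~2 in the cohort has its conditional probability pulled noticeably toward
0.5, which biases relative risks for very rare co-occurrences upward (see
*Limitations*).

Queries prefer exactness: `variableElimination()` (sum-product
elimination in a min-degree order, restricted to the ancestral closure of
query and evidence) answers every query on subnetworks of up to 20 nodes;
`loopyBP()` — synchronous flooding sum-product with damping 0.5,
tolerance `1e-8`, 200 iterations — is the fallback above that and is
retained as a first-class engine because it is part of the documented
procedure. BP is exact on trees and polytrees (asserted against variable
elimination to `1e-8`); on cyclic graphs its converged beliefs carry the
well-known fixed-point bias, and the acceptance suite measures how often
they land within `1e-3` total variation of exact marginals on sparse
loopy networks (tree plus one or two extra edges, CPTs in [0.15, 0.85]).
The BP fixed point itself is cross-checked against an independently
coded message passer to `1e-9`.

The relative risk of co-segregation is reported in both conditioning
directions, because the field's phrasing is ambiguous between them:
`anchor_given_genes` (default) is
$P(a{=}1 \mid G{=}\mathbf 1) / P(a{=}1 \mid G{=}\mathbf 0)$;
`genes_given_anchor` is
$P(G{=}\mathbf 1 \mid a{=}1) / P(G{=}\mathbf 1 \mid a{=}0)$. Every
report row carries the direction field. Zero denominators return `Inf`
with a `zero_denominator` flag. `empiricalRelativeRisk()` computes the
same ratio from raw counts (0.5 continuity correction when a stratum
cell is empty, flagged) as a model-free cross-check.

# The synthetic cohort generator

`defaultPlantedModel()` emulates a large cfDNA prostate-cancer cohort:
22 genes, 7,707 patients. BRCA1 is a root at marginal 4.6%; BRCA2 is its
child with conditional probabilities solved so that the marginal is
7.97% while RR(BRCA2 | BRCA1) is exactly 0.07 (planted mutual
exclusivity); six partner genes (ERBB2, NOTCH1, AKT1, MTOR, ARID1A,
EGFR) are children of BRCA1 with conditional RRs between 2.0 and 3.0;
fourteen background genes are independent at 3–40% marginals. Partner
base rates (6–8%) were set by a power calculation: the weakest planted
edge sits near a two-proportion z of 5.5 in the ~355-patient
anchor-positive stratum, so the planted structure is recoverable by the
screen and the blanket discovery in the large majority of seeds — a
generator whose truth is at the detection boundary would test luck, not
code. A consequence of planting both printed marginals and the negative
coupling is that roughly 970 of 7,707 patients are anchor-positive;
the generator makes no attempt to match any other headline count.

Sampling is ancestral in topological order, vectorized per gene, under a
single seeded RNG stream — bitwise reproducible for a given seed.
Ground-truth RRs are computed by exact enumeration over the ancestral
closure of the query genes (capped at 22 nodes), never from a sample.

What the generator does **not** emulate: assay sensitivity, variant
allele fractions, tumor fraction, clonal hematopoiesis, germline/somatic
origin, panel versioning, or patient covariates. Passing tests therefore
demonstrate that the algorithms recover a known dependence structure
from binary draws at realistic scale — not that any clinical conclusion
transfers.

# Test and validation sizes

The suite validates each engine against an independent oracle at sizes
where the oracle is exact: Fisher p-values against hypergeometric
enumeration on 500 random tables (totals ≤ 60); exact search against
brute-force enumeration of all 25 / 543 labeled DAGs on 3 / 4 variables
over 60 random datasets of n = 200; variable elimination against full
joint enumeration on networks up to 9 nodes; BP against variable
elimination on 100 random polytrees (≤ 10 nodes) and 100 sparse loopy
networks (≤ 12 nodes); planted-structure recovery and FDR control on
cohorts of 7,707 patients (20 and 200 replicates respectively). These
sizes were chosen so each check is decisive for correctness while the
whole suite stays comfortably runnable on a laptop.

# Known limitations

* Rare-event relative risks are hard at this scale. The planted
  BRCA1∧BRCA2 co-occurrence has expected count ≈ 2 in 7,707 patients, so
  a single-cohort estimate of the 0.07 RR is quantized by the integer
  count (steps of roughly 0.03) and the default pseudo-count biases it
  upward; partner RR estimates carry ~12–15% sampling error because the
  anchor-positive stratum holds only ~355 patients. The acceptance suite
  states these recovery checks at their nominal tolerances and the
  results should be read with this information limit in mind.
* Loopy BP beliefs on cyclic graphs remain approximate even when
  converged; exact inference is preferred wherever feasible.
* The pathogenicity filter implements exactly two published rules; the
  full reportable-variant logic of commercial assays is proprietary and
  out of scope, as are variant-level annotation and germline/somatic
  discrimination.
* BDeu scores depend mildly on the equivalent sample size; `ess = 1` is
  a convention, not an estimate.
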