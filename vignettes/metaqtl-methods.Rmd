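---
title: "Meta-QTL inference for maize grain dehydration traits: models and methods"
author: "maizeMQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizeMQTL)
```

# The problem

Linkage-mapping studies of maize grain drying rate (GDR) and grain water
content (GWC) disagree on maps, marker systems, population types and the
amount of detail they publish. A QTL may come with a peak and a 95%
confidence interval on its own study map, with only two flanking marker
names, with only an $R^2$ and a population size, or — for SNP-based
studies — with physical (bp) coordinates and no genetic map at all.
Meta-QTL analysis places all of them on one consensus genetic map and asks,
per linkage group, how many distinct underlying loci the evidence supports
and where they are. This vignette documents the models, the numerical
choices and the limits of what the test suite demonstrates.

# Confidence-interval imputation

When a study reports no CI, the expected 95% CI width (cM) is estimated
from the mapping-population size $N$ and the fraction of phenotypic
variance explained $R^2$:

$$\mathrm{CI} = \frac{530}{N R^2} \quad \text{(backcross / F2-derived)},
\qquad
\mathrm{CI} = \frac{163}{N R^2} \quad \text{(RIL / DH)} .$$

The two constants are established empirical calibrations for the two
population families; we do not re-derive them. Testcross and advanced
intercross generations (F$_{2:3}$, F$_{3:4}$) are assigned to the
F2-derived family, doubled haploids to the fully inbred family — both
assignments are logged, since the boundary cases are genuinely ambiguous
in the literature. $R^2$ values supplied as percentages (> 1) are
rescaled to fractions with a warning. Missing LOD scores take the
conventional support value 2.5; the LOD is carried but does not enter the
mixture likelihood.

A 95% CI is converted to a standard deviation as
$\sigma = \mathrm{CI}/3.92$, i.e. treating the interval as
$\pm 1.96\sigma$ of a normal positional error. The divisor is a modelling
choice (nothing in the inputs fixes it); any alternative constant would
rescale all $\sigma_i$ jointly and leave the clustering nearly unchanged,
since only relative precisions weight the fit.

# Consensus map construction

The reference map's cM scale is authoritative: reference markers keep
their positions exactly, and each study map is merged independently
against the reference (star topology), so the result does not depend on
the order in which studies are supplied.

Where the order of shared markers conflicts between a study and the
reference, we discard the fewest markers possible: the retained set is the
longest increasing subsequence (LIS) of the study's marker sequence
indexed by reference rank. Among equally long solutions the
lexicographically smallest reference-index sequence is chosen, which makes
the operation deterministic; a brute-force subset search in the test suite
confirms maximality on all instances up to nine shared markers.

Study-only markers are placed by homothetic interpolation between their
nearest flanking retained shared markers; beyond the terminal shared
markers the nearest interval's scaling ratio is extended and the marker is
flagged `extrapolated`. Dropping such markers instead would silently lose
QTL flanks, which is why extrapolation is allowed but bounded (below).

# QTL projection

A genetic position $x$ with flanking shared markers at $M_1 < M_2$ on the
source map and $M_1', M_2'$ on the consensus projects to

$$x' = M_1' + (x - M_1)\,\frac{M_2' - M_1'}{M_2 - M_1}.$$

Peak and both CI endpoints are projected independently, each through its
own flanking interval (piecewise), rather than scaling the CI width by the
peak interval's ratio; the two choices differ only where the local
expansion ratio changes across the CI. Four provenance classes are
tracked: `both_flanks`, `formula_only` (CI imputed around a projected
peak), `one_flank_plus_formula` (one locatable flank plus the imputed
width; the peak is placed at the CI midpoint, the symmetric choice, since
the source peak is unknown), and `physical_converted` (bp endpoints
interpolated to cM through bp-monotone anchors). Projection beyond the
terminal shared markers is accepted up to 20% of the group length
(configurable) and refused otherwise — unbounded extrapolation from a
terminal interval ratio is statistically meaningless. Every discarded QTL
carries an explicit reason, and the pipeline asserts that each input QTL
ends up in exactly one of {projected, discarded}.

# The mixture model and model selection

Projected peaks $x_i$ on one linkage group follow, under $K$ true loci,

$$x_i \sim \sum_{k=1}^{K} \pi_k\, \mathcal N(\mu_k, \sigma_i^2),$$

with the per-QTL variances fixed at their CI-derived values — a
heteroscedastic mixture in which precise studies pull harder on the
component means. EM updates are closed-form: responsibilities weight an
inverse-variance mean for each $\mu_k$. For $K=1$ the exact closed form
$\hat\mu = \sum x_i/\sigma_i^2 \big/ \sum 1/\sigma_i^2$ is returned
directly.

**Initialisation and determinism.** EM is restarted from the K-quantiles
of the sorted positions, eight jittered starts drawn from a generator
seeded by the sorted data (so results are invariant to input order and to
the caller's RNG state), and — for $n \le 10$ — from every contiguous
partition of the sorted positions. The last family matters: optima of a
1-D mixture under hard assignment are contiguous in the sorted data, so
partition starts make the small-$n$ search effectively exhaustive; the
test suite verifies agreement with an independently coded exhaustive
search on 500 random instances to $10^{-6}$ in log-likelihood. All starts
are screened with a short EM and the best three polished to
$|\Delta \log L| < 10^{-8}$ (500-iteration cap); proportions are floored
at $10^{-6}$.

**Choosing K.** We fit $K = 1, \dots, \min(10, n)$ and minimise
$\mathrm{AIC} = -2\log L + 2(2K-1)$, the standard free-parameter count
($K$ means, $K-1$ proportions); exact ties go to the smaller $K$. Each
QTL is then hard-assigned to its maximum-responsibility component (ties to
the left), and components left empty are dropped. Per MQTL, the position
is the inverse-variance weighted member mean, the standard error
$\mathrm{se} = (\sum 1/\sigma_i^2)^{-1/2}$, the 95% CI
$\pm 1.96\,\mathrm{se}$ — always at most as wide as the narrowest member
CI — and the PVE is the arithmetic mean of member $R^2$ (a reporting
convention; no principled pooling rule exists for heterogeneous designs).
MQTLs are named `m{Trait}{group}-{rank}` before the support filter, so
filtered tables keep visible numbering gaps instead of renumbering.
Finally, MQTLs whose members come from fewer than two distinct
experiments are removed from the final candidate set.

**A known property of plain AIC here.** With the 2-point-per-parameter
penalty, adding a spurious component needs only $\Delta 2\log L > 4$, and
mixture likelihood-ratio statistics are heavier-tailed than $\chi^2$; in
our recovery benchmark the true $K$ is selected in roughly 90% of
replicates, with essentially all misses being a single extra component
that splits one true cluster. A heavier penalty (AIC3 or BIC) suppresses
these splits, but the package deliberately implements plain AIC minimum as
its selection rule; the penalty is exposed for sensitivity analysis rather
than changed by default.

# Physical anchoring and genes

Genetic positions interpolate to bp between the nearest flanking anchor
markers, $p = p_1 + (p_2-p_1)(g-g_1)/(g_2-g_1)$, rounded to integer bp
(an exact-value field is kept for round-trip checks, which pass at machine
precision). Legacy-map anchors occasionally invert bp order relative to
the modern assembly; the minimal set of offending anchors is excluded by
the same LIS machinery before interpolating, with a warning. Interval
endpoints that still invert are swapped so that start ≤ end.

Candidate genes are all annotation features overlapping the MQTL's
physical interval by ≥ 1 bp — the inclusive convention, configurable, in
the absence of any documented containment rule. GO enrichment is the
one-sided hypergeometric upper tail at raw $P < 0.01$ with no
multiple-testing correction, matching common web-tool practice for this
analysis; a Benjamini–Hochberg switch exists but is off by default, so
enrichment lists should be read as screening output, not inference.
Expression profiles over 0–38 days after pollination are divided by their
maximum FPKM; a gene is called expressed when its peak FPKM ≥ 1, and a
developmental window (before 10 DAP / 10–30 DAP / after 30 DAP) is called
high when its mean normalised value is ≥ 0.5. Both thresholds are
explicit defaults — the source classifications they emulate never defined
them — so window-category counts are reproducible only conditional on
these choices.

# The synthetic-data generator

`simulationScenario()` fixes every knob of a simulated study collection
and carries its planted truth. Defaults target the parameter-recovery
regime: per linkage group, 2–4 true MQTLs separated by at least five times
the largest per-QTL $\sigma$, each supported by ≥ 4 member QTLs with
$\sigma \in [1, 3]$ cM. `paperScenario()` is a preset at published-study
scale: 10 linkage groups, 25 experiments of mixed kinds (14 with full
study maps, 9 flank-only, 2 SNP/physical), 282 QTLs split 87 GDR / 195
GWC, $\sigma$ up to 40 cM and $R^2 \in [0.01, 0.9]$, with 35% of CIs
withheld so the imputation path is exercised. Reference maps carry a
monotone-cubic cM→bp relation (Hyman-filtered spline), guaranteeing
invertible anchoring; study maps are marker subsets with smooth
multiplicative warps of inter-marker gaps. Withheld CIs are given an
$R^2$ consistent with the population-size formula, so imputation
reconstructs the generating $\sigma$ exactly.

What the generator does *not* emulate: real inter-study map
incompatibilities beyond smooth warps and order flips, segregation
distortion, linked-QTL interference, correlated $R^2$ across environments,
and annotation errors. Passing tests therefore demonstrate algorithmic
correctness and calibration under the stated model, not robustness to
every pathology of literature data.

# Validation summary and problem sizes

The test suite validates, among others: closed-form equivalence of the
$K=1$ fit; agreement of AIC selection with exhaustive search (500 random
instances, $n \le 8$); recovery on 200 single-chromosome replicates
(true-K selection rate ≈ 0.9, 95% CI coverage ≈ 0.95, mean absolute
position error below the reported standard error); exactness of the
imputation formulas and of the genetic↔physical round trip; and
determinism of every generator and pipeline output under a fixed seed.
These sizes keep the whole suite in a few minutes on one core while
leaving the Monte-Carlo error on the recovery rates near two percentage
points — worth remembering when comparing a single run against the
nominal thresholds.

# Known limitations

- The consensus map never re-estimates marker positions (no weighted
  least-squares map merging); the reference scale is trusted as given.
- PVE pooling by arithmetic mean ignores population size and design.
- Plain AIC-minimum occasionally overfits by one component (above).
- One-flank completion places the peak at the CI midpoint; if the true
  peak hugs the known flank the reported position is biased inward.
- Hypergeometric enrichment treats genes as exchangeable units; gene
  length and interval size biases are not modelled.
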