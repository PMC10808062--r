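---
title: "Methods: measuring the depth of sequence constraint in multispecies alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the depth of sequence constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(constraintdepth)
```

## The problem

A genomic element that tolerates no substitutions across a clade of species
is, by inference, under purifying selection. How *deep* that constraint
reaches in the phylogeny — only across primates (roughly the last 65 My),
across all placental mammals (~100 My), or out to distant vertebrates
(160–400 My) — dates the origin of the element's function. Detecting
constraint that is *specific to primates* is statistically hard: the branch
length separating primate species is a small fraction of the mammalian
total, so the absence of change may simply reflect the short time available
for mutations to arise. This package implements the full inferential chain
for that problem at desk scale, paired with a generator that plants known
constraint so every stage can be checked against ground truth.

## The model

**Neutral background.** Sequence evolution is modeled as a reversible
continuous-time Markov chain on {A,C,G,T}: rate matrix
$Q_{ij} = s_{ij}\pi_j$ ($i \ne j$), symmetric exchangeabilities $s_{ij}$,
equilibrium frequencies $\pi$, rows summing to zero, normalized so the
expected substitution rate at stationarity is one. All rate variation is
carried by branch lengths (from the input Newick) and scale factors, which
makes the parameterization identifiable. Transition kernels
$P(t) = e^{Q\rho t}$ come from the symmetric eigendecomposition of
$\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}$, which reversibility
guarantees has a real spectrum.

`fit_neutral_model()` fits $s$, $\pi$ and one global branch-length
multiplier to designated neutral columns by an EM-style scheme: $\pi$ is set
from observed symbol frequencies (its expected sufficient statistic at
stationarity, with a unit pseudocount), and each outer iteration runs a
short bounded quasi-Newton step over the log exchangeabilities and log tree
scale. The log-likelihood trace is monotone by construction (a step that
fails to improve is rejected), convergence is declared below an absolute
improvement of `1e-6`, and non-convergence after 500 iterations is reported
via a flag rather than an error. Per-branch re-estimation of lengths is
deliberately out of scope: the input phylogeny is treated as a fixed guide
tree, and only the global scaling is free.

**Likelihood engine.** Column likelihoods use Felsenstein pruning,
vectorized across columns with per-column rescaling, so alignments with
hundreds of tips do not underflow. Both `-` and `N` are treated as missing
data and marginalized (a partial-likelihood vector of ones); they remain
distinguished in storage because the relaxed ultraconserved-element scan
counts them but the strict scan does not. The hot path is a small compiled
kernel; a pure-R implementation of the identical recursion is retained and
the two are cross-checked in the tests, alongside a brute-force oracle that
enumerates internal-node states on ≤5-tip trees.

**Constraint and acceleration scores.** For a base or an element,
`phylop_site()` / `phylop_element()` test $H_0\!: \rho = 1$ against
$H_1\!: \rho \ge 0$ free, where $\rho$ scales the branch lengths of the
target clade (the subtree plus its stem — the same edge set the simulator
scales, so planted and tested signals coincide). The MLE $\hat\rho$ comes
from a deterministic golden-section search on $[10^{-4}, 20]$ (tolerance
$10^{-4}$); element tests share one $\rho$ across all columns of the
element, which is where the power gain over per-base tests comes from. The
p-value is $P(\chi^2_1 \ge \mathrm{LRT})$ and the signed score is
$-\log_{10} p$, positive when $\hat\rho < 1$ (constraint), negative when
$\hat\rho > 1$ (acceleration). A score above 1.3 therefore corresponds to
$p < 0.05$.

Two genuinely open choices are resolved as follows and validated by
simulation rather than by matching an external implementation: the null is
a plain $\chi^2_1$ (no 50:50 boundary mixture — $\rho$ is interior under the
free-scaling alternative), and element tests share one $\rho$ rather than
averaging per-site scores. Null calibration is verified empirically: on 500
simulated neutral elements the p-values are uniform (KS test) and the 5%
type-I error rate is within binomial tolerance.

**Conserved-element segmentation.** `phastcons_segment()` runs a two-state
phylo-HMM along the reference: the neutral state emits columns under the
neutral model, the conserved state under the same model with every branch
scaled by `rho` (default 0.31). Transitions derive from an expected
conserved length $L$ (default 45 bp; exit rate $\mu = 1/L$) and a prior
coverage $\gamma$ (default 0.3; entry rate $\nu = \gamma\mu/(1-\gamma)$),
so the chain's stationary conserved fraction is exactly $\gamma$. Discrete
elements are maximal conserved runs of the Viterbi path (posterior-threshold
decoding is available via `decode = "posterior"`); per-base posteriors come
from forward–backward in log space, and the forward and backward total
likelihoods are required to agree to $10^{-8}$ in the tests. Coverage gaps
restart the chain.

**Multiple testing and depth classification.** `storey_qvalues()` estimates
the null proportion at a single fixed $\lambda = 0.5$ (no spline smoothing;
deterministic and testable), with a $+1$ safeguard that clamps $\pi_0$ into
$(0,1]$, and assigns step-up q-values; forcing $\pi_0 = 1$ reproduces
Benjamini–Hochberg exactly, which the tests assert against `p.adjust`.
`classify_depth()` then applies the nested exclusivity ladder at a 5% FDR:
significant in primates only → primate (~65 Ma); primates and mammals but
not vertebrates → mammal (~100 Ma); all three → vertebrate (160–400 Ma);
none, without conserved-segment overlap → unconstrained; none, but
overlapping a conserved segment → excluded as ambiguous (such elements mix
recent and deep constraint). Non-nested patterns (e.g. mammal-significant
but not primate-significant) are contradictory evidence and are also
excluded — the ladder is nested by design, so there is no "mammal-only"
category.

A subtlety that matters for correctness: the mammal- and vertebrate-depth
tests must not include the primate branch, or a purely primate signal leaks
into the deeper tests and promotes the element up the ladder. The pipeline
therefore scores depth on disjoint clades — primates; non-primate mammals;
the outgroup — emulating background models built after excluding the
primate branch.

## Synthetic data: what it emulates, and what it does not

`simulate_alignment()` draws a root sequence from $\pi$ and evolves it edge
by edge; inside planted elements the clade's branches are scaled by the
element's $\rho$ ($\rho = 0$ freezes the clade at its ancestral state).
Missing data is injected per (species, column) as `N`, i.i.d. by default or
in geometric blocks to emulate assembly gaps. Planted invariant intervals
model ultraconserved elements. The default desk-scale world
(`demo_tree()`) is a 24-tip primate clade nested in a 40-tip mammal tree
plus 8 outgroup tips, with subtree totals of 1.6 / 1.6 / 1.2 expected
substitutions per site — chosen once as a realistic miniature of a dense
primate alignment inside a mammal alignment, and small enough that the
end-to-end suite runs in minutes. `primate_tree()` provides a 239-tip,
4-substitutions-per-site smoke tree for per-column behavior at realistic
species density; per-column tests (directional scoring, $\rho$ recovery,
segmentation of a planted 60-bp element) run there because single-column
information on a 48-tip tree is materially lower. On the 48-tip tree the
segmentation example recovers the planted element in every replicate but
emits an extra 5–15 bp spurious segment in ~7% of runs — expected behavior
under a 0.3-coverage prior at that density, not a defect the tests should
hide.

The generator deliberately omits: indel evolution (gaps arise only through
missingness), context-dependent mutation, selection on codon structure,
alignment error, and incomplete lineage sorting. A green suite therefore
establishes that the inferential chain is correct under its own model
assumptions — not that those assumptions hold for any particular real
alignment.

`simulate_pip_table()` emulates the two-tail structure of fine-mapped
variant sets: causal variants (2% by default) fall in the annotation at
`causal_enrichment` times the 10% background rate, with PIPs drawn from
Beta(5, 1.2) (mass above 0.5) versus Beta(0.08, 4) (mass below 0.01) for
non-causal variants. Because the high tail is not perfectly pure, the
measured enrichment slightly attenuates the planted ratio (≈4.6 for a
planted 5), which is the behavior of the statistic, not a generator bug.
`simulate_footprints()` plants the length-detection bias: motifs have
Gaussian length preferences, so motif identity correlates with footprint
length, and mammal-constraint calls depend on length through a logistic
confounder. An unbinned per-motif odds ratio is then biased; splitting
footprints into 10 equal-count length bins (global bins over the footprint
universe, with inverse-ECDF breaks computed by index to avoid quantile
floating-point wobble) and pooling per-bin Woolf log odds ratios
(Haldane–Anscombe 0.5 on zero cells) by inverse-variance fixed-effects
meta-analysis removes the bias — asserted as a property in the tests.

## Numerical and policy choices

* Coordinates are 0-based half-open everywhere internally; conversions
  happen only at I/O boundaries (BED is native; a 1-based inclusive TSV
  dialect is converted on read).
* A species absent from a MAF block is `N` (no alignment), never `-`
  (an observed deletion).
* $\rho$ search bounds $[10^{-4}, 20]$ cover biologically plausible
  scalings; a flat likelihood returns $\hat\rho = 1$ with a flag. Columns
  informative in fewer than 3 clade species are scored but flagged
  `low-coverage`; all-missing targets return $p = 1$, score 0,
  `uninformative`.
* The enrichment statistic compares strict tails ($\mathrm{PIP} > 0.5$ vs
  $< 0.01$); variants between the thresholds belong to neither group.
  Confidence intervals and p-values are Fisher's exact test on the 2×2
  table.
* The residual assembly error rate is reported as the intercept of the
  mismatch-on-heterozygosity OLS fit — the mismatch rate extrapolated to
  zero heterozygosity. The alternative reading (mean residual at mean
  heterozygosity) equals the fitted mean and would not isolate the
  heterozygosity-free component.
* The reporter-assay correlation truncates constraint scores below zero
  (negative values indicate acceleration, not effect magnitude) and uses
  the absolute per-position mean effect; the sign convention is exposed via
  `use_absolute`.
* Storey's $\lambda$ is fixed at 0.5 and exposed; FDR is controlled per
  clade per element class, mirroring per-annotation test batches.
* Strict ultraconserved columns tolerate no missing species; the relaxed
  scan tolerates $\lfloor 0.01 \cdot n \rfloor$ (2 of 239). An all-missing
  column is never conserved. Runs never cross coverage gaps.

## Known limitations

Branch lengths are fixed up to a global scale during neutral fitting;
per-branch re-estimation, rate-category (gamma) models, codon models and
ancestral reconstruction are out of scope. The segmentation HMM has fixed
transition parameters (as in standard practice for conserved-element
calling); they are not estimated from data. Genome-scale throughput is a
non-goal — the performance contract is that the full simulated pipeline
(~25 kb, 48 tips, three clade scans) runs in well under a minute per
replicate on one CPU.
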