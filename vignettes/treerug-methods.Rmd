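---
title: "Diagnosing rugged phylodynamic tree landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing rugged phylodynamic tree landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treerug)
```

## The problem

Bayesian phylodynamic inference integrates over dated phylogenies of
heterochronous pathogen sequences by MCMC. Because such datasets combine many
taxa with very little genetic signal, the posterior over topologies is
diffuse and often **multimodal**: a few sequences are supported at two or
more attachment points several nodes apart, each choice defining a "peak" of
comparable posterior density. The intermediate topologies along the
NNI path between two attachments are genuinely worse than either endpoint
(a valley), and the single SPR move that would hop the valley directly is
proposed with probability inversely proportional to roughly the square of the
taxon count — so chains either sit on different peaks (nonconvergence) or
commute rarely (poor mixing). `treerug` implements the diagnostic workflow
for this regime: quantify sampling at the tree, clade, site and branch level;
visualize the landscape; attribute problems to individual tips; and verify
repairs by pruning those tips from the sampled trees.

Everything operates on **rooted clades** (the tip set below an internal
node), not unrooted splits: time trees are rooted objects and clade-level
quantities (tMRCA, subtending-branch rate) are the estimands of interest.
Topology identity is clade-set equality; a binary rooted tree on $n$ tips has
exactly $n-2$ nontrivial clades (singletons and the full set are excluded
everywhere — they occur in every tree and carry no information; including
them would only shrink ASDCF toward zero).

## Diagnostics

**ESS.** For a series $x_1,\dots,x_N$ the effective sample size is
$N / (1 + 2\sum_k \hat\rho_k)$ with empirical autocorrelations summed by the
initial-positive-sequence rule: summation stops before the first lag pair
$(2k, 2k+1)$ whose autocorrelations sum to $\le 0$, with a maximum lag of
$\min(N-1, 2000)$. The estimate is clipped to $[1, N]$. This variant is
validated against analytic limits rather than bit-matched to any particular
tool: for i.i.d. input ESS $\approx N$; for an AR(1) process with
autocorrelation $\rho$ the integrated autocorrelation time is
$(1+\rho)/(1-\rho)$, so at $\rho = 0.9$ ESS $\approx N/19$. A zero-variance
series has no defined ESS and is reported as *undefined* — never as a pass
or a fail.

**PSRF.** The potential scale reduction factor is the rank-normalized
split-$\hat R$: each chain is halved, the pooled sample is transformed to
normal scores $\Phi^{-1}\!\big((r - 3/8)/(S + 1/4)\big)$, and the classical
$\sqrt{((N-1)/N\,W + B/N)/W}$ is computed over the half-chains (chains are
truncated to a common length first, as one would when mixing runs of unequal
length). Two boundary cases are distinguished deliberately: a pooled-constant
input gives `NaN` (nothing to compare), while chains that are internally
constant but differ give `Inf` — between-chain variance with *zero*
within-chain variance is the most extreme nonconvergence, and mapping it to
`NaN` would hide exactly the stuck-chain pathology the diagnostic exists for.

**Clade diagnostics.** A clade's occurrence across samples is a binary
series; its ESS measures how often the chain actually revisits the decision.
SDCF is the sample SD (denominator $m-1$) of the clade's $m$ per-chain
frequencies — for two chains at frequencies 1 and 0 it is $0.7071$, the
two-chain maximum — and ASDCF is the mean SDCF over *all* observed clades
(no frequency filter by default; `min_clade_freq` exists as an option).
Cutoffs follow standard practice: ESS 200, PSRF 1.1, ASDCF 0.01 with 0.02 as
the lenient alternative, SDCF 0.1 for a nonconverging clade. Clades whose
pooled frequency is 0 or 1 are skipped for clade-ESS (no information) but
participate in ASDCF.

**Tree-level diagnostics.** The posterior over topologies has no scalar
sufficient statistic, so tree ESS/PSRF are built from distance traces:
`n_refs` (default 5, seeded) reference trees are drawn from the trace
(pseudo-ESS) or pooled chains (PSRF); for each reference the rooted-RF
distance from every sample gives a continuous series fed to `ess()` /
`psrf()`; the median (ESS) or maximum (PSRF, the pessimistic choice) over
references is reported. The exact constructions in the literature vary; this
distance-to-reference form is documented here as the package's choice and
validated by its behavior: near $N$ for diffuse i.i.d.-like sampling,
matching the peak-membership indicator's ESS for two-peak traces, $>1.1$
for chains stuck apart, $\approx 1$ for chains sampling the same mixture.

**Parsimony-score diagnostics.** The Fitch score — the minimum number of
mutations the alignment requires on a topology — is computed over IUPAC
state sets (gaps and `?`/`N` are fully missing, not a fifth state) by
bitmask intersection/union, per site. It depends only on the topology given
the alignment, so its trace is immune to noise in continuous-parameter
sampling; its ESS/PSRF (alignment-wise and per-site) are cheap,
model-independent topology diagnostics. Branch-level mutation mapping
resolves one most-parsimonious reconstruction deterministically
(ACCTRAN-style: the root takes the lexicographically smallest member of its
Fitch set, each child keeps the parent's state when compatible, else its own
smallest member), so branch counts always sum to the total. The same
machinery on a multistate location character counts parsimony dispersal
events, directed parent-to-child under the same deterministic resolution
(the direction policy is a documented choice; totals are policy-invariant
and tested against unit-cost Sankoff).

## Tree space and valley geometry

Pairwise rooted-RF distances (symmetric difference of clade sets) feed
classical MDS: double-center the squared distance matrix, eigendecompose,
scale the top eigenvectors by the square roots of their eigenvalues
(negative eigenvalues truncated to zero), and report a residual stress. This
is exact on Euclidean input, which the tests exploit. Posterior-density
overlays come in three forms: mean density per grid cell (50×50 default —
fine enough to separate peaks at desk scale, coarse enough that cells hold
multiple samples), the top fraction of samples by density (default 1%), and
density-as-z scatter data; the core returns plot-ready tables so rendering
stays optional (`autoplot()` methods supply ggplot2 figures).

`relocate_tip()` implements the rooted SPR that moves a pendant tip to a
destination branch identified by *the clade below it in the tree without the
focal tip* — a representation that stays valid on every peak. The "k nodes
apart" convention counts internal nodes strictly between the old and new
attachment points; it makes the paired facts come out right: a relocation
across k nodes changes exactly 2k clades (RF = 2k) and decomposes into
exactly k rooted NNIs, each sliding the attachment across one node (RF 2 per
step). Since one rooted NNI changes exactly one clade, RF/2 = k lower-bounds
any NNI path and the constructed path is minimal. The new attachment node is
placed at the midpoint of the feasible height interval
$[\max(h_{tip}, h_{child}),\, h_{parent}]$ — any valid height suffices for
topology-level diagnostics, and the midpoint is deterministic; a tip older
than the whole destination branch is an error. Exact rSPR distance is
provided for $\le 10$ tips by bidirectional BFS over topology classes (an
oracle for tests and small studies; large-instance rSPR is out of scope).

## Summaries, attribution, repair

The **MCC tree** is the sampled tree maximizing the summed log pooled clade
probability, ties broken by first occurrence; node heights are annotated with
the mean, median and central 95% interval of the clade's MRCA height *over
the trees containing the clade* (one of several conventions in circulation;
this one is documented and tested, and both mean and median are emitted).
Samples lacking a clade are masked in clade-variable traces, with the
presence fraction reported — present-only concatenation is a documented
choice where no standard exists.

**Tip ranking** formalizes the attribution step: a tip's score is the
maximum SDCF over its containing nontrivial clades of size at most
$\max(3, \lceil 0.1\,n\rceil)$ (the cap focuses on local attachment clades —
a wobbler disrupts many large clades, but so does everything near it), with
ties broken by the PSRF of the tip's pendant branch *rate* (when
annotations exist) and then branch *duration*. The rate tie-break is the
discriminating signal: a wobbler's pendant rate is topology-dependent, while
its bystander neighbors' rates are stable even though their durations change
when the wobbler's attachment node appears and disappears next to them.
Rate/duration series that are constant up to a relative tolerance of $10^{-9}$
are treated as constant — a duration-weighted mean of equal rates differs
from them only in the last floating-point digit, and that must not register
as discordance.

**Pruning** removes tips from every sampled tree, suppressing freed degree-2
nodes: durations add, and the merged branch's rate is the duration-weighted
mean of the merged pieces, preserving the expected number of substitutions
along the merged path. Untouched node heights are preserved exactly, so
diagnostics recomputed on pruned traces are directly comparable — an
MCMC-free assessment of sequence removal.

**Root-to-tip regression** re-roots a substitutions-scaled tree by
minimizing the RSS of distance-vs-date regression. For a root at position
$x$ along a branch, every tip distance is $d_i^0 \pm x$, so the RSS is
quadratic in $x$ and is minimized analytically per branch; the global
optimum over all branches (ties to the smallest branch index) gives the
rooting, slope (clock rate), x-intercept (origin date) and per-tip
residuals. Outliers are tips with $|$internally studentized residual$| > 3$
— the threshold is this package's choice, monotone in the cutoff; an
essentially exact fit reports no outliers rather than studentizing rounding
noise.

## The synthetic generator: what it emulates, what it does not

The generator is the package's fixture source and defines its study
conditions; it is a diagnostics test bed, not an inference engine.

* `simulate_time_tree()` draws a heterochronous constant-$N_e$ coalescent:
  lineages pairwise-coalesce at rate $1/N_e$ between sampling events.
  Default studies use $N_e = 5$ time units with tips sampled uniformly over
  5 years — tree depths of order a decade, as in the densely sampled viral
  datasets the method targets.
* `simulate_alignment()` lays a Poisson mutation process (per-site rate =
  `clock_rate`, every event a state change; JC or equal-frequency HKY with
  transition bias `kappa`) along branches and logs every event's branch —
  the truth record that parsimony mapping is tested against (parsimony
  $\le$ truth, with equality when no site is hit twice).
* `make_multimodal_trace()` defines $S$ wobbling tips; each peak is an exact
  topology class (the base tree with each wobbler at its current
  attachment), each chain an independent Markov chain over the $2^S$ peak
  combinations with per-step stay probability $p$ (default 0.98; $p=1$
  models stuck chains; chains initialize on maximally different
  combinations). Wobbler pendant rates are `base_rate` (0.002
  substitutions/site/year, a typical viral clock) on the base peak and twice
  that on the alternative — emulating the topology-dependent branch rates
  observed at problematic sequences — while all other branches keep the
  baseline. Pseudo log-densities are per-peak offsets plus small Gaussian
  noise; intermediate (valley) topologies are never emitted, mirroring
  valleys that MCMC never samples. Spec validity is enforced by
  construction: all $2^S$ peak trees must build and be pairwise distinct
  topologies, otherwise the specs are rejected as interacting.

What passing tests on this generator show: the diagnostics detect exactly
the failure mode they were designed for (discrete peaks from tip
relocations) at the stated thresholds, and the attribution/pruning loop
recovers planted wobblers. What they do not show: behavior under
within-peak topological jitter, model misspecification, rate variation
across sites, recombination, or the diffuse near-flat posteriors of real
data — on real output the diagnostics remain estimates with their own
sampling noise, and visual inspection of the MDS landscape is advised
alongside the automated flags.

## Numerical choices and problem sizes

Burn-in is a fraction of samples (CLI default 0.1), with absolute-iteration
burn-in also accepted; the retained count is
$\lceil (M - \lceil bM\rceil)/\text{thin} \rceil$. Heights are measured
before the latest tip (height 0); undated logs get relative heights.
Cross-chain statistics truncate chains to the shortest length. Reference
trees for tree-level diagnostics are drawn with a fixed default seed so
reports are reproducible; the generator derives all its randomness from one
root seed and identical seeds give byte-identical studies. Distance matrices
over large traces subsample at a deterministic even stride (not randomly),
for reproducibility. NaN diagnostics propagate as *undefined* and are
excluded from pass/fail counts.

The validation suite runs at desk scale by design: oracle equivalence uses
$\le 7$-tip trees against exhaustive enumeration and unit-cost Sankoff;
rSPR checks use $\le 10$ tips; end-to-end studies use 10–24 taxa with tens
to hundreds of samples per chain; root-to-tip recovery uses 50 replicates of
40 tips over 10 years at rate $2\times10^{-3}$ with 10,000 sites (the scale
of the viral genomes the regression is applied to — at a few hundred sites
Poisson counting noise alone exceeds the recovery band being tested). These
sizes keep the full suite under a few minutes while exercising every code
path at the regimes where the exact oracles are available.

## Known limitations

Trees must be binary (multifurcations arise only transiently during
pruning); annotated-NEXUS parsing covers the BEAST dialect (translate table,
`[&key=value]` comments before or after branch lengths, scalar values —
vector annotations are ignored); rSPR is exact only to 10 tips; the
dispersal direction policy is one deterministic most-parsimonious choice
among several; the tip-ranking heuristic assumes problems are caused by a
small number of tips and loses discrimination when chains mix well (scores
then reflect binomial noise — which is the correct answer, as nothing is
then problematic); and pseudo-densities are not model likelihoods, so
landscape overlays on synthetic studies validate plumbing and geometry, not
inference.
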