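---
title: "Models and methods behind f2binmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind f2binmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(f2binmap)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices in the
package. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The cross and the genotype model

An F2 intercross between two fully homozygous founders P1 and P2
segregates 1 (P1/P1) : 2 (heterozygous) : 1 (P2/P2) at every locus,
written AA : H : BB throughout. Along a chromosome the genotype process
of one individual is a three-state Markov chain: across an interval with
recombination fraction $r$, the transition matrix built from two
independent meioses is

$$T(r) = \begin{pmatrix}
(1-r)^2 & 2r(1-r) & r^2 \\
r(1-r) & (1-r)^2 + r^2 & r(1-r) \\
r^2 & 2r(1-r) & (1-r)^2
\end{pmatrix},$$

with stationary distribution $(\tfrac14, \tfrac12, \tfrac14)$, which is
also the chain's initial distribution. `f2_transition()` implements this;
rows sum to one for every $r$, $T(0)$ is the identity and $T(0.5)$ the
stationary kernel — properties the test suite asserts.

## Sequencing observation model

Each site in each sample is observed through `observe()`:

* read depth $k \sim \text{Poisson}(\mu)$, default $\mu = 10$;
* from a heterozygote each read carries either allele with probability
  $\tfrac12$ before error; per-read error flips the reported allele with
  probability $\varepsilon$ (two-allele model). Because the error is
  symmetric, a heterozygote still emits each allele with probability
  exactly $\tfrac12$;
* the call is heterozygous iff both alleles are seen; depth 0 and a
  `missing_rate` fraction of sites yield no call. Depth 0 and a dropped
  call deliberately collapse to the same no-call symbol.

Closed forms follow: a homozygous state produces the *wrong* homozygous
call with probability $\varepsilon^k$, a heterozygote produces a
homozygous-looking call with probability $2 \cdot (\tfrac12)^k$. Both are
verified by simulation in the tests and reused as the HMM emission model,
which keeps the corrector exactly matched to the generator.

## Genotype coding and HMM correction

`code_genotype()` codes each progeny call at a parent-unique locus over
{AA, BB, H, C, D, −}: homozygous calls are confident (AA/BB) at depth
$\ge$ `depth_threshold` (default 5, the published coding rule) and
provisional (D/C) below it.

`hmm_correct()` runs scaled forward–backward per progeny per scaffold.
Physical distance is converted to genetic distance at `cm_per_mb`
(default 1 cM/Mb, the genome-wide average implied by a ~100 cM
chromosome arm per ~100 Mb in typical small plant genomes; the simulator
uses a uniform rate, so the default is exact there), then to $r$ by
inverse Kosambi. Decisions at each locus:

* **C, D, −**: replaced by the argmax state when its posterior reaches
  `posterior_threshold` (default 0.95), otherwise set missing. This is
  deliberately conservative — a torn posterior near a recombination
  breakpoint stays missing rather than guessing the breakpoint side.
* **AA, H, BB**: kept unless the posterior support of the observed state
  falls below $1 - $ `posterior_threshold` (singleton-error removal), and
  then flipped only if the argmax clears the threshold. The asymmetry
  prevents the chain from erasing true double recombinants wholesale.

A consequence worth knowing: an isolated *confident* wrong homozygote
inside a long run (e.g. a depth-8 BB amid AA) is reassigned to **H**, not
to the flanking state, because $(\tfrac12)^k \gg \varepsilon^k$ — a
heterozygote miscall explains the evidence far better than $k$
simultaneous read errors. The exhaustive path-enumeration oracle in the
tests confirms this is the exact posterior argmax, not an artifact.

The upstream HMM literature for this task leaves its correction
parameters unstated; this module therefore defines its own fully
specified stand-in: $\varepsilon = 0.005$, 1 cM/Mb, threshold 0.95.
Posterior decoding (not Viterbi) is used so that per-locus confidence is
available for the imputation rules.

## Bin collapsing

`collapse_bins()` merges maximal runs of adjacent loci whose corrected
vectors *co-segregate*: two vectors belong to one bin when they agree in
every progeny where both are observed, and the bin's representative is
the run consensus. A missing entry never breaks a run — it carries no
information. This differs from a literal identical-vector rule in
exactly one situation: a no-call at a breakpoint-adjacent locus. Under
the literal rule that NA propagates into the representative vector and
censors precisely the recombinant progeny from adjacent-bin linkage,
which measurably shrinks the map (the conservative imputation above
concentrates NAs at breakpoints). Consensus collapsing removes that
selection bias; on error-free data (no missing entries) the two rules
coincide, and the boundary-equivalence acceptance property is unchanged.

Bins are tested against 1:2:1 by a plain chi-square (df = 2, missing
excluded); bins with $p \le$ `seg_alpha` (default 0.05) are discarded as
distorted.

## Two-point linkage and grouping

`estimate_rf()` maximizes the multinomial likelihood of the nine
two-locus genotype classes by EM; the double-heterozygote class mixes
coupling and repulsion phase, contributing $2r^2/((1-r)^2+r^2)$ expected
recombinant gametes. LOD is $\log_{10} L(\hat r) - \log_{10} L(0.5)$.
`pairwise_linkage()` evaluates all pairs at once through indicator
cross-products, so the EM runs element-wise on nine count matrices.
A grid-search oracle over $r \in \{0, 10^{-4}, \dots, 0.5\}$ backs the
estimator in the tests.

Linkage groups are connected components of the graph with edges where
LOD $\ge$ `min_lod` (8.0) **and** $\hat r \le$ `max_rf` (0.35) — the
mirrored protocol lists both thresholds without stating their combination;
AND is the conservative choice. Groups of at most `min_group_size`
(10) bins are discarded and reported, mirroring the published
small-group rule.

## Bin ordering

`order_bins()` minimizes
$S = \sum_{\text{pairs: LOD} \ge 3} \text{LOD}_{ij}\,(D_{ij} - d_{ij})^2$
where $D_{ij}$ is the map distance implied by the order (summed adjacent
Kosambi distances) and $d_{ij}$ the two-point Kosambi distance — an
explicit, testable replacement for proprietary regression-mapping
internals. The search runs greedy best-position insertion *and* a
LOD-weighted one-dimensional scaling start (classical PCoA refined by
Guttman-transform iterations), refines the better one by window-3
ripple, single-bin relocation, and 2-opt reversal, and breaks ties by
bin id; orientation is canonicalized by the terminal bin ids. The
scaling start matters: on dense groups (hundreds of bins) greedy
insertion can misplace whole terminal blocks that no sequence of local
moves repairs, while the least-squares criterion itself clearly prefers
the true order. On small instances the result is checked against
exhaustive minimization over all orders.

For distance conversion $\hat r$ is clamped at 0.49 (Kosambi diverges at
0.5); within a correctly ordered group adjacent fractions are far below
the clamp, which exists only to keep pathological pairs finite.

Two conventions copy the published arithmetic: average bin/marker
intervals divide length by *count* (not count − 1), and a gap is an
adjacent-bin interval strictly greater than 5 cM. Linkage groups are
numbered by descending marker count, since the published numbering was
arbitrary.

## Trait scan

For a binary, fully penetrant trait a single-position penetrance
likelihood suffices — the composite-interval machinery (cofactors,
10 cM windows) of general QTL scans is out of scope by design. At each
bin, and at `scan_step` (2 cM) virtual positions, the genotype class
probabilities of each progeny come from the observed bin genotype or
from flanking markers through $T(r)$. The model gives the affected
class its own phenotype probability (recessive model: the homozygous
class carrying the recessive allele vs everything else); LOD is the
log10 ratio to the single-frequency null, maximized by EM when class
weights are fractional and in closed form when they are 0/1.
$R^2 = 1 - \text{RSS}_{\text{model}}/\text{RSS}_{\text{null}}$ on the
0/1 phenotype at the peak; the support interval is the 1-LOD drop on the
peak's linkage group (the mirrored protocol reports two interval estimates without
stating a rule; 1-LOD is the field default).

`permutation_threshold()` permutes the phenotype and takes the
$1-\alpha$ quantile of the genome-wide maximum LOD (default 1,000
permutations, $\alpha = 0.05$), deterministically from its seed. When
every scan position has 0/1 weights the permutations reduce to one
matrix product over class counts; the EM path handles the general case.

`cosegregation()` reports the percentage of progeny whose marker
genotype predicts phenotype under the model, pooled over populations.
The protocol's "coefficient of determination" for PCR markers is read as
this co-segregation percentage, not a regression $R^2$ — the 94.4–100%
range and the "entirely co-segregated" phrasing fit a match proportion.

Yates-corrected chi-square (`yates_chisq()`) clamps the correction at
zero deviation, so a perfect fit scores exactly 0.

## Deletion detection

`find_zero_runs()` reports maximal runs with depth $\le$ `max_depth`
(default 0 — the evidence class here is a hard alignment gap) of length
$\ge$ `min_length` (default 1 kb) on run-length coverage profiles.
Intervals are 1-based inclusive and run length is end − start + 1; the
published fragment size is quoted to 0.1 kb, where the ±1 bp convention
is invisible. Marker-window physical spans, by contrast, use end − start,
which is the arithmetic that reproduces the published kb figure for the
trait interval. A primer pair is predicted ABSENT when either primer
site intersects a deletion (a partially deleted annealing site cannot
prime); genes fully inside a call are lost, boundary-overlapping ones
truncated, abutting ones unaffected.

## The synthetic generator: what it does and does not emulate

`sim_config()` defaults state the emulated world: 120 progeny, 10x mean
depth, per-read error 0.005, parent-unique loci with ~10.5% originating
from P1 (the published ratio — the determinate parent was near-isogenic
with the reference, so few loci are unique to it), a fully penetrant
recessive determinacy locus (3:1 segregation), and an optional ~25 kb
deletion carried by a separately re-sequenced line. Missing rate
defaults to 0.05 — the real data lose far more calls to mapping
artifacts, but those losses are not depth-driven and a flat rate is the
honest desk-scale stand-in. Crossovers are Poisson per gamete with
breakpoints uniform on the genetic map: **no interference**, although
Kosambi distances downstream assume some — at the short adjacent-bin
distances that dominate map construction the two are numerically close,
and the simplification is deliberate and documented rather than hidden.
The generator also does not emulate: InDels, base-quality structure,
mapping bias, segmental duplication artifacts, segregation distortion,
or variable recombination rate (cM/bp is uniform per scaffold).

A green test on this world therefore establishes that the *algorithms*
are correct and internally consistent — not that the pipeline is robust
to reference-genome pathology, which only real data can show.

## Degenerate inputs and tie-breaks

Single-locus chains get the prior-weighted emission posterior; an
all-missing progeny row stays missing. Bins with all progeny missing are
discarded with their own reason. Pairs with fewer than two co-observed
progeny have undefined linkage and are flagged, not guessed. A constant
phenotype yields an all-zero scan and a zero permutation threshold.
Ordering ties break on bin id; argmax ties in posterior decoding take
the first state (AA < H < BB); group sizes tie-break by component index.
All randomness flows from a single integer seed per run.

## Known limitations

* The ordering search is heuristic beyond brute-force size; the tests
  bound its quality (criterion equality at small size, rank correlation
  and map-length recovery at realistic size) but global optimality on
  dense groups is not guaranteed.
* The permutation threshold's EM path is much slower than the
  closed-form path; genome-scale permutation counts with fractional
  weights are costly in pure R.
* The deletion caller assumes contiguous coverage profiles and hard
  zero coverage; noisy low-coverage data need `max_depth` raised, with
  the attendant false-positive risk.
* Map lengths inherit the variance of the realized crossover count
  (SD $\approx \sqrt{2nL}$ events around $2nL$), so a single simulated
  chromosome's estimated length scatters around its nominal genetic
  length even with perfect genotyping.
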