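---
title: "Polyploid haplotype assembly as a masked tensor factorization"
author: "tensorphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyploid haplotype assembly as a masked tensor factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorphase)
```

## The problem

A k-ploid organism carries k homologous copies of each chromosome. At the m
variant (SNP) sites, each copy is described by a haplotype: a length-m
sequence over at most four alleles, coded here as integers 0--3. Sequencing
reads sample one copy at a time, cover only a handful of SNP sites each, and
carry substitution errors, so reconstructing the k haplotypes means jointly
partitioning the reads by chromosomal origin and calling a consensus allele
per (site, haplotype) — the haplotype assembly (phasing) problem. The
standard objective is minimum error correction (MEC): find haplotypes
minimizing the number of allele calls in the reads that would have to change
for every read to be consistent with one haplotype. MEC optimization is
NP-hard, and polyploid instances (k > 2) are far harder than diploid ones:
the number of candidate phasings grows like $2^{(m-1)}(k-1)^m$ under the
all-heterozygous model alone.

## Model

Reads are one-hot encoded: allele $a \in \{0,1,2,3\}$ becomes the standard
basis vector $e_{a+1} \in \{0,1\}^4$, an uncalled entry the zero vector. The
n reads restricted to their covered sites form a sparse $n \times m \times 4$
binary tensor; its mode-1 unfolding is the $n \times 4m$ matrix
$\bar{R}$, where channel $c$ of site $j$ occupies column $(c-1)m + j$ —
the four frontal slices become four contiguous column blocks. The set
$\Omega$ of covered (read, site) fibers defines the masking operator
$\mathcal{P}_\Omega$; everything outside $\Omega$ is zero-filled.

If reads were error-free, $\bar{R}$ restricted to $\Omega$ would equal
$U \bar{V}^\top$, where $\bar{V} \in \{0,1\}^{4m \times k}$ stacks the
one-hot encodings of the k haplotypes and $U \in \{0,1\}^{n \times k}$ has
standard-basis rows indicating each read's origin. A short argument (each
wrong fiber contributes squared distance 2) turns MEC into the masked
factorization problem

$$
\mathrm{MEC} \;=\; \min_{U,\;\bar{V}}\; \tfrac12
\bigl\lVert \mathcal{P}_\Omega\!\left(\bar{R} - U\bar{V}^\top\right)
\bigr\rVert_F^2,
\qquad u_i \in \{e_1,\dots,e_k\},\; \bar{V} \in \{0,1\}^{4m\times k},
$$

which the solver relaxes by replacing the binary constraint on $\bar{V}$
with the box $[0,1]^{4m \times k}$.

## The alternating solver

`assembleHaplotypes()` alternates two updates until the relative objective
decrease falls below `tolerance` (default $10^{-6}$) or `maxIterations`
(default 500) is reached:

1. **Read reassignment.** For each read independently, $u_i$ is set to the
   basis vector minimizing the masked squared distance between the read's
   row and each column of $\bar{V}$; ties go to the lowest column index.
   Because k is small this exhaustive scan is cheap, and because $U$ has
   indicator rows every masked entry of $U\bar{V}^\top$ is just a single
   entry of $\bar{V}$, so the solver works entirely on the observed triplets
   and sparse matrix products.
2. **Projected gradient step on $\bar{V}$.** With
   $G = -\left(\mathcal{P}_\Omega(\bar{R} - U\bar{V}^\top)\right)^\top U$,
   the update is $\bar{V} \leftarrow \Pi_{[0,1]}(\bar{V} - \alpha G)$ with
   the adaptive step
   $\alpha = C\,\lVert G\rVert_F^2 / \lVert\mathcal{P}_\Omega(U G^\top)\rVert_F^2$.
   For any $C \in (0,2)$ this step cannot increase the objective, so the
   recorded trace is monotonically non-increasing; `C = 1`, the midpoint,
   is the default and is exposed as a parameter.

The relaxed solution is rounded site-by-site to the channel argmax (ties to
the lowest channel; an all-zero fiber, which arises exactly at sites covered
by no read, is reported uncalled).

### Starting points

The relaxed objective is nonconvex, and its landscape under short fragments
(1--3 SNPs per read is typical for paired-end data at a SNP rate of 1/300)
is dominated by near-degenerate optima that differ by per-site relabelings
of the haplotype columns. The choice of starting point therefore decides the
result, and the package ships two:

* `init = "spectral"` (`initializeSolver()`): the rank-k SVD of the
  zero-filled $\bar{R}$ rescaled by the inverse observed-fiber fraction,
  computed by seeded power iteration, with
  $\bar{V}_0 = \Pi_{[0,1]}(W_k \Sigma_k^{1/2})$ from the top-k right
  singular factors. Each singular vector's sign is first fixed so its sum is
  positive — without this canonicalization the clamp annihilates
  mostly-negative columns. This is the classical matrix-completion start; in
  our experiments it is reliable only when reads cover many SNPs each
  (e.g. full-length fragments), because the right singular vectors mix the
  haplotype columns by an unknown rotation that clamping cannot undo.
* `init = "guided"` (default; `seedHaplotypes()`): a combinatorial seed
  built directly from the reads, then handed to the same alternation:
  1. *Genotypes.* Per site, the allele multiplicity vector maximizing a
     multinomial likelihood in which a read drawn from a copy with allele b
     reports allele a with probability
     $(\mathrm{mult}_a/k)(1-\epsilon) + ((k-\mathrm{mult}_a)/k)\epsilon/3$.
     The error floor $\epsilon = 0.02$ lets a rarely-observed allele be
     attributed to sequencing error rather than forced into the genotype.
     Sites whose best and second-best compositions are within 3 log-likelihood
     units are flagged ambiguous and may be re-decided later with phase
     information.
  2. *Phase.* Sites are decided one at a time in Prim order: always the
     undecided site with the most read-link observations into the already
     decided region (ties broken randomly under the run's seed). The site's
     multiset-to-column assignment is chosen to minimize the accumulated
     per-read mismatch count, each read scored under its best column.
     Deciding sites by linkage strength rather than genomic order avoids
     anchoring early sites before any linking evidence exists.
  3. *Repair.* Site-wise ICM sweeps (re-deciding each site's column
     permutation, and its multiplicities where flagged ambiguous), a greedy
     left-to-right suffix-permutation pass that removes switch errors, and a
     segment-relabeling local search that finds contiguous runs of sites
     whose joint column permutation lowers MEC — the move class that single
     site flips and suffix switches both miss. The segment sweep is a
     compiled kernel and is run, together with the alternation, on the best
     of `restarts` (default 2) independently seeded light seeds, selected by
     MEC.

  The published account of this algorithm family specifies the spectral
  start only in outline; the guided seed is this package's own answer to
  that gap, and everything downstream of the starting point is the
  alternation described above.

Sites covered exclusively by single-SNP reads are linked to nothing: their
column order is unidentifiable no matter the optimizer, so by default
(`maskUnlinked = TRUE`) they are reported uncalled rather than in an
arbitrary order. An optional `splitBlocks = TRUE` partitions reads into
connectivity components and assembles each independently, with per-block
arbitrary column order — with long-insert libraries the fragment graph is
almost always one block, so the default is off.

## Scoring

`mecScore()` implements the MEC sum with the standard allele dissimilarity:
two calls disagree only if both are called and differ, so uncalled haplotype
entries never count as errors. `cprScore()` computes the correct phasing
rate, $\mathrm{CPR} = 1 - \min_{\mathcal{M}} \mathrm{cost}(\mathcal{M})/(mk)$
over one-to-one mappings $\mathcal{M}$ between estimated and true columns —
exhaustive over the $k!$ permutations for $k \le 8$, and by an $O(k^3)$
shortest-augmenting-path assignment solver beyond that (the two routes are
cross-checked in the tests). Because the dissimilarity treats uncalled
estimate entries as agreement, CPR is an *optimistic* measure when coverage
(or linkage) is incomplete; this follows the metric's definition literally
and is worth remembering when comparing runs with different amounts of
missing data. The CLI reports CPR as a percentage.

## The read simulator

`simulateHaplotypes()` + `simulateReads()` emulate the evaluation protocol
used throughout the package's own checks:

* SNP positions with geometric inter-SNP gaps, mean `1/snpRate` = 300 bp;
* biallelic mode: two distinct allele codes per site, each copy carrying one
  of them, redrawn until at least two copies differ (so every site is a real
  SNP); polyallelic mode: uniform draws over the four codes with
  monomorphic sites redrawn;
* paired-end reads: one haplotype chosen uniformly per pair, start uniform
  over the genome, two mates of `readLength` (default 250 bp) separated by a
  gap drawn from Normal(`insertMean` = 10 kb, 10% sd), truncated at zero; a
  pair's fragment is the set of SNPs inside either mate, and pairs covering
  no SNP are discarded;
* uniform substitution noise: each covered allele call is replaced, with
  probability `errorRate`, by one of the other three codes chosen uniformly;
  flips are recorded as `plantedErrors` for validation;
* pairs are generated until the realized SNP coverage reaches the target.
  `coverage` is interpreted per haplotype by default (mean covering reads
  per (site, copy) pair); `coverageMode = "total"` gives the alternative
  reading, since published per-ploidy coverage figures are ambiguous between
  the two.

The simulator does **not** model platform-specific error profiles, indels or
structural variation, genotyping bias, or base-level sequence outside SNP
sites. Passing tests on these simulations therefore demonstrates correct
behaviour under uniform substitution noise and idealized read geometry, not
performance on any particular instrument's data.

## Theory diagnostics

`incoherence()` and `conditionNumber()` compute $\mu$ (the smallest value
satisfying the row-energy bounds on the top-k singular factors) and
$\kappa = \sigma_1/\sigma_k$, via the same seeded power-iteration SVD as the
solver. `coverageCondition()`, `errorBound()`, `mecBound()` and
`cprBound()` evaluate the sufficient-coverage condition

$$C_{\mathrm{snp}} > \max\left\{C_0\sqrt[3]{\mu^4 k^{14}\kappa^{12}C_{\mathrm{seq}}},\;
\frac{p_e k^2 \kappa^6}{2C_1}\right\}$$

and the associated guarantees
$\lVert\bar{M}-U^*\bar{V}^{*\top}\rVert_F^2 \le C_1\kappa^4 p_e k m / (2C_{\mathrm{snp}})$,
$\mathbb{E}[\mathrm{MEC}] \le 2p_e(C_{\mathrm{seq}}m + \kappa^4 C_1 k)$ and
$\mathbb{E}[\mathrm{CPR}] \ge 1 - C_1\kappa^4 p_e k/(nC_{\mathrm{snp}})$
(clamped to $[0,1]$). The constants $C_0, C_1$ are genuinely unspecified in
the underlying analysis; they default to 1 and the outputs are diagnostics
evaluated on concrete instances, not certified guarantees. $\mu$ and
$\kappa$ can be computed either from the zero-filled observed matrix or from
a supplied ground-truth signal matrix; the bound functions take them as
plain arguments so either route works.

## Numerical and design choices

* Internally all read/site indices are 1-based (the R convention); the
  fragment file format keeps its 1-based starts, so the on-disk contract is
  unchanged.
* Stopping: relative decrease $(f_t - f_{t+1})/\max(f_t, 1) < 10^{-6}$ or
  500 iterations; the descent property makes the trace monotone to within
  $10^{-9}$.
* All tie-breaks (read assignment, channel rounding, assignment mapping)
  go to the lowest index, so a fixed seed reproduces runs bit-identically.
* A haplotype column that receives no reads keeps its current values (its
  gradient block is zero); it is reported as unanchored in verbose mode.
* Single-SNP reads are retained — they carry MEC weight even though they
  cannot inform phase.
* No genotype or all-heterozygous constraint is imposed by the solver; the
  guided seed estimates genotypes only to build its starting point, and the
  subsequent alternation is free to overrule them.
* Degenerate inputs (empty fragment sets, out-of-range sites or alleles,
  k exceeding the matrix rank) are rejected with informative errors.

## Problem sizes used in the checks

The package's own validation uses scaled simulation sizes chosen to keep a
full run on one CPU comfortable: table-style accuracy summaries use
haplotype blocks of m = 1000 with 6--10 seeds per setting, exact-recovery
checks use m = 200, property tests use reads over m ≤ 25, and the
tiny-instance oracle comparisons use n ≤ 6 reads over m ≤ 4 sites where the
MEC optimum is found by exhaustive enumeration over all binary diploid
haplotype pairs.

## Known limitations

* With short fragments the MEC landscape contains large label-switch blocks
  whose relabeling costs only a handful of MEC units; no MEC-driven
  optimizer can distinguish such solutions reliably, and at per-haplotype
  coverage 10 with 2x250 bp pairs a minority of seeds converge to such
  blocks. Higher coverage or longer reads removes the degeneracy — at
  coverage 20--30 the assembler reconstructs essentially perfectly.
* Biallelic tetraploid phasing from two-SNP fragments is only weakly
  identifiable: sites with a 2--2 allele split admit pairwise-consistent
  but globally wrong assignments that only three-way read evidence can
  reject, and such evidence is scarce in this read geometry. Accuracy for
  k = 4 biallelic data is accordingly lower than for diploid/triploid.
* Polyallelic genotype calling at low coverage (e.g. 5 reads per copy over
  four alleles) is the accuracy bottleneck for polyallelic tetraploids; the
  allele-frequency model used by the seed is deliberately simple.
* CPR's treatment of uncalled entries (counted as agreement) makes it
  optimistic under incomplete coverage; report it together with MEC.
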