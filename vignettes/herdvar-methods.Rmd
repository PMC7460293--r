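---
title: "Methods: pedigree and genomic diversity estimation in herdvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree and genomic diversity estimation in herdvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`herdvar` implements the estimators used to characterise genetic diversity
in closed or semi-closed studbook populations from two complementary data
sources: the pedigree and medium-density SNP genotypes. This vignette
explains each model, the tunable parameters, the synthetic-data generator
used for validation, and the numerical and design choices that were
genuinely open.

## Pedigree data model

A pedigree is a set of records (id, sire, dam, birth year, sex, origin)
stored in topological order. Both `"0"` and the empty string are accepted as
the unknown-parent token on input; `"0"` is written. Parents referenced but
never listed become implicit founders. Validation enforces unique ids,
acyclicity (the offending cycle is reported), and sex-consistent parent
usage: a known male used as dam is a hard error, while an unknown-sex animal
used in both roles (deliberate selfing in experimental designs) is only
warned about. A parent not older than its child is a warning and a flag, not
an error — real studbooks contain such rows; `strict = TRUE` drops them,
mirroring the editing step with which historical datasets are usually
prepared. Animals without a birth year stay in the pedigree but are excluded
from the completeness and generation-interval denominators (their count is
reported); no imputation of birth years is attempted.

## Pedigree statistics

**Completeness (PC).** Per birth-year cohort, the share of known parent
slots among `2 * n_born`; overall, the cohort shares averaged with weights
`n_born`. **Equivalent generations (EqGen)** is
$\sum_{\text{known ancestors}} (1/2)^k$ (k = 1 parents, 2 grandparents, …),
computed by the recursion $EqGen_i = \sum_{p}\,(1+EqGen_p)/2$ over known
parents; a brute-force path enumeration verifies it in the tests.
**Generation lengths** are mean parent ages at offspring birth over the four
gamete pathways (sire–son, sire–daughter, dam–son, dam–daughter);
unknown-sex offspring are skipped and counted.

## Probability of gene origin

Gene flow is diffused from a reference population upward: every reference
animal injects $1/|R|$, each animal passes half its mass to each known
parent, and mass reaching an unknown parent slot terminates at that animal
as a founder contribution. The expected founder contributions $p_j$ sum to
one by construction.

Ancestors (founders or not) are selected greedily by **marginal
contribution**: at each round every candidate is scored by the mass flowing
through it when the already-selected ancestors absorb flow (their parents
are treated as unknown), multiplied by the fraction of the candidate's
upward gene lineages that terminate at *unselected* founder slots. The
second factor matters: without it, mass passing through a candidate and
onward into a previously selected ancestor is counted twice, and the
recorded marginals can sum above one. With it, $\sum_k q_k \le 1$, the $q_k$
are non-increasing, and the greedy step is verified in the tests against a
literal enumeration of gene-lineage paths. Ties are broken by the higher
unblocked contribution, then lexicographic id. Selection stops when the
residual unexplained contribution falls below `tol = 1e-6`.

From the contributions: $f_e = 1/\sum_j p_j^2$, $f_a = 1/\sum_k q_k^2$,
their ratio, and `a50`, the smallest number of top ancestors whose
cumulative contribution reaches 50 % (boundary included, since the target is
a "reaches" statement). $f_a \le f_e$ is an *empirical* bottleneck property,
not an algebraic identity: on random-mating or fragmentary pedigrees the
ancestor decomposition can be marginally more even than the founder one
(ratios slightly above 1 were observed on random pedigrees). Under
popular-sire conditions — the conditions of every studbook this package
targets, and of its default simulator — the ratio sits comfortably below 1,
and that is where the property suite asserts it.

## Pedigree inbreeding and relatedness

**F_trad** is computed with the Meuwissen–Luo ancestor-tracing algorithm and
equals the diagonal of the numerator relationship matrix minus one; a
memoised pairwise-recursion oracle (Wright's rules) confirms agreement to
1e-12 on random pedigrees up to n = 200. Unknown parents contribute nothing.

**F_rec** addresses incomplete pedigrees: an animal with any unknown parent
is assigned the mean inbreeding of complete-record newborns of its birth
year, and the assignment propagates to descendants because the relationship
recursion carries the inflated diagonal (1 + F). Cohort means depend on
assigned values downstream, so the assignment is iterated to a fixed point
(`tol = 1e-6` on the maximum F change, at most 20 rounds; convergence is
flagged). On a complete pedigree F_rec equals F_trad exactly; an animal
alone in its cohort receives 0. An alternative semantics — modelling the
unknown parent as an unrelated phantom carrying the cohort-mean inbreeding —
was considered and rejected: an unrelated phantom leaves the animal's own F
at zero, which contradicts both the estimator's published description and
its observed behaviour (population-level F_rec well above F_trad in
incomplete studbooks).

**Average relatedness** AR$_i$ is the mean of row i of A over all n animals,
self term included (so two unrelated founders have AR = 0.5, not 0); it is
computed without forming A via the $A = TDT'$ decomposition — one bottom-up
pass for the column sums of T, one top-down pass — and checked against dense
row means.

**ΔF and Ne.** $\Delta F_i = 1 - (1-F_i)^{1/(EqGen_i-1)}$; animals with
EqGen ≤ 1 carry no rate information, get ΔF = 0, are flagged, and are
excluded from group means. $N_e = 1/(2\overline{\Delta F})$, reported per
decade of birth (floor(year/10)·10) and overall; empty decades are omitted.

## Genotype QC

Markers are filtered in a fixed, recorded order: MAF (drop < 0.01, computed
on non-missing calls), call rate (drop ≤ 0.90 — the boundary itself is
dropped), exact Hardy–Weinberg test (drop p < 1e-6). The HWE test uses the
conditional (allele-count-fixed) exact distribution evaluated with a
log-scale ratio recurrence, mid-p off; the tests verify it against a direct
log-factorial evaluation. The counted allele is frozen to the sample minor
allele at read time so dosage orientation is stable across the pipeline.
QC is per-marker only; per-individual pruning, imputation and strand
handling are out of scope. Allosomes are removed by an explicit
`autosome_filter()` with configurable labels (equine default `1:31`).

## Genomic inbreeding

**F_het** compares observed and expected homozygous counts per individual
over its non-missing loci, with the finite-sample heterozygosity correction
$2\hat p(1-\hat p)\cdot 2n/(2n-1)$; monomorphic loci contribute 1 to the
expectation, so no special-casing is needed. F_het can be negative
(outbred relative to the sample) — that is informative, not an error.

**ROH detection** uses the consecutive-runs formulation: a run extends over
successive SNPs while gaps stay ≤ 1000 kb and at most one heterozygous and
one missing call accumulate (per-run totals, not sliding-window allowances);
runs never start or end on a non-homozygous call. Candidate runs are then
filtered by ≥ 15 SNPs, length ≥ 500 kb (length defined as `end_bp −
start_bp`, a declared convention) and density ≥ 1 SNP/100 kb evaluated on
the final run. Emitted runs are *maximal*: no run is contained in another
qualifying run; overlapping maximal runs can legitimately coexist. The
implementation is a two-pointer frontier scan with a bounded backward search
for the largest qualifying endpoint; it is proven equivalent, in the
acceptance suite, to a brute-force enumerator that tests every interval
against all five criteria and keeps the containment-maximal ones.

**F_roh** divides each individual's summed run length by `L_AUTO`, by
default the marker-covered span (first-to-last SNP per chromosome, summed).
Length classes use left-open/right-closed bins (0–1], (1–2], (2–4], (4–8],
(8–∞) Mb; the class table reports run counts, their share, the mean count
per carrier and the mean length.

## LD-based historical Ne

For every intra-chromosome SNP pair with separation in [0.5, 26] Mb the
squared dosage correlation (composite LD, no phasing) is averaged within 18
log-spaced distance bins. Each bin's mean distance maps to a recombination
fraction through the Haldane function at 1.24 cM/Mb (an average equine
genome-wide rate; configurable), and the Sved model is inverted:
$N_e = \frac{1}{4c}(1/r^2_{adj} - \alpha)$ at $t = 1/(2c)$ generations ago.
$r^2_{adj}$ subtracts 1/n for unphased dosage correlations (1/(2n) for
phased input; `"none"` disables the correction for analytic work — the
model then round-trips exactly, which the tests exploit). The mutation
modifier α defaults to 2.2 (Sved–Feldman) with α = 1 available for
mutation-free analyses such as gene-dropped data. Bins with non-positive
adjusted r² or Ne are dropped with a flag. Short distances inform deeper
time; the trajectory reports both scales.

## Population structure

Genotypes are one-hot encoded (three classes per locus) and factorised as
$X \approx QG$ with Q rows on the probability simplex and per-component
genotype-class probability triplets in G, by weighted multiplicative updates
(ridge 1e-8 in the denominators as the sparsity analogue). Model choice is
by held-out **masked cross-entropy**: 5 % of non-missing genotype entries
are masked per run before fitting, and the cross-entropy of the true classes
at masked cells scores the run; the best of `n_runs` restarts is kept and K
is chosen as the cross-entropy argmin (ties to the smaller K, flagged).
K = 1 is handled in closed form (marginal class frequencies), giving the
baseline entropy. The fit criterion is recorded per iteration; simplex
re-normalisation makes strict monotonicity not guaranteed, so the suite
asserts improvement over initialisation rather than per-step descent.

IBS distance is one minus the mean per-locus allele-sharing proportion
(1, 0.5, 0 for dosage differences 0, 1, 2) over loci genotyped in both
individuals. The k-NN network (default k = 10) takes each node's k nearest
neighbours (ties by id order), symmetrises, and attaches connected
components and modularity-based (Louvain) communities. Super-paramagnetic
clustering was deliberately not implemented: the network stage exists for
grouping and visualisation, and standard community detection serves that
purpose with far better-understood behaviour. Subpopulation assignment is
argmax over ancestry components (ties to the lower index, flagged); a
Q-threshold rule was considered and rejected because it leaves individuals
unassigned, which the downstream per-subpopulation analyses cannot use.

## ROH islands

Incidence counts, per SNP, the individuals with at least one run covering
its position (overlapping runs of one individual count once). Islands are
maximal runs of consecutive SNPs whose incidence fraction strictly exceeds
the threshold ("more than 60 %"/"more than 70 %" read literally), bounded at
the outermost qualifying SNPs, never spanning chromosomes. No minimum island
size is imposed by default (real islands below 100 kb are reported in
horses); floors are available. Two island sets are compared by any-overlap
(≥ 1 bp, same chromosome). BED export converts the internal 1-based
inclusive coordinates to 0-based half-open.

## The synthetic generator, and what it does and does not emulate

`simulate_pedigree()` builds ten decades (default) of records: a native
founder base (40 animals), imported founders entering in decades 4 and 6 (12
each) — episodic base enlargements as seen in real draught-horse studbooks —
and 80 newborns per decade bred from dams of the two previous decades, with
only 6 breeding sires per lineage per decade. Offspring inherit the dam's
lineage; imported stallions enter lineage L1's sire pool with probability
0.8, creating two sub-lineages with different import ancestry (one more
open, one more closed). These sizes are chosen to produce, at desk scale,
the qualitative regime of a real heavy-horse studbook: completeness ~90 %,
EqGen ~3, mean pedigree F a few percent rising over decades, f_a/f_e below
1, two detectable ancestry clusters with differing F distribution.

`gene_drop()` assigns uniquely labelled haplotypes to every founder (and to
every unknown-parent slot), recombines with Poisson crossover counts on the
Haldane map (no interference), and emits dosages on a regular 1 SNP/50 kb
grid from founder-specific alleles drawn at Beta(0.5, 0.5) frequencies
truncated to [0.05, 0.95]. True autozygosity is the genome fraction where
the two haplotype labels agree — exact, marker-free truth.

The default genome is 16 chromosomes × 50 Mb (16,000 markers). A smaller
5 × 50 Mb genome was evaluated and kept available for fast unit tests, but
at 250 Mb an individual's F_roh averages over too few independent IBD
segments, and the rank agreement between F_het and F_roh fluctuates across
simulation seeds; at ~800 Mb (about a third of the equine autosomal span)
the between-individual ranks stabilise while everything still runs in
seconds to a couple of minutes.

Not emulated: chip ascertainment and the real allele-frequency spectrum,
genotyping error, mutation, crossover interference, chromosome-specific
recombination rates, and selection on phenotypes. Consequently, passing
tests demonstrate internal consistency of the estimators and correct
recovery of pedigree-driven signal — not robustness to array artefacts or
to demographic features the simulator lacks.

## Problem sizes and runtime choices

The validation suite uses: random pedigrees up to n = 200 for the
relationship-matrix oracle (100 replicates); 300-SNP chromosomes for the
brute-force ROH oracle (50 replicates); 500 gene-dropping replicates for the
full-sib autozygosity expectation and 200 for the five-generation selfing
line; a 30-generation random-mating population of 50 for LD-Ne recovery
(estimates in the 5–15 generations-ago window are required to fall within a
factor of two of truth); two Balding–Nichols populations at Fst = 0.1
(n = 100 each, 2,000 SNPs) for ancestry recovery across five seeds; and the
default 784-animal studbook with 160 genotyped animals for the cross-method
coherence checks. The ancestry stage of the full pipeline subsamples to
4,000 evenly spaced markers — admixture-style estimation does not need the
full panel, and this keeps repeated K-scans cheap.

## Known limitations

* Dense relationship matrices are built for the recursive-F iteration
  (O(n²) memory); fine to a few thousand animals, not for a 65,000-animal
  studbook. F_trad and AR use O(n) recursions and scale much further.
* The NMF ancestry model ignores linkage between markers (as do the
  standard admixture estimators); tightly linked panels should be thinned.
* LD-based Ne inherits the Sved model's assumptions (constant-size ideal
  population per bin, unrelated sampled individuals); estimates from
  structured or recently admixed samples are biased upward.
* ROH islands are reported as intervals only; gene and QTL annotation is
  intentionally out of scope (export as BED and annotate externally).
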