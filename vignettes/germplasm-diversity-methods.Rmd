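---
title: "Methods: diversity, kinship and structure of SNP germplasm panels"
author: "maizediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, kinship and structure of SNP germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizediv)
```

`maizediv` estimates the genetic diversity and vulnerability of a
commercial germplasm panel from diploid biallelic SNP genotypes. This
vignette is the package's own account of the statistical machinery: the
models, the parameters that matter, the numerical conventions, and what
the synthetic-data validation does and does not establish.

## Data model and quality control

The central object is a `SnpPanel`: an individuals × markers matrix of
allele-B dosages (0, 1, 2, `NA`), marker metadata, and an optional group
(company or population) assignment. Allele A at each marker is the
*alphabetically first* observed allele, so the dosage coding is a pure
function of the data, never of file row order. The conventional numeric
recoding 1/2/3 is dosage + 1, with missing kept as an explicit `NA` —
never folded into a numeric code. Heterozygotes are unordered ("AG" and
"GA" are the same call). When a marker is monomorphic in a letter-call
file the unobserved partner allele is unknowable; a deterministic
placeholder (the first nucleotide alphabetically after the observed one)
keeps the two allele labels distinct.

`qcFilter()` retains exactly the markers with call rate ≥ 90% **and**
MAF ≥ 5% by default. Both thresholds are inclusive: stated minimums are
met at the boundary. MAF is computed over all individuals present in the
matrix being filtered, on non-missing allele copies; consequently a
combined hybrid + reference panel is filtered *after* marker
intersection, on the combined matrix — the defensible choice when the
combined population is itself the object of study, and the one this
package makes wherever two arrays are merged. `intersectPanels()`
re-orients dosages wherever two sources stored a marker with swapped
allele labels, and refuses markers whose allele sets cannot be
reconciled at all (e.g. A/G vs C/T).

## Diversity statistics

Per locus, with allele frequencies $p_i$ estimated from non-missing
calls:

* gene diversity $D = 1 - \sum_i p_i^2$ (for biallelic loci exactly
  $2pq$, maximum 0.5);
* $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (maximum
  0.375, always ≤ $D$);
* heterozygosity $H = Q/(P+Q+R)$ from genotype counts (P major
  homozygotes, Q heterozygotes, R minor homozygotes);
* $\mathrm{MAF} = (Q + 2R)/2(P+Q+R)$, the minor-allele count over the
  allele count, equivalently $\min(p, q)$. One typeset source of this
  formula is ambiguous about the numerator; the allele-counting form is
  the one consistent with its own symbol definitions and is what the
  package implements.

Group summaries average the per-locus values over **all** QC-retained
markers, not only those polymorphic within the group. This matters for
interpretation: a company represented by one F1 hybrid has $p \in \{0,
0.5, 1\}$ at every locus, so its mean gene diversity collapses toward
the hybrid's heterozygous fraction times 0.5, while its heterozygosity
stays high — depressed $D$ with high $H$ is the signature of a
single-hybrid group, not of inbreeding. Markers with no calls inside a
group drop out of that group's mean and the count of contributing loci
is reported.

A private allele is one whose count over non-missing calls is positive
in exactly one group. Between-group relationships are summarized by
Pearson correlation of allele-A frequency profiles (consistent
orientation, so signs cannot flip between pairs), with two-sided
p-values from the t statistic on $L-2$ degrees of freedom and
significance conventionally read at 1%; no multiple-testing correction
is applied, matching standard practice for these descriptive tables.
Pairs sharing fewer than 3 markers are refused; a zero-variance profile
yields a flagged `NA` rather than a number.

## Nei DA distance and UPGMA with bootstrap support

The distance between two frequency units is Nei's
$D_A = \frac{1}{r}\sum_{j=1}^r\bigl(1 - \sum_i \sqrt{x_{ij}
y_{ij}}\bigr)$ over the $r$ loci defined in both units. The square root
is essential — without it $d(x, x) > 0$ for any non-fixed profile, so
the "distance" is not a distance; the package defaults to the
square-root form and exposes the literal no-root variant behind
`sqrtForm = FALSE` purely for comparison with sources that typeset it
that way. Individuals are one-member frequency units: a heterozygote
contributes (0.5, 0.5), which is what makes an individual-level
dendrogram of hybrids meaningful. Missing loci are deleted pairwise and
$r$ is the per-pair shared-locus count.

`upgmaTree()` is standard unweighted average linkage with node heights
at half the merge distance (so cophenetic distances equal merge
distances). Ties are broken deterministically on the lexicographically
smallest pair of cluster representative labels (a cluster is represented
by its alphabetically first leaf), with a $10^{-15}$ comparison slack so
floating-point jitter cannot reorder exact ties; heights are passed
through a running maximum to absorb rounding, since exact UPGMA is
monotone. The suite cross-checks the implementation against
average-linkage `hclust` and `phangorn::upgma` cophenetic matrices.

Bootstrap support resamples **loci** with replacement — the standard
choice for marker-based dendrograms, and the only one that treats
individuals as fixed study units — rebuilds the tree, and scores each
internal node of the full-data tree by the percentage of replicate trees
containing the same leaf set (consistency-of-node convention, not a
majority-rule consensus). Markers are put into a canonical sorted order
before resampling so the support values are invariant to input column
order under a fixed seed. Nodes below 50% are reported by `weakNodes()`;
units beneath them are conventionally left ungrouped. The production
default is 2,000 replicates; tests and examples use fewer.

## Genomic kinship, Fst and effective size

The relationship matrix is the VanRaden-style
$G = WW' / \sum_i 2 p_i q_i$ with $W$ the dosage matrix column-centered
by $2p_i$ and allele frequencies taken from the analyzed matrix itself.
Missing cells are mean-imputed (zero after centering) rather than
pairwise-deleted, which keeps $G$ positive semi-definite (verified to
$10^{-8}$). This is the construction whose mean diagonal equals $1 + F$,
so the within-population inbreeding coefficient is estimated as
$F_{st} = \overline{\mathrm{diag}(G)} - 1$; panmictic data give values
near 0 (possibly slightly negative, reported as-is with a warning) and
fully inbred lines give values near 1 — in fact exactly 1 for a
homozygous panel with in-sample frequencies, an algebraic identity the
tests exploit.

Effective sizes follow $N_e = N/(1+F_{st})$ for the panel itself and
$N_e = N/(2F_{st})$ for the panel's parents. The unscaled forms
$1/(1+F_{st})$ and $1/(2F_{st})$ appear in some typeset sources but
cannot exceed 1 individual for the first form and are inconsistent with
effective sizes reported alongside them; they are retained behind
`mode = "as_printed"` for fidelity, with `n_scaled` the default. $N$ is
always an explicit argument — whether the parents' formula should count
hybrids or parental gametes is a judgment the caller makes, not the
package.

## Admixture model and Evanno ΔK

The admixture model: individual $i$ has ancestry proportions $q_i$ over
$K$ ancestral populations; each of the two allele copies at each marker
draws an origin $k \sim q_i$ and then an allele from the origin's
frequency $p_{kl}$. The Gibbs sampler (C++, R's RNG, hence fully
reproducible under a seed) alternates: latent origins from
$\Pr(z = k) \propto q_{ik} f(\text{allele} \mid p_{kl})$; frequencies
from their Beta($\lambda + n^1_{kl}$, $\lambda + n^0_{kl}$) conjugate
posterior; ancestries from Dirichlet($\alpha + m_{ik}$). Missing calls
are skipped. The Dirichlet parameter is **fixed** (default
$\alpha = 1$): a Metropolis update for $\alpha$ would break full
conjugacy and reproducibility for little gain at panel sizes of tens of
individuals; $\lambda$ defaults to 1 (uniform). The data
log-likelihood is recorded at every post-burn-in sweep and Q is the
posterior mean; every Q row sums to 1 by construction. A split-half
discrepancy in $L(K)$ beyond 5 trace standard deviations flags (but
does not fail) the chain.

$L(K)$ is the Evanno summary mean(lnL) − var(lnL)/2, and
$\Delta K = m\bigl(|L(K+1) - 2L(K) + L(K-1)|\bigr) / s[L(K)]$ with $m$
the mean over replicate-paired second differences and $s$ the sample
standard deviation across replicates, following the original
formulation. ΔK is undefined at the endpoints of the K grid and wherever
$s = 0$ or only one replicate exists; those entries are `NA`, never
guessed. Because chains at different K are independent, each
(K, replicate) chain draws its own seed from a fixed integer hash of the
master seed, so adding replicates never perturbs earlier ones. Replicate
label switching is undone by greedily matching Q columns to the first
replicate (minimum column RMSE); membership uses the strict rule
max $Q_{ik} > 0.60$, with exactly 0.60 classified "mixed" — "exceeds"
means exceeds. Production-scale chains (10⁶ sweeps, half burn-in) are
configurable; the desk-scale default is 10,000 sweeps with 5,000
burn-in, which the recovery tests show is ample for panels of this size.

## The synthetic-data generator

Validation data come from the Balding–Nichols model: ancestral
frequencies $p \sim U(0.1, 0.9)$ by default, population frequencies
$\sim \mathrm{Beta}\bigl(p(1-F)/F,\ (1-p)(1-F)/F\bigr)$, ancestry
one-hot ("pure") or Dirichlet($\alpha$), and allele copies drawn through
the admixture model itself. Balding–Nichols is the canonical
$F$-parameterized generator and matches both the kinship module's
estimand and the admixture model's prior, so parameter recovery is
well-posed end to end. Inbred panels duplicate a single drawn allele per
locus; F1 hybrids are parental dosage means (heterozygous parents are an
error); missingness is MCAR with a seeded mask. All randomness flows
from one master seed through fixed named substreams (frequencies,
ancestry, copies, missingness), so components can be varied
independently, and complete truth records (ancestral and population
frequencies, true Q, pedigree) ride along with every panel.

`simulateStudyPanels()` fixes the study-scale geometry the pipeline and
acceptance checks run at: 20 F1 hybrids in 7 company groups (sizes 1, 3,
4, 5, 2, 1, 4) at 768 SNPs with 2% missing calls, and 27 fully inbred
reference lines at 1,536 SNPs with 1% missing, sharing 340 marker ids.
Company breeding pools are Balding–Nichols populations at $F = 0.10$
around a shared elite pool (itself at $F = 0.15$ from the global
ancestral pool); each company's hybrids are single crosses of inbred
parents drawn from its pool. Reference lines come from four diverse
populations at $F = 0.30$, except the first, drawn from the elite pool
so that a founder-line analogue co-clusters with the hybrids in the
combined analysis. These differentiation levels were chosen once as
representative of elite commercial pools versus global diversity panels;
under them the simulated hybrid panel shows a small positive inbreeding
coefficient and ~85–90% QC survival.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: linkage disequilibrium and
recombination maps (loci are exchangeable, which locus-bootstrap
resampling assumes anyway), ascertainment bias of commercial SNP arrays
(real elite panels lose far more markers to the MAF filter than the
~12% seen here), genotyping error and allele dropout, selection, and
pedigree structure deeper than a single cross.

## Problem sizes, tolerances, and degenerate inputs

The automated checks run at sizes chosen to finish on one CPU while
leaving the estimators no room to pass by luck: 50 random 20 × 50 panels
for statistic-oracle equality at $10^{-12}$; 1,000 random frequency
pairs for the DA axioms; 100 random matrices for UPGMA ultrametricity;
500 bootstrap replicates for the two-pair support check ($F = 0.4$, 200
loci, both pair nodes ≥ 95%); 20 replicates of 200 × 500 panels for
$F_{st}$ recovery at |bias| < 0.05; K = 2 recovery on 120 individuals ×
200 loci with 10,000 sweeps (Q RMSE ≤ 0.10); and ΔK selection of true
K = 3 on a 1–5 grid with 5 replicates across 10 independent master seeds
(≥ 8 must succeed, observed 10/10 at 500 sweeps).

Degenerate inputs are handled explicitly rather than by accident: empty
matrices, all-markers-filtered panels (valid empty result plus warning),
all-missing units and groups (errors naming the offender), monomorphic
denominators in G (error), zero replicate spread in ΔK (`NA`), fewer
than 3 shared markers in a correlation (error), and K = 1 chains (Q
degenerates to a column of ones and $L(1)$ matches the pooled binomial
likelihood up to the known posterior-sampling offset of about ¾ unit per
locus).

## Limitations

Fst-from-G is an inbreeding-style estimator relative to the panel's own
allele frequencies, not a multi-population Weir–Cockerham estimator;
with strong internal structure the two diverge. The admixture sampler
omits STRUCTURE's linkage model and correlated-frequency (F-model)
prior, so it is conservative for tightly linked panels and recent
admixture. ΔK cannot, by construction, select K at the grid endpoints —
in particular it cannot distinguish K = 1 from K = 2; inspect $L(K)$
directly when panmixia is plausible. Bootstrap support assumes
exchangeable loci. And a panel of tens of individuals estimates group
frequencies noisily: single-hybrid groups yield diversity statistics
that reflect one cross, not a company's germplasm.
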