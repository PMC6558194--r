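---
title: "Methods and design notes for IGHGpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for IGHGpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`IGHGpop` analyses nucleotide-level diversity of the IGHG1, IGHG2 and
IGHG3 gene segments. This vignette explains the models and procedures the
package implements, the parameters that matter, the choices made where the
design was genuinely open, and what the packaged synthetic data can and
cannot establish.

## The catalog and its coordinate system

The canonical coordinate of a variant is *(segment, exon, 1-based position
within the exon on the coding strand)*. The genes lie on the minus strand
of chromosome 14, so GRCh37 chromosome positions decrease as exonic
positions increase; chromosome coordinates are carried as annotation only
and a validity check enforces the strict monotonicity. Alleles are stored
as sets of departures from a per-exon consensus plus, for IGHG3, a
hinge-exon presence pattern (H1–H4). Hinge copy-number differences are part
of allele identity but are **not** substitutions: they are excluded from
every site-based statistic (LD, site frequency spectra) and contribute only
an optional, weight-0-by-default character to the allele networks, which
reproduces the conventional grouping of IGHG3\*11/IGHG3\*12 (identical in
sequence, different in hinge size).

Two quirks of the printed source tables are preserved verbatim rather than
"repaired": IGHG3\*01 and IGHG3\*05 have identical printed definitions
(both unobserved; the loader warns, and the validity check only rejects
duplicates among *observed* alleles), and IGHG3\*27's printed allotype
(26,27,28) omits G3m21 although the allele carries the Gm21-conferring
CH2:181 T state and differs from IGHG3\*14 only by a synonymous change; the
rule-based derivation therefore predicts 21,26,27,28 for it, and the
exhaustive rules-versus-catalog consistency check covers the previously
described alleles, where rules and printed columns agree everywhere.

## Grantham distances

The Grantham (1974) distance combines side-chain composition, polarity and
volume: \(D = \rho[\alpha(\Delta c)^2 + \beta(\Delta p)^2 +
\gamma(\Delta v)^2]^{1/2}\), with \(\alpha = 1.833\), \(\beta = 0.1018\),
\(\gamma = 0.000399\) and \(\rho = 50.723\) scaling the mean over all pairs
to 100. The published 1974 matrix — the form quoted throughout the
literature and in the catalog's annotations — is not exactly reproducible
from the formula: several entries differ by one unit from the recomputation
(Leu/Met prints 15, computes 14.3; Ser/Gly 56 vs 55.3; Val/Met 21 vs 21.5),
and no alternative scale factor removes the inconsistencies (Leu/Met = 15
needs \(\rho > 51.4\) while Pro/Arg = 103 needs \(\rho < 51.1\)); Asp/Trp
is a lone larger outlier (181 printed, 190.6 computed). `granthamDistance()`
therefore returns the published matrix, and `granthamFormula()` retains the
constants-based computation as a cross-check; a test pins their agreement
to within one unit everywhere except the documented Asp/Trp entry.

## Typing and novel-allele logic

A genotype record is a set of unordered base pairs at catalog site columns
(hinge presence enters as a pseudo-site with states P/A, mirroring the
laboratory observability of hinge size through amplicon length). Typing
enumerates every unordered pair of catalog alleles whose state union
reproduces the record exactly; missing calls are excluded from the
compatibility check and such records never contribute to novel-allele
discovery. Phase certainty is classified by the number of heterozygous
sites and the number of consistent decompositions; with two or more
heterozygous sites and more than one consistent decomposition the record is
flagged `ambiguous_requires_phasing` — the situation resolved by molecular
cloning in the laboratory. This is not hypothetical even within the known
catalog: the unphased genotype of (IGHG2\*03, IGHG2\*08) is also exactly
explained by (IGHG2\*12, IGHG2\*13).

When no catalog pair fits, decompositions are ranked by parsimony: fewest
novel alleles invoked, then fewest total novel variant states, then
lexicographic order. The rationale is to explain observations with known
alleles plus minimal novelty; the rule is a package decision, since no
published procedure covers the multi-way case before cloning. Provisional
names (`IGHG1*novel-1`, …) never reuse official suffixes; promoting a
provisional allele to an official name is a catalog edit, not automatic.

## Gm marker rules

Serological markers are conjunctions of required states at one or more
sites. Single-site rules cannot express the two-site markers: G3m5 requires
the consensus state at both EU 435 and 436, and G1m1 at both EU 356 and
358. For markers whose determining sites are not annotated with an
allotype switch in the variant table (G3m 6/10/13/14/24/26/27/28), the
requirements were chosen as the minimal site sets that reproduce every
previously described allele's printed allotype column exactly; that
exhaustive agreement is asserted in the test suite. Haplotype strings are
written in chromosomal order G3m;G1m;G2m with `(.)` for an empty marker
list, and Lefranc letters are attached by lookup for the strings attested
in the packaged table.

## Population-genetic machinery

**Hardy–Weinberg.** The exact test conditions on allele counts (Levene's
distribution). Arrays are fully enumerated when at most `max_enum` = 2×10⁵
arrays exist; otherwise a Guo–Thompson Monte Carlo chain is used: a random
transposition walk on the pairing of the 2n gene copies, whose stationary
law on genotype arrays is exactly the conditional distribution, with
100,000 kept steps after 10,000 dememorization steps by default and a
batch-means standard error (50 batches) that honestly reflects chain
autocorrelation. The p-value sums the probability of arrays no more
probable than the observed one (inclusive, so the test is valid). Note that
the all-heterozygote array is modal only for n ≤ 2; for larger samples its
exact p-value is below 1.

**EM haplotypes.** The pseudo-Bayesian ELB reconstruction used by common
software is replaced by plain EM over three-locus haplotypes with a uniform
start plus five random restarts (the replacement is deliberate: ELB's
tuning parameters are unpublished, EM is deterministic given the seed, and
only frequencies — not individual phases — feed the downstream Gm tables).
Convergence is declared when the log-likelihood gain falls below 10⁻¹⁰;
monotonicity is asserted at every iteration. A single double-heterozygote
stays at the symmetric 4 × 0.25 stationary point by design — there is no
information to break the tie.

**LD.** D, Lewontin's D′ and r² from two-locus haplotype frequencies;
unphased input is resolved per site pair by the same EM. Monomorphic or
multi-allelic sites are skipped with a message.

**F<sub>ST</sub>.** A Weir–Cockerham-type variance-component estimator on
allele counts (haploid form), with among- and within-population components
summed over all alleles of all three segments before the ratio is taken.
Negative estimates are reported as computed; for two identical samples the
unbiased estimator is slightly negative, not zero. The same estimator
recomputes the published pairwise matrix from the published frequency
table to within 0.05 on every population pair (most pairs to three or more
decimals), which is the package's evidence that this reconstruction matches
the original AMOVA-based computation.

**Exact differentiation.** A Metropolis chain over contingency tables with
fixed margins (probability ∝ 1/∏ nᵢⱼ!), ±1 swaps on random 2×2 subtables;
p is the visited fraction of tables no more probable than the observed one.
It reproduces Fisher's exact p on 2×2 tables and is calibrated under the
null within the binomial interval at α = 0.05 in the test suite. Per-pair
p-values over the three segments are combined by Fisher's method and also
reported Bonferroni-adjusted.

**PCA** is a column-centred SVD (covariance PCA) of the populations ×
Gm-haplotype frequency matrix; correlation scaling would up-weight rare
haplotypes, which is not wanted for compositional profiles.

## Median-joining networks

The network is grown from the minimum spanning network at tolerance ε
(a link is feasible iff its length is within ε of the Kruskal connection
level of its endpoints; at the default ε = 0 every tie link of every
minimum spanning tree is included). Median vectors are per-site majority
consensus of linked triplets, added until stable, and medians that end
with degree ≤ 1 are pruned. ε defaults to 0 and ties in link selection are
broken lexicographically for reproducibility. The published runs' ε and
weights are unknown, so network assertions are structural (the most
frequent alleles are hubs; node set ⊇ observed alleles; spanning-tree
weight preserved), not edge-exact.

## Neutrality statistics

Statistics are computed from the site frequency spectrum after complete
deletion of sites with non-ACGT symbols; triallelic ingroup sites are
excluded, and with an outgroup, sites where it carries a gap or third
state are excluded from the whole analysis so the folded and unfolded
spectra count the same sites. Tajima's D follows the 1989 variance
coefficients; Fu & Li's D and F use the outgroup to count mutations on
external branches (derived singletons), and D\*/F\* are their
outgroup-free versions, all with the Simonsen-corrected variance terms;
Fay & Wu's H is the original unnormalized π − θ<sub>H</sub> (the form the
standard software reports). Requesting an outgroup-polarized statistic
without an outgroup is an error, never a silent fold. With S = 0 the
statistics are undefined markers with p = 1.

Significance comes from standard neutral coalescent simulation conditioned
on the observed S (mutations placed uniformly on branches), matching the
"given S" convention; a θ-mode (Poisson mutations at rate θ/2 per unit
branch length) is kept for calibration against E[S] = θa₁. P-values are
lower-tail proportions, since the alternatives of interest (hitchhiking,
sweeps, purifying selection) push the statistics negative. The tests
calibrate the rejection rate at α = 0.05 over 500 neutral replicates at
2n = 92 and S = 16 — sample sizes of the order of the study populations,
where the statistics are fine-grained enough for the uniformity check to
be meaningful (at very small n and S their discreteness makes an exact 5%
level unattainable for any implementation).

## Nei–Gojobori selection test

Site counts per codon are s = (synonymous single-base mutants)/3 and
n = 3 − s; mutations to stop codons are counted on the non-synonymous
side (the convention of the widely used implementations, and the one
consistent with the package's worked ATGTTT/ATGTTA example, where
N̄ = 5.5). Multi-hit codons are averaged over all minimal mutational
pathways excluding those through stop codons (all pathways are used only
if every one is blocked). Proportions are Jukes–Cantor corrected; p ≥ 3/4
leaves the distance undefined and flagged. The codon Z-test compares the
overall mean pairwise dS and dN with a variance from B = 1000 bootstrap
resamples of codon columns (seeded; two seeds at B = 1000 differ by less
than 0.02 in p on the catalog fixtures) and a one-tailed normal p-value.
Reproducing the published per-segment p-values would require the true
consensus coding sequences, which are not printed; the packaged consensus
is synthetic (below), so the selection test over the real alleles is an
optional analysis for users who supply real consensus FASTA, not a
package claim.

## The synthetic-data generator

`simulatePopulation()` draws chromosomes from configured allele or
three-segment haplotype frequencies — by default with deterministic
largest-remainder counts (ties broken by descending frequency, then name),
so a printed frequency table maps to exactly one sample composition — and
pairs them by random permutation, i.e. Hardy–Weinberg proportions. It
emits the unphased genotype table the typing module consumes, optional
independent per-call missingness, and a truth ledger for round-trip tests.
`simulateAlignment()` reconstructs allele sequences over the CH exons and
adds an outgroup: the consensus plus Poisson(divergence × length) extra
substitutions at non-catalog positions (default divergence 0.05 per site,
of the order of human–macaque divergence), so polarization is informative
without disturbing ingroup polymorphism.

The packaged per-exon consensus is **synthetic**: arbitrary fixed bases
everywhere except the catalog site columns (where it carries the catalog
consensus base), kept free of in-frame stop codons. Coordinates, state
patterns, allele identities, frequencies and all site-based statistics are
therefore faithful; codon context, real flanking sequence, true
inter-segment homology and real outgroup alignment are not. Consequently
the passing tests establish the correctness of the machinery and the
internal consistency of the catalog, not sequence-level claims about the
real genes; analyses that need real sequence (dN/dS over true alleles,
outgroup-calibrated neutrality on real data) accept user-supplied FASTA.

What the generator deliberately does not model: sequencing error beyond
site masking, gene conversion (assessed descriptively through
`alleleHamming()` patterns), recombination within segments, and population
structure beyond independent populations.

## Problem sizes and numerical conventions

The test suite runs the simulations at the study's own scales (populations
of 46–57 individuals, 2n = 92–116; EM recovery at n = 200 with total
variation tolerance 0.05; HWE chains of 4×10⁴ steps; differentiation
chains of 6×10³ steps; coalescent nulls of 10⁴ replicates), chosen as
realistic for this study design. Frequencies are conserved to 10⁻¹² in Gm
aggregation; EM haplotypes below 10⁻⁸ are dropped from reports; Monte
Carlo p-value comparisons use batch-means standard errors; all stochastic
stages take explicit seeds and the pipeline manifest records them next to
md5 checksums of every output, so reruns are byte-identical.

## Known limitations

IGHG4 is out of scope (its frequent duplications need a different typing
strategy). The hinge sub-structure of the IGHG3 catalog encodes the
recoverable presence/absence pattern and substitution states, but two
hinge consensus bases are synthetic choices, flagged in the catalog notes.
The exact test and HWE chain p-values are Monte Carlo estimates; their
standard errors are reported and should be respected when comparing to
published significance stars. The FST reconstruction matches the published
matrix only approximately (within 0.05) because the original estimator
variant and its treatment of per-segment missingness are unstated.
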