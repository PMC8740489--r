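---
title: "Inferring TRB germline variation from expressed repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring TRB germline variation from expressed repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbkit)
```

# The problem

An individual's T cell receptor beta (TRB) repertoire is assembled by
V(D)J recombination from germline V, D and J gene segments. Which alleles
of those segments an individual actually carries — their repertoire
genotype — and how alleles are distributed over the two chromosomes —
their haplotype — are poorly documented, because the TRB locus is
repetitive and hard to sequence directly. trbkit infers this germline
variation from AIRR-seq rearrangement data instead: undocumented allele
candidates, per-gene genotypes, genes deleted from the expressed
repertoire on both chromosomes, and anchor-based haplotypes, for
full-length (5'RACE-style) as well as partial (BIOMED-2-style and
Adaptive-style) sequencing designs.

# Protocol windows, merged genes and allele patterns

Partial protocols only observe the 3' part of each V gene, so some genes
(and many alleles) become indistinguishable. A `protocol_spec` carries a
per-gene primer-end position (IMGT numbering); the protocol view of an
allele is its suffix starting just after the primer. Distances between
genes are minimum unit-cost alignments (mismatch, insertion, deletion all
cost one) with a free padded beginning, so suffix windows of unequal
length can align at zero cost. Genes at distance zero are merged under a
slash-joined label, transitively, so the label is well defined. Within a
(possibly merged) gene, alleles with identical windows collapse into
partial allelic-variation pattern groups named `gene*bp01`, `gene*bp02`,
... under the BIOMED-2-style design and `gene*ap01`, ... under the
Adaptive-style design; the group representative is the window of the
member with the longest full reference. Under the full protocol, groups
keep their allele's own name; identical alleles of a merged gene pair
share one record named `mergedgene*allele` (e.g. `TRBV6-2/TRBV6-3*01`).
When merged genes carry same-named alleles with *different* sequences,
the allele designator is disambiguated with the source gene so names stay
unique and parseable as `gene*allele`.

Primer coordinates are data, not code: they ship as editable YAML
(`read_protocol()`), since primer tables belong to the library design,
not to the method.

# The native assigner

Reads are scored against the pattern representatives (V) and whole
alleles (D, J). V alignment is ungapped and 5'-anchored with a search
over 3' trims (score = matched length − 2·mismatches); J is the mirror
image. All references achieving the top score are kept as a comma-joined
multi-call — ties are the "single assignment" signal the genotyping
filter needs, so they are never broken arbitrarily. D segments are
assigned by the longest exact germline substring inside the junction
interval; exact matching is sufficient because D-mismatch reads are
excluded from D genotyping anyway, and it makes the documented
TRBD2 mis-assignment channel (below) directly observable. Productivity
follows the junction: in-frame (length divisible by three) and stop-free
is productive; frame-shifted or stop-containing is not; an unlocatable
junction is `NA` and belongs to neither stratum.

# Undocumented alleles

Candidates are recurrent exact mismatch patterns inside the boundary
window, which runs from five positions after the primer end (or sequence
start) to IMGT position 316 — i.e. it stops short of the junction, where
trimming and N-addition would masquerade as polymorphism. For reference
sets that carry an explicit junction Cys anchor (such as the bundled toy
set), the window end defaults to the position just before that anchor,
which is the same design choice at toy scale. Candidates are named
`base_allele_<ref><pos><alt>` with IMGT positions, multi-SNP candidates
concatenate tokens.

Five filters follow. Support: an exact match to at least 5% of the
gene's alignments. Diversity: at least two CDR3 lengths and two TRBJ
genes among supporting reads (a germline allele is used across many
rearrangements; an error or chimera is not). Chimera: an exhaustive scan
over all ordered allele pairs from different genes and all breakpoints —
if any prefix+suffix concatenation reproduces the candidate exactly over
the window, it is discarded; the brute force *is* the definition, and the
switch exists because the rule is only warranted for noisy libraries.
SNP stretch: more than one SNP within four adjacent positions indicates a
local artefact. Modality: across a population, a real allele's usage
fraction among the gene's assignments is bi- or tri-modal (absent /
heterozygous / homozygous); the default test is deliberately simple — a
0.1-wide histogram needs either a carrier at fraction ≥ 0.20 or at least
two modes of mass ≥ 2 samples. The histogram was chosen over a formal
dip test because cohort sizes here are tens of samples, far below what a
dip statistic needs for power; the threshold and bin width are exposed as
arguments. Candidate floors (≥ 2 supporting reads, ≥ 1% of gene
alignments) keep candidate lists tractable before filtering.

Passing candidates are appended to the reference
(`augment_reference()`) and the sample is re-assigned, giving
individual-specific reference directories before genotyping.

# Bayesian genotyping

For each gene, reads with a single best V call and at most one boundary
window mismatch (for D: single call, no mismatches, matched length ≥ 9
nt) are counted per allele. The model space is every non-empty subset of
the top four observed alleles; under a k-allele model, members share the
non-error mass equally, (1−ε)/k each, and the mis-assignment mass ε is
split over the observed non-members. The call is the maximum-likelihood
model under a uniform prior, and the reported confidence `lk` is the
base-10 log Bayes factor between the best and runner-up models — base 10
so that `lk = 2` reads as a hundred-to-one factor; that is also the
default reporting threshold, configurable. V genes default to ε = 0.01;
TRBD2 is deliberately *not* genotyped this way, because its
mis-assignment is asymmetric (next section).

# TRBD2 genotype groups via equilibrium points

The two TRBD2 alleles differ by one G/A SNP inside a G run
(`GGGACTAGCGGGGGGG` vs `GGGACTAGCGGGAGGG`). Recombination trims the D
ends and N-addition is G-biased, so a trimmed *02 followed by added Gs
looks exactly like *01 — mis-assignment is common and asymmetric. The
per-sample fraction of TRBD2*01 among unambiguous TRBD2 reads is
therefore tri-modal over a population: homozygous *02 samples near
0.125, heterozygous near 0.45, homozygous *01 near 0.96.

Samples are first cut at 0.2 and 0.8; each group's mean and SD (sample
SD, n−1) define refined borders as the equilibrium point between two
normals — the x between the means where the two tail probabilities are
equal, in closed form x = (μ₁σ₂ + μ₂σ₁)/(σ₁ + σ₂) — and samples are
re-assigned once (an iterate-to-convergence mode exists, capped at 10
passes, but a single pass is the default procedure). The homozygous
group means double as mis-assignment estimates, ε₀₁→₀₂ = 1 − μ(hom01)
and ε₀₂→₀₁ = μ(hom02), and the heterozygous usage corrected for both
errors is the linear unmixing t = (μ(het) − ε₀₂→₀₁)/(1 − ε₀₁→₀₂ −
ε₀₂→₀₁): the observed heterozygous mean is t(1−ε₀₁→₀₂) + (1−t)ε₀₂→₀₁,
and t inverts that relation. Degenerate cohorts (an empty coarse group,
or a group too small for an SD) fall back to the coarse cut points with
a warning. `hwe_test()` provides the Hardy-Weinberg bookkeeping used to
sanity-check group frequencies; under random mating the heterozygote
frequency 2p(1−p) can never exceed one half.

# Double chromosome deletions

A gene absent from a sample's expressed repertoire on both chromosomes
leaves a usage signature: essentially zero reads where the population
expresses the gene at a stable rate. For each gene the reference rate P
is the smallest per-sample usage above a cutoff (0.0005 of unique reads;
samples at or below the cutoff are themselves candidates and do not set
P — the "self-exclusion" reading of the rule). Each (sample, gene) pair
is scored by the lower binomial tail Pr[Bin(N, P) ≤ X] and declared
deleted when the Bonferroni-adjusted p-value over all tested pairs falls
below α = 0.01 (the significance policy is this package's choice).
Deletions are statements about the expressed repertoire; promoter or RSS
variants could silence a structurally intact gene.

# Anchor-gene haplotypes

A heterozygous anchor gene (TRBJ1-6, or TRBD2 with caution) tags each
read's chromosome of origin. For every V allele, the counts (n₁, n₂) of
reads co-occurring with each anchor allele are compared under three
binomial models — on chromosome 1 only, on chromosome 2 only, on both —
where a read's anchor is flipped with probability ε; the winning model
places the allele and `lk` is again the base-10 log Bayes factor to the
runner-up. ε is 0.125 when TRBD2*02 dominates the sample's TRBD2 reads,
0.04 when *01 dominates, and 0.01 for the J anchor. A chromosome with no
allele while the gene is confidently expressed from the other chromosome
is `Del`; anything under the confidence floor (`lk` < 2) or the
informative-read floor (4 reads) is `Unk`. TRBD2-anchored haplotypes are
noisier than TRBJ1-6-anchored ones for the same reason TRBD2 genotyping
is special: the anchor itself is frequently mis-assigned.

# Usage statistics

`usage_table()` computes per-sample gene usage over unique reads, with
multi-call reads split fractionally (default) or by first call.
`family_usage()` sums J usage by family; `conditional_usage()` gives
P(J | D) over reads whose germline D match exceeds 7 nt — shorter calls
are too unreliable to condition on — restricted to TRBJ2 genes for
TRBD2, which cannot recombine upstream. Group comparisons use two-tailed
Mann-Whitney tests, Bonferroni-corrected within one gene panel (not
pooled across panels), with the usual 0.05/0.01/0.001 star convention.

# The simulator and what it does (not) show

`simulate_population()` draws genotypes in Hardy-Weinberg proportions,
couples TRBD2 and TRBJ1-6 alleles on a chromosome (linkage
disequilibrium, default coupling 0.9), carries the TRBV4-3+TRBV3-2
deletion in cis with TRBV7-2*02, and emits reads by choosing a
chromosome uniformly, a V gene from that chromosome, a D gene with
allele-dependent TRBD2 propensity, a J honouring the TRBD2-to-TRBJ2
constraint, geometric end trimming (mean 1.5 nt at V 3' and J 5', 2.5 nt
at each D end), Poisson(3) N-addition with P(G) = 0.5, uniform per-base
substitution error (default 0.1%), and protocol truncation. The D-trim
mean and G bias are set so that the emergent mis-assignment channel
reproduces the documented asymmetric regime (*02 read as *01 at roughly
three times the opposite rate); the fraction-level cohort generator
`simulate_d2_cohort()` encodes that regime directly (heterozygous usage
0.393 ± 0.08 between individuals, mis-assignment 0.04/0.125 with small
per-individual jitter, binomial sampling at 300 TRBD2 reads).

The bundled toy germline set (27 V genes of 60 nt, real TRBD1/TRBD2
sequences, 13 J genes) reproduces the locus's structural problems —
identical gene pairs at full length, pairs indistinguishable only under
partial windows, biallelic genes, the TRBD2 SNP — at a scale where a
simulation finishes in seconds. What passing tests on it do *not* show:
performance on real read lengths (real V genes are ~300 nt, so real
boundary windows are far larger), real primer chemistry, PCR chimeras,
UMI structure, or clonal expansion; reads here are unique by
construction after deduplication, and upstream preprocessing (pairing,
quality, dedup) is assumed done.

# Numerical choices and problem sizes

Assignment ties are kept; trims are searched to 8 nt; reads whose best V
or J alignment exceeds a 20% mismatch rate are flagged unusable rather
than dropped. The Bayes machinery works in log space throughout;
equilibrium points use the closed form (checked against a numeric root
finder to 1e-9 in the tests). The test suite exercises the pipeline at
deliberately modest sizes chosen as a sensible desk-scale design:
populations of 2-16 individuals at 800-14,000 reads per sample, six
seeded replicates for genotype recovery (~150 gene-level calls), six
planted-allele replicates, three deletion cohorts, and a deep two-sample
cohort for haplotypes, where the informative-read arithmetic (roughly 8%
of reads carry a TRBJ1-6 assignment) dictates the depth. The acceptance
script re-runs the same computations at the same scale plus a
786-individual fraction-level TRBD2 cohort.

# Known limitations

Internal IMGT gaps inside the boundary window are mapped but the
assigner compares ungapped windows, so indel alleles are out of scope.
Novel-allele augmentation requires the base pattern to resolve to a
concrete reference allele, so the discovery loop is most useful on
full-length data; on partial data candidates are still detected and
reported per pattern group. TRBD1 genotyping is limited by its 12 nt
length against the ≥ 9 nt rule. The deletion test inherits the usual
Bonferroni conservatism; at very low depth the cutoff semantics
(0.0005 of unique reads) lose meaning and power.
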