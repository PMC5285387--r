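---
title: "Methods: comparing sexual and aposporous pistil transcriptomes"
author: "apoPistil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing sexual and aposporous pistil transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoPistil)
```

# The problem

*Hypericum perforatum* (St John's wort) reproduces either sexually or by
aposporous apomixis, in which an unreduced embryo sac arises from a
somatic nucellar cell and the embryo develops without fertilisation.
Comparing pistil transcriptomes of sexual and aposporous accessions at
two floral stages — stage 11, spanning (apo)meiosis and aposporous
initial differentiation, and stage 14, spanning gametogenesis — is a
direct way to find genes whose deregulation accompanies the switch to
apomixis. apoPistil implements that comparison as a reusable pipeline:
single-channel array intensities in, cluster-labelled differential
genes, co-expression networks, GO over-representation, ordination and
qPCR validation statistics out. A synthetic-data module generates every
input with known ground truth, so the full pipeline is testable
end-to-end without any external download.

# Design and differential expression

The design is 2 reproductive modes x 2 floral stages x 3 biological
replicates = 12 arrays. Intensities are normalised per sample to the
sample's 75th percentile, then rescaled by the median of the per-sample
75th percentiles so values remain on the intensity scale; the rescaling
constant cancels out of every fold change. The 75th percentile uses
linear interpolation between order statistics (the `quantile()` type-7
default). We document this because the quantile convention changes the
normalisation constants, though not the calls.

Four canonical comparisons are tested, each contrasting a test group
against a reference group — the sexual samples, or within a mode the
earlier stage:

| comparison | reference | test | up | down |
|---|---|---|---|---|
| Sex11_vs_Sex14 | sexual, 11 | sexual, 14 | C1 | C2 |
| Apo11_vs_Apo14 | apomictic, 11 | apomictic, 14 | C3 | C4 |
| Sex11_vs_Apo11 | sexual, 11 | apomictic, 11 | C5 | C6 |
| Sex14_vs_Apo14 | sexual, 14 | apomictic, 14 | C7 | C8 |

Per gene and comparison an unpaired pooled-variance t-test is computed
(df = n1 + n2 - 2, two-sided); a Welch variant sits behind a flag. With
only three replicates per group a zero pooled variance is possible in
degenerate synthetic inputs; we adopt the convention p = 1 for equal
means and p = 0 for unequal means and document it rather than emitting
NaN. Whether the original analysis tested raw or log-scale intensities
is not determinable from the record; both are exposed (`logScale`),
raw-scale being the default, and neither is asserted as the historical
choice.

The fold change is the ratio of arithmetic group means of normalised
linear intensities, reported signed: the ratio itself when >= 1 and the
negative reciprocal otherwise, so +/-2 are symmetric thresholds. A gene
is called into a cluster when p < 0.01 (strict) and |signed FC| >= 2
(inclusive); the inequality directions follow the stated wording of the
thresholds. No multiple-testing correction enters the calls — the
procedure filters on raw p — but BH q-values are reported alongside for
information.

# The synthetic study and what "truth" means

The generator draws per-gene baseline intensities log-normally
(log2 mean 7, sd 1 by default), multiplies the test group of each
planted differential gene by the planted fold change (or its
reciprocal for down clusters), and applies multiplicative log-normal
noise with a configurable coefficient of variation, 0.1 by default — a
realistic replicate CV for single-channel arrays. At zero noise the
planted ratios are recovered exactly by the fold-change definition.

One structural point deserves emphasis. The four comparisons form a
cycle over the four (mode, stage) groups, so the product of the four
test/reference ratios is identically 1 for any gene. A gene perturbed
in a single group is therefore differential in exactly two comparisons
— its planted cluster and the induced "mirror" in the other comparison
sharing the perturbed group. The generator records the complete induced
truth (gene x comparison x cluster, derived arithmetically from the
planted group multipliers), and recovery is always measured against
that full table. Defaults plant 5 genes in each of C1..C8 among 2000
genes at 4-fold effects.

Co-expression modules are planted in non-differential genes: each
module shares one latent per-sample log2 profile (sd 1) plus per-gene
jitter (sd 0.05 log2), which puts within-module Pearson r near 0.998 —
comfortably above the 0.98 edge threshold while leaving recovery
non-trivial. Module genes deliberately carry no group effect, keeping
DEG truth and module truth independent.

What the generator does *not* emulate: probe-level spatial artifacts,
dye chemistry, background subtraction, batch structure, and the heavy
right tail and probe cross-hybridisation of real arrays. Passing tests
show the pipeline's statistics behave as specified under the assumed
noise model, not that the model captures every property of deposited
data.

# Correlation network and sub-networks

Pearson correlations are computed across all 12 samples on normalised
linear intensities, over the differential gene set. Edges require
|r| >= 0.98; the threshold notation in common use is ambiguous about
inclusivity, so the inclusive reading is the default and a `strict`
flag gives the open interval. Zero-variance genes are excluded with a
warning instead of generating undefined correlations.

Sub-networks are first neighbourhoods: seed nodes are DEGs satisfying a
boolean cluster predicate such as `(C1|C2)&(C5|C6)`; all edges incident
to a seed and the endpoints of those edges form the sub-network, and
isolated seeds are dropped. Extraction is idempotent and always returns
a subgraph of its input. Exports cover SIF, a tab-delimited edge list
and GraphML with `r` written at full double precision so a round trip
preserves correlations to 1e-12.

# GO over-representation

A minimal OBO v1.2 reader builds a typed DAG over `is_a` and `part_of`;
obsolete terms are dropped and cycles are a hard error naming one
cycle. Annotations are closed under the true-path rule before testing.
For every term with at least one study hit, the upper-tail
hypergeometric probability P(X >= k | N, K, n) is computed; the
universe defaults to all population genes with at least one propagated
annotation (the "annotated reference" convention of common enrichment
plugins) and is configurable. BH correction runs over the tested terms
only (m = number of terms with k >= 1), and only over-representation is
tested. Exactness is verified against direct combinatorial enumeration
for all N <= 20 on a grid.

# Ordination

"PCA using Manhattan distances" is realised as principal coordinates
analysis (classical MDS) on the Manhattan distance matrix — the only
coherent reading of a PCA parameterised by a non-Euclidean distance;
plain covariance PCA is provided alongside. Manhattan metrics need not
be Euclidean-embeddable, so negative eigenvalues can occur; they are
truncated to zero for the explained-variance denominator and their
total magnitude is reported. Both per-sample and per-group-centroid
modes exist, since the original displays centroid the replicates for
the reproduction-related gene subset.

# Annotation transfer

Unigene-to-genome alignments (PSL, 0-based half-open, forward query
coordinates) are filtered in two stages: match >= 50 bases and fraction
identity >= 0.97, both inclusive; then the end-overhang rule. Per end,
with u the unaligned unigene bases and g the corresponding strand-aware
unaligned contig bases, the end passes iff u <= 10 (untrimmed-adapter
allowance), or g < u, or g < 3 (the alignment effectively reaches the
contig edge). The written rule attaches the 3-bp escape only to one end
while stating the criteria apply to both; we apply all three disjuncts
symmetrically by default and expose `threeBpEscape = "3prime-only"`.
The rule also only constrains the case g >= u, so whether g < u with
u > 10 was retained historically is unknowable; `contigShorterLenient`
selects either behaviour (lenient default). Under the lenient reading
the 3-bp escape is logically subsumed by g < u; it becomes operative
under the strict reading — both are tested against brute-force
enumeration of the predicate over 1296 overhang combinations.

Per unigene the surviving hit with the most matches wins, ties broken
by identity then contig id (a ranking we fixed, as none is stated).
Genomic flanks of 100–1001 bases beyond the aligned interval are
extracted per side when at least 100 bases are available, reported in
the unigene's orientation. Annotation then prefers a direct protein hit
(E <= 1e-9 and similarity >= 70%) and falls back to the best flank hit
(E <= 1e-10); whether "similarity" means BLAST positives or identity is
configurable via the hit-table column supplied.

# qPCR quantification

Technical replicates are averaged, then per biological replicate
dCt = Ct_target - Ct_reference (reference defaulting to the HpTIP4
housekeeping gene), ddCt subtracts the calibrator-group mean dCt, and
the per-replicate ratio is 2^(-ddCt). Groups are summarised by the
geometric mean — ratios are multiplicative, and the geometric mean
makes the calibrator's self-ratio exactly 1 — with an arithmetic mode
behind a flag; the standard error is computed over the per-replicate
ratios (a stated convention, since SE-over-ddCt is equally defensible).
The efficiency-corrected Pfaffl ratio
E_t^dCt_t / E_ref^dCt_ref reduces exactly to 2^(-ddCt) at E = 2;
efficiencies are inputs in [1, 2], as efficiency estimation from raw
fluorescence belongs to instrument software.

# Pipeline, reproducibility and problem sizes

`validateConfig()` reads a YAML key-value file, fills the documented
defaults (p = 0.01, fc = 2, r = +/-0.98) and reports every violation at
once; `runPipeline()` executes import → normalise → DEG → Venn →
network → sub-networks → optional enrichment → ordination, stamps every
artifact with an MD5 hash of the configuration, and is byte-identical
on rerun with identical inputs. All generator randomness flows through
a single seed.

The shipped tests and the acceptance script run the generators at 2000
genes x 12 samples with 40 planted DEGs and two 5-gene modules — sizes
chosen to keep full correlation matrices and exhaustive predicate grids
exact and fast while matching the design's group structure. Known
limitations: no moderated-variance testing (three replicates would
benefit from shrinkage, but the pipeline reproduces the plain t-test
procedure by design), no batch correction, no GOslim reduction, and
fold changes assume strictly positive normalised means.
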