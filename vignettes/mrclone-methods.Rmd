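---
title: "Models and methods behind mrclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrclone)
```

`mrclone` analyses intratumour heterogeneity from multi-region,
multi-timepoint bulk sequencing of one patient. This vignette is the
package's own account of the models it fits, the thresholds it applies,
what the synthetic cohort generator does and does not emulate, and the
design choices made where more than one reasonable implementation exists.

## Somatic calling with a panel-of-normals error model

At every candidate site the technical mismatch rate is modelled as a
beta-binomial fitted from the control (normal) samples. Mismatch fractions
are regularised with a 0.5 / 1.0 pseudocount and the beta-binomial shape is
estimated by method of moments using the relation
$\mathrm{Var}(x/n) = \mu(1-\mu)/\bar n \,(1 + (\bar n - 1)\rho)$ with
$\rho = 1/(\alpha+\beta+1)$; when the moment estimate of the
overdispersion is not positive the model falls back to a pooled binomial,
represented as a beta with concentration $10^6$. The full empirical-Bayes
machinery of panel-of-normals callers is intentionally out of scope: the
per-site moment fit is transparent, fast, and accurate to within the
sampling noise of a typical 8-sample panel (the test suite compares it with
a grid-search maximum-likelihood oracle).

A site is called somatic when all three filters pass: tumour VAF $\ge$
`t_cand` (0.10), matched-normal VAF $<$ `t_ctrl` (0.05), and upper-tail
beta-binomial probability $P(X \ge \text{alt} \mid n, \alpha, \beta) <$
`p_max` (0.001). The tail is computed by direct summation of the
beta-binomial mass, which is exact and cheap up to the deepest coverages
used here (about 2500 reads).

## Expected VAF, presence, and clonality

For a mutation carried by a fraction $f$ of tumour cells on $m$ of the
$C_t$ tumour copies in a sample of purity $\rho$,

$$\mathrm{E}[\mathrm{VAF}] = \frac{f \rho m}{\rho C_t + 2(1-\rho)}.$$

A clonal heterozygous diploid variant at 60% purity has expected VAF 0.30;
that reference point anchors the presence rule. A variant is *present* in
sample $s$ when its VAF reaches

$$t_s = 0.10 \times \frac{\mathrm{E[VAF]}(1, \rho_s, C_t(s), 1)}{0.30},$$

i.e. the 10% cutoff rescaled proportionally to the locally expected VAF.
This is one concrete reading of "the threshold is adjusted for copy
number"; it is configurable (`t_clonal`). Presence testing uses $m = 1$
(the conservative heterozygous assumption); multiplicity is not estimated.
Variants that cannot be located in any segment are assumed diploid and
flagged. A variant present in all samples is *clonal*, in exactly one
*subclonal-specific*, otherwise *subclonal*.

## Purity and binomial-mixture clustering

Clustering is restricted to variants on segments called (1, 1) in every
sample — the copy-number-neutral mask. Purity per sample is twice the
median VAF of the highest-mean cluster from a one-dimensional
pre-clustering, clipped to (0, 1]; clusters holding less than 10% of the
variants cannot anchor the estimate, because the clonal peak is by
definition a sizeable share of the neutral variants and tiny high-mean
noise clusters would bias purity upward.

The multi-sample model is a binomial mixture: variant $i$ in cluster $k$
has alt counts $\mathrm{Bin}(d_{is}, \theta_{ks})$ independently across
samples. EM runs to a relative log-likelihood tolerance of $10^{-6}$
(at most 500 iterations) with 10 seeded restarts (k-means on the VAF
matrix seeds the first). Zero VAFs are floored at $10^{-10}$ so the
likelihood stays finite — the same guard the original clustering tools
apply. K runs from 1 to `k_max` (20) and is chosen by BIC, followed by two
refinements that address known failure modes of a plain K-sweep:

- *backward-merge refitting*: from the BIC-best model, EM refits seeded
  from every pairwise merge of cluster centres are accepted whenever they
  improve BIC — the K-wise search can miss a better optimum one cluster
  down;
- *outlier-cluster dissolution*: clusters retaining fewer than 3 variants
  are dissolved and their members re-attached by an EM refit at the
  reduced K. This implements post-hoc attachment of outlying variants to
  their nearest cluster.

Cluster centres convert to cellular fractions as $2\theta_{ks}/\rho_s$,
truncated to [0, 1]; scaling happens after model selection.

## Clone-tree rules

Clusters with cellular fraction above `founding_cf` (0.90) in *all*
samples merge into the founding clone (trunk). Remaining clusters are
grouped by presence pattern (CF $\ge$ `presence_cf`, 0.05). Same-pattern
clusters whose CF vectors agree within `merge_cf` (0.05) in every sample
are grouped into a single clone — clusters that close in CF space are one
population measured twice, and keeping them distinct would fabricate
lineage depth; same-pattern clusters with genuinely different CFs remain
distinct clones chained in decreasing mean CF. Each clone's parent is the
clone with the smallest presence superset, ties broken by larger mean CF
and then by id; clusters with no superset parent attach to the trunk with
an `unplaced` flag rather than failing. Branch lengths are SNV counts, and
patients with fewer than `min_snvs` (5) informative SNVs return an
explicit insufficient-signal result. Sibling CF sums exceeding the parent
by more than 0.05 are reported as warnings, never silently repaired.
Samples are annotated at their deepest contained clone; a sample carrying
clones outside that clone's ancestry is flagged as clonal intermixing.

## Joint segmentation, phasing and MSAI

Per-sample allele-specific segments are refined to the union of
breakpoints; each sample's states are carried onto the refined intervals
and intervals identical in every sample merge back. For each joint segment
with at least `min_snps` (10) heterozygous SNPs, the sample with the
strongest significant allelic imbalance (exact binomial test of pooled
B counts against 0.5 at `msai_p` = 0.01; score $|BAF-0.5|\sqrt{n}$)
anchors the phase: SNP alleles at BAF above 0.5 in that reference are
assigned to the amplified haplotype, called A. All samples' phased
haplotype-A BAFs are then computed on this fixed phase, `(cnA, cnB)` is
oriented accordingly, and orientations contradicted by a significant
phased BAF are flipped (total copy number is conserved). Segments with no
imbalanced sample stay unphased. An MSAI event is emitted when at least
one sample significantly favours haplotype A and at least one favours B on
the same joint segment. No multiple-testing correction is applied within a
patient, matching the descriptive use of these calls; the thresholds are
explicit stand-ins surfaced in the configuration.

The synthetic BAF tables orient the B allele consistently to haplotype B
within a patient, as if SNPs arrived pre-phased in blocks; the phasing
code nonetheless performs per-SNP reference-anchored flips, so it also
handles arbitrary per-SNP orientation.

## Copy-number event classes and summaries

With baseline $b = \mathrm{round}(\text{ploidy})$: total copy number 0 is
a deep loss; a lost haplotype with total at or below $b$ is LOH (this
includes copy-neutral LOH); totals at or above $2b+1$ are amplifications;
totals between are gains. The amplification cutoff and the 50% cytoband
coverage rule are package choices, both configurable. A joint segment is
clonal when the same non-neutral class appears in every sample — a 3-copy
and a 4-copy gain in different samples are one clonal gain. Genome
fractions use the total tiled autosomal length as denominator. A
chromosome is whole-chromosome altered when every non-neutral event on it
spans at least 95% of its length, segmental otherwise.

## Minimum-event phylogenies

The directed distance between two haplotype copy-number vectors is the
minimum number of contiguous segmental $\pm 1$ events transforming one
into the other, computed per chromosome as the sum of positive increments
of the positive and negative parts of the difference signal; a transition
from 0 to a positive copy number is infeasible because lost genetic
material cannot be regained. The test suite proves this scanline equal to
an exhaustive breadth-first search over event sequences on small profiles.

For tree building each pair is symmetrised as the minimum of both direct
directions and the path through a common-ancestor candidate $z =
\min(a, b)$ floored at one copy wherever either profile is positive. The
through-ancestor bound matters: two siblings that each lost different
segments are mutually infeasible directly, and any flat penalty would make
them look unrelated, destroying the additivity neighbour joining relies
on. Neighbour joining (with a diploid pseudo-sample for rooting, negative
branch lengths clamped to zero) builds the topology; this is a deliberate
simplification relative to full minimum-evolution search, with no
whole-genome-doubling events. The triangle inequality is not asserted for
these distances — it does not generally hold under irreversibility.

Ancestral genomes are reconstructed per segment and haplotype by a Sankoff
dynamic programme with unit cost per copy step, the 0-to-positive bar, the
root fixed diploid, and ties broken toward the smaller copy number; branch
event counts are then recomputed as minimum-event distances between the
reconstructed profiles. Jackknife support drops 50% of the joint segments
uniformly in each of 100 replicates (both parameters are package choices —
the resampling unit is the joint segment) and scores each original
bipartition by the percentage of replicates containing it.

## UHR classification

A biopsy is telomere-maintenance positive with any of: high TERT
expression (a boolean input or a user threshold; no threshold is
re-derived here), MYCN amplification (boolean, or derived from the focal
2p24 copy number via the amplification rule), TERT rearrangement, or ALT.
UHR requires additionally a TP53 or RAS/MAPK pathway mutation at VAF
strictly above `uhr_vaf` (0.05). The default pathway list (TP53; ALK,
HRAS, NRAS, KRAS, BRAF, NF1, PTPN11, FGFR1, RAF1) is fully overridable.
Both per-biopsy calls and a patient-level summary (heterogeneous when
biopsies disagree; direction `acquired`/`lost` across timepoints) are
emitted, since whether subclonal pathway mutations should count toward a
patient label is a judgement call left to the reader.

## The synthetic cohort generator

The generator emulates the *structure* of a multi-region neuroblastoma
study: 3 biopsies per patient by default, purity drawn from (0.6, 0.95)
(biopsies are macrodissected above a 60% tumour-cell floor), Poisson
depths at 346x (exome) or 2500x (targeted), a 22-autosome genome of equal
100 Mb chromosomes tiled by 44 segments, 20 trunk and 10 per-clone SNVs,
one copy-number event per clone branch on average, and a per-segment MSAI
probability of 0.05 — about two planted mirrored events per patient,
matching the observation that repeated MSAI occurs in a minority of
patients rather than everywhere.

Clone trees grow by uniform attachment, so linear and branched shapes both
occur. Cellular fractions are allocated top-down: each non-founding clone
occupies a random subset of its parent's samples (spatial localisation)
and present children split a random fraction of the parent's CCF, so
lineage consistency holds exactly. By default the generator rejects CCF
configurations that are not *recoverable in principle*: every clone must
be captured by at least one biopsy at CCF 0.15 or more, non-founding CCFs
stay within [0.15, 0.85], pairwise clone separations reach `min_ccf_gap`
(0.15), and the rule-based reconstruction applied to the true CCFs must
return the true parents with a mean-CF decision margin of at least 0.10
(rule decisions closer than that flip under estimation noise and test
nothing about the code). Hard tree shapes relax these requirements
progressively, with a warning. Expected VAFs are computed from the full
clone mixture — exclusive cell fractions times the copy number of the
variant's haplotype in each carrier clone — which reduces to $m = 1$ on
unaltered segments and lets multiplicity follow later gains of the mutant
haplotype.

What the generator does **not** emulate: read-level artefacts (mapping
error, strand bias, FFPE damage), sequencing-error base context, sex
chromosomes, subclonal copy number visible as non-integer segment calls
(per-sample segment tables are the rounded clone-mixture consensus, as an
allele-specific caller would report), germline contamination structure
beyond a flat 0.002 technical error rate, and sampling of physically
adjacent regions. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not performance on real
reads. One consequence worth knowing: variants sitting on segments whose
copy-number change is hidden by the consensus rounding have systematically
shifted VAFs, and a well-fitting mixture model will occasionally give them
their own cluster; this is a property of VAF-only clustering, not a bug,
and it is why the recovery studies quote both exact-tree recovery and
clustering accuracy on the model-conform variants.

## Problem sizes and numerical choices

The bundled studies use the sizes at which their questions are sharp: the
clone-tree recovery study runs 20 cohorts of 3 samples and 5 clones at
500x; the MSAI operating point uses 100 planted events and 1000 null
segment-samples with 50 SNPs per segment at depth 100 and purity 0.7; the
copy-number phylogeny study runs 50 replicates of 7-clone trees on a
110-segment genome at 8 events per branch — the regime the method is for,
since biopsy pairs in the motivating data differ by hundreds of segments,
and branches carrying fewer than about 2 events are indistinguishable from
polytomies (estimated trees are compared after collapsing internal edges
shorter than 2 events). Exhaustive oracle comparisons for the event
distance cover all profile pairs at up to 3 segments and seeded
random-source sweeps at 4-6 segments, copy numbers up to 4.

Determinism: every random stage derives its seed from the master seed via
a fixed integer map; reruns are byte-identical, and RNG state is restored
after each call so the package never perturbs a session's random stream.
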