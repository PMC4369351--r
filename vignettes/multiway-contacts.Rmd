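---
title: "Multi-way chromatin contacts: models, parameters and design choices"
author: "multiway3c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-way chromatin contacts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiway3c)
```

## The problem

Chromosome-conformation-capture assays crosslink chromatin, digest it with
restriction enzymes, religate fragments that were spatially close, and
paired-end sequence the products.  When digestion uses frequently cutting
4-base enzymes, ligation junctions are dense enough that a single 100 bp
read end often *spans* a junction — it is chimeric, composed of sequence
from two genomic loci.  Standard Hi-C pipelines discard such reads.  This
package recovers them, and with them something standard pipelines cannot
see at all: contacts among three or four loci captured simultaneously in
one molecule, i.e. evidence that the loci were close together in the same
nucleus at the same time rather than pairwise-close in different cells.

The package implements the full computational path: two-phase read mapping
with restriction-site splitting, multi-way contact enumeration, binned
contact maps, copy-number-aware matrix normalization for near-haploid
genomes, A/B compartment calls, enrichment statistics over chromatin
annotations, and whole-genome 3D structure inference under a Poisson
model with explicit homolog beads.  A simulator generates libraries with
planted ground truth so every stage is testable without external data.

## Two-phase mapping and contact enumeration

Each read end is first aligned as a whole.  An alignment is accepted when
it is unique, has mapping quality at least 30, and edit distance at most 3;
such ends are *fully mapped* (F).  Ends that fail to map are scanned for
recognition sites of the digestion enzymes (all enzymes pooled; overlapping
occurrences and both orientations counted — the bundled 4-cutter motifs are
palindromic, so the reverse-complement scan only matters for custom
enzymes).  Reads with exactly one site are split at it, *preserving the
entire recognition sequence on both fragments*: with the site at offset
$s$ and width $w$ in a read of length $L$, the fragments are
$[0, s+w)$ and $[s, L)$.  This mirrors the religation chemistry: a
reconstituted site sits at the junction, and both flanks continue into
their source loci through the full site, so both fragments are exact
genomic substrings.  Split fragments shorter than 16 bp are not emitted
(too short to align uniquely).  Fragments are re-aligned under a stricter
edit-distance bound of 1 (they are short); ends with one or two uniquely
mapping fragments are *partially mapped* (P1, P2).

Reads with zero sites cannot be chimeric and are dropped from phase two.
Reads with two or more sites are discarded: with ~100 bp ends, a read with
two junctions splits into three pieces of which the middle one is rarely
alignable, and the junction structure is ambiguous.  (Descriptions of this
filtering step are ambiguous about reads with exactly two sites; this
package discards them, and `emitted_fragments()` documents the rule.)

A read pair with mapped locus set $L$ yields every subset of size 2
(doubles), 3 (triples) and 4 (quadruples): F+F gives one double; P2+F
gives three doubles and one triple; P2+P2 gives six doubles, four triples
and one quadruple.  Contacts are classed by their mapping route (`F-F`,
`P-F`, `P-P`) and by chromosomal span (`intra`, `inter`, `mixed` —
`mixed` meaning at least two but not all loci share a chromosome).  Each
locus is represented by the 0-based genomic coordinate of the fragment's
5' base (the convention is arbitrary but must be fixed; 5'-of-read is
what aligners report most directly).

Two distance filters matter.  Molecules are sonicated to roughly 250 bp,
so an unligated (non-chimeric) molecule produces an F-F pair at a short
genomic distance; a 1 kb intrachromosomal threshold removes all of these.
Genome-scale analyses additionally use a 20 kb threshold.  A contact is
dropped when *any* two of its loci on one chromosome are closer than the
threshold, so e.g. a triple whose three loci include one close pair is
removed while its distant sub-double survives.

Per-end read-orientation signatures (`"+/-"`, `"++/-"`, ...) provide a
quality diagnostic: genuine religation junctions are orientation-free, so
beyond 1 kb the sign combinations of each contact type should be uniform,
whereas sonication products concentrate on one inward combination.  The
test suite verifies the uniform limit on simulated religation libraries.

## Contact maps and scaling

Doubles are accumulated into a symmetric sparse matrix over fixed-width
bins (0-based, half-open, ceiling division keeps the last partial bin per
chromosome; the bundled hg19 chromosome lengths give 3113 one-megabase
bins).  The distance-scaling curve bins intrachromosomal doubles into
multiplicative distance bins (factor $\sqrt 2$ from 1 kb — fine enough to
resolve a power law, coarse enough to keep counts per bin) and divides by
the number of genomic position pairs at that distance, so a
distance-independent library is flat and a power-law library has the
power-law's slope in log–log coordinates; the suite checks that a planted
$s^{-1}$ law is recovered within $\pm 0.15$.  Chromosome-pair mean
matrices average counts over bin pairs whose bins are both at least 50%
uniquely mappable; copy-number gains and translocations appear as
elevated rows/entries.

## Copy-number-aware normalization

Iterative correction (ICE) assumes every locus is equally "visible":
observed counts are true frequencies times a product of per-locus biases,
removable by alternately rescaling rows and columns to uniform coverage.
A near-haploid genome with a few two-copy chromosomes breaks the
assumption — two-copy loci legitimately collect twice the reads.  The
package therefore:

1. **Deduplicates** counts onto homolog *beads* (one bead per copy of
   each bin).  A count between a haploid and a two-copy locus is split
   half-and-half between the two bead pairs; between two two-copy loci,
   the two same-copy pairs (A–A, B–B) get half each and the inter-homolog
   pairs are set to zero.  This encodes the working assumption that
   homologous chromosomes interact in identical ways and not with each
   other — contact data cannot phase homologs, so the symmetric split is
   the maximum-entropy choice.  Splitting then re-summing is exactly the
   identity, which the suite asserts.
2. **Filters** the 10% of loci with the highest fraction of zero
   intrachromosomal entries (lowest signal-to-noise, typically poor
   mappability).  Ties break by locus index; chromosomes with fewer than
   two bins are exempt because their zero-fraction is undefined.
3. Runs **ICE at the bead level** until the maximum relative coverage
   deviation is below `tol` (default `1e-5`, at most 300 iterations; both
   values are ordinary convergence controls).  The bias vector is
   normalized to unit geometric mean over retained loci — the fixed point
   is unique only up to one global constant, and this convention pins it;
   consequently the normalized matrix is reproducible up to that global
   scale, which is immaterial to every downstream use (ratios,
   correlations, and distances in arbitrary units).
4. **Re-sums** homolog beads to loci.  Because ICE equalized bead
   coverage, two-copy loci end with exactly twice the coverage of
   single-copy loci; the accuracy of the factor 2 is limited only by the
   ICE tolerance, so analyses that quantify it tightly should pass a
   smaller `tol` (the test suite uses `1e-9` to verify the ratio to
   `1e-6`).

## Compartments

Per chromosome, the normalized intrachromosomal matrix (filtered bins
dropped, reinserted afterwards as NA) is turned into a row-row Pearson
correlation matrix and eigendecomposed.  The sign of the leading
eigenvector partitions bins into the two megabase-scale compartments.
When the first eigenvector is single-signed (ignoring NAs and exact
zeros) it reflects overall coverage rather than compartmentalization and
the second eigenvector is used instead.  Because an eigenvector's sign is
arbitrary, the vector is first scaled so its largest-magnitude entry is
positive (removing solver dependence), and the biological orientation is
then fixed by GC content: the sign group with higher mean GC is "open"
(open chromatin is GC-rich).  An exact GC tie keeps "+" as open with a
warning.  Track agreement is the percentage of bins labelled in both
tracks that match; the suite checks 100%/0%/~50% for identical,
complemented and independent tracks, and ≥95% recovery of planted
two-block structure at moderate noise.

## Enrichment statistics

Do multi-way contacts prefer open chromatin?  The comparison needs an
exact null.  Over bins that are at least 50% mappable and labelled, the
package enumerates — in closed form from per-chromosome label counts —
all interchromosomal bin pairs and all bin triples on three distinct
chromosomes, splitting them into all-open / all-closed / mixed.  With
equal open/closed counts per chromosome these expected fractions are
25/25/50% for pairs and 12.5/12.5/75% for triples.  Observed fractions
weight the same groups by contacts (interchromosomal doubles; triples
linking three distinct chromosomes), and the observed/expected ratio per
group equals 1 under uniform sampling — verified against brute-force
tuple enumeration and Monte-Carlo resampling in the suite.  The same
machinery applies to DNase-hypersensitivity classes: windows are sorted
by decreasing DHS count and the top `floor(n/2)` labelled "high" (ties by
bin index, deterministically).

For topological domains (consumed as BED intervals from an external
caller), the statistic is the fraction of intrachromosomal triples with
all three loci in one domain.  Triples spanning less than 20 kb and
triples linking two loci within the same 40 kb window are excluded from
numerator and denominator — at 40 kb calling resolution they would count
as "within domain" trivially.  ("Short range" is implemented as maximum
pairwise span < 20 kb; any such triple is also nearly always caught by
the 40 kb window rule, so the choice between max-span and min-pair-span
is inconsequential.)  Significance comes from a shuffled-domain null:
within each chromosome arm, the observed domain and inter-domain gap
lengths are re-laid consecutively in a uniformly random order, preserving
the per-arm multiset of domain lengths and the covered fraction exactly;
the observed fraction's z-score is taken against (by default) 100 such
shuffles.  When the null is degenerate (e.g. equal-length domains tiling
an arm completely, where every shuffle reproduces the same cover) the
standard deviation is zero and z is defined as 0.  Domain-boundary
overlap between two decompositions treats each domain start/end as a 1 bp
feature and counts a boundary as shared when a boundary of the other set
coincides or is adjacent (within `tol` bp, default 1; pass the bin size
for binned calls).

## 3D structure inference

Each chromosome copy is a chain of beads at the binning resolution.  For
a genome with two-copy regions there are $n$ beads but only $m \le n$
observable loci; $\Phi$ maps beads to loci, and an observed count
$c_{kl}$ is the sum of contributions of the homolog bead pairs of
$(k, l)$.  The model: each bead-pair contribution $\mu_{ij} c_{kl}$
(with $\sum \mu = 1$ per locus pair) is Poisson with mean
$d_{ij}^{\alpha}$, $\alpha = -3$ — the empirically supported power law
relating contact frequency to distance.  The log-likelihood summed over
the set $D$ of non-zero counts is
$\sum_{(i,j) \in D} \mu_{ij} c \,\alpha \log d_{ij} - d_{ij}^{\alpha} -
\log\Gamma(\mu_{ij} c + 1)$, the factorial relaxed to $\Gamma$ because
apportioned counts need not be integers.  Zero-count locus pairs are
excluded by construction of $D$.  There is no multiplicative intensity
coefficient, so coordinate units are fixed by the counts themselves
(distance 1 is where the expected count is 1).

Constraints and their interpretation:

* $d \le d_{\max}$, with $d_{\max}$ the 97% quantile (type-7 linear
  interpolation) of expected adjacent-bead distances $c_{i,i+1}^{-1/3}$
  over single-copy stretches.  Because $d_{\max}$ is derived from
  *adjacent*-bead counts, the bound is enforced on the chain distances of
  consecutive beads: its role is to keep the polymer chain intact where
  normalization artifacts produce outlier near-zero adjacent counts.
  (Applied to all pairs it would force the entire genome inside a ball of
  one adjacent-bead radius, which cannot be intended.)  The bound enters
  as a smooth quadratic hinge penalty (weight 100, raised tenfold on
  violation when the step is run standalone); each returned model carries
  a feasibility flag.
* $0.3 \le \mu_{ij} \le 0.7$ for bead pairs that both lie in the same
  copy of a two-copy region (diploid–diploid groups): both homolog
  configurations must carry a substantial share, implementing the same
  cannot-phase symmetry as the normalization.  Haploid–diploid
  apportionments are free on $[0, 1]$ — the constraint's wording ties it
  to pairs *within* diploid copies, and a likelihood check confirms this
  reading: boxing haploid–diploid pairs forces mass onto the distant
  homolog and pushes the generative truth far below the fitted optimum,
  while under the adopted reading the truth scores near-optimally.

Optimization alternates two ascent steps: (1) bead coordinates by
L-BFGS-B with an analytic gradient on the penalized objective;
(2) apportionments by exhaustive grid search with step 0.01 within each
locus-pair group (groups are at most two bead pairs under the homolog
model, so the lattice is tiny; the enumerator handles larger groups for
custom setups).  Both steps ascend the same fixed objective, so the
iteration is monotone — asserted by the tests — and stops at relative
change $10^{-6}$ or 50 outer iterations.  The problem is non-convex:
inference restarts from random initializations (coordinates isotropic
Gaussian scaled to the $d_{\max}$ ball, apportionments uniform), sorts
models by log-likelihood and reports the top 10% (mirroring
1000-restart/keep-100 practice at cluster scale; the package default is
10 restarts, sized for desk-scale genomes).  Restart $r$ seeds the RNG
with `seed + r - 1`, making runs bit-reproducible.

The recovery tests plant a 30-bead genome (20-bead haploid chromosome
plus a 5-locus two-copy chromosome whose second copy is a translated
duplicate), draw counts from the forward model at unit intensity, and
require the best-likelihood model to match the planted structure within
10% of its diameter after Procrustes superposition (reflection allowed —
the likelihood is mirror-invariant).  The planted structure is compact
(diameter < 1 in count units) because at unit intensity the Poisson means
$d^{-3}$ carry information only for distances near or below 1; that is a
property of the study design, not of the implementation.

## The simulator: what it emulates, and what it does not

`simulate_genome()` draws uniform-composition random chromosomes (4-bp
motif density $4^{-4} \approx 1/256$ per bp, so restriction fragments
average ~256 bp, matching real 4-cutter digests in order of magnitude).
`simulate_library()` assembles molecules of four classes — sonication
products and 2-, 3-, 4-fragment ligation chimeras (defaults 40/40/15/5%,
keeping sonication the largest class as in real libraries while
exercising every contact type) — by excising restriction fragments and
joining them at reconstituted recognition sites, each fragment randomly
reverse-complemented (palindromic sites religate in either orientation).
Junction positions inside 2-fragment molecules are uniform, so both
fully-mapped and split-mapped configurations arise; 3- and 4-fragment
molecules place one junction inside each relevant read with at least
16 bp flanks, the geometry that makes a triple/quadruple recoverable.
The truth table records, per read pair, the end statuses and 5' loci
implied by the molecule *geometry alone*, computed independently of the
sequence-level pipeline; the suite then asserts that the pipeline output
equals the truth-implied contact set exactly, and separately that the
truth coordinates are sequence-consistent (each stated locus reproduces
its read fragment from the genome).

Not emulated: sequencing errors by default (an optional uniform
substitution mode exists for exercising edit-distance filters with
external aligners), base-quality realism, mapping biases and repeat
structure beyond an optional planted repeat, PCR duplication, ligation
preference by fragment length, and polymer-physics contact statistics.
Passing the end-to-end tests therefore demonstrates the correctness of
the splitting/filtering/enumeration logic and the internal consistency of
the statistical machinery — not robustness to noisy real-world alignment,
which is delegated to the external aligner consumed via SAM/BAM.

## Problem sizes and numerical choices

Test and example workloads are sized for a laptop-class single core:
simulated genomes of 1–4 chromosomes at 40–200 kb, libraries of 30–300
read pairs, matrices up to ~100 bins, and 3D inference on 30 beads with
8 restarts (~30 s).  All stages scale to real genomes (the bin/bead
machinery is exercised at the 3113-bin human scale in the tests), but
whole-genome 3D inference with ~1000 restarts is cluster-scale by nature
and is exercised here only through its building blocks.

Numerical conventions collected in one place: coordinates 0-based
half-open everywhere; loci binned by 5' coordinate; ICE tolerance on
coverage deviation `1e-5` (300 iterations max, unit-geometric-mean bias);
eigenvector sign fixed by largest-magnitude entry; GC ties resolved to
"+" with a warning; DHS median split `floor(n/2)` high, ties by index;
sparsity-filter ties by index, short chromosomes exempt; quantiles type 7;
likelihood errors on coincident beads within $D$ rather than silent
clamping; shuffle z defined 0 when the null is degenerate.

## Known limitations

* Uniqueness semantics of external aligners vary; the SAM reader uses
  `X0`/`XA` when present and otherwise trusts primary/non-supplementary
  status, which may over-call uniqueness for aligners that report
  neither.
* The exactly-two-site read policy discards a class of reads that a
  longer-read protocol could rescue.
* The homolog symmetry assumptions (equal split, zero inter-homolog
  counts, boxed diploid apportionment) are irreducible without phased
  variants; structures for two-copy regions are correspondingly
  consensus-like.
* The within-domain statistic conditions on externally supplied domain
  calls; it does not propagate their uncertainty.
* The 3D model has no intensity coefficient, so absolute coordinate units
  are meaningful only relative to the count scale of the input matrix.
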