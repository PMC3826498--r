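---
title: "Analysing non-coding human accelerated regions as developmental enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing non-coding human accelerated regions as developmental enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncharlab)
```

## The problem

Non-coding human accelerated regions (ncHARs) are mammalian-conserved
sequences with an excess of substitutions on the human branch. Because
conserved non-coding DNA is enriched for regulatory elements, the
working hypothesis is that many ncHARs are developmental enhancers whose
activity may differ between human and chimpanzee. `ncharlab` implements
the computational side of that investigation: compiling a non-redundant
ncHAR catalogue from heterogeneous published interval sets, layering
gene-context and functional-genomics evidence, predicting enhancers and
their tissues, scoring binding-site divergence between species, ranking
candidates for transgenic validation, and turning embryo staining tables
into reproducible activity calls.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data module does
and does not emulate.

## Interval compilation

Coordinates are 0-based half-open (BED convention) throughout; GTF/GFF
input is converted on read. Merging collapses overlapping **and
bookended** intervals — the weaker "overlap only" rule is not idempotent
(two touching survivors could merge on a second pass), and idempotence
(`merge(merge(S)) = merge(S)`) is a property the tests rely on. A merged
interval carries the union of its members' source labels, so provenance
survives compilation.

The coding filter drops a region on ≥ 1 bp overlap with any coding exon
of any transcript; a region that merely abuts an exon (no shared base
under half-open semantics) is kept. Context classification applies a
fixed precedence — pseudogene > lincRNA exon > miRNA > intronic >
intergenic — so that every region gets exactly one label and category
fractions sum to 1. "Intronic" means overlap with a protein-coding gene
span after the coding filter has run.

TSS distance is measured from the **region midpoint** (integer floor) to
the nearest transcription start site, signed along the coordinate axis,
and 0 when a TSS falls inside the region. The midpoint anchor is a
package choice — boundary-anchored distance would differ by half a
region length, negligible at the 100 kb–1 Mb scales of interest.

Distribution comparisons use a Mann–Whitney U test with midrank ties.
The p-value is exact where feasible — the exact null distribution
(`pwilcox`) when there are no ties, full enumeration of label
assignments when ties are present and C(n, n1) ≤ 2·10^5 — and otherwise
a normal approximation with tie-corrected variance. Literal enumeration
is impossible beyond tiny samples (C(40, 20) ≈ 1.4·10^11), so the exact
distribution stands in for it; the two are identical, which the tests
verify by enumeration for n1 + n2 ≤ 10.

## Region–gene association and enrichment

Gene association uses the same midpoint-to-TSS distance with an
inclusive 1 Mb default window; nearest-gene ties break towards the
lexicographically smaller gene id so results are deterministic.

Term enrichment re-implements the basal-plus-extension regulatory-domain
scheme: each gene gets a strand-aware basal window (defaults 5 kb
upstream, 1 kb downstream of the TSS), extended in both directions up to
1 Mb from the TSS but stopping at a neighbour's basal window. The 1 Mb
cap is anchored at the TSS; anchoring at the basal boundary would differ
by at most the basal size (0.6 %), and the choice is recorded here
because descriptions of the scheme are ambiguous on this point. A region
hits a term when its **midpoint** falls inside any domain of a
term-annotated gene. Against the whole-genome background the p-value is
the binomial tail P(X ≥ k) with n regions and hit probability equal to
the fraction of the genome covered by the term's domains; against a
region-set background (e.g. conserved non-coding elements) it is the
hypergeometric tail on hit counts. Multiple testing is
Benjamini–Hochberg across the tested terms. Curated domain exceptions
and mappability corrections used by web services are not reconstructed;
with a toy genome the mappable fraction is 1.

## Functional-genomics overlap

A region hits a (mark, context) peak set on ≥ 1 bp overlap by default; a
minimum-overlap fraction is configurable. Segmentation states are
assigned by per-base majority over the covered part of the region,
pooling segments that share a state, with ties going to the leftmost
covering segment; a region overlapping no segment is "unannotated". The
majority rule subsumes the simpler midpoint rule whenever the region is
covered, and is what a per-base oracle reproduces.

## The two-stage enhancer classifier

`enhancer_finder()` is the package's model object (S3, with `print`,
`summary`, `predict`, `plot`). Stage 1 is a soft-margin SVM (C = 1)
separating developmental enhancers from genomic background; stage 2 fits
a one-vs-rest SVM per tissue (brain, heart, limb, neural tube) on the
labelled positives only — training stage 2 on stage-1 *predictions*
would leak stage-1 errors into the tissue models. A tissue needs at
least 5 positive examples to be trained.

Features come in named blocks and the kernel is a weighted sum of
per-block linear kernels, each trace-normalized (K_b divided by
tr(K_b)/n) so blocks of different dimensionality contribute on a common
scale; weights default to equal. Two numerical choices matter in
practice:

* **Block centering.** Each block is centred on its training means
  before kernel construction (training means are stored and re-applied
  at prediction). k-mer *frequency* vectors share a large constant
  component, and without centering the linear Gram matrix is dominated
  by that rank-one direction, leaving the SVM almost no usable geometry.
* **Class weighting.** Classes are weighted inversely to frequency, so
  the zero decision threshold — which is also the default tissue
  assignment cut-off — stays meaningful under imbalance (stage 2 is
  intrinsically imbalanced one-vs-rest).

The sequence block is a reverse-complement-collapsed k-mer spectrum
(default k = 5, i.e. 512 canonical 5-mers), normalized to frequencies;
windows containing N contribute nothing. Classification windows are a
fixed 1.5 kb centred on the region midpoint (odd widths give the left
flank the shorter half); windows clipped at chromosome ends are
truncated, not N-padded, and flagged. The decision-value sign returned
by the underlying SVM library depends on factor-level order, so the sign
is calibrated after fitting (positives score high) and stored.

`predict()` marks an element an enhancer when the stage-1 decision value
exceeds 0 and assigns every tissue whose stage-2 decision value exceeds
the assignment threshold (default 0) — multiple tissues are allowed, and
an enhancer with no tissue above threshold has an explicitly empty
assignment. Stage-2 assignments never fire on stage-1 negatives.

## TFBS divergence

PWMs (TRANSFAC or MEME minimal input) are normalized per position with a
pseudocount (default 0.01) and scored as log2 odds against a uniform
background (sequence-derived backgrounds are configurable). Scanning
covers both strands; a hit is any window scoring at least a fraction
(default 0.8) of the motif's maximum achievable score. The
fraction-of-max rule is the package's choice in the absence of a
published threshold; note it differs from the common "percentage"
convention that interpolates between the minimum and maximum score.
Windows containing N are skipped rather than scored.

Divergence for a TF is Δ = n_human − n_chimp over equal-length
(pre-aligned, ungapped) ortholog sequences; ncHARs are short and highly
conserved, so ungapped comparison is the default. Significance comes
from a permutation null that re-scatters the observed substitutions
(count and substituted-to bases preserved) uniformly over the chimpanzee
sequence and recomputes Δ, with the add-one estimator
p = (1 + #{|Δ_null| ≥ |Δ_obs|})/(n_perm + 1), so p is never 0 and pairs
without substitutions return p = 1. Significance is reported uncorrected
at α = 0.1 across TFs. Because Δ is integer-valued, the permutation p is
discrete and conservative (super-uniform): its distribution under the
null has an atom at 1 of size P(Δ = 0). Calibration tests therefore
check uniformity of the standard randomized (tie-broken) Monte-Carlo
p-value — exactly U(0,1) for a calibrated test — alongside explicit
super-uniformity bounds on the reported p; `divergence_significance(...,
detail = TRUE)` exposes the null deltas for such studies.

## Prioritization

The published candidate selection was expert curation; the package
replaces it with a declared, deterministic surrogate so the pipeline is
end-to-end runnable: composite = 0.4·minmax(score1) +
0.3·min(n_sig_TFs, 5)/5 + 0.1·[dev gene ≤ 1 Mb] + 0.1·[TF nearest] +
0.1·[DE gene ≤ 1 Mb], ranked descending with lexicographic tie-breaks.
The weights encode that direct enhancer evidence outranks divergence
evidence, which outranks gene-context flags; the cap keeps a single
TF-rich region from dominating. The output is labelled a surrogate;
`select_top()` adds greedy quota satisfaction (e.g. minimum candidates
per predicted tissue) and draws negative controls from the bottom of the
ranking.

## Validation calls

Activity follows the three-embryo rule with human and chimpanzee embryos
pooled: a domain is active at ≥ 3 stained embryos, a construct is an
enhancer at ≥ 1 active domain. Within-domain consistency is
operationalized through `pattern_id` labels — an encoding of the
qualitative within-domain patterns that visual annotation produces; the
package cannot model the visual judgment itself, only its recorded
outcome. High confidence requires ≥ 3 embryos sharing a pattern in every
active domain. A species difference requires, in some domain, ≥ 3
embryos of one species with a consistent pattern and ≥ 3 embryos of the
other species unstained (or consistently stained with a different
pattern), and the construct is only called different when such a domain
is high-confidence in the active species. Limb staining extent is
compared with a two-sample t-test (equal-variance Student by default,
Welch by flag) on per-embryo stained fractions, which are inputs — image
processing is out of scope. Report percentages round half-up to
integers, matching how such cohort figures are conventionally printed.

## The synthetic-data module

Every pipeline input can be generated with planted truth from a single
mandatory seed (`sim_config()`); generators restore the caller's RNG
state, and identical seeds give bit-identical outputs, which the
determinism tests assert end to end (including pipeline manifest
checksums).

What it emulates, and the defaults:

* **Genome**: i.i.d. bases on toy chromosomes (default 2 × 100 kb) —
  large enough for 1 Mb-free interval arithmetic at desk scale while
  keeping the full test suite fast; no repeats, isochores or GC
  structure.
* **Annotations**: 30 genes with three exons (coding middle exon for
  protein-coding genes), mixed gene types, strand-aware TSSs; tag
  fractions 0.15 TF / 0.3 developmental / 0.3 differentially expressed;
  flat term sets. Conserved elements (default 300, lengths ~ N(257,
  171²) nt truncated at 20 — the published length moments of the ncHAR
  cohort) are mutually disjoint and avoid coding exons; accelerated sets
  sample them with a configured inter-set reuse fraction (default 0.3)
  so merging and filtering are genuinely exercised.
* **Training elements**: 1.5 kb windows; positives (default 400/400)
  receive 8 near-consensus instances (per-base fidelity 0.95) of their
  tissue's 2 width-8 motifs — functional binding sites are high-affinity
  instances, and homotypic site clustering is typical of developmental
  enhancers. Marks are simulated per cellular context (3 marks × 4
  tissue-matched contexts): a positive is peak-enriched (rate 0.8) in
  the context matching its tissue and at background rate (0.1)
  elsewhere. This mirrors how tissue information enters the real
  method — through functional genomics across cell types — and it is
  what makes stage 2 learnable; tissue-blind marks would carry no
  tissue signal at any sample size.
* **Genome-embedded enhancers**: a fraction (default 0.3, the scale of
  enhancer prevalence estimated for accelerated regions) of compiled
  regions get motif sites written into the genome around their midpoint
  plus context-matched mark evidence, giving the end-to-end prediction
  stage recoverable truth.
* **Ortholog pairs**: 200 bp sequences with one planted consensus site;
  10 substitutions per pair by default, with a configured fraction of
  pairs receiving one substitution inside the site (a binding-site loss
  on the human branch). Substitutions draw a uniformly random different
  base; transition/transversion structure is not modelled because the
  divergence statistic is count-based.
* **Embryo tables**: per-embryo staining derived from construct truth
  with an independent per-domain flip probability; at noise 0 calls
  equal truth. The packaged 29-construct fixture is this generator at
  noise 0 with a truth table built so the cohort totals match the
  published assay summary; the per-embryo composition is synthetic
  (flagged in the filename) because per-embryo data are not published.

Passing recovery tests on these data shows the implementation is
correct and calibrated under the generator's assumptions — short,
motif-driven signals in i.i.d. background with context-matched marks.
It does not show that real enhancers are this separable: real sequence
background is repetitive and compositionally structured, real marks are
noisier and correlated across contexts, and VISTA-style labels are
themselves imperfect.

## Problem sizes and runtime choices

Tests run at deliberately small scale: 100 kb toy chromosomes for
interval oracles, 500 bp sequences for scanning oracles, 400/400
elements for classifier recovery (five-fold CV), 200 held-out elements
for tissue recall, 500 pairs × 199 permutations for calibration, and 50
replicates for binding-site-loss recovery. These sizes keep the suite
minutes-scale while leaving the statistical assertions comfortable
margins; all of them are configurable upwards through `sim_config()`.

## Known limitations

* Genome-scale published counts (e.g. cohort sizes, genome-wide overlap
  tallies) depend on external resources (published region sets, genome
  annotation releases, ENCODE peak calls, TRANSFAC) and are not
  reproduced; the package reproduces procedures and desk-scale
  worked-example totals.
* The divergence test's permutation null is this package's explicit
  construction; the originally cited divergence model is not described
  in enough detail to re-implement.
* GO term structure is flat — no DAG propagation.
* No liftOver: all inputs must share one assembly.
* The composite prioritization score is a documented surrogate for what
  was originally expert curation.
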