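---
title: "Context-dependent substitution dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent substitution dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxsub)
```

## The inference model

`ctxsub` studies how the two flanking bases on each side of a nucleotide
site — the tetranucleotide context, written `L2L1.R1R2` 5'→3' on the strand
carrying the site — shape substitution rates and their long-run
compositional consequences, contrasting fourfold-degenerate (FFD) third
codon positions with intergenic noncoding (NC) sites.

Substitutions are inferred from **triplets** of closely related homologous
sequences. Each non-reference member is globally aligned to the reference
member with affine gap penalties (match 2, mismatch −1, gap open −2, gap
extend −0.5, a gap of length L costing `open + extend·(L−1)`), and the two
pairwise alignments are merged on reference coordinates; any locus whose
merged alignment carries more than 30 gap characters is excluded. A column
is scored only when the focal base and the four flanking bases are present
(no gaps, no ambiguity codes) and the flank is identical in all three
members, so the context of every observation is unambiguous. Scoring uses
two-agree parsimony: three identical bases contribute one conserved
(diagonal) observation per lineage; when exactly two agree, the shared base
is ancestral and the odd member carries one substitution event (the only
configuration in a triplet whose direction is assignable without an
outgroup); three-way disagreements are skipped. Multiple hits are ignored —
the analysis is built for the low-divergence regime (~0.08 substitutions
per site per triplet), where they are rare.

FFD columns are third codon positions whose conserved 5' dinucleotide is
one of the eight FFD codon-family prefixes. Codon position is the 1-based
alignment column index modulo 3 from the CDS anchor, **gaps included**:
this operationalises the assumption that alignment gaps do not disrupt the
reading frame. The alternative (counting ungapped reference positions)
differs only at loci that survive the 30-gap filter with frame-shifting
indels, which the filter makes rare; the gaps-included rule was chosen as
the more literal reading of that assumption.

Counts accumulate into one 4 × 4 matrix per context and site class. Because
substitution chemistry is strand-symmetric at the level of double-stranded
DNA, each context's matrix is merged with the complement-relabelled matrix
of its reverse-complement context (`combined(c) = M(c) +
relabel(M(revcomp(c)))`). The combined matrices of a complement pair are
exact relabel-images, so analyses keep one matrix per complement class —
128 coding-strand FFD contexts extend to a 192-context combined universe in
100 classes. The additivity convention above makes combined totals exactly
double the single-strand totals; published combined totals produced by
other conventions (e.g. partial exclusion rules) need not match ours, and
we do not force them.

## From counts to equilibria

Row-normalising a count matrix gives a Markov transition matrix; its
stationary vector π (`πP = π`, `Σπ = 1`) is the base composition those
sites would reach if the context's dynamics ran indefinitely. π is found by
solving the linear system with the unit-sum constraint, cross-checked
against the eigen-decomposition (disagreement beyond 1e−6 is an error);
uniqueness is verified by the null-space dimension of `Pᵀ − I` (singular
values below 1e−8). Reducible chains — possible in sparse synthetic
matrices — are flagged and excluded rather than silently resolved, though a
unique limiting distribution with absorbing states (e.g. π = (1,0,0,0)) is
reported. Rows with zero observations make the matrix unusable for
equilibrium analysis and are flagged. Emitted equilibria satisfy `πP = π`
within 1e−8.

Sampling error of the equilibrium A+T content is estimated by the
row-conditional bootstrap: each resample keeps every diagonal and every
row's off-diagonal total, redrawing the allocation of that row's
substitutions across its three off-diagonal cells with replacement
(multinomial with probabilities proportional to the observed cells);
default 1000 resamples. Each context draws from its own RNG stream derived
from the root seed and the context label, so results do not depend on
iteration order. Note what this bootstrap conditions on: it captures
*where* a row's substitutions go, not *how many* there are, so it slightly
understates the full sampling variance of the equilibrium. Matrices with
fewer than 10 substitutions (configurable) are flagged sparse and excluded
from comparative statistics.

## Comparative layers

Paired FFD/NC values per context (rates per base, class rates, equilibrium
A+T, skews) are summarised by the proportion of contexts in which the FFD
value is higher (ties count as "not higher" and are reported separately —
they are measure-zero on real counts), the mean relative excess in each
direction, and the squared Pearson correlation on untransformed values
(the natural scale on which the results are plotted against the equality
line). Proportions get a Bayes factor against an even split: point null
p = 0.5 versus p ~ Beta(1, 1), `BF = [B(k+1, n−k+1)/B(1,1)]/0.5ⁿ`. The
uniform prior is the simplest reading of "equal probability either type is
higher"; published Bayes factors computed with unspecified priors are not
reproducible from this form and are not asserted anywhere.

The six-way class breakdown groups off-diagonals by weak/strong base
classes (W = {A,T}, S = {C,G}) and transition/transversion status; a class
rate divides the class's events by the total observations of its source
bases.

The CG (CpG deamination) effect is a 2 × 2 odds ratio: focal substitution
(C→T with a 3' G, or equivalently G→A with a 5' C on the other strand)
versus all other outcomes of the same rows, in CG versus non-CG contexts.
Only the inner neighbour defines the contrast; outer bases are ignored. On
complement-combined matrices the two framings tabulate the same events and
give identical odds ratios; on single-strand matrices they differ by strand
asymmetry of the sample. `exclude_cg()` drops the C row of contexts with
R1 = G and the G row of contexts with L1 = C — both strand framings of a CG
dinucleotide containing the site — so comparisons can be rerun without the
CG signal.

Hexanucleotide-weighted predictions ask whether FFD/NC differences are
explained by different occupancy of the wider context: for each FFD
tetranucleotide context, `AT_w` (and per-base `R_w`) is the average of the
NC values over the 16 outer-pair extensions, weighted by the observed
hexanucleotide frequencies at FFD sites in genes. Contexts missing any of
their 16 NC extensions are skipped with a warning; contexts never observed
in the gene input fall back to uniform weights with a warning.

## The synthetic generator

The simulator provides the statistical structure the inference assumes, so
every stage can be validated by parameter recovery. Its defaults are the
study conditions:

- equilibrium A+T 0.7 (the A+T-rich regime of plastid DNA);
- transition:transversion 2:1 (HKY-like exchangeabilities);
- strand-symmetric: `model(context) = relabel(model(revcomp(context)))`;
- per-context log-normal rate factors, `sdlog = 0.5`, mirrored across
  complements — a realistic order of context modulation;
- branch lengths 0.08/3 per lineage, anchoring the ~0.08 substitutions per
  site per triplet regime;
- optional CG boost multiplying C→T with a 3' G (and its strand mirror).

Evolution is sweep-based: per-site Bernoulli draws with the site's current
context, contexts frozen within a sweep and re-evaluated between sweeps,
with the branch split into enough sweeps that no row's per-sweep
substitution probability exceeds 0.02. This matches the single-hit regime
the analysis assumes while letting contexts co-evolve; it is not an exact
continuous-time simulation, which the low-rate regime does not require.
The event log is complete — replaying it on the ancestor reproduces each
descendant exactly — and every lineage draws from a named substream of the
root seed. The generator plants no indels (single-base deletions are
available separately for alignment tests), emulates no selection,
rate-across-loci variation beyond the context factors, or ambiguity codes;
passing recovery tests therefore demonstrates correctness of the
inference machinery under its own assumptions, not robustness to
everything real data can contain.

NC fixture matrices (tetranucleotide and hexanucleotide) are drawn
multinomially from the model at a chosen depth; the hexanucleotide fixture
splits each tetranucleotide cell uniformly across the 16 extensions, so it
marginalises exactly to the tetranucleotide fixture while its per-extension
matrices vary stochastically.

## Validation design and known limitations

Recovery checks compare pipeline output against the planted model in units
of sampling error. Conditional substitution proportions (per ancestral row,
within contexts holding at least 200 planted events) use the 3-multinomial-SE
band, applied only to rows with at least 30 inferred events — below that
the normal approximation behind the SE band is unreliable. Equilibrium A+T
uses the ±3 bootstrap-SD band. Problem sizes: a 100 kb triplet at 0.02
substitutions/site per lineage for the proportion and equilibrium checks,
chosen so a handful of contexts qualify and the family of simultaneous
3-sigma checks stays small.

The CG-boost check needs a different design. The pooled odds ratio over CG
versus non-CG contexts has two error components: counting noise, which
shrinks with sequence length, and a model-lottery offset from the random
per-context factors (CG contexts may simply draw hotter or colder factors),
which does not shrink. The CG recovery simulation therefore plants *only*
the CG modulation (`context_sdlog = 0`) on a 600 kb triplet (over 400k
scored C observations), where the odds ratio's expectation is the planted
boost and the band reflects counting noise alone.

Two biases are worth knowing about. First, parallel substitutions in two
lineages defeat two-agree parsimony: the derived base wins the vote and the
event is inferred in the wrong direction on the third lineage. The effect
is quadratic in branch length and enriched for the fastest substitution
types, which slightly inflates their reverse rates and pulls equilibria
toward the ancestral composition; at 0.02 substitutions/site per branch it
is detectable but sits within the bootstrap bands used here. For the same
reason the count of inferred events approaches the planted count only in a
genuinely low-rate regime — flank-conservation requirements discard a
noticeable share of events at higher divergence. Second, as noted above,
the row-conditional bootstrap understates full sampling variance; its SD
is the uncertainty measure used throughout because it is the estimator the
analysis defines, not because it is a complete error model.

Numerical conventions: coordinates are 0-based half-open internally and
1-based in reports; context labels serialise as `L2L1.R1R2`; canonical
complement-class representatives are the lexicographically smaller label;
alignment tie-breaks are delegated to the deterministic traceback of the
underlying aligner, so equal-scoring alignments resolve identically across
runs and platforms; all tabular artifacts are TSV with headers, with JSON
sidecar manifests recording inputs, parameters, seed, version and counts.

## Input formats

Triplets enter as a TSV manifest with inline sequences (`seq1..seq3`) or
as FASTA files referenced by record id (`file`, `id1..id3`), typed
`coding` (frame-anchored; only FFD columns scored) or `noncoding` (all
scoreable columns; optional CDS boundary coordinates yield the NC30
subset, sites within 30 nt of a start/stop boundary). Annotated-flat-file
parsing is out of scope: sequences are expected pre-extracted, which keeps
the package's input surface to standard FASTA/TSV.
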