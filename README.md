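# ctxsub

Context-dependent substitution analysis of coding and noncoding DNA.

## The problem

In A+T-rich plastid genomes, the rate and direction of nucleotide
substitution depend strongly on the immediately flanking bases. `ctxsub`
implements the comparative machinery for studying that dependence at two
classes of putatively neutral sites:

- **FFD sites** — fourfold-degenerate third codon positions (codon families
  CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN, i.e. 5' prefixes
  `{CT, GT, TC, CC, AC, GC, CG, GG}`);
- **NC sites** — intergenic noncoding positions, with an **NC30** subset
  within 30 nt of an annotated CDS start or stop codon.

Substitutions are inferred from triplets of closely related homologous
sequences by two-agree parsimony, conditioned on the tetranucleotide
context {N₂N₁[N₀]N₁N₂} being conserved and gap-free in all three members.
Because the genetic code forbids an FFD site from having a 5' A, there are
8 × 16 = 128 coding-strand FFD contexts; adding reverse complements gives a
192-context combined universe that collapses into 100
complement-equivalence classes.

For every context the package accumulates a 4 × 4 count matrix (rows =
ancestral base; off-diagonals = substitutions, diagonal = conserved
site-lineage observations), row-normalises it into a Markov transition
matrix P, and solves the stationary vector π (πP = π, Σπ = 1). From π come
the predicted equilibrium A+T content (π_A + π_T) and the compositional
skews (A−T)/(A+T) and (G−C)/(G+C); a row-conditional bootstrap (1000
resamples redrawing each row's off-diagonal allocation) gives the sampling
error of the equilibrium A+T. Comparative layers pair FFD and NC results
per context: proportions of contexts with the higher FFD value (with
Beta-binomial Bayes factors against an even split), r², the six-way
substitution-class breakdown (W↔S transitions/transversions, W = {A,T},
S = {C,G}), hexanucleotide-weighted predictions (AT_w, R_w), and the CpG
deamination (CG) effect measured as a 2 × 2 odds ratio of C→T within CG
dinucleotides versus elsewhere.

A neighbour-dependent evolution simulator (strand-symmetric, A+T-biased,
transition-biased, log-normal per-context rate factors, optional CG boost)
generates triplets under a known model so that every stage is verifiable by
parameter recovery — no external data needed.

## Worked example

```r
library(ctxsub)
library(dplyr)

length(enumerate_ffd_contexts())
#> [1] 128
u <- combined_context_universe()
length(u$contexts); nrow(u$classes)
#> [1] 192
#> [1] 100

## CG-effect odds ratio from a 2x2 table (G -> A vs everything else
## observed from G, in CG vs DG contexts)
cg_odds_ratio(34376, 304753, 55100, 699456)
#> # A tibble: 1 × 5
#>       a      b     c      d odds_ratio
#>   <dbl>  <dbl> <dbl>  <dbl>      <dbl>
#> 1 34376 304753 55100 699456       1.43

## simulate a 50 kb triplet under a known context-dependent model with a
## planted 1.4x CG boost, then run the inference pipeline on it
model <- evolution_model(seed = 1, cg_boost = 1.4)
trip  <- make_triplet(model, 50000, seed = 1)
aln   <- as_triplet_alignment(trip$descendants)
scored   <- infer_substitutions(aln, seq_len(50000), site_class = "NC")
counts   <- accumulate_counts(scored$events, scored$diagonals)
combined <- combine_complements(counts)

eq <- equilibrium_profile(filter(combined, context == class),
                          bootstrap_n = 200, seed = 1)
select(as_tibble(eq), context, n_subs, AT_eq, AT_boot_sd, skew_AT, flag) |> head(4)
#> # A tibble: 4 × 6
#>   context n_subs AT_eq AT_boot_sd  skew_AT flag
#>   <chr>    <int> <dbl>      <dbl>    <dbl> <chr>
#> 1 AA.AA       55 0.748     0.0400  0.00890 ok
#> 2 AA.AC       39 0.631     0.0593 -0.351   ok
#> 3 AA.AG       18 0.671     0.0819 -0.0674  ok
#> 4 AA.AT      140 0.626     0.0234 -0.159   ok

cg_effect(select(combined, -class))
#> # A tibble: 2 × 6
#>   framing     a     b     c     d odds_ratio
#>   <chr>   <dbl> <dbl> <dbl> <dbl>      <dbl>
#> 1 C_row      87  4638   463 27281       1.11
#> 2 G_row      87  4638   463 27281       1.11
```

Per-context equilibria land around the model's A+T-biased equilibrium
(~0.70) with bootstrap SDs reflecting the handful of substitutions per
context at this genome size. The CG odds ratio is unbiased but imprecise at
50 kb (87 focal events here); the acceptance script below measures it at
600 kb, where it concentrates near the planted 1.4.

The same analysis runs as a plain-file pipeline with TSV/JSON artifacts and
per-stage manifests:

```r
cfg <- run_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)   # simulate -> count -> combine -> equilibrium ->
                    # compare -> cgeffect -> weights
```

`compare_contexts()` objects support `tidy()`, `glance()` and
`autoplot()`; `equilibrium_profile()` tibbles have an `autoplot()` method;
`plot_class_breakdown()` charts the six-class FFD-vs-NC proportions.

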