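test_that("FFD columns require frame position and a conserved FFD prefix", {
  aln <- as_triplet_alignment(rep("GGATTTCCG", 3))
  ## codon 1 (GG-) and codon 3 (CC-) qualify; TT- is not an FFD prefix
  expect_identical(identify_ffd_columns(aln), c(3L, 9L))
  ## a 5' dinucleotide differing between members disqualifies the column
  aln2 <- as_triplet_alignment(c("GGATTTCCG", "GCATTTCCG", "GGATTTCCG"))
  expect_identical(identify_ffd_columns(aln2), 9L)
  ## second-position A (prefix TA) can never be FFD
  aln3 <- as_triplet_alignment(rep("TAGTAGTAG", 3))
  expect_identical(identify_ffd_columns(aln3), integer())
})

test_that("two-agree parsimony scores events and conserved tallies", {
  ## column 3: (T,T,G) within conserved flank CC..AA -> event on lineage 3
  aln <- as_triplet_alignment(c("CCTAAGCC", "CCTAAGCC", "CCGAAGCC"))
  sc <- infer_substitutions(aln, 1:8, site_class = "NC")
  expect_identical(nrow(sc$events), 1L)
  ev <- sc$events
  expect_identical(ev$context, "CC.AA")
  expect_identical(ev$ancestral, "T")
  expect_identical(ev$derived, "G")
  expect_identical(ev$lineage, 3L)
  ## agreeing lineages at the event column add 2 diagonal observations;
  ## fully conserved column 6 (G within AA..CC) adds 3
  d <- sc$diagonals
  expect_identical(sum(d$n[d$column == 3]), 2L)
  expect_identical(sum(d$n[d$column == 6]), 3L)

  ## all-different columns are skipped
  aln2 <- as_triplet_alignment(c("CCTAAGCC", "CCAAAGCC", "CCGAAGCC"))
  sc2 <- infer_substitutions(aln2, 1:8, site_class = "NC")
  expect_identical(nrow(sc2$events), 0L)
  expect_false(3 %in% sc2$diagonals$column)
})

test_that("no event or tally is scored at gapped or non-conserved-flank columns", {
  set.seed(11)
  model <- evolution_model(seed = 2)
  tr <- make_triplet(model, 3000, seed = 8)
  seqs <- tr$descendants
  seqs[2] <- delete_bases(seqs[2], 4, seed = 9)
  aln <- align_triplet(seqs, locus = "gappy")
  sc <- infer_substitutions(aln, seq_len(ncol(aln$mat)), site_class = "NC")
  cols <- c(sc$events$column, sc$diagonals$column)
  M <- aln$mat
  for (cc in unique(cols)) {
    win <- M[, (cc - 2):(cc + 2)]
    expect_false(any(win == "-"))
    flank <- win[, c(1, 2, 4, 5)]
    expect_true(all(flank[1, ] == flank[2, ] & flank[2, ] == flank[3, ]))
  }
})

test_that("accumulated matrices conserve event counts and reject bad contexts", {
  model <- evolution_model(seed = 5)
  tr <- make_triplet(model, 20000, seed = 4)
  aln <- as_triplet_alignment(tr$descendants)
  sc <- infer_substitutions(aln, seq_len(20000), site_class = "NC")
  counts <- accumulate_counts(sc$events, sc$diagonals)
  offd <- context_totals(counts)
  expect_identical(sum(offd$n_subs), nrow(sc$events))
  ## independent recount straight from the event list
  by_ctx <- table(sc$events$context)
  for (ctx in names(by_ctx)) {
    expect_identical(offd$n_subs[offd$context == ctx], as.integer(by_ctx[[ctx]]))
  }
  bad <- sc$events
  bad$context[1] <- "XX.YY"
  expect_error(accumulate_counts(bad, sc$diagonals), "invalid contexts")
})

test_that("noncoding sites are classified by CDS proximity", {
  res <- classify_nc_sites(c(110, 131), cds_boundaries = 100)
  expect_identical(res$nc30, c(TRUE, FALSE))   # 10 nt in, 31 nt out
  expect_identical(res$site_class, c("NC", "NC"))
  expect_warning(res2 <- classify_nc_sites(5, NULL), "NC30 unavailable")
  expect_true(is.na(res2$nc30))
})

test_that("complement combination equals a both-strand recount", {
  model <- evolution_model(seed = 3)
  tr <- make_triplet(model, 30000, seed = 12)
  aln <- as_triplet_alignment(tr$descendants)
  sc <- infer_substitutions(aln, seq_len(30000), site_class = "NC")
  counts <- accumulate_counts(sc$events, sc$diagonals)
  combined <- combine_complements(counts)

  ## oracle: score the reverse-complement strand independently and add
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  aln_rc <- as_triplet_alignment(unname(vapply(tr$descendants, rc, character(1))))
  sc_rc <- infer_substitutions(aln_rc, seq_len(30000), site_class = "NC")
  counts_rc <- accumulate_counts(sc_rc$events, sc_rc$diagonals)

  for (ctx in unique(combined$context)) {
    fwd <- counts_matrix(counts, ctx, "NC")
    rev <- counts_matrix(counts_rc, ctx, "NC")
    expect_equal(counts_matrix(combined, ctx, "NC"), fwd + rev, info = ctx)
  }
  ## additivity of totals: combined totals double the single-strand totals
  expect_identical(sum(context_totals(combined)$n_subs),
                   2L * sum(context_totals(counts)$n_subs))

  ## combined matrices of a complement pair are exact relabel-images
  for (ctx in sample(unique(combined$context), 20)) {
    expect_equal(counts_matrix(combined, ctx, "NC"),
                 relabel_complement(counts_matrix(combined, revcomp_context(ctx), "NC")),
                 info = ctx)
  }
})

test_that("self-complementary contexts merge with their own relabelled image", {
  ## one A->G event in CT.AG (revcomp(CT.AG) = CT.AG)
  ev <- tibble::tibble(
    locus = "L", column = 3L, ref_pos = 3L, site_class = "NC",
    context = "CT.AG", ancestral = "A", derived = "G", lineage = 1L
  )
  dg <- ev[0, c("locus", "column", "ref_pos", "site_class", "context")]
  dg$base <- character(); dg$n <- integer()
  counts <- accumulate_counts(ev, dg)
  combined <- combine_complements(counts)
  m <- counts_matrix(combined, "CT.AG", "NC")
  expect_identical(m["A", "G"], 1)   # original
  expect_identical(m["T", "C"], 1)   # relabelled image of the same event
  expect_identical(sum(m), 2)
})

test_that("count_triplets integrates alignment, filtering and NC30 splitting", {
  model <- evolution_model(seed = 9)
  sim <- simulate_triplet_set(model, 4, 600, seed = 21, coding = FALSE)
  loci <- sim$loci
  loci$cds_boundaries <- rep(list(c(0, 601)), nrow(loci))
  res <- count_triplets(loci, align = FALSE)
  expect_setequal(unique(res$counts$site_class), c("NC", "NC30"))
  tot <- context_totals(res$counts)
  n_nc <- sum(tot$n_obs[tot$site_class == "NC"])
  n_nc30 <- sum(tot$n_obs[tot$site_class == "NC30"])
  expect_lt(n_nc30, n_nc)
  expect_gt(n_nc30, 0)
  ## NC30 observations come only from columns within 30 nt of a boundary
  ev30 <- res$events[res$events$site_class == "NC30", ]
  expect_true(all(pmin(abs(ev30$ref_pos - 0), abs(ev30$ref_pos - 601)) <= 30))

  ## a locus whose alignment exceeds 30 gaps is excluded
  loci2 <- sim$loci[1:2, ]
  loci2$seq2[1] <- delete_bases(loci2$seq2[1], 35, seed = 5)
  res2 <- count_triplets(loci2, align = TRUE)
  expect_identical(res2$excluded, loci2$locus[1])
})
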