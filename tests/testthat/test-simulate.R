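test_that("ancestors honour composition and coding structure", {
  expect_identical(sample_ancestor(50, c(A = 1, C = 0, G = 0, T = 0), seed = 1),
                   strrep("A", 50))
  cod <- sample_ancestor(300, coding = TRUE, seed = 2)
  codons <- substring(cod, seq(1, 298, by = 3), seq(3, 300, by = 3))
  expect_true(all(substr(codons, 1, 2) %in% ffd_prefixes()))
  ## law of large numbers: 100 kb empirical composition within 3 binomial SD
  comp <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  s <- sample_ancestor(1e5, comp, seed = 3)
  obs <- table(factor(strsplit(s, "")[[1]], levels = names(comp))) / 1e5
  se <- sqrt(comp * (1 - comp) / 1e5)
  expect_true(all(abs(obs - comp) <= 3 * se))
  expect_error(sample_ancestor(10, c(A = 0.5, C = 0.6, G = 0, T = 0)),
               "composition")
})

test_that("evolution is seeded, logged, and replayable", {
  model <- evolution_model(seed = 4)
  anc <- sample_ancestor(5000, model$composition, seed = 5)
  ## zero branch length: no change, empty log
  still <- evolve_sequence(anc, model, 0, seed = 6)
  expect_identical(still$sequence, anc)
  expect_identical(nrow(still$events), 0L)
  ev <- evolve_sequence(anc, model, 0.05, seed = 6)
  expect_gt(nrow(ev$events), 0)
  expect_identical(replay_events(anc, ev$events), ev$sequence)
  ## determinism
  ev2 <- evolve_sequence(anc, model, 0.05, seed = 6)
  expect_identical(ev2$sequence, ev$sequence)
  ## terminal bases (no full context) never substitute
  expect_false(any(ev$events$site %in% c(1, 2, 4999, 5000)))
})

test_that("substitution draws match the planted single-context probability", {
  ## a model that substitutes only A -> G, only within the AA.AA context
  model <- evolution_model(seed = 7)
  model$probs[] <- 0
  cid <- match("AA.AA", model$contexts)
  model$probs[cid, 1, 3] <- 1
  model$row_total <- apply(model$probs, c(1, 2), sum)
  anc <- strrep("A", 50000)
  ev <- evolve_sequence(anc, model, 0.05, seed = 8)
  expect_true(all(ev$events$from == "A" & ev$events$to == "G"))
  ## eligible sites: interior A's in an all-A neighbourhood at sweep 1;
  ## overall expected frequency 0.05 per eligible site (across sweeps)
  n_eligible <- 50000 - 4
  p <- 0.05
  se <- sqrt(p * (1 - p) / n_eligible)
  ## events at sites whose context decayed after earlier hits stop, so the
  ## realised frequency undershoots slightly; allow 3 SE around the mean
  expect_lt(abs(nrow(ev$events) / n_eligible - p), 3 * se + 0.002)
})

test_that("strand-symmetric models are relabel-invariant and CG boost targets CG", {
  model <- evolution_model(seed = 9, cg_boost = 1.4)
  perm <- match(complement_base(BASES4), BASES4)
  for (ctx in c("AA.AA", "CT.AG", "GC.TA", "TT.GC")) {
    i <- match(ctx, model$contexts)
    j <- match(revcomp_context(ctx), model$contexts)
    expect_equal(model$probs[i, , ], model$probs[j, perm, perm],
                 tolerance = 1e-12, info = ctx)
  }
  ## C->T boosted iff R1 = G, relative to an unboosted twin model
  plain <- evolution_model(seed = 9, cg_boost = 1)
  iC <- match("C", BASES4); iT <- match("T", BASES4)
  cg_ctx <- match("AC.GA", model$contexts)    # R1 = G
  ch_ctx <- match("AC.AA", model$contexts)
  ratio_cg <- model$probs[cg_ctx, iC, iT] / plain$probs[cg_ctx, iC, iT]
  ratio_ch <- model$probs[ch_ctx, iC, iT] / plain$probs[ch_ctx, iC, iT]
  ## both models renormalise to one substitution/site per branch unit, so
  ## the boost appears as a 1.4-fold ratio between the two context ratios
  expect_equal(ratio_cg / ratio_ch, 1.4, tolerance = 1e-9)
})

test_that("triplets attribute lineages and recover planted counts at low rates", {
  model <- evolution_model(seed = 10, branch_lengths = c(0, 0, 0.03))
  tr <- make_triplet(model, 30000, seed = 11)
  expect_identical(tr$descendants[1], tr$ancestor)
  expect_identical(tr$descendants[2], tr$ancestor)
  sc <- infer_substitutions(as_triplet_alignment(tr$descendants),
                            seq_len(30000), "NC")
  expect_true(all(sc$events$lineage == 3L))

  ## low-rate regime: inferred events within 10% of planted events
  model2 <- evolution_model(seed = 12, branch_lengths = rep(0.002, 3))
  tr2 <- make_triplet(model2, 100000, seed = 13)
  sc2 <- infer_substitutions(as_triplet_alignment(tr2$descendants),
                             seq_len(100000), "NC")
  expect_lt(abs(nrow(sc2$events) - nrow(tr2$events)) / nrow(tr2$events), 0.10)
})

test_that("fixture matrices marginalise and recover the model equilibrium", {
  model <- evolution_model(seed = 14, context_sdlog = 0.3)
  fix <- make_nc_fixture(model, depth = 1e5, seed = 15)
  ## hexanucleotide fixture marginalises exactly to the tetranucleotide one
  hex_marg <- fix$hex |>
    dplyr::group_by(site_class, context, ancestral) |>
    dplyr::summarise(dplyr::across(c(A, C, G, T), sum), .groups = "drop") |>
    dplyr::arrange(context, ancestral)
  expect_equal(as.data.frame(hex_marg),
               as.data.frame(fix$tetra |> dplyr::select(names(hex_marg))))

  ## stationary vector of the fixture transition matrix is within 3 SE of
  ## the ground truth (multinomial delta method for the full-row sampling)
  set.seed(16)
  for (ctx in sample(model$contexts, 12)) {
    m <- counts_matrix(fix$tetra, ctx, "NC")
    at_hat <- sum(stationary_vector(to_transition_matrix(m)$P)[c("A", "T")])
    at_true <- fix$truth$AT_eq[fix$truth$context == ctx]
    se <- oracle_at_delta_sd(m)
    expect_true(abs(at_hat - at_true) < 3 * se + 1e-6, info = ctx)
  }
})

test_that("class scaling rebalances exactly the targeted substitution class", {
  base <- evolution_model(seed = 18)
  up <- scale_model_classes(base, "W->W", 2)
  iA <- 1; iT <- 4; iG <- 3
  expect_equal(up$probs[, iA, iT] / base$probs[, iA, iT], rep(2, 256))
  expect_equal(up$probs[, iT, iA] / base$probs[, iT, iA], rep(2, 256))
  expect_equal(up$probs[, iA, iG], base$probs[, iA, iG])
  ## restricting by type leaves the other type untouched
  ti_only <- scale_model_classes(base, "S->W", 3, type = "transition")
  iC <- 2
  expect_equal(ti_only$probs[, iC, iT] / base$probs[, iC, iT], rep(3, 256))
  expect_equal(ti_only$probs[, iC, iA], base$probs[, iC, iA])
})
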