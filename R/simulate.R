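## context index arithmetic: contexts are indexed 1..256 by
## ((l2-1)*4 + (l1-1))*16 + (r1-1)*4 + (r2-1) + 1 with bases coded A=1..T=4
ctx_index <- function(l2, l1, r1, r2) {
  ((l2 - 1L) * 4L + (l1 - 1L)) * 16L + (r1 - 1L) * 4L + (r2 - 1L) + 1L
}

ctx_index_labels <- function() {
  g <- expand.grid(r2 = 1:4, r1 = 1:4, l1 = 1:4, l2 = 1:4)
  lab <- character(256)
  lab[ctx_index(g$l2, g$l1, g$r1, g$r2)] <-
    ctx_label(BASES[g$l2], BASES[g$l1], BASES[g$r1], BASES[g$r2])
  lab
}

#' Construct a context-dependent neighbour-modulated substitution model
#'
#' The ground-truth model for the simulator: per-context 4 x 4 per-site
#' substitution probabilities. The base process is HKY-like — strand
#' symmetric, with an A+T-biased equilibrium and a transition:transversion
#' preference — multiplied by a log-normal per-context factor (mirrored
#' across reverse complements when `strand_symmetric`) and an optional CG
#' boost on C -> T when the 3' neighbour is G (and, symmetrically, on
#' G -> A when the 5' neighbour is C). Probabilities are scaled so that one
#' branch-length unit corresponds to one expected substitution per site for
#' an i.i.d. sequence at the ancestral composition.
#'
#' @param seed Integer seed for the per-context factors.
#' @param branch_lengths Expected substitutions per site on the three
#'   lineages (default `c(0.0267, 0.0267, 0.0267)`, so a triplet accumulates
#'   about 0.08 substitutions per site in total).
#' @param at_eq Equilibrium A+T content of the base process (default 0.7,
#'   the A+T-rich regime of chloroplast DNA).
#' @param titv Transition:transversion rate ratio (default 2).
#' @param context_sdlog Log-normal standard deviation of the per-context
#'   rate factors (default 0.5).
#' @param cg_boost Multiplier on C -> T with a 3' G (and its strand mirror);
#'   default 1 (no CG effect).
#' @param strand_symmetric Mirror context factors across reverse
#'   complements so that `model(context) = relabel(model(revcomp(context)))`.
#' @return An object of class `evolution_model`: list with `probs`
#'   (256 x 4 x 4 array, unit branch scale, zero diagonal), `row_total`
#'   (256 x 4), `contexts`, `composition`, `branch_lengths`, `cg_boost`,
#'   `strand_symmetric`, `seed`.
#' @export
evolution_model <- function(seed = 1L, branch_lengths = rep(0.08 / 3, 3),
                            at_eq = 0.7, titv = 2, context_sdlog = 0.5,
                            cg_boost = 1, strand_symmetric = TRUE) {
  stopifnot(length(branch_lengths) == 3L, all(branch_lengths >= 0),
            at_eq > 0, at_eq < 1, titv > 0, cg_boost > 0)
  pi0 <- setNames(c(at_eq / 2, (1 - at_eq) / 2, (1 - at_eq) / 2, at_eq / 2),
                  BASES)
  ## HKY exchange: q_ij = kappa_ij * pi_j, kappa = titv for transitions
  Q <- outer(rep(1, 4), unname(pi0))
  diag(Q) <- 0
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (k in seq_len(nrow(transitions))) {
    i <- match(transitions[k, 1], BASES); j <- match(transitions[k, 2], BASES)
    Q[i, j] <- Q[i, j] * titv
  }

  labels <- ctx_index_labels()
  old <- .Random.seed_exists()
  set.seed(as.integer(seed %% 2147483629))
  on.exit(restore_seed(old), add = TRUE)
  fac <- stats::rlnorm(256, meanlog = 0, sdlog = context_sdlog)
  if (strand_symmetric) {
    canon <- canonical_context(labels)
    fac <- fac[match(canon, labels)]
  }

  probs <- array(0, dim = c(256, 4, 4))
  for (c_id in 1:256) probs[c_id, , ] <- Q * fac[c_id]
  if (cg_boost != 1) {
    r1 <- substr(labels, 4L, 4L)
    l1 <- substr(labels, 2L, 2L)
    iC <- match("C", BASES); iG <- match("G", BASES)
    iT <- match("T", BASES); iA <- match("A", BASES)
    probs[r1 == "G", iC, iT] <- probs[r1 == "G", iC, iT] * cg_boost
    probs[l1 == "C", iG, iA] <- probs[l1 == "C", iG, iA] * cg_boost
  }
  ## scale: one branch unit = one expected substitution per site for an
  ## i.i.d. ancestor at pi0
  p_ctx <- numeric(256)
  g <- expand.grid(r2 = 1:4, r1 = 1:4, l1 = 1:4, l2 = 1:4)
  p_ctx[ctx_index(g$l2, g$l1, g$r1, g$r2)] <-
    pi0[g$l2] * pi0[g$l1] * pi0[g$r1] * pi0[g$r2]
  row_total <- apply(probs, c(1, 2), sum)
  mean_rate <- sum(p_ctx * (row_total %*% unname(pi0)))
  probs <- probs / mean_rate
  row_total <- row_total / mean_rate

  structure(
    list(probs = probs, row_total = row_total, contexts = labels,
         composition = pi0, branch_lengths = branch_lengths,
         cg_boost = cg_boost, strand_symmetric = strand_symmetric,
         seed = seed),
    class = "evolution_model"
  )
}

#' Scale a substitution class of an evolution model
#'
#' Multiplies the model's substitution probabilities for one base-class
#' pair (optionally restricted to transitions or transversions) by a
#' constant, in every context. Substitution classes are complement-closed,
#' so strand symmetry is preserved. Used to plant class-specific rate
#' differences between site types (e.g. a W->W excess in noncoding
#' regions).
#'
#' @param model An `evolution_model`.
#' @param class_pair One of `"W->W"`, `"W->S"`, `"S->W"`, `"S->S"`.
#' @param factor Positive multiplier.
#' @param type Optional `"transition"` or `"transversion"` restriction.
#' @return The modified `evolution_model`.
#' @export
scale_model_classes <- function(model, class_pair, factor, type = NULL) {
  stopifnot(inherits(model, "evolution_model"), factor > 0)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      cl <- classify_substitution(BASES[i], BASES[j])
      if (cl$class_pair != class_pair) next
      if (!is.null(type) && cl$type != type) next
      model$probs[, i, j] <- model$probs[, i, j] * factor
    }
  }
  model$row_total <- apply(model$probs, c(1, 2), sum)
  model
}

#' Ground-truth equilibrium composition of an evolution model
#'
#' The stationary vector of each context's substitution process (invariant
#' to the branch-length scaling), for comparison against pipeline
#' estimates.
#'
#' @param model An `evolution_model`.
#' @return Tibble: `context`, `pi_A` ... `pi_T`, `AT_eq`.
#' @export
model_equilibrium <- function(model) {
  s <- 0.01 / max(model$row_total, 1e-12)
  rows <- lapply(1:256, function(c_id) {
    P <- s * model$probs[c_id, , ]
    diag(P) <- 1 - rowSums(P)
    pi_v <- stationary_fast(P)
    tibble(context = model$contexts[c_id],
           pi_A = pi_v[1], pi_C = pi_v[2], pi_G = pi_v[3], pi_T = pi_v[4],
           AT_eq = pi_v[1] + pi_v[4])
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$context)
}

#' Sample an ancestral sequence
#'
#' In noncoding mode, bases are drawn i.i.d. from `composition`. In coding
#' mode, the sequence is a concatenation of codons from fourfold-degenerate
#' families — the first two bases of every codon form an FFD prefix (drawn
#' with probability proportional to the composition of their bases) and the
#' third base is drawn from `composition` — so every third position is an
#' FFD site.
#'
#' @param length Sequence length (rounded down to whole codons in coding
#'   mode).
#' @param composition Named probabilities for A, C, G, T (sum 1).
#' @param coding Coding mode flag.
#' @param seed Integer seed.
#' @return A nucleotide string.
#' @export
sample_ancestor <- function(length, composition = c(A = 0.35, C = 0.15,
                                                    G = 0.15, T = 0.35),
                            coding = FALSE, seed = 1L) {
  stopifnot(length > 0)
  composition <- composition[BASES]
  if (anyNA(composition) || abs(sum(composition) - 1) > 1e-8 ||
      any(composition < 0)) {
    abort("sample_ancestor(): composition must be named A/C/G/T probabilities summing to 1")
  }
  old <- .Random.seed_exists()
  set.seed(as.integer(seed %% 2147483629))
  on.exit(restore_seed(old), add = TRUE)
  if (!coding) {
    return(paste0(sample(BASES, length, replace = TRUE, prob = composition),
                  collapse = ""))
  }
  n_codon <- length %/% 3L
  stopifnot(n_codon > 0)
  pre <- ffd_prefixes()
  wpre <- composition[substr(pre, 1, 1)] * composition[substr(pre, 2, 2)]
  prefixes <- sample(pre, n_codon, replace = TRUE, prob = wpre / sum(wpre))
  thirds <- sample(BASES, n_codon, replace = TRUE, prob = composition)
  paste0(paste0(prefixes, thirds), collapse = "")
}

#' Evolve a sequence under a context-dependent model
#'
#' Per-site Bernoulli substitution draws with probabilities given by each
#' site's current tetranucleotide context, applied in sweeps: contexts are
#' frozen within a sweep and re-evaluated between sweeps, and the branch
#' length is split into enough sweeps that no row's substitution
#' probability exceeds `max_sweep_prob` (the single-hit regime). The two
#' terminal bases on each end have no full context and never substitute.
#'
#' @param sequence Nucleotide string (A/C/G/T).
#' @param model An `evolution_model`.
#' @param branch_length Expected substitutions per site (model units).
#' @param seed Integer seed.
#' @param max_sweep_prob Per-sweep per-row substitution probability cap
#'   (default 0.02).
#' @return A list: `sequence` (descendant string) and `events` (tibble:
#'   `site`, `sweep`, `from`, `to`, `context` — the context at event time).
#' @export
evolve_sequence <- function(sequence, model, branch_length, seed = 1L,
                            max_sweep_prob = 0.02) {
  stopifnot(inherits(model, "evolution_model"), branch_length >= 0)
  x <- match(strsplit(toupper(sequence), "")[[1]], BASES)
  if (anyNA(x)) abort("evolve_sequence(): sequence must be A/C/G/T only")
  L <- length(x)
  events <- list()
  if (branch_length > 0 && L >= 5L) {
    max_row <- max(model$row_total)
    n_sweeps <- max(1L, ceiling(branch_length * max_row / max_sweep_prob))
    s <- branch_length / n_sweeps
    if (s * max_row > 0.3) abort("evolve_sequence(): per-sweep row probability exceeds 0.3")
    old <- .Random.seed_exists()
    set.seed(as.integer(seed %% 2147483629))
    on.exit(restore_seed(old), add = TRUE)
    pos <- 3:(L - 2L)
    for (sw in seq_len(n_sweeps)) {
      cid <- ctx_index(x[pos - 2L], x[pos - 1L], x[pos + 1L], x[pos + 2L])
      from <- x[pos]
      p_sub <- s * model$row_total[cbind(cid, from)]
      u <- stats::runif(length(pos))
      hit <- which(u < p_sub)
      if (length(hit)) {
        ch <- cid[hit]; fh <- from[hit]
        tp <- cbind(
          model$probs[cbind(ch, fh, 1L)], model$probs[cbind(ch, fh, 2L)],
          model$probs[cbind(ch, fh, 3L)], model$probs[cbind(ch, fh, 4L)]
        )
        tot <- model$row_total[cbind(ch, fh)]
        r <- stats::runif(length(hit)) * tot
        c1 <- tp[, 1]; c2 <- c1 + tp[, 2]; c3 <- c2 + tp[, 3]
        to <- 1L + (r > c1) + (r > c2) + (r > c3)
        events[[length(events) + 1L]] <- tibble(
          site = pos[hit], sweep = sw,
          from = BASES[fh], to = BASES[to],
          context = model$contexts[ch]
        )
        x[pos[hit]] <- to
      }
    }
  }
  list(
    sequence = paste0(BASES[x], collapse = ""),
    events = if (length(events)) dplyr::bind_rows(events) else tibble(
      site = integer(), sweep = integer(), from = character(),
      to = character(), context = character()
    )
  )
}

#' Simulate one triplet of descendants from a common ancestor
#'
#' Samples an ancestor and evolves three descendants independently along
#' branches of the model's branch lengths. The event log carries every
#' planted substitution with its lineage and the context at event time;
#' replaying the log on the ancestor reproduces each descendant exactly
#' ([replay_events()]).
#'
#' @param model An `evolution_model`.
#' @param length Ancestor length.
#' @param seed Integer root seed (lineage substreams are derived from it).
#' @param coding Coding-mode ancestor (see [sample_ancestor()]).
#' @return An object of class `synthetic_triplet`: `ancestor`,
#'   `descendants` (character 3), `events` (tibble with `lineage` column),
#'   `seed`, `coding`.
#' @export
make_triplet <- function(model, length, seed = 1L, coding = FALSE) {
  anc <- sample_ancestor(length, composition = model$composition,
                         coding = coding, seed = context_seed(seed, "anc"))
  desc <- character(3)
  events <- list()
  for (k in 1:3) {
    ev <- evolve_sequence(anc, model, model$branch_lengths[k],
                          seed = context_seed(seed, paste0("lineage", k)))
    desc[k] <- ev$sequence
    events[[k]] <- ev$events |> dplyr::mutate(lineage = k, .before = 1L)
  }
  structure(
    list(ancestor = anc, descendants = desc,
         events = dplyr::bind_rows(events), seed = seed, coding = coding),
    class = "synthetic_triplet"
  )
}

#' Replay an event log on an ancestor
#'
#' @param ancestor Ancestor string.
#' @param events Event tibble for one lineage (columns `site`, `sweep`,
#'   `from`, `to`), as from [evolve_sequence()] or one lineage of
#'   [make_triplet()].
#' @return The descendant string.
#' @export
replay_events <- function(ancestor, events) {
  x <- strsplit(ancestor, "")[[1]]
  ev <- events |> dplyr::arrange(.data$sweep)
  for (i in seq_len(nrow(ev))) {
    if (x[ev$site[i]] != ev$from[i]) {
      abort("replay_events(): event log inconsistent with sequence state")
    }
    x[ev$site[i]] <- ev$to[i]
  }
  paste0(x, collapse = "")
}

#' Simulate a set of triplet loci ready for counting
#'
#' Convenience wrapper over [make_triplet()]: simulates `n_loci`
#' independent loci and returns them in the tibble layout consumed by
#' [count_triplets()], together with the pooled ground-truth event log.
#'
#' @param model An `evolution_model`.
#' @param n_loci Number of loci.
#' @param locus_length Length of each locus.
#' @param seed Integer root seed.
#' @param coding Coding-mode loci (`TRUE`) or noncoding (`FALSE`).
#' @return A list: `loci` (tibble `locus`, `type`, `seq1`, `seq2`, `seq3`,
#'   `frame_anchor`) and `events` (planted events with `locus` column).
#' @export
simulate_triplet_set <- function(model, n_loci, locus_length, seed = 1L,
                                 coding = FALSE) {
  trips <- lapply(seq_len(n_loci), function(i) {
    make_triplet(model, locus_length, seed = context_seed(seed, paste0("locus", i)),
                 coding = coding)
  })
  loci <- tibble(
    locus = sprintf("locus%03d", seq_len(n_loci)),
    type = if (coding) "coding" else "noncoding",
    seq1 = vapply(trips, function(t) t$descendants[1], character(1)),
    seq2 = vapply(trips, function(t) t$descendants[2], character(1)),
    seq3 = vapply(trips, function(t) t$descendants[3], character(1)),
    frame_anchor = 1L
  )
  events <- dplyr::bind_rows(lapply(seq_len(n_loci), function(i) {
    trips[[i]]$events |> dplyr::mutate(locus = loci$locus[i], .before = 1L)
  }))
  list(loci = loci, events = events)
}

#' Plant single-base deletions into a sequence
#'
#' Test utility for the alignment stage: deletes `n` distinct single bases
#' at uniformly drawn positions.
#'
#' @param sequence Nucleotide string.
#' @param n Number of single-base deletions.
#' @param seed Integer seed.
#' @return The shortened sequence.
#' @export
delete_bases <- function(sequence, n, seed = 1L) {
  x <- strsplit(sequence, "")[[1]]
  stopifnot(n < length(x))
  old <- .Random.seed_exists()
  set.seed(as.integer(seed %% 2147483629))
  on.exit(restore_seed(old), add = TRUE)
  drop <- sample(length(x), n)
  paste0(x[-drop], collapse = "")
}

#' Sample noncoding-style fixture count matrices from a model
#'
#' Stands in for externally derived noncoding context matrices: for every
#' tetranucleotide context, each row's counts are a multinomial draw of
#' `depth` observations with substitution probabilities `subs_scale` times
#' the model's conditional probabilities (diagonal = remainder). A matching
#' hexanucleotide fixture is drawn by splitting each tetranucleotide cell
#' uniformly across the 16 outer-pair extensions, so the hexanucleotide
#' fixture marginalises exactly to the tetranucleotide one.
#'
#' @param model An `evolution_model`.
#' @param depth Observations per matrix row.
#' @param seed Integer seed.
#' @param subs_scale Expected substitutions/site scale of the fixture
#'   (default 0.08).
#' @param site_class Site-class label (default `"NC"`).
#' @return A list: `tetra` (count tibble over the 256 contexts), `hex`
#'   (count tibble with an extra `outer` column), `truth`
#'   ([model_equilibrium()] of the model).
#' @export
make_nc_fixture <- function(model, depth = 1e5, seed = 1L, subs_scale = 0.08,
                            site_class = "NC") {
  stopifnot(depth >= 1)
  smax <- subs_scale * max(model$row_total)
  if (smax > 0.5) {
    abort("make_nc_fixture(): subs_scale too large for this model (row probability > 0.5)")
  }
  old <- .Random.seed_exists()
  set.seed(context_seed(seed, "ncfix"))
  on.exit(restore_seed(old), add = TRUE)

  rows <- vector("list", 256 * 4)
  hex_rows <- vector("list", 256 * 4)
  all_outer <- sort(as.vector(outer(BASES, BASES, paste0)))
  k <- 0L
  for (c_id in 1:256) {
    for (i in 1:4) {
      p <- subs_scale * model$probs[c_id, i, ]
      p[i] <- 1 - sum(p)
      cnt <- as.integer(stats::rmultinom(1, size = depth, prob = p))
      k <- k + 1L
      rows[[k]] <- tibble(
        site_class = site_class, context = model$contexts[c_id],
        ancestral = BASES[i],
        A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4]
      )
      split <- vapply(cnt, function(nn) {
        as.integer(stats::rmultinom(1, size = nn, prob = rep(1 / 16, 16)))
      }, integer(16))
      hex_rows[[k]] <- tibble(
        site_class = site_class, context = model$contexts[c_id],
        outer = all_outer, ancestral = BASES[i],
        A = split[, 1], C = split[, 2], G = split[, 3], T = split[, 4]
      )
    }
  }
  list(
    tetra = dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$context, .data$ancestral),
    hex = dplyr::bind_rows(hex_rows) |>
      dplyr::arrange(.data$context, .data$outer, .data$ancestral),
    truth = model_equilibrium(model)
  )
}

#' Summarise hexanucleotide fixture matrices into NC prediction inputs
#'
#' Turns hexanucleotide count matrices into the per-extension table
#' consumed by [weighted_predictions()]: equilibrium A+T and per-base
#' rates for each (tetranucleotide context, outer pair).
#'
#' @param hex_counts Hexanucleotide count tibble (columns `context`,
#'   `outer`, `ancestral`, `A` ... `T`), as from [make_nc_fixture()].
#' @return Tibble: `context`, `outer`, `AT_eq`, `rate_A` ... `rate_T`
#'   (`NA` where a matrix has an unobserved row or no unique equilibrium).
#' @export
hex_matrix_results <- function(hex_counts) {
  hex_counts |>
    dplyr::group_by(.data$context, .data$outer) |>
    dplyr::group_modify(function(d, key) {
      m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
      m[d$ancestral, ] <- as.matrix(d[, BASES])
      rt <- rowSums(m)
      rates <- ifelse(rt > 0, (rt - diag(m)) / rt, NA_real_)
      at <- NA_real_
      if (all(rt > 0)) {
        pi_v <- stationary_fast(m / rt)
        if (!is.null(pi_v)) at <- pi_v[1] + pi_v[4]
      }
      tibble(AT_eq = at, rate_A = rates[1], rate_C = rates[2],
             rate_G = rates[3], rate_T = rates[4])
    }) |>
    dplyr::ungroup()
}
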