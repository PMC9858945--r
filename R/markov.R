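#' Per-base substitution rates of a count matrix
#'
#' The rate for each matrix row is the number of off-diagonal observations
#' in that row divided by the row total; under the single-hit assumption of
#' closely related triplets this is the substitutions-per-site rate for
#' that base in that context.
#'
#' @param counts Count tibble (see [accumulate_counts()]).
#' @return A tibble with columns `site_class`, `context`, `base`,
#'   `off_diagonal`, `row_total`, `rate` (`NA` with a flag when the row
#'   total is zero) and `defined`.
#' @examples
#' cm <- tibble::tibble(site_class = "NC", context = "CT.AG",
#'                      ancestral = "A", A = 90L, C = 0L, G = 10L, T = 0L)
#' row_rates(cm)
#' @export
row_rates <- function(counts) {
  counts |>
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "observed",
                        values_to = "n") |>
    dplyr::group_by(.data$site_class, .data$context, base = .data$ancestral) |>
    dplyr::summarise(
      off_diagonal = sum(.data$n[.data$observed != .data$base]),
      row_total = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate = ifelse(.data$row_total > 0, .data$off_diagonal / .data$row_total,
                    NA_real_),
      defined = .data$row_total > 0
    )
}

#' Row-normalise a count matrix into a Markov transition matrix
#'
#' `P[i, j] = counts[i, j] / rowtotal(i)`. Rows with zero observations are
#' undefined; the matrix is then flagged unusable for equilibrium analyses.
#'
#' @param m 4 x 4 count matrix (rows = ancestral base), as from
#'   [counts_matrix()].
#' @return A list with `P` (4 x 4 row-stochastic matrix, `NA` rows where
#'   undefined) and `defined` (logical, all rows defined).
#' @export
to_transition_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4L), all(m >= 0))
  rt <- rowSums(m)
  P <- m / rt
  P[rt == 0, ] <- NA_real_
  dimnames(P) <- list(BASES, BASES)
  list(P = P, defined = all(rt > 0))
}

#' Stationary vector of a row-stochastic transition matrix
#'
#' Solves the left fixed point `pi P = pi`, `sum(pi) = 1` as a linear
#' system, with an eigen-decomposition cross-check. When the chain has more
#' than one recurrent class (the fixed point is not unique) the matrix is
#' rejected rather than silently resolved; a unique limiting distribution
#' with absorbing states (e.g. `pi = (1, 0, 0, 0)`) is reported.
#'
#' @param P 4 x 4 row-stochastic matrix.
#' @param tol Numerical tolerance for stochasticity and uniqueness checks.
#' @return Numeric stationary vector `pi` named A, C, G, T.
#' @examples
#' P <- matrix(0.25, 4, 4)
#' stationary_vector(P)
#' @export
stationary_vector <- function(P, tol = 1e-10) {
  stopifnot(is.matrix(P), all(dim(P) == 4L))
  if (anyNA(P)) abort("stationary_vector(): matrix has undefined rows")
  if (any(abs(rowSums(P) - 1) > 1e-8) || any(P < -tol)) {
    abort("stationary_vector(): matrix is not row-stochastic")
  }
  A <- t(P) - diag(4)
  ## uniqueness: the fixed point is unique iff null space of (P' - I) is 1-d
  sv <- svd(A)$d
  if (sum(sv < 1e-8) != 1L) {
    abort("stationary_vector(): chain is reducible (stationary vector not unique)")
  }
  sol <- qr.solve(rbind(A, rep(1, 4)), c(rep(0, 4), 1))
  sol[abs(sol) < tol] <- 0
  if (any(sol < 0)) abort("stationary_vector(): negative stationary entries")
  pi_lin <- sol / sum(sol)
  ## eigen route cross-check
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  pi_eig <- Re(e$vectors[, k])
  pi_eig <- pi_eig / sum(pi_eig)
  if (max(abs(pi_eig - pi_lin)) > 1e-6) {
    abort("stationary_vector(): linear-system and eigen solutions disagree")
  }
  setNames(pi_lin, BASES)
}

#' Equilibrium composition summaries of a stationary vector
#'
#' @param pi Stationary vector named A, C, G, T.
#' @return A one-row tibble: `AT_eq` (`pi_A + pi_T`), `skew_AT`
#'   (`(pi_A - pi_T) / (pi_A + pi_T)`), `skew_GC`
#'   (`(pi_G - pi_C) / (pi_G + pi_C)`); a skew is `NA` when its denominator
#'   is zero.
#' @examples
#' equilibrium_summary(c(A = 0.6, C = 0.1, G = 0.1, T = 0.2))
#' @export
equilibrium_summary <- function(pi) {
  stopifnot(length(pi) == 4L, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  pi <- setNames(as.numeric(pi), BASES)
  at <- pi[["A"]] + pi[["T"]]
  gc <- pi[["G"]] + pi[["C"]]
  tibble(
    AT_eq = at,
    skew_AT = if (at > 0) (pi[["A"]] - pi[["T"]]) / at else NA_real_,
    skew_GC = if (gc > 0) (pi[["G"]] - pi[["C"]]) / gc else NA_real_
  )
}

## deterministic per-context RNG stream below 2^31, derived from a root
## seed and the context label so bootstrap results do not depend on the
## order contexts are processed
context_seed <- function(seed, context) {
  h <- sum(utf8ToInt(context) * seq_len(nchar(context))^2)
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483629)
}

#' Bootstrap uncertainty of the equilibrium A+T content
#'
#' Each resample keeps every diagonal entry and every row's off-diagonal
#' total fixed, redrawing how that row's substitutions fall among its three
#' off-diagonal cells (multinomial, probabilities proportional to the
#' observed off-diagonal counts — i.e. drawing the substitutions from the
#' row with replacement). The equilibrium A+T content is recomputed for
#' each resampled matrix; its mean and standard deviation over `n`
#' resamples estimate the sampling error.
#'
#' @param m 4 x 4 count matrix.
#' @param n Number of resamples (default 1000).
#' @param seed Integer seed (combined with `context` into a deterministic
#'   stream).
#' @param context Context label used to derive the per-context RNG stream.
#' @param keep_resamples Also return the resampled matrices (for
#'   diagnostics; memory-heavy for large `n`).
#' @return A list: `mean`, `sd`, `n`, `n_failed` (resamples whose matrix
#'   had no unique stationary vector, excluded from the summaries), and —
#'   when `keep_resamples` — `resamples`, a list of matrices.
#' @export
bootstrap_equilibrium <- function(m, n = 1000, seed = 1L, context = "NN.NN",
                                  keep_resamples = FALSE) {
  stopifnot(is.matrix(m), all(dim(m) == 4L))
  if (n < 2) abort("bootstrap_equilibrium(): need at least 2 resamples")
  off_idx <- lapply(1:4, function(i) setdiff(1:4, i))
  totals <- vapply(1:4, function(i) sum(m[i, off_idx[[i]]]), numeric(1))
  withr_seed <- context_seed(seed, context)
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(restore_seed(old), add = TRUE)

  draws <- lapply(1:4, function(i) {
    if (totals[i] == 0) {
      matrix(0, nrow = 3, ncol = n)
    } else {
      stats::rmultinom(n, size = totals[i], prob = m[i, off_idx[[i]]] / totals[i])
    }
  })
  ats <- rep(NA_real_, n)
  base_m <- m
  resamples <- if (keep_resamples) vector("list", n) else NULL
  for (r in seq_len(n)) {
    mr <- base_m
    for (i in 1:4) mr[i, off_idx[[i]]] <- draws[[i]][, r]
    if (keep_resamples) resamples[[r]] <- mr
    rt <- rowSums(mr)
    if (any(rt == 0)) next
    pi_r <- stationary_fast(mr / rt)
    if (is.null(pi_r)) next
    ats[r] <- pi_r[1] + pi_r[4]
  }
  ok <- !is.na(ats)
  out <- list(mean = mean(ats[ok]), sd = stats::sd(ats[ok]),
              n = n, n_failed = sum(!ok))
  if (keep_resamples) out$resamples <- resamples
  out
}

## fast stationary solve used inside the bootstrap loop: pi (I - P + 1) = 1
## (valid when the fixed point is unique; returns NULL otherwise)
stationary_fast <- function(P) {
  out <- tryCatch(solve(t(diag(4) - P + 1), rep(1, 4)),
                  error = function(e) NULL)
  if (is.null(out) || any(out < -1e-9)) return(NULL)
  out / sum(out)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Equilibrium profile of a set of count matrices
#'
#' For every (site class, context) matrix with all rows observed and a
#' unique stationary vector, computes the equilibrium base composition and
#' its summaries, with optional bootstrap uncertainty for the A+T content.
#' Matrices with undefined rows, non-unique equilibria, or fewer than
#' `min_subs` substitutions are flagged rather than silently dropped.
#'
#' @param counts Count tibble.
#' @param bootstrap_n Bootstrap resamples per context (0 to skip).
#' @param seed Root seed for the bootstrap streams.
#' @param min_subs Sparse-matrix threshold: contexts with fewer total
#'   substitutions are flagged `sparse` and normally excluded from
#'   comparative statistics.
#' @return A tibble of class `ctx_equilibrium`: `site_class`, `context`,
#'   `n_subs`, `pi_A` ... `pi_T`, `AT_eq`, `skew_AT`, `skew_GC`,
#'   `AT_boot_mean`, `AT_boot_sd`, `sparse`, `flag` (`"ok"`, `"zero_row"`
#'   or `"reducible"`).
#' @export
equilibrium_profile <- function(counts, bootstrap_n = 0, seed = 1L,
                                min_subs = 10) {
  tot <- context_totals(counts, min_subs = min_subs)
  keys <- counts |> dplyr::distinct(.data$site_class, .data$context)
  rows <- purrr::pmap(keys, function(site_class, context) {
    m <- counts_matrix(counts, context, site_class)
    tm <- to_transition_matrix(m)
    out <- tibble(
      site_class = site_class, context = context,
      pi_A = NA_real_, pi_C = NA_real_, pi_G = NA_real_, pi_T = NA_real_,
      AT_eq = NA_real_, skew_AT = NA_real_, skew_GC = NA_real_,
      AT_boot_mean = NA_real_, AT_boot_sd = NA_real_, flag = "ok"
    )
    if (!tm$defined) {
      out$flag <- "zero_row"
      return(out)
    }
    pi_v <- tryCatch(stationary_vector(tm$P), error = function(e) NULL)
    if (is.null(pi_v)) {
      out$flag <- "reducible"
      return(out)
    }
    s <- equilibrium_summary(pi_v)
    out[, c("pi_A", "pi_C", "pi_G", "pi_T")] <- as.list(pi_v)
    out[, c("AT_eq", "skew_AT", "skew_GC")] <- s
    if (bootstrap_n > 0) {
      b <- bootstrap_equilibrium(m, n = bootstrap_n, seed = seed,
                                 context = context)
      out$AT_boot_mean <- b$mean
      out$AT_boot_sd <- b$sd
    }
    out
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::left_join(tot |> dplyr::select("site_class", "context",
                                          "n_subs", "sparse"),
                     by = c("site_class", "context")) |>
    dplyr::relocate("n_subs", .after = "context")
  class(res) <- c("ctx_equilibrium", class(res))
  res
}
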