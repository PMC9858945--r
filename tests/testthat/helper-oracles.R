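## Independent oracles used across the suite. These deliberately avoid the
## code paths they check.

BASES4 <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

## Global affine-gap alignment score by memoised three-state recursion
## (gap of length L costs open + extend * (L - 1); end gaps penalised).
## Independent of the Needleman-Wunsch implementation behind align_pair().
oracle_align_score <- function(a, b, params = ctxsub::alignment_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) params$match else params$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= n) {
      g <- if (prev == "ga") params$gap_extend else params$gap_open
      best <- max(best, g + rec(i + 1, j, "ga"))
    }
    if (j <= m) {
      g <- if (prev == "gb") params$gap_extend else params$gap_open
      best <- max(best, g + rec(i, j + 1, "gb"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

## Stationary distribution by power iteration: a row of P^k for large k.
oracle_power_stationary <- function(P, iters = 1000) {
  M <- diag(4)
  for (k in seq_len(iters)) M <- M %*% P
  as.numeric(M[1, ])
}

## Random strictly positive row-stochastic 4x4 matrix.
random_positive_P <- function() {
  M <- matrix(stats::runif(16, min = 0.01, max = 1), 4, 4)
  M / rowSums(M)
}

## Random nucleotide string.
random_seq <- function(n) paste0(sample(BASES4, n, replace = TRUE), collapse = "")

## Relabel a 4x4 base-indexed matrix through complementation.
relabel_complement <- function(m) {
  perm <- match(ctxsub::complement_base(BASES4), BASES4)
  out <- m[perm, perm]
  dimnames(out) <- list(BASES4, BASES4)
  out
}

## Delta-method SD of the equilibrium A+T of a count matrix whose rows are
## independent multinomials, via numerical differentiation of AT_eq with
## respect to every cell.
oracle_at_delta_sd <- function(m, h = 1e-3) {
  at_of <- function(mm) {
    P <- mm / rowSums(mm)
    pv <- ctxsub::stationary_vector(P)
    pv[["A"]] + pv[["T"]]
  }
  var_total <- 0
  for (i in 1:4) {
    ni <- sum(m[i, ])
    p <- m[i, ] / ni
    Sigma <- ni * (diag(p) - tcrossprod(p))
    grad <- numeric(4)
    for (j in 1:4) {
      up <- m; up[i, j] <- up[i, j] + h
      dn <- m; dn[i, j] <- dn[i, j] - h
      grad[j] <- (at_of(up) - at_of(dn)) / (2 * h)
    }
    var_total <- var_total + drop(t(grad) %*% Sigma %*% grad)
  }
  sqrt(var_total)
}

## Delta-method SD matching the row-conditional bootstrap: each row's
## off-diagonal total is fixed and its allocation across the three
## off-diagonal cells is multinomial.
oracle_at_delta_sd_offdiag <- function(m, h = 1e-3) {
  at_of <- function(mm) {
    P <- mm / rowSums(mm)
    pv <- ctxsub::stationary_vector(P)
    pv[["A"]] + pv[["T"]]
  }
  var_total <- 0
  for (i in 1:4) {
    off <- setdiff(1:4, i)
    Ti <- sum(m[i, off])
    if (Ti == 0) next
    q <- m[i, off] / Ti
    Sigma <- Ti * (diag(q) - tcrossprod(q))
    grad <- numeric(3)
    for (k in 1:3) {
      up <- m; up[i, off[k]] <- up[i, off[k]] + h
      dn <- m; dn[i, off[k]] <- dn[i, off[k]] - h
      grad[k] <- (at_of(up) - at_of(dn)) / (2 * h)
    }
    var_total <- var_total + drop(t(grad) %*% Sigma %*% grad)
  }
  sqrt(var_total)
}

## Build a one-class count tibble from a named list context -> 4x4 matrix.
counts_from_matrices <- function(mats, site_class = "NC") {
  dplyr::bind_rows(lapply(names(mats), function(ctx) {
    m <- mats[[ctx]]
    tibble::tibble(
      site_class = site_class, context = ctx, ancestral = BASES4,
      A = m[, 1], C = m[, 2], G = m[, 3], T = m[, 4]
    )
  }))
}

## Random sparse count matrices over a context set (fixed RNG state caller's).
random_count_matrices <- function(contexts, lambda_off = 8, diag_n = 300) {
  mats <- lapply(contexts, function(ctx) {
    m <- matrix(stats::rpois(16, lambda_off), 4, 4)
    diag(m) <- diag_n + stats::rpois(4, 50)
    dimnames(m) <- list(BASES4, BASES4)
    m
  })
  names(mats) <- contexts
  mats
}
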