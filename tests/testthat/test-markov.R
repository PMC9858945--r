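test_that("row rates are off-diagonal counts over row totals", {
  cm <- tibble::tibble(
    site_class = "NC", context = "CT.AG", ancestral = c("A", "C", "G"),
    A = c(90L, 0L, 0L), C = c(0L, 40L, 0L), G = c(10L, 0L, 0L),
    T = c(0L, 0L, 0L)
  )
  rr <- row_rates(cm)
  expect_equal(rr$rate[rr$base == "A"], 0.10)
  expect_equal(rr$rate[rr$base == "C"], 0)     # all-diagonal row
  expect_true(is.na(rr$rate[rr$base == "G"]))  # zero row total
  expect_false(rr$defined[rr$base == "G"])
})

test_that("transition matrices are row-normalised counts", {
  m <- diag(c(5, 7, 9, 11))
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  expect_equal(to_transition_matrix(m)$P, diag(4), ignore_attr = TRUE)
  m2 <- matrix(10, 4, 4)
  expect_equal(to_transition_matrix(m2)$P, matrix(0.25, 4, 4),
               ignore_attr = TRUE)
  set.seed(1)
  for (k in 1:20) {
    mm <- matrix(stats::rpois(16, 20) + 1, 4, 4)
    expect_equal(rowSums(to_transition_matrix(mm)$P), rep(1, 4),
                 ignore_attr = TRUE)
  }
  m3 <- m2; m3[2, ] <- 0
  tm <- to_transition_matrix(m3)
  expect_false(tm$defined)
  expect_true(all(is.na(tm$P[2, ])))
})

test_that("stationary vectors solve the fixed point and match power iteration", {
  ## rank-one chain: every row q implies pi = q
  q <- c(0.4, 0.3, 0.2, 0.1)
  P <- matrix(q, 4, 4, byrow = TRUE)
  expect_equal(unname(stationary_vector(P)), q, tolerance = 1e-10)
  ## absorbing A has the unique limiting distribution (1, 0, 0, 0)
  Pa <- matrix(0, 4, 4); Pa[, 1] <- 0.2; diag(Pa) <- 0.8; Pa[1, 1] <- 1
  expect_equal(unname(stationary_vector(Pa)), c(1, 0, 0, 0), tolerance = 1e-10)
  ## two closed classes: not unique, rejected
  Pr <- diag(4)
  expect_error(stationary_vector(Pr), "reducible")
  expect_error(stationary_vector(matrix(0.3, 4, 4)), "row-stochastic")
  set.seed(99)
  for (k in 1:50) {
    P <- random_positive_P()
    v <- stationary_vector(P)
    expect_lt(max(abs(v %*% P - v)), 1e-8)
    expect_lt(max(abs(unname(v) - oracle_power_stationary(P))), 1e-8)
  }
})

test_that("equilibria of complement-relabelled matrices are relabelled equilibria", {
  set.seed(5)
  perm <- match(complement_base(c("A", "C", "G", "T")), c("A", "C", "G", "T"))
  for (k in 1:20) {
    P <- random_positive_P()
    v <- unname(stationary_vector(P))
    v_rel <- unname(stationary_vector(P[perm, perm]))
    expect_equal(v_rel, v[perm], tolerance = 1e-9)
  }
})

test_that("equilibrium summaries compute A+T and skews", {
  s <- equilibrium_summary(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(unlist(s), c(AT_eq = 0.5, skew_AT = 0, skew_GC = 0))
  s2 <- equilibrium_summary(c(A = 0.5, C = 0, G = 0, T = 0.5))
  expect_equal(s2$AT_eq, 1)
  expect_equal(s2$skew_AT, 0)
  expect_true(is.na(s2$skew_GC))   # zero denominator flagged as undefined
  s3 <- equilibrium_summary(c(A = 0.6, C = 0.1, G = 0.1, T = 0.2))
  expect_equal(s3$skew_AT, 0.5)
  expect_equal(s3$skew_GC, 0)
})

test_that("equilibrium A+T is monotone in the G->A count", {
  base <- matrix(c(180, 4, 6, 10,
                   3, 150, 5, 12,
                   7, 6, 140, 4,
                   9, 5, 3, 170), 4, 4, byrow = TRUE)
  dimnames(base) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  at_of <- function(m) {
    v <- stationary_vector(to_transition_matrix(m)$P)
    v[["A"]] + v[["T"]]
  }
  ats <- vapply(seq(0, 60, by = 5), function(extra) {
    m <- base; m["G", "A"] <- m["G", "A"] + extra; at_of(m)
  }, numeric(1))
  expect_true(all(diff(ats) >= 0))
})

test_that("bootstrap resampling is seeded, preserves totals, and flags degeneracy", {
  expect_identical(eval(formals(bootstrap_equilibrium)$n), 1000)
  m <- matrix(c(500, 10, 5, 15,
                8, 400, 12, 20,
                6, 14, 450, 9,
                11, 7, 13, 520), 4, 4, byrow = TRUE)
  b1 <- bootstrap_equilibrium(m, n = 100, seed = 7, context = "CT.AG")
  b2 <- bootstrap_equilibrium(m, n = 100, seed = 7, context = "CT.AG")
  expect_identical(b1$mean, b2$mean)
  b3 <- bootstrap_equilibrium(m, n = 100, seed = 8, context = "CT.AG")
  expect_false(identical(b1$mean, b3$mean))

  bk <- bootstrap_equilibrium(m, n = 50, seed = 1, context = "AA.AA",
                              keep_resamples = TRUE)
  for (r in bk$resamples) {
    expect_identical(diag(r), diag(m))
    expect_identical(rowSums(r) - diag(r), rowSums(m) - diag(m))
  }
  ## no off-diagonals anywhere: every resample is the input, SD = 0
  md <- diag(c(50, 60, 70, 80))
  b0 <- bootstrap_equilibrium(md, n = 10, seed = 1)
  expect_true(is.na(b0$mean) || b0$sd == 0)  # all-diagonal: no unique pi
  expect_error(bootstrap_equilibrium(m, n = 1), "at least 2")
})

test_that("bootstrap SD agrees with the multinomial delta method at large counts", {
  m <- matrix(c(5000, 120, 60, 180,
                90, 5000, 150, 240,
                70, 160, 5000, 110,
                130, 80, 140, 5000), 4, 4, byrow = TRUE)
  b <- bootstrap_equilibrium(m, n = 5000, seed = 13, context = "GT.CA")
  ## the row-conditional bootstrap matches the delta method with row
  ## off-diagonal totals held fixed (the diagonal carries no variance here)
  delta <- oracle_at_delta_sd_offdiag(m)
  expect_lt(abs(b$sd - delta) / delta, 0.15)
})

test_that("equilibrium profiles flag sparse and degenerate matrices", {
  mats <- list(
    "CT.AG" = matrix(c(300, 10, 8, 12, 9, 280, 7, 14, 6, 11, 310, 9,
                       13, 8, 10, 295), 4, 4, byrow = TRUE),
    "GG.AA" = diag(c(50, 60, 70, 80)),                 # reducible
    "AC.GT" = matrix(c(40, 1, 0, 1, 0, 38, 1, 0, 1, 0, 44, 1,
                       0, 1, 1, 41), 4, 4, byrow = TRUE) # sparse (< 10 subs)
  )
  counts <- counts_from_matrices(mats)
  prof <- equilibrium_profile(counts, bootstrap_n = 50, seed = 3)
  expect_s3_class(prof, "ctx_equilibrium")
  p1 <- prof[prof$context == "CT.AG", ]
  expect_identical(p1$flag, "ok")
  expect_false(p1$sparse)
  expect_false(is.na(p1$AT_boot_sd))
  ## fixed point verified on the emitted equilibrium
  P <- to_transition_matrix(mats[["CT.AG"]])$P
  v <- c(p1$pi_A, p1$pi_C, p1$pi_G, p1$pi_T)
  expect_lt(max(abs(v %*% P - v)), 1e-8)
  expect_identical(prof$flag[prof$context == "GG.AA"], "reducible")
  expect_true(prof$sparse[prof$context == "AC.GT"])
})
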