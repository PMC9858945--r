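#' Pair FFD and NC values per context and summarise their relationship
#'
#' Joins two per-context result tables (e.g. rates from [row_rates()] or
#' equilibrium A+T from [equilibrium_profile()]) on context (and base, when
#' present in both), producing one comparison record per pair plus a
#' summary: the proportion of cases where the FFD value exceeds the NC
#' value (ties count as not higher and are reported separately), the mean
#' relative excess in each direction, and the squared Pearson correlation
#' on untransformed values.
#'
#' @param ffd,nc Tibbles with a `context` column, optionally a `base`
#'   column, and the value column named by `quantity`.
#' @param quantity Name of the value column (e.g. `"rate"`, `"AT_eq"`).
#' @return An object of class `ctx_comparison`: list with `records` (tibble:
#'   `context`, optional `base`, `value_ffd`, `value_nc`, `higher_in_ffd`,
#'   `tie`) and `summary` (list: `n`, `n_higher`, `prop_higher`, `n_ties`,
#'   `mean_excess_ffd`, `mean_excess_nc`, `r_squared`, `quantity`).
#' @examples
#' ffd <- tibble::tibble(context = c("CT.AG", "GG.AA"), rate = c(0.1, 0.2))
#' nc <- tibble::tibble(context = c("CT.AG", "GG.AA"), rate = c(0.05, 0.25))
#' compare_contexts(ffd, nc, "rate")
#' @export
compare_contexts <- function(ffd, nc, quantity) {
  stopifnot(quantity %in% names(ffd), quantity %in% names(nc))
  keys <- intersect(c("context", "base"), intersect(names(ffd), names(nc)))
  f <- ffd |> dplyr::select(dplyr::all_of(keys), value_ffd = dplyr::all_of(quantity))
  g <- nc |> dplyr::select(dplyr::all_of(keys), value_nc = dplyr::all_of(quantity))
  rec <- dplyr::inner_join(f, g, by = keys) |>
    dplyr::filter(is.finite(.data$value_ffd), is.finite(.data$value_nc))
  if (!nrow(rec)) abort("compare_contexts(): no shared contexts with finite values")
  rec <- rec |>
    dplyr::mutate(
      higher_in_ffd = .data$value_ffd > .data$value_nc,
      tie = .data$value_ffd == .data$value_nc
    )
  up <- rec$higher_in_ffd
  dn <- !rec$higher_in_ffd & !rec$tie
  summary <- list(
    quantity = quantity,
    n = nrow(rec),
    n_higher = sum(up),
    prop_higher = mean(up),
    n_ties = sum(rec$tie),
    mean_excess_ffd = if (any(up & rec$value_nc > 0)) {
      mean((rec$value_ffd[up & rec$value_nc > 0] -
              rec$value_nc[up & rec$value_nc > 0]) /
             rec$value_nc[up & rec$value_nc > 0])
    } else NA_real_,
    mean_excess_nc = if (any(dn & rec$value_ffd > 0)) {
      mean((rec$value_nc[dn & rec$value_ffd > 0] -
              rec$value_ffd[dn & rec$value_ffd > 0]) /
             rec$value_ffd[dn & rec$value_ffd > 0])
    } else NA_real_,
    r_squared = if (nrow(rec) >= 2 &&
                    isTRUE(stats::sd(rec$value_ffd) > 0) &&
                    isTRUE(stats::sd(rec$value_nc) > 0)) {
      stats::cor(rec$value_ffd, rec$value_nc)^2
    } else NA_real_
  )
  structure(list(records = rec, summary = summary), class = "ctx_comparison")
}

#' @export
print.ctx_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ctx_comparison> %s: %d pairs; FFD higher in %.1f%% (%d ties); r^2 = %.3f\n",
    s$quantity, s$n, 100 * s$prop_higher, s$n_ties,
    ifelse(is.na(s$r_squared), NA, s$r_squared)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_contexts
#' @param x A `ctx_comparison`.
#' @param ... Unused.
#' @export
tidy.ctx_comparison <- function(x, ...) x$records

#' @rdname compare_contexts
#' @export
glance.ctx_comparison <- function(x, ...) as_tibble(x$summary[-1])

#' Per-context rates of the six substitution classes
#'
#' Off-diagonal counts are grouped by [classify_substitution()] class
#' (W->S / S->W transitions; W->S, S->W, S->S, W->W transversions); the
#' class rate in a context is the class's substitution count divided by the
#' total observations of its source bases in that context.
#'
#' @param counts Count tibble.
#' @return Tibble: `site_class`, `context`, `class_pair`, `type`,
#'   `sub_class`, `n_subs`, `n_source_obs`, `rate`.
#' @export
class_rates <- function(counts) {
  long <- counts |>
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "observed",
                        values_to = "n")
  row_tot <- long |>
    dplyr::group_by(.data$site_class, .data$context, .data$ancestral) |>
    dplyr::summarise(row_total = sum(.data$n), .groups = "drop")
  offd <- long |>
    dplyr::filter(.data$ancestral != .data$observed)
  cls <- classify_substitution(offd$ancestral, offd$observed)
  offd$class_pair <- cls$class_pair
  offd$type <- cls$type
  ## source-base observations per class: W classes draw on A and T rows,
  ## S classes on C and G rows
  src <- row_tot |>
    dplyr::mutate(src_class = ifelse(.data$ancestral %in% WEAK, "W", "S")) |>
    dplyr::group_by(.data$site_class, .data$context, .data$src_class) |>
    dplyr::summarise(n_source_obs = sum(.data$row_total), .groups = "drop")
  offd |>
    dplyr::group_by(.data$site_class, .data$context, .data$class_pair,
                    .data$type) |>
    dplyr::summarise(n_subs = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(src_class = substr(.data$class_pair, 1L, 1L)) |>
    dplyr::left_join(src, by = c("site_class", "context", "src_class")) |>
    dplyr::mutate(
      sub_class = paste(.data$class_pair, .data$type),
      rate = ifelse(.data$n_source_obs > 0, .data$n_subs / .data$n_source_obs,
                    NA_real_)
    ) |>
    dplyr::select("site_class", "context", "class_pair", "type", "sub_class",
                  "n_subs", "n_source_obs", "rate")
}

#' Substitution-class breakdown of the FFD-vs-NC comparison
#'
#' For each of the six substitution classes, the proportion of contexts in
#' which the FFD class rate exceeds the NC class rate, with a Bayes factor
#' against an even (p = 0.5) chance of either site type being higher.
#'
#' @param ffd_counts,nc_counts Count tibbles for the two site types (same
#'   context universe; typically complement-combined, one row set per
#'   equivalence class).
#' @param min_subs Contexts whose total substitutions fall below this in
#'   either site type are excluded.
#' @return Tibble: `sub_class`, `n_contexts`, `n_higher_ffd`, `prop_higher`,
#'   `n_ties`, `bayes_factor`.
#' @export
class_breakdown <- function(ffd_counts, nc_counts, min_subs = 10) {
  keep <- function(counts) {
    tot <- context_totals(counts, min_subs = min_subs)
    counts |>
      dplyr::semi_join(tot |> dplyr::filter(!.data$sparse),
                       by = c("site_class", "context"))
  }
  f <- class_rates(keep(ffd_counts)) |> dplyr::rename(rate_ffd = "rate")
  g <- class_rates(keep(nc_counts)) |> dplyr::rename(rate_nc = "rate")
  paired <- dplyr::inner_join(
    f |> dplyr::select("context", "sub_class", "rate_ffd"),
    g |> dplyr::select("context", "sub_class", "rate_nc"),
    by = c("context", "sub_class")
  ) |>
    dplyr::filter(is.finite(.data$rate_ffd), is.finite(.data$rate_nc))
  present <- unique(paired$sub_class)
  missing <- setdiff(substitution_classes(), present)
  if (length(missing)) {
    warn(paste0("class_breakdown(): no contexts for classes: ",
                paste(missing, collapse = ", ")))
  }
  paired |>
    dplyr::group_by(.data$sub_class) |>
    dplyr::summarise(
      n_contexts = dplyr::n(),
      n_higher_ffd = sum(.data$rate_ffd > .data$rate_nc),
      prop_higher = mean(.data$rate_ffd > .data$rate_nc),
      n_ties = sum(.data$rate_ffd == .data$rate_nc),
      .groups = "drop"
    ) |>
    dplyr::mutate(bayes_factor = purrr::map2_dbl(
      .data$n_higher_ffd, .data$n_contexts, bayes_factor_binomial
    )) |>
    dplyr::arrange(factor(.data$sub_class, levels = substitution_classes()))
}

#' Bayes factor for a binomial proportion against an even split
#'
#' Evidence for `H1: p ~ Beta(a, b)` (default uniform) against the point
#' null `H0: p = 0.5`, given `k` successes in `n` trials:
#' `BF10 = [B(k + a, n - k + b) / B(a, b)] / 0.5^n` (the binomial
#' coefficients cancel). `BF10 > 1` favours an uneven proportion.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param prior Length-2 vector of Beta shape parameters (default `c(1, 1)`,
#'   the uniform prior).
#' @return The Bayes factor (positive scalar).
#' @examples
#' bayes_factor_binomial(1, 2)     # 2/3
#' bayes_factor_binomial(20, 20)   # overwhelming
#' @export
bayes_factor_binomial <- function(k, n, prior = c(1, 1)) {
  if (n <= 0 || k < 0 || k > n) abort("bayes_factor_binomial(): need 0 <= k <= n, n > 0")
  if (length(prior) != 2L || any(prior <= 0)) {
    abort("bayes_factor_binomial(): prior must be two positive Beta shapes")
  }
  exp(lbeta(k + prior[1], n - k + prior[2]) - lbeta(prior[1], prior[2]) -
        n * log(0.5))
}
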