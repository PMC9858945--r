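#' Hexanucleotide-extension frequencies of FFD sites in gene sequences
#'
#' Scans in-frame coding sequences for FFD third codon positions and, for
#' each FFD tetranucleotide context, tallies the relative frequency of the
#' 16 outer (L3, R3) base pairs — the two bases three sites removed from
#' the substitution site, which extend the tetranucleotide to the
#' hexanucleotide context.
#'
#' @param gene_sequences Character vector of in-frame coding sequences
#'   (frame anchored at position 1).
#' @return A tibble with columns `context`, `outer` (2-letter string
#'   `L3R3`) and `freq`; frequencies sum to 1 within each context. FFD
#'   contexts never observed in the input receive uniform weights, with a
#'   warning.
#' @export
hex_frequencies <- function(gene_sequences) {
  tallies <- purrr::map(gene_sequences, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    p <- seq(3L, n, by = 3L)
    p <- p[p - 3L >= 1L & p + 3L <= n]
    if (!length(p)) return(NULL)
    pref <- paste0(ch[p - 2L], ch[p - 1L])
    p <- p[pref %in% ffd_prefixes()]
    if (!length(p)) return(NULL)
    win <- cbind(ch[p - 3L], ch[p - 2L], ch[p - 1L], ch[p + 1L],
                 ch[p + 2L], ch[p + 3L])
    keep <- rowSums(matrix(win %in% BASES, nrow = length(p))) == 6L
    win <- win[keep, , drop = FALSE]
    if (!nrow(win)) return(NULL)
    tibble(
      context = ctx_label(win[, 2], win[, 3], win[, 4], win[, 5]),
      outer = paste0(win[, 1], win[, 6])
    )
  })
  obs <- dplyr::bind_rows(tallies) |>
    dplyr::count(.data$context, .data$outer, name = "n")
  all_outer <- as.vector(outer(BASES, BASES, paste0))
  grid <- tidyr::expand_grid(context = enumerate_ffd_contexts(),
                             outer = sort(all_outer))
  freqs <- grid |>
    dplyr::left_join(obs, by = c("context", "outer")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$context) |>
    dplyr::mutate(
      total = sum(.data$n),
      freq = ifelse(.data$total > 0, .data$n / .data$total, 1 / 16)
    ) |>
    dplyr::ungroup()
  unseen <- freqs |> dplyr::filter(.data$total == 0) |>
    dplyr::distinct(.data$context)
  if (nrow(unseen)) {
    warn(sprintf(
      "hex_frequencies(): %d FFD contexts never observed; uniform weights used",
      nrow(unseen)
    ))
  }
  freqs |> dplyr::select("context", "outer", "freq")
}

#' Weighted noncoding predictions for FFD tetranucleotide contexts
#'
#' For each FFD tetranucleotide context, predicts the equilibrium A+T
#' content (`AT_w`) and per-base substitution rates (`R_w`) expected at
#' sites following noncoding substitution dynamics but distributed across
#' hexanucleotide contexts the way FFD sites are: the weighted average of
#' the NC hexanucleotide values over the 16 outer-pair extensions, with
#' weights given by the observed hexanucleotide frequencies among FFD
#' sites ([hex_frequencies()]).
#'
#' @param hex_freqs Tibble `context`, `outer`, `freq` from
#'   [hex_frequencies()].
#' @param nc_hex_table Tibble of NC hexanucleotide results with columns
#'   `context`, `outer`, `AT_eq`, and per-base rate columns `rate_A`,
#'   `rate_C`, `rate_G`, `rate_T` (schema written by [make_nc_fixture()]
#'   or assembled from NC hexanucleotide matrices).
#' @return A tibble with one row per context: `context`, `AT_w`, `Rw_A`,
#'   `Rw_C`, `Rw_G`, `Rw_T`. Contexts whose 16 extensions are not all
#'   present in `nc_hex_table` are skipped with a warning.
#' @export
weighted_predictions <- function(hex_freqs, nc_hex_table) {
  need <- c("context", "outer", "AT_eq", paste0("rate_", BASES))
  stopifnot(all(need %in% names(nc_hex_table)))
  joined <- hex_freqs |>
    dplyr::inner_join(nc_hex_table, by = c("context", "outer"))
  complete <- joined |>
    dplyr::group_by(.data$context) |>
    dplyr::filter(dplyr::n() == 16L) |>
    dplyr::ungroup()
  skipped <- setdiff(unique(hex_freqs$context), unique(complete$context))
  if (length(skipped)) {
    warn(sprintf(
      "weighted_predictions(): %d contexts skipped (missing hexanucleotide entries)",
      length(skipped)
    ))
  }
  if (!nrow(complete)) abort("weighted_predictions(): no complete contexts")
  complete |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      AT_w = sum(.data$freq * .data$AT_eq) / sum(.data$freq),
      Rw_A = sum(.data$freq * .data$rate_A) / sum(.data$freq),
      Rw_C = sum(.data$freq * .data$rate_C) / sum(.data$freq),
      Rw_G = sum(.data$freq * .data$rate_G) / sum(.data$freq),
      Rw_T = sum(.data$freq * .data$rate_T) / sum(.data$freq),
      .groups = "drop"
    )
}
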