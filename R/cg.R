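#' Odds ratio of a 2 x 2 substitution contingency table
#'
#' @param a Focal substitutions in the CG context.
#' @param b All other outcomes (including conserved observations) in the CG
#'   context.
#' @param c Focal substitutions outside the CG context.
#' @param d All other outcomes outside the CG context.
#' @return A one-row tibble of class `cg_table`: the four cells and
#'   `odds_ratio` (`a * d / (b * c)`; `NA` when `b * c = 0`).
#' @examples
#' cg_odds_ratio(34376, 304753, 55100, 699456)
#' @export
cg_odds_ratio <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  out <- tibble(
    a = a, b = b, c = c, d = d,
    odds_ratio = ifelse(b * c > 0, (a * d) / (b * c), NA_real_)
  )
  class(out) <- c("cg_table", class(out))
  out
}

#' The CG effect: elevated C -> T substitution in CG dinucleotides
#'
#' Deamination of methylated cytosine elevates the C -> T rate when the C
#' is immediately 5' of a G. Every scored C is classified by whether its 3'
#' neighbour is G. Two framings of the same contrast are computed from the
#' context matrices: the C-row framing (contexts with inner right neighbour
#' R1 = G, focal outcome C -> T vs everything else observed from C) and
#' the complementary G-row framing (contexts with inner left neighbour
#' L1 = C, focal outcome G -> A vs everything else observed from G). On
#' complement-combined matrices the two framings tabulate the same events
#' and give identical odds ratios; on single-strand matrices they differ by
#' the strand asymmetry of the sample.
#'
#' @param counts Count tibble (one site class), typically complement-
#'   combined over the full context universe.
#' @return A tibble of class `cg_table` with two rows (`framing` = `"C_row"`
#'   and `"G_row"`), cells `a`, `b`, `c`, `d` and `odds_ratio`.
#' @export
cg_effect <- function(counts) {
  if (dplyr::n_distinct(counts$site_class) > 1L) {
    abort("cg_effect(): one site class at a time")
  }
  p <- ctx_parts(counts$context)
  row_tot <- rowSums(counts[, BASES])

  cell <- function(rows, focal_col) {
    a <- sum(counts[[focal_col]][rows])
    c(a = a, rest = sum(row_tot[rows]) - a)
  }
  c_rows <- counts$ancestral == "C"
  g_rows <- counts$ancestral == "G"
  cg_c <- cell(c_rows & p$r1 == "G", "T")
  ch_c <- cell(c_rows & p$r1 != "G", "T")
  cg_g <- cell(g_rows & p$l1 == "C", "A")
  dg_g <- cell(g_rows & p$l1 != "C", "A")

  out <- dplyr::bind_rows(
    cg_odds_ratio(cg_c[["a"]], cg_c[["rest"]], ch_c[["a"]], ch_c[["rest"]]),
    cg_odds_ratio(cg_g[["a"]], cg_g[["rest"]], dg_g[["a"]], dg_g[["rest"]])
  )
  out <- dplyr::mutate(out, framing = c("C_row", "G_row"), .before = 1L)
  class(out) <- c("cg_table", class(out))
  out
}

#' Exclude potential CG substitutions from count matrices
#'
#' Drops the C row of every context whose inner right neighbour is G and
#' the G row of every context whose inner left neighbour is C — the two
#' strand framings of a CG dinucleotide that contains the substitution
#' site. Remaining rows are unchanged. Comparative analyses on the
#' filtered matrices show whether FFD-vs-NC differences persist without
#' the CG effect.
#'
#' @param counts Count tibble.
#' @return The filtered count tibble.
#' @examples
#' cm <- tibble::tibble(site_class = "NC", context = "CT.GA",
#'                      ancestral = c("A", "C"), A = c(5L, 0L), C = c(0L, 9L),
#'                      G = c(0L, 0L), T = c(0L, 1L))
#' exclude_cg(cm)  # C row of CT.GA removed (R1 = G)
#' @export
exclude_cg <- function(counts) {
  p <- ctx_parts(counts$context)
  drop <- (counts$ancestral == "C" & p$r1 == "G") |
    (counts$ancestral == "G" & p$l1 == "C")
  counts[!drop, , drop = FALSE]
}
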