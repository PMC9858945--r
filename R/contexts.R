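#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
WEAK <- c("A", "T")
PURINES <- c("A", "G")

#' Complement of nucleotide symbols
#'
#' Vectorised Watson-Crick complement for single-letter nucleotide symbols.
#'
#' @param base Character vector of symbols among `A`, `C`, `G`, `T`.
#' @return Character vector of complements.
#' @examples
#' complement_base(c("A", "C"))
#' @export
complement_base <- function(base) {
  out <- COMPLEMENT[base]
  if (anyNA(out)) abort("complement_base(): symbols must be A, C, G or T")
  unname(out)
}

## A tetranucleotide context is the 4-letter string "L2L1.R1R2": the two
## flanking bases on each side of a (removed) central site, written 5'->3'
## on the strand carrying the site; L1/R1 are the inner neighbours.
ctx_label <- function(l2, l1, r1, r2) paste0(l2, l1, ".", r1, r2)

ctx_parts <- function(context) {
  if (!all(grepl("^[ACGT]{2}\\.[ACGT]{2}$", context))) {
    abort("context labels must look like 'CT.AG'")
  }
  list(
    l2 = substr(context, 1L, 1L), l1 = substr(context, 2L, 2L),
    r1 = substr(context, 4L, 4L), r2 = substr(context, 5L, 5L)
  )
}

#' Reverse complement of a tetranucleotide context label
#'
#' Reverse complementation swaps the left and right flanks with
#' complementation: `revcomp("L2L1.R1R2") = "comp(R2)comp(R1).comp(L1)comp(L2)"`.
#' It is an involution on the 256 tetranucleotide contexts.
#'
#' @param context Character vector of context labels such as `"CT.AG"`.
#' @return Character vector of reverse-complement context labels.
#' @examples
#' revcomp_context("CT.AG")  # self-complementary
#' revcomp_context("GG.AT")
#' @export
revcomp_context <- function(context) {
  p <- ctx_parts(context)
  ctx_label(
    complement_base(p$r2), complement_base(p$r1),
    complement_base(p$l1), complement_base(p$l2)
  )
}

#' All 256 tetranucleotide context labels
#'
#' @return Character vector of the 256 context labels, sorted.
#' @export
all_contexts <- function() {
  g <- expand.grid(r2 = BASES, r1 = BASES, l1 = BASES, l2 = BASES,
                   stringsAsFactors = FALSE)
  sort(ctx_label(g$l2, g$l1, g$r1, g$r2))
}

#' Dinucleotide prefixes of fourfold-degenerate codon families
#'
#' The eight first-two-base pairs whose codon family is fourfold degenerate
#' under the standard genetic code (Leu4, Val, Ser4, Pro, Thr, Ala, Arg4,
#' Gly). A site is a potential fourfold-degenerate (FFD) third codon
#' position only when preceded by one of these prefixes; note no prefix has
#' second base A, so no FFD site has a 5' A neighbour.
#'
#' @return Character vector of eight dinucleotides.
#' @examples
#' ffd_prefixes()
#' @export
ffd_prefixes <- function() {
  c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
}

#' Enumerate the FFD coding-strand tetranucleotide contexts
#'
#' All tetranucleotide contexts whose 5' dinucleotide (L2, L1) is an FFD
#' codon-family prefix; the 3' pair is unrestricted. There are 8 x 16 = 128
#' such contexts.
#'
#' @return Character vector of 128 context labels, sorted.
#' @export
enumerate_ffd_contexts <- function() {
  g <- expand.grid(r2 = BASES, r1 = BASES, pre = ffd_prefixes(),
                   stringsAsFactors = FALSE)
  sort(paste0(g$pre, ".", g$r1, g$r2))
}

#' Canonical representative of a complement-equivalence class
#'
#' A context and its reverse complement describe the same double-stranded
#' neighbourhood; the canonical representative is the lexicographically
#' smaller of the two labels, giving deterministic matrix labelling.
#'
#' @param context Character vector of context labels.
#' @return Character vector of canonical labels.
#' @export
canonical_context <- function(context) {
  rc <- revcomp_context(context)
  ifelse(context <= rc, context, rc)
}

#' The combined-strand context universe
#'
#' Scoring substitutions on both strands extends the 128 FFD coding-strand
#' contexts by their reverse complements, a union of 192 contexts. Since a
#' context and its reverse complement carry redundant (relabel-image)
#' matrices after complement combination, the union collapses into 100
#' complement-equivalence classes (self-complementary contexts are their own
#' class).
#'
#' @return A list with `contexts` (character, 192 labels) and `classes`
#'   (tibble with columns `class` — canonical label — and `members`, a
#'   list-column of the 1 or 2 member contexts).
#' @examples
#' u <- combined_context_universe()
#' length(u$contexts)   # 192
#' nrow(u$classes)      # 100
#' @export
combined_context_universe <- function() {
  ffd <- enumerate_ffd_contexts()
  universe <- sort(union(ffd, revcomp_context(ffd)))
  cls <- tibble(context = universe, class = canonical_context(universe))
  classes <- cls |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(members = list(sort(unique(.data$context))),
                     .groups = "drop")
  list(contexts = universe, classes = classes)
}

#' Classify a substitution by base class and transition/transversion
#'
#' Bases fall into the weak class W = \{A, T\} and strong class S = \{C, G\}.
#' A substitution is a transition when it exchanges two purines or two
#' pyrimidines, otherwise a transversion. The six resulting substitution
#' classes (W->S and S->W transitions; W->S, S->W, S->S and W->W
#' transversions) behave differently between site types, so comparisons are
#' broken down by them.
#'
#' @param from,to Character vectors of ancestral and derived bases
#'   (`from != to` elementwise).
#' @return A tibble with columns `from`, `to`, `class_pair` (one of
#'   `"W->W"`, `"W->S"`, `"S->W"`, `"S->S"`) and `type` (`"transition"` or
#'   `"transversion"`).
#' @examples
#' classify_substitution("C", "T")
#' @export
classify_substitution <- function(from, to) {
  if (!all(from %in% BASES) || !all(to %in% BASES)) {
    abort("classify_substitution(): bases must be A, C, G or T")
  }
  if (any(from == to)) abort("classify_substitution(): from and to must differ")
  fw <- ifelse(from %in% WEAK, "W", "S")
  tw <- ifelse(to %in% WEAK, "W", "S")
  ti <- (from %in% PURINES) == (to %in% PURINES)
  tibble(
    from = from, to = to,
    class_pair = paste0(fw, "->", tw),
    type = ifelse(ti, "transition", "transversion")
  )
}

## Six substitution-class labels used in class breakdowns.
substitution_classes <- function() {
  c("W->S transition", "S->W transition", "W->S transversion",
    "S->W transversion", "S->S transversion", "W->W transversion")
}

## hexanucleotide context label "L3L2L1.R1R2R3" from a tetra context and an
## outer pair written as the 2-letter string "L3R3"
hex_label <- function(context, outer) {
  p <- ctx_parts(context)
  paste0(substr(outer, 1L, 1L), p$l2, p$l1, ".", p$r1, p$r2, substr(outer, 2L, 2L))
}

hex_to_tetra <- function(hex) {
  stopifnot(all(grepl("^[ACGT]{3}\\.[ACGT]{3}$", hex)))
  list(
    context = paste0(substr(hex, 2L, 3L), ".", substr(hex, 5L, 6L)),
    outer = paste0(substr(hex, 1L, 1L), substr(hex, 7L, 7L))
  )
}
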