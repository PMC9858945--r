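#' Default pairwise alignment parameters
#'
#' Global affine-gap alignment scores: match 2, mismatch -1, gap open -2,
#' gap extend -0.5, under the convention that a gap of length L costs
#' `open + extend * (L - 1)`.
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
alignment_params <- function() {
  list(match = 2, mismatch = -1, gap_open = -2, gap_extend = -0.5)
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, scored with
#' the default parameters of [alignment_params()]. End gaps are penalised.
#' Backed by [Biostrings::pairwiseAlignment()]; the gap-cost convention is
#' `gap_open + gap_extend * (L - 1)` for a gap of length L.
#'
#' @param a,b Nucleotide strings (A/C/G/T; ambiguity symbols allowed but
#'   scored as mismatches downstream columns containing them are excluded).
#' @param params Alignment parameters, as from [alignment_params()].
#' @return A list with `a`, `b` (gapped strings of equal length), `score`,
#'   and `gaps` (total gap characters across both rows).
#' @examples
#' align_pair("ACGT", "AGT")
#' @export
align_pair <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("align_pair(): sequences must be non-empty")
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE
  )
  ## Biostrings charges gapOpening + gapExtension * L for a length-L gap;
  ## open' = open - extend, extend' = extend reproduces open + extend*(L-1).
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    type = "global", substitutionMatrix = submat,
    gapOpening = -(params$gap_open - params$gap_extend),
    gapExtension = -params$gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  list(
    a = unname(ga), b = unname(gb),
    score = Biostrings::score(aln),
    gaps = sum(strsplit(paste0(ga, gb), "")[[1]] == "-")
  )
}

#' Merge two reference-anchored pairwise alignments into a triplet alignment
#'
#' The three members of a triplet are aligned pairwise to the first
#' (reference) member and merged on reference coordinates. Insertions
#' relative to the reference are kept as gap columns in the other rows so
#' that alignment-column indices count gaps; reference positions within two
#' columns of any indel are additionally masked (flank context there is
#' ambiguous across members).
#'
#' @param seqs Character vector of three nucleotide strings; the first is
#'   the reference.
#' @param locus Locus identifier carried into the result.
#' @param params Alignment parameters.
#' @return A list of class `triplet_alignment`: `locus`, `mat` (3 x L
#'   character matrix with `-` gaps), `gaps` (total gap characters),
#'   `indel_mask` (logical, columns too close to an indel), `scores`.
#' @export
align_triplet <- function(seqs, locus = "locus", params = alignment_params()) {
  stopifnot(length(seqs) == 3L)
  a12 <- align_pair(seqs[1], seqs[2], params)
  a13 <- align_pair(seqs[1], seqs[3], params)

  ## expand each aligned pair onto a common column scale keyed by reference
  ## position, with insertion columns (ref gap) interleaved deterministically:
  ## member-2 insertions first, then member-3 insertions, after the shared
  ## reference position.
  key12 <- ref_column_keys(a12$a, shift = 0.25)
  key13 <- ref_column_keys(a13$a, shift = 0.50)
  keys <- sort(unique(c(key12, key13)))
  row_on <- function(keys_own, gapped) {
    out <- rep("-", length(keys))
    out[match(keys_own, keys)] <- strsplit(gapped, "")[[1]]
    out
  }
  ref <- row_on(key12, a12$a)
  ref13 <- row_on(key13, a13$a)
  take <- ref == "-" & ref13 != "-"
  ref[take] <- ref13[take]
  mat <- rbind(ref, row_on(key12, a12$b), row_on(key13, a13$b))
  dimnames(mat) <- NULL

  gap_cols <- which(colSums(mat == "-") > 0L)
  mask <- rep(FALSE, ncol(mat))
  for (g in gap_cols) mask[max(1L, g - 2L):min(ncol(mat), g + 2L)] <- TRUE
  structure(
    list(
      locus = locus, mat = mat,
      gaps = sum(mat == "-"),
      indel_mask = mask,
      scores = c(a12$score, a13$score)
    ),
    class = "triplet_alignment"
  )
}

## Column keys for a gapped reference string: reference position for match
## columns, position + a fractional offset for insertion columns. Distinct
## `shift` values for the two pairwise alignments keep their insertion
## columns separate and deterministically ordered when merged.
ref_column_keys <- function(gapped_ref, shift) {
  ch <- strsplit(gapped_ref, "")[[1]]
  pos <- cumsum(ch != "-")
  key <- as.numeric(pos)
  ins <- which(ch == "-")
  if (length(ins)) {
    off <- stats::ave(seq_along(ins), pos[ins], FUN = seq_along)
    key[ins] <- pos[ins] + shift + 0.2 * off / (max(off) + 1)
  }
  key
}

#' Gap-count filter for a triplet alignment
#'
#' A locus alignment with more than `max_gaps` total gap characters is
#' excluded from further analysis (strictly more; 30 gaps is kept).
#'
#' @param aln A `triplet_alignment`.
#' @param max_gaps Maximum tolerated total gap characters (default 30).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
keep_alignment <- function(aln, max_gaps = 30) {
  aln$gaps <= max_gaps
}
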