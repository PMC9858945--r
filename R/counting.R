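#' Build a triplet alignment from already-aligned (or gap-free) sequences
#'
#' Utility for sequences that are already columnwise homologous (e.g.
#' simulator output, which plants no indels): wraps them in the same
#' `triplet_alignment` structure produced by [align_triplet()].
#'
#' @param seqs Character vector of three equal-length sequences (may contain
#'   `-` gap characters).
#' @param locus Locus identifier.
#' @return A `triplet_alignment`.
#' @export
as_triplet_alignment <- function(seqs, locus = "locus") {
  stopifnot(length(seqs) == 3L)
  if (length(unique(nchar(seqs))) != 1L) {
    abort("as_triplet_alignment(): sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  dimnames(mat) <- NULL
  structure(
    list(locus = locus, mat = mat, gaps = sum(mat == "-"),
         indel_mask = rep(FALSE, ncol(mat)), scores = NULL),
    class = "triplet_alignment"
  )
}

## integer-coded alignment matrix: 1..4 for A,C,G,T; NA for gaps and
## ambiguity codes (columns containing them are never scored)
code_matrix <- function(mat) {
  m <- match(mat, BASES)
  dim(m) <- dim(mat)
  m
}

## columns where all three members carry the identical unambiguous base
conserved_columns <- function(M) {
  ok <- colSums(!is.na(M)) == 3L
  ok & M[1, ] == M[2, ] & M[2, ] == M[3, ]
}

#' Identify fourfold-degenerate columns of a triplet alignment
#'
#' A column is a potential FFD site when it falls at the third codon
#' position — alignment-column index counted from the codon anchor, gaps
#' included (gaps are assumed not to change the reading frame) — and its 5'
#' dinucleotide is gap-free, identical in all three members, and one of the
#' eight FFD codon-family prefixes ([ffd_prefixes()]).
#'
#' @param aln A `triplet_alignment`.
#' @param frame_anchor 1-based alignment column of the first codon base.
#' @return Integer vector of FFD column indices.
#' @export
identify_ffd_columns <- function(aln, frame_anchor = 1L) {
  M <- code_matrix(aln$mat)
  L <- ncol(M)
  cols <- seq_len(L)
  third <- (cols - frame_anchor) %% 3L == 2L & cols >= frame_anchor + 2L
  cand <- which(third & cols >= 3L)
  if (!length(cand)) return(integer())
  din_ok <- conserved_columns(M)[cand - 2L] & conserved_columns(M)[cand - 1L]
  cand <- cand[din_ok & !is.na(din_ok)]
  prefix <- paste0(aln$mat[1, cand - 2L], aln$mat[1, cand - 1L])
  cand[prefix %in% ffd_prefixes()]
}

#' Classify noncoding site positions, optionally by CDS proximity
#'
#' Labels positions as noncoding (NC) and, when CDS boundary coordinates
#' are supplied, flags the NC30 subset: sites whose distance to the nearest
#' annotated CDS start or stop codon boundary is at most `proximity`
#' nucleotides.
#'
#' @param positions Integer vector of site coordinates (same coordinate
#'   system as `cds_boundaries`).
#' @param cds_boundaries Integer vector of CDS start/stop boundary
#'   coordinates, or `NULL` when no annotation is available.
#' @param proximity Maximum distance for the NC30 subset (default 30).
#' @return A tibble with columns `position`, `site_class` (`"NC"`) and
#'   `nc30` (logical; `NA` when no annotation was supplied).
#' @examples
#' classify_nc_sites(c(110, 131), cds_boundaries = 100)
#' @export
classify_nc_sites <- function(positions, cds_boundaries = NULL, proximity = 30) {
  if (is.null(cds_boundaries) || !length(cds_boundaries)) {
    warn("classify_nc_sites(): no CDS annotation supplied; NC30 unavailable")
    return(tibble(position = positions, site_class = "NC", nc30 = NA))
  }
  d <- vapply(positions, function(p) min(abs(p - cds_boundaries)), numeric(1))
  tibble(position = positions, site_class = "NC", nc30 = d <= proximity)
}

#' Infer substitutions and conserved-site tallies from a triplet alignment
#'
#' For each scoreable column — gap-free focal base in all three members and
#' a gap-free, fully conserved tetranucleotide flank — applies the
#' two-agree parsimony rule: if all three bases agree, one conserved
#' (diagonal) observation is tallied per lineage; if exactly two agree, the
#' shared base is taken as ancestral and the minority member contributes one
#' substitution event (the two agreeing lineages still contribute conserved
#' observations); columns where all three differ are skipped.
#'
#' @param aln A `triplet_alignment`.
#' @param columns Integer vector of candidate focal columns (e.g. from
#'   [identify_ffd_columns()], or all columns for noncoding loci).
#' @param site_class Site-class label stamped on the output (`"FFD"`,
#'   `"NC"`, ...).
#' @return A list with `events` (tibble: `locus`, `column`, `ref_pos`,
#'   `site_class`, `context`, `ancestral`, `derived`, `lineage`) and
#'   `diagonals` (tibble: `locus`, `column`, `ref_pos`, `site_class`,
#'   `context`, `base`, `n`).
#' @export
infer_substitutions <- function(aln, columns, site_class = "NC") {
  M <- code_matrix(aln$mat)
  L <- ncol(M)
  cons <- conserved_columns(M)
  ref_pos <- cumsum(aln$mat[1, ] != "-")
  ref_pos[aln$mat[1, ] == "-"] <- NA_integer_

  cand <- columns[columns >= 3L & columns <= L - 2L]
  if (length(cand)) {
    flank_ok <- cons[cand - 2L] & cons[cand - 1L] & cons[cand + 1L] & cons[cand + 2L] &
      !aln$indel_mask[cand]
    focal_ok <- colSums(!is.na(M))[cand] == 3L
    cand <- cand[flank_ok & focal_ok]
  }
  empty_events <- tibble(
    locus = character(), column = integer(), ref_pos = integer(),
    site_class = character(), context = character(),
    ancestral = character(), derived = character(), lineage = integer()
  )
  empty_diag <- tibble(
    locus = character(), column = integer(), ref_pos = integer(),
    site_class = character(), context = character(),
    base = character(), n = integer()
  )
  if (!length(cand)) return(list(events = empty_events, diagonals = empty_diag))

  ctx <- ctx_label(aln$mat[1, cand - 2L], aln$mat[1, cand - 1L],
                   aln$mat[1, cand + 1L], aln$mat[1, cand + 2L])
  b1 <- M[1, cand]; b2 <- M[2, cand]; b3 <- M[3, cand]
  e12 <- b1 == b2; e13 <- b1 == b3; e23 <- b2 == b3
  all_same <- e12 & e13
  n_agree <- e12 + e13 + e23

  diagonals <- empty_diag
  events <- empty_events

  if (any(all_same)) {
    diagonals <- tibble(
      locus = aln$locus, column = cand[all_same],
      ref_pos = ref_pos[cand[all_same]], site_class = site_class,
      context = ctx[all_same], base = BASES[b1[all_same]], n = 3L
    )
  }
  two <- !all_same & n_agree == 1L
  if (any(two)) {
    dev <- ifelse(e12[two], 3L, ifelse(e13[two], 2L, 1L))
    idx <- cbind(dev, cand[two])
    shared <- ifelse(e12[two], b1[two], ifelse(e13[two], b1[two], b2[two]))
    derived <- M[idx]
    events <- tibble(
      locus = aln$locus, column = cand[two], ref_pos = ref_pos[cand[two]],
      site_class = site_class, context = ctx[two],
      ancestral = BASES[shared], derived = BASES[derived], lineage = dev
    )
    diagonals <- dplyr::bind_rows(diagonals, tibble(
      locus = aln$locus, column = cand[two], ref_pos = ref_pos[cand[two]],
      site_class = site_class, context = ctx[two],
      base = BASES[shared], n = 2L
    ))
  }
  ## columns where all three differ are skipped silently
  list(events = events, diagonals = diagonals)
}

#' Accumulate substitution events and conserved tallies into count matrices
#'
#' Builds one 4 x 4 ancestral-by-observed count matrix per tetranucleotide
#' context and site class, in tidy form: one row per (site class, context,
#' ancestral base), one column per observed base. Off-diagonal cells count
#' substitution events; diagonal cells count conserved site-lineage
#' observations. Total off-diagonals equal the number of input events.
#'
#' @param events,diagonals Tibbles as returned by [infer_substitutions()]
#'   (possibly row-bound across many loci).
#' @return A tibble with columns `site_class`, `context`, `ancestral`,
#'   `A`, `C`, `G`, `T`.
#' @export
accumulate_counts <- function(events, diagonals) {
  bad <- unique(c(events$context, diagonals$context))
  bad <- bad[!grepl("^[ACGT]{2}\\.[ACGT]{2}$", bad)]
  if (length(bad)) {
    abort(paste0("accumulate_counts(): invalid contexts: ",
                 paste(bad, collapse = ", ")))
  }
  long <- dplyr::bind_rows(
    events |>
      dplyr::count(.data$site_class, .data$context, .data$ancestral,
                   observed = .data$derived, name = "n"),
    diagonals |>
      dplyr::group_by(.data$site_class, .data$context,
                      ancestral = .data$base, observed = .data$base) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  )
  counts_from_long(long)
}

## long (site_class, context, ancestral, observed, n) -> wide count tibble
counts_from_long <- function(long) {
  long |>
    dplyr::group_by(.data$site_class, .data$context, .data$ancestral,
                    .data$observed) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "observed", values_from = "n",
                       values_fill = 0L) |>
    add_missing_base_cols() |>
    dplyr::select("site_class", "context", "ancestral",
                  dplyr::all_of(BASES)) |>
    dplyr::arrange(.data$site_class, .data$context, .data$ancestral)
}

add_missing_base_cols <- function(tbl) {
  for (b in BASES) if (!b %in% names(tbl)) tbl[[b]] <- 0L
  tbl
}

#' Extract one context's 4 x 4 count matrix
#'
#' @param counts Count tibble as from [accumulate_counts()].
#' @param context Context label.
#' @param site_class Site-class label (default: the only one present).
#' @return A 4 x 4 numeric matrix with rows/columns A, C, G, T (absent rows
#'   are zero).
#' @export
counts_matrix <- function(counts, context, site_class = NULL) {
  x <- counts |> dplyr::filter(.data$context == .env$context)
  if (!is.null(site_class)) {
    x <- x |> dplyr::filter(.data$site_class == .env$site_class)
  } else if (dplyr::n_distinct(x$site_class) > 1L) {
    abort("counts_matrix(): several site classes present; specify one")
  }
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  if (nrow(x)) m[x$ancestral, ] <- as.matrix(x[, BASES])
  m
}

#' Combine complementary context matrices onto both strands
#'
#' For each context `c` in the union of the input contexts and their
#' reverse complements, the combined matrix is
#' `M(c) + relabel(M(revcomp(c)))`, where `relabel` maps ancestral and
#' observed bases through complementation. Combined matrices for a context
#' and its reverse complement are exact relabel-images of each other, so
#' analyses use one matrix per complement-equivalence class (column
#' `class`, the canonical label).
#'
#' @param counts Count tibble (coding-strand matrices).
#' @return Count tibble over the union universe, with an extra `class`
#'   column naming the complement-equivalence class of each context.
#' @export
combine_complements <- function(counts) {
  long <- counts |>
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "observed",
                        values_to = "n")
  mirrored <- long |>
    dplyr::mutate(
      context = revcomp_context(.data$context),
      ancestral = complement_base(.data$ancestral),
      observed = complement_base(.data$observed)
    )
  combined <- counts_from_long(dplyr::bind_rows(long, mirrored))
  combined |> dplyr::mutate(class = canonical_context(.data$context))
}

#' Per-context substitution totals and sparseness flags
#'
#' @param counts Count tibble.
#' @param min_subs Minimum total substitutions for a matrix to enter
#'   comparative statistics (default 10).
#' @return Tibble: `site_class`, `context`, `n_subs`, `n_obs`, `sparse`.
#' @export
context_totals <- function(counts, min_subs = 10) {
  counts |>
    tidyr::pivot_longer(dplyr::all_of(BASES), names_to = "observed",
                        values_to = "n") |>
    dplyr::group_by(.data$site_class, .data$context) |>
    dplyr::summarise(
      n_subs = sum(.data$n[.data$ancestral != .data$observed]),
      n_obs = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(sparse = .data$n_subs < min_subs)
}

#' Score a set of triplet loci into context count matrices
#'
#' End-to-end counting: optionally aligns each locus triplet (pairwise to
#' the first member, merged on reference coordinates), applies the gap
#' filter, identifies FFD or noncoding columns, infers substitutions, and
#' accumulates coding-strand count matrices.
#'
#' @param loci A tibble with columns `locus`, `type` (`"coding"` or
#'   `"noncoding"`), `seq1`, `seq2`, `seq3`; optionally `frame_anchor`
#'   (default 1) and, for noncoding loci, `cds_boundaries` (list-column of
#'   boundary coordinates for NC30 classification).
#' @param align Align triplets with [align_triplet()] (`TRUE`) or treat the
#'   sequences as already columnwise homologous (`FALSE`).
#' @param max_gaps Gap-filter threshold; loci whose alignment carries more
#'   gap characters are excluded.
#' @param nc30_proximity Distance threshold for the NC30 subset.
#' @param params Alignment parameters.
#' @return A list with `counts` (tidy count tibble; site classes `FFD`,
#'   `NC` and — when boundaries were supplied — `NC30`), `events` (per-event
#'   tibble), and `excluded` (character vector of loci dropped by the gap
#'   filter).
#' @export
count_triplets <- function(loci, align = TRUE, max_gaps = 30,
                           nc30_proximity = 30, params = alignment_params()) {
  stopifnot(all(c("locus", "type", "seq1", "seq2", "seq3") %in% names(loci)))
  events <- list(); diagonals <- list(); excluded <- character()
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    seqs <- c(row$seq1, row$seq2, row$seq3)
    aln <- if (align) align_triplet(seqs, locus = row$locus, params = params)
           else as_triplet_alignment(seqs, locus = row$locus)
    if (!keep_alignment(aln, max_gaps)) {
      excluded <- c(excluded, row$locus)
      next
    }
    if (row$type == "coding") {
      anchor <- if ("frame_anchor" %in% names(loci)) row$frame_anchor else 1L
      cols <- identify_ffd_columns(aln, frame_anchor = anchor)
      sc <- infer_substitutions(aln, cols, site_class = "FFD")
    } else {
      cols <- seq_len(ncol(aln$mat))
      sc <- infer_substitutions(aln, cols, site_class = "NC")
      bounds <- if ("cds_boundaries" %in% names(loci)) row$cds_boundaries[[1]] else NULL
      if (!is.null(bounds)) {
        mark30 <- function(tbl) {
          d <- vapply(tbl$ref_pos,
                      function(p) min(abs(p - bounds)), numeric(1))
          dplyr::bind_rows(tbl,
                           tbl[d <= nc30_proximity, ] |>
                             dplyr::mutate(site_class = "NC30"))
        }
        sc$events <- mark30(sc$events)
        sc$diagonals <- mark30(sc$diagonals)
      }
    }
    events[[length(events) + 1L]] <- sc$events
    diagonals[[length(diagonals) + 1L]] <- sc$diagonals
  }
  events <- dplyr::bind_rows(events)
  diagonals <- dplyr::bind_rows(diagonals)
  if (!nrow(events) && !nrow(diagonals)) {
    abort("count_triplets(): no scoreable columns in any locus")
  }
  list(
    counts = accumulate_counts(events, diagonals),
    events = events,
    excluded = excluded
  )
}

#' Read and write count-matrix files
#'
#' Count matrices are exchanged as TSV with columns `context`, `ancestral`,
#' `A`, `C`, `G`, `T` (one file per site class), the schema used by all
#' matrix artifacts of the pipeline.
#'
#' @param counts Count tibble (a single site class).
#' @param path File path.
#' @return `read_count_matrices()` returns a count tibble (with the
#'   `site_class` column restored from the `site_class` argument).
#' @param site_class Site-class label to stamp on rows when reading.
#' @export
write_count_matrices <- function(counts, path) {
  if (dplyr::n_distinct(counts$site_class) > 1L) {
    abort("write_count_matrices(): one site class per file")
  }
  readr::write_tsv(counts |> dplyr::select("context", "ancestral",
                                           dplyr::all_of(BASES)), path)
  invisible(path)
}

#' @rdname write_count_matrices
#' @export
read_count_matrices <- function(path, site_class) {
  readr::read_tsv(path, col_types = readr::cols(
    context = readr::col_character(), ancestral = readr::col_character(),
    .default = readr::col_double()
  )) |>
    dplyr::mutate(site_class = site_class, .before = 1L)
}
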