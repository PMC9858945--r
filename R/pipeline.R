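#' Pipeline run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. Defaults are
#' the analysis constants used throughout: alignment scores match 2 /
#' mismatch -1 / gap open -2 / gap extend -0.5, gap-exclusion threshold 30,
#' sparse-matrix minimum 10 substitutions, 1000 bootstrap resamples, NC30
#' proximity 30 nt.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer root seed for every stochastic stage.
#' @param manifest Optional path to a triplet manifest (TSV with columns
#'   `locus`, `type`, and either `seq1`..`seq3` or `file`, `id1`..`id3`
#'   naming records in a FASTA file); when `NULL` the `simulate` stage
#'   provides the input.
#' @param align Run the aligner on each triplet (disable for pre-aligned
#'   or indel-free input).
#' @param max_gaps Gap-exclusion threshold.
#' @param min_subs Sparse-matrix minimum substitution count.
#' @param bootstrap_n Bootstrap resamples for equilibrium uncertainty.
#' @param nc30_proximity NC30 distance threshold (nt).
#' @param alignment Alignment parameter list ([alignment_params()]).
#' @param sim Simulation settings for the `simulate` stage: a list with
#'   `n_coding_loci`, `n_noncoding_loci`, `locus_length`, and arguments
#'   passed to [evolution_model()] (`at_eq`, `titv`, `context_sdlog`,
#'   `cg_boost`, `branch_lengths`).
#' @param nc_hex_path Optional path to a hexanucleotide NC results table
#'   for the `weights` stage (defaults to the fixture written by the
#'   `simulate` stage).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, manifest = NULL, align = TRUE,
                       max_gaps = 30, min_subs = 10, bootstrap_n = 1000,
                       nc30_proximity = 30, alignment = alignment_params(),
                       sim = list(n_coding_loci = 40, n_noncoding_loci = 40,
                                  locus_length = 999),
                       nc_hex_path = NULL) {
  stopifnot(max_gaps >= 0, min_subs >= 0, bootstrap_n >= 0,
            nc30_proximity >= 0)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), manifest = manifest,
         align = align, max_gaps = max_gaps, min_subs = min_subs,
         bootstrap_n = bootstrap_n, nc30_proximity = nc30_proximity,
         alignment = alignment, sim = sim, nc_hex_path = nc_hex_path),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_stages <- function() {
  c("simulate", "count", "combine", "equilibrium", "compare", "cgeffect",
    "weights")
}

stage_path <- function(config, file) file.path(config$out_dir, file)

write_manifest <- function(config, stage, inputs, outputs, extra = list()) {
  manifest <- c(
    list(stage = stage, version = as.character(utils::packageVersion("ctxsub")),
         seed = config$seed, inputs = inputs, outputs = outputs,
         parameters = list(max_gaps = config$max_gaps,
                           min_subs = config$min_subs,
                           bootstrap_n = config$bootstrap_n,
                           nc30_proximity = config$nc30_proximity,
                           alignment = config$alignment)),
    extra
  )
  path <- stage_path(config, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s': missing upstream artifact '%s'", stage, path))
  }
  path
}

#' Run pipeline stages
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' (TSV tables with headers, JSON sidecars) plus a manifest recording
#' inputs, parameters, seed, version and record counts to the configured
#' output directory. Stages are idempotent; a rerun with the same
#' configuration reproduces deterministic artifacts byte-identically.
#' Stages: `simulate` (synthetic triplet loci, ground-truth model and NC
#' fixtures), `count` (triplet alignment, site classification, count
#' matrices), `combine` (complement combination), `equilibrium`
#' (stationary vectors, skews, bootstrap), `compare` (FFD-vs-NC rate and
#' equilibrium comparisons with class breakdown), `cgeffect` (CG
#' contingency tables), `weights` (hexanucleotide-weighted predictions).
#'
#' @param config A `run_config`.
#' @param stages Character vector of stages (default: all, in order).
#' @return Invisibly, a named list of artifact paths per stage.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (st in pipeline_stages()[pipeline_stages() %in% stages]) {
    message("[ctxsub] stage: ", st)
    out[[st]] <- switch(
      st,
      simulate = stage_simulate(config),
      count = stage_count(config),
      combine = stage_combine(config),
      equilibrium = stage_equilibrium(config),
      compare = stage_compare(config),
      cgeffect = stage_cgeffect(config),
      weights = stage_weights(config)
    )
  }
  invisible(out)
}

stage_simulate <- function(config) {
  s <- config$sim
  model_args <- s[intersect(names(s), names(formals(evolution_model)))]
  model_args$seed <- config$seed
  model <- do.call(evolution_model, model_args)

  coding <- simulate_triplet_set(model, s$n_coding_loci, s$locus_length,
                                 seed = context_seed(config$seed, "coding"),
                                 coding = TRUE)
  noncod <- simulate_triplet_set(model, s$n_noncoding_loci, s$locus_length,
                                 seed = context_seed(config$seed, "noncoding"),
                                 coding = FALSE)
  loci <- dplyr::bind_rows(coding$loci, noncod$loci) |>
    dplyr::mutate(locus = sprintf("%s_%s", .data$type, .data$locus))
  events <- dplyr::bind_rows(
    coding$events |> dplyr::mutate(locus = paste0("coding_", .data$locus)),
    noncod$events |> dplyr::mutate(locus = paste0("noncoding_", .data$locus))
  )
  loci_path <- stage_path(config, "loci.tsv")
  events_path <- stage_path(config, "planted_events.tsv")
  readr::write_tsv(loci, loci_path)
  readr::write_tsv(events, events_path)

  fixture <- make_nc_fixture(model, depth = s$nc_fixture_depth %||% 2e4,
                             seed = config$seed)
  tetra_path <- stage_path(config, "nc_fixture_tetra.tsv")
  hex_path <- stage_path(config, "nc_fixture_hex.tsv")
  readr::write_tsv(fixture$tetra, tetra_path)
  readr::write_tsv(fixture$hex, hex_path)

  model_path <- stage_path(config, "model.json")
  jsonlite::write_json(
    list(seed = model$seed, composition = as.list(model$composition),
         branch_lengths = model$branch_lengths, cg_boost = model$cg_boost,
         strand_symmetric = model$strand_symmetric,
         equilibrium = model_equilibrium(model)),
    model_path, auto_unbox = TRUE, digits = NA
  )
  write_manifest(config, "simulate", inputs = list(),
                 outputs = list(loci = loci_path, events = events_path,
                                model = model_path),
                 extra = list(n_loci = nrow(loci),
                              n_planted_events = nrow(events)))
  list(loci = loci_path, events = events_path, model = model_path,
       nc_hex = hex_path, nc_tetra = tetra_path)
}

read_triplet_manifest <- function(path) {
  loci <- readr::read_tsv(path, show_col_types = FALSE)
  if (all(c("seq1", "seq2", "seq3") %in% names(loci))) return(loci)
  if (!all(c("file", "id1", "id2", "id3") %in% names(loci))) {
    abort("triplet manifest needs seq1..seq3 or file + id1..id3 columns")
  }
  pull_seqs <- function(file, ids) {
    fa <- Biostrings::readDNAStringSet(file)
    miss <- setdiff(ids, names(fa))
    if (length(miss)) {
      abort(paste0("manifest ids missing from ", file, ": ",
                   paste(miss, collapse = ", ")))
    }
    as.character(fa[ids])
  }
  seqs <- purrr::map2(loci$file, purrr::pmap(loci[c("id1", "id2", "id3")], c),
                      pull_seqs)
  loci$seq1 <- vapply(seqs, `[[`, character(1), 1L)
  loci$seq2 <- vapply(seqs, `[[`, character(1), 2L)
  loci$seq3 <- vapply(seqs, `[[`, character(1), 3L)
  loci
}

stage_count <- function(config) {
  manifest_path <- config$manifest %||% stage_path(config, "loci.tsv")
  require_artifact(manifest_path, "count")
  loci <- read_triplet_manifest(manifest_path)
  res <- count_triplets(loci, align = config$align,
                        max_gaps = config$max_gaps,
                        nc30_proximity = config$nc30_proximity,
                        params = config$alignment)
  paths <- character()
  for (sc in unique(res$counts$site_class)) {
    p <- stage_path(config, paste0("counts_", sc, ".tsv"))
    write_count_matrices(res$counts |> dplyr::filter(.data$site_class == sc), p)
    paths[sc] <- p
  }
  events_path <- stage_path(config, "inferred_events.tsv")
  readr::write_tsv(res$events, events_path)
  write_manifest(config, "count",
                 inputs = list(manifest = manifest_path),
                 outputs = as.list(paths),
                 extra = list(n_events = nrow(res$events),
                              n_excluded_loci = length(res$excluded),
                              excluded = res$excluded))
  c(as.list(paths), list(events = events_path))
}

count_artifacts <- function(config, prefix) {
  files <- list.files(config$out_dir, pattern = paste0("^", prefix, "_.*\\.tsv$"),
                      full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  setNames(files, sub(paste0("^", prefix, "_(.*)\\.tsv$"), "\\1",
                      basename(files)))
}

stage_combine <- function(config) {
  files <- count_artifacts(config, "counts")
  if (!length(files)) abort("stage 'combine': missing upstream artifact 'counts_*.tsv'")
  paths <- character()
  n_subs <- list()
  for (sc in names(files)) {
    counts <- read_count_matrices(files[[sc]], site_class = sc)
    combined <- combine_complements(counts)
    p <- stage_path(config, paste0("combined_", sc, ".tsv"))
    readr::write_tsv(combined, p)
    paths[sc] <- p
    n_subs[[sc]] <- context_totals(combined, config$min_subs)$n_subs |> sum()
  }
  write_manifest(config, "combine", inputs = as.list(files),
                 outputs = as.list(paths),
                 extra = list(n_substitutions = n_subs))
  as.list(paths)
}

read_combined <- function(path, sc) {
  readr::read_tsv(path, col_types = readr::cols(
    site_class = readr::col_character(), context = readr::col_character(),
    ancestral = readr::col_character(), class = readr::col_character(),
    .default = readr::col_double()
  ))
}

stage_equilibrium <- function(config) {
  files <- count_artifacts(config, "combined")
  if (!length(files)) abort("stage 'equilibrium': missing upstream artifact 'combined_*.tsv'")
  paths <- character()
  for (sc in names(files)) {
    combined <- read_combined(files[[sc]], sc)
    reps <- combined |> dplyr::filter(.data$context == .data$class)
    eq <- equilibrium_profile(reps, bootstrap_n = config$bootstrap_n,
                              seed = config$seed, min_subs = config$min_subs)
    p <- stage_path(config, paste0("equilibrium_", sc, ".tsv"))
    readr::write_tsv(
      eq |> dplyr::select("context", "n_subs", "AT_eq", "AT_boot_mean",
                          "AT_boot_sd", "skew_AT", "skew_GC", "sparse",
                          "flag"),
      p
    )
    paths[sc] <- p
  }
  write_manifest(config, "equilibrium", inputs = as.list(files),
                 outputs = as.list(paths))
  as.list(paths)
}

stage_compare <- function(config) {
  cfiles <- count_artifacts(config, "combined")
  efiles <- count_artifacts(config, "equilibrium")
  for (sc in c("FFD", "NC")) {
    require_artifact(cfiles[sc] %||% "", "compare")
    require_artifact(efiles[sc] %||% "", "compare")
  }
  load_side <- function(sc) {
    combined <- read_combined(cfiles[[sc]], sc)
    reps <- combined |> dplyr::filter(.data$context == .data$class)
    tot <- context_totals(reps, config$min_subs)
    usable <- tot |> dplyr::filter(!.data$sparse)
    rates <- row_rates(reps |> dplyr::semi_join(usable, by = c("site_class", "context")))
    eq <- readr::read_tsv(efiles[[sc]], show_col_types = FALSE) |>
      dplyr::filter(!.data$sparse, .data$flag == "ok")
    list(counts = reps |> dplyr::semi_join(usable, by = c("site_class", "context")),
         rates = rates, eq = eq)
  }
  ffd <- load_side("FFD")
  nc <- load_side("NC")

  rate_cmp <- compare_contexts(ffd$rates, nc$rates, "rate")
  eq_cmp <- compare_contexts(ffd$eq, nc$eq, "AT_eq")
  breakdown <- class_breakdown(ffd$counts, nc$counts, config$min_subs)

  rate_path <- stage_path(config, "comparison_rates.tsv")
  eq_path <- stage_path(config, "comparison_equilibrium.tsv")
  breakdown_path <- stage_path(config, "class_breakdown.tsv")
  summary_path <- stage_path(config, "comparison_summary.json")
  readr::write_tsv(tidy(rate_cmp), rate_path)
  readr::write_tsv(tidy(eq_cmp), eq_path)
  readr::write_tsv(breakdown, breakdown_path)
  jsonlite::write_json(
    list(
      rates = c(rate_cmp$summary,
                list(bayes_factor = bayes_factor_binomial(
                  rate_cmp$summary$n_higher, rate_cmp$summary$n))),
      equilibrium_AT = c(eq_cmp$summary,
                         list(bayes_factor = bayes_factor_binomial(
                           eq_cmp$summary$n_higher, eq_cmp$summary$n)))
    ),
    summary_path, auto_unbox = TRUE, digits = NA
  )
  write_manifest(config, "compare",
                 inputs = as.list(c(cfiles[c("FFD", "NC")],
                                    efiles[c("FFD", "NC")])),
                 outputs = list(rates = rate_path, equilibrium = eq_path,
                                breakdown = breakdown_path,
                                summary = summary_path),
                 extra = list(n_rate_pairs = rate_cmp$summary$n,
                              n_eq_pairs = eq_cmp$summary$n))
  list(rates = rate_path, equilibrium = eq_path, breakdown = breakdown_path,
       summary = summary_path)
}

stage_cgeffect <- function(config) {
  cfiles <- count_artifacts(config, "combined")
  require_artifact(cfiles["FFD"] %||% "", "cgeffect")
  combined <- read_combined(cfiles[["FFD"]], "FFD")
  cg <- cg_effect(combined |> dplyr::select(-"class"))
  path <- stage_path(config, "cg_effect.json")
  jsonlite::write_json(cg, path, auto_unbox = TRUE, digits = NA)
  write_manifest(config, "cgeffect", inputs = list(combined = cfiles[["FFD"]]),
                 outputs = list(cg_effect = path))
  list(cg_effect = path)
}

stage_weights <- function(config) {
  loci_path <- config$manifest %||% stage_path(config, "loci.tsv")
  require_artifact(loci_path, "weights")
  hex_path <- config$nc_hex_path %||% stage_path(config, "nc_fixture_hex.tsv")
  require_artifact(hex_path, "weights")
  loci <- read_triplet_manifest(loci_path)
  genes <- loci |> dplyr::filter(.data$type == "coding")
  if (!nrow(genes)) abort("stage 'weights': no coding loci for hexanucleotide frequencies")
  freqs <- hex_frequencies(c(genes$seq1, genes$seq2, genes$seq3))
  hex_counts <- readr::read_tsv(hex_path, show_col_types = FALSE)
  nc_hex <- hex_matrix_results(hex_counts)
  pred <- weighted_predictions(freqs, nc_hex)
  path <- stage_path(config, "weighted_predictions.tsv")
  readr::write_tsv(pred, path)
  write_manifest(config, "weights",
                 inputs = list(loci = loci_path, nc_hex = hex_path),
                 outputs = list(weighted_predictions = path),
                 extra = list(n_contexts = nrow(pred)))
  list(weighted_predictions = path)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
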