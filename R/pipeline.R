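#' Load a dataset directory
#'
#' Expects `manifest.tsv`, `layout.tsv`, optional `mask.tsv`, and one
#' `<gene>.fasta` per layout gene (missing gene files are tolerated and
#' surface downstream as unresolved).
#'
#' @param dir Input directory.
#' @return A list with `alignments`, `manifest`, `layout`.
#' @export
load_dataset <- function(dir) {
  if (!dir.exists(dir)) {
    stop_tetmat(sprintf("input directory not found: %s", dir), "tetmat_config_error")
  }
  mf <- file.path(dir, "manifest.tsv")
  lf <- file.path(dir, "layout.tsv")
  if (!file.exists(mf) || !file.exists(lf)) {
    stop_tetmat(sprintf("input directory %s lacks manifest.tsv/layout.tsv", dir),
                "tetmat_config_error")
  }
  manifest <- read_strain_manifest(mf)
  layout <- read_chromosome_layout(lf)
  mask <- if (file.exists(file.path(dir, "mask.tsv"))) {
    read_coding_mask(file.path(dir, "mask.tsv"))
  }
  alignments <- list()
  for (g in layout$gene) {
    fp <- file.path(dir, paste0(g, ".fasta"))
    if (!file.exists(fp)) next
    alignments[[g]] <- read_gene_alignment(fp, mask = mask, gene = g,
                                           manifest = manifest)
  }
  if (length(alignments) == 0) {
    stop_tetmat(sprintf("no per-gene FASTA files found in %s", dir),
                "tetmat_config_error")
  }
  list(alignments = alignments, manifest = manifest, layout = layout)
}

#' Run the full mat-chromosome analysis pipeline
#'
#' Chains every stage: allelic divergence, per-gene NJ genealogies with
#' bootstrap supports, phase calls, suppressed-region demarcation, boundary
#' comparison, conversion detection with template direction and ancestral
#' merging, crossover detection, and homogenization rates. When `out_dir` is
#' given, a complete report bundle is written (TSV tables, per-gene Newick,
#' JSON events, text summary, and a MANIFEST of completed stages — retained
#' even when a stage fails). All randomness is governed by
#' `thresholds$seed`, fanned out per gene, so reruns are byte-identical.
#'
#' @param input A dataset directory, a [simulate_dataset()] result, or a
#'   [sim_config()] (simulated on the fly).
#' @param out_dir Optional output directory.
#' @param thresholds A [support_thresholds()] (bootstrap replicates, support
#'   cutoffs, together-distance, seed).
#' @param min_diffs Divergence classification threshold (raw differences).
#' @param strict Strict three-adjacent-gene conversion windows.
#' @param persistence Crossover persistence (informative genes).
#' @param direction_majority Clade purity for template/affiliation calls.
#' @param merge_max_diffs,merge_max_prop Ancestral-merge identity tolerance.
#' @param n_lineages Lineage count for rates (default: distinct lineages in
#'   the manifest).
#' @param T_divergence Lineage divergence time in million years.
#' @param trees Optional named list of user-supplied [supported_tree()]
#'   objects (e.g. externally inferred ML/Bayesian trees); genes present here
#'   skip NJ/bootstrap.
#' @return A list of class `tet_pipeline` with every stage's tibbles.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         thresholds = support_thresholds(),
                         min_diffs = 2L, strict = FALSE, persistence = 2L,
                         direction_majority = 1, merge_max_diffs = 0L,
                         merge_max_prop = NULL, n_lineages = NULL,
                         T_divergence = 4.6, trees = NULL) {
  data <- if (is.character(input)) {
    load_dataset(input)
  } else if (inherits(input, "tet_sim_config")) {
    simulate_dataset(input)
  } else if (inherits(input, "tet_sim")) {
    input
  } else {
    stop_tetmat("input must be a directory, tet_sim or tet_sim_config",
                "tetmat_config_error")
  }
  alignments <- data$alignments
  manifest <- data$manifest
  layout <- data$layout
  if (is.null(n_lineages)) n_lineages <- length(unique(manifest$lineage))

  done <- character(0)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  }
  log_stage <- function(name) {
    done <<- c(done, name)
    if (!is.null(out_dir)) {
      writeLines(done, file.path(out_dir, "MANIFEST"))
    }
    message(sprintf("[%s] stage %s complete", format(Sys.time(), "%H:%M:%S"), name))
  }
  on.exit({
    if (!is.null(out_dir)) writeLines(done, file.path(out_dir, "MANIFEST"))
  })

  div <- divergence_table(alignments, manifest, layout)
  if (!is.null(out_dir)) write_divergence_table(div, file.path(out_dir, "divergence.tsv"))
  log_stage("divergence")

  classes <- classify_allele_pairs(div, min_diffs = min_diffs)
  maps <- suppression_maps(classes, layout)
  boundaries <- compare_boundaries(maps, layout)
  if (!is.null(out_dir)) {
    write_suppression_maps(maps, layout, file.path(out_dir, "suppression_classes.tsv"),
                           file.path(out_dir, "boundaries.tsv"))
  }
  log_stage("suppression")

  if (is.null(trees)) trees <- list()
  for (g in names(alignments)) {
    if (!is.null(trees[[g]])) next
    trees[[g]] <- bootstrap_supports(alignments[[g]],
                                     reps = thresholds$bootstrap_reps,
                                     seed = derive_seed(thresholds$seed,
                                                        paste0("bootstrap:", g)))
  }
  if (!is.null(out_dir)) {
    for (g in names(trees)) {
      write_supported_tree(trees[[g]], file.path(out_dir, "trees", paste0(g, ".nwk")))
    }
  }
  log_stage("trees")

  phases <- phase_matrix(trees, manifest, layout, thresholds)
  if (!is.null(out_dir)) write_phase_matrix(phases, file.path(out_dir, "phases.tsv"))
  log_stage("phases")

  conversions <- detect_conversions(phases, maps, layout, strict = strict)
  if (nrow(conversions) > 0) {
    conversions$template <- map_chr(seq_len(nrow(conversions)), function(i) {
      g <- conversions$gene[i]
      infer_template_direction(trees[[g]], conversions$pair_id[i],
                               manifest, thresholds, direction_majority,
                               exclude_pairs = conversions$pair_id[conversions$gene == g])
    })
  } else {
    conversions$template <- character(0)
  }
  merged <- merge_ancestral_events(conversions, alignments, manifest,
                                   max_diffs = merge_max_diffs,
                                   max_prop = merge_max_prop)
  if (nrow(merged) > 0) {
    # re-infer template on the merged unit: for ancestral events all
    # co-converted alleles must be excluded from the clade context
    merged$template <- map_chr(seq_len(nrow(merged)), function(i) {
      g <- merged$gene[i]
      conv_pairs <- unique(unlist(strsplit(merged$pairs[merged$gene == g], ",",
                                           fixed = TRUE)))
      infer_template_direction(trees[[g]],
                               strsplit(merged$pairs[i], ",", fixed = TRUE)[[1]],
                               manifest, thresholds, direction_majority,
                               exclude_pairs = conv_pairs)
    })
  }
  crossovers <- detect_crossovers(trees, manifest, layout, thresholds,
                                  persistence = persistence,
                                  direction_majority = direction_majority)
  log_stage("events")

  rates <- rate_table(merged, n_lineages = n_lineages, T = T_divergence)
  if (!is.null(out_dir)) {
    write_event_report(merged, crossovers, rates, file.path(out_dir, "events.json"),
                       signals = conversions, boundaries = boundaries)
    readr::write_tsv(rates, file.path(out_dir, "rates.tsv"), progress = FALSE)
  }
  log_stage("rates")

  result <- structure(list(
    divergence = div, classes = classes, maps = maps, boundaries = boundaries,
    trees = trees, phases = phases, conversions = conversions,
    merged = merged, crossovers = crossovers, rates = rates,
    params = list(thresholds = thresholds, min_diffs = min_diffs,
                  strict = strict, persistence = persistence,
                  direction_majority = direction_majority,
                  merge_max_diffs = merge_max_diffs,
                  merge_max_prop = merge_max_prop,
                  n_lineages = n_lineages, T_divergence = T_divergence),
    out_dir = out_dir
  ), class = "tet_pipeline")

  if (!is.null(out_dir)) {
    writeLines(pipeline_summary(result), file.path(out_dir, "summary.txt"))
  }
  log_stage("report")
  result
}

pipeline_summary <- function(x) {
  p <- x$params
  lines <- c(
    "mat-chromosome pipeline summary",
    sprintf("thresholds: bootstrap >= %s%%, posterior >= %s, %d replicates, seed %d",
            p$thresholds$bootstrap_min, p$thresholds$posterior_min,
            p$thresholds$bootstrap_reps, p$thresholds$seed),
    sprintf("classification: diverged at >= %d raw differences", p$min_diffs),
    "",
    "suppressed region per pair:"
  )
  for (m in x$maps) {
    lines <- c(lines, sprintf("  %-7s %s .. %s (internal homoallelic: %s)",
                              m$pair_id, m$region_start_gene %||% "-",
                              m$region_end_gene %||% "-",
                              paste(m$internal_homoallelic_genes, collapse = ",")))
  }
  inside <- filter(x$merged, .data$in_region)
  lines <- c(lines, "",
             sprintf("gene conversion events inside the suppressed span: %d (%d per-pair signals)",
                     nrow(inside), sum(inside$n_pairs)),
             sprintf("crossover events: %d", nrow(x$crossovers)), "",
             sprintf("homogenization rates (K = events/%d lineages, T = %.1f MY):",
                     p$n_lineages, p$T_divergence))
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    lines <- c(lines, sprintf("  %-7s events=%d  K=%.3f  r=%.3f per site per MY",
                              r$gene, r$events, r$K, r$r_per_event_rounded))
  }
  lines
}

#' @export
print.tet_pipeline <- function(x, ...) {
  cat(paste(pipeline_summary(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname tetmat-generics
#' @param x A `tet_pipeline`.
#' @param ... Unused.
#' @exportS3Method
glance.tet_pipeline <- function(x, ...) {
  inside <- filter(x$merged, .data$in_region)
  tibble(
    n_genes = length(unique(x$divergence$gene)),
    n_pairs = length(x$maps),
    n_conversion_events = nrow(inside),
    n_conversion_signals = sum(inside$n_pairs),
    n_crossovers = nrow(x$crossovers),
    n_boundary_deviations = sum(x$boundaries$left_differs | x$boundaries$right_differs)
  )
}

#' @rdname tetmat-generics
#' @exportS3Method
tidy.tet_pipeline <- function(x, ...) {
  x$merged
}
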