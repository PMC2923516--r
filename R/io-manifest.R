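#' Read and validate a strain manifest
#'
#' The manifest lists one homokaryotic single mating-type component strain per
#' row. Strains are organised in heterokaryon pairs: every `pair_id` must map
#' to exactly one `mat A` and one `mat a` strain, the unit of all downstream
#' allelic comparisons.
#'
#' @param path Path to a tab-separated file with columns `strain_id`,
#'   `mating_type` (`"A"` or `"a"`), `lineage` and `pair_id`.
#' @return A tibble with one row per strain (class `tet_manifest`).
#' @export
#' @examples
#' read_strain_manifest(tetmat_example("tetrasperma_strains.tsv"))
read_strain_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_tetmat(sprintf("manifest file not found: %s", path), "tetmat_format_error")
  }
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_tetmat(sprintf("cannot parse manifest: %s", conditionMessage(e)),
                                    "tetmat_format_error")
  )
  as_tet_manifest(df)
}

#' Validate a strain manifest data frame
#'
#' @param df Data frame with columns `strain_id`, `mating_type`, `lineage`,
#'   `pair_id`.
#' @return The validated tibble, classed `tet_manifest`.
#' @export
as_tet_manifest <- function(df) {
  needed <- c("strain_id", "mating_type", "lineage", "pair_id")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0 || nrow(df) == 0) {
    stop_tetmat(
      sprintf("manifest must contain columns %s%s", paste(needed, collapse = ", "),
              if (nrow(df) == 0) " and at least one row" else
                sprintf(" (missing: %s)", paste(missing_cols, collapse = ", "))),
      "tetmat_format_error"
    )
  }
  df <- as_tibble(df)[needed]
  df$strain_id <- as.character(df$strain_id)
  df$mating_type <- as.character(df$mating_type)
  df$lineage <- as.character(df$lineage)
  df$pair_id <- as.character(df$pair_id)
  check_values(df$mating_type, c("A", "a"), "mating_type")
  if (anyDuplicated(df$strain_id)) {
    stop_tetmat("duplicated strain_id in manifest", "tetmat_validation_error")
  }
  bad_pairs <- df |>
    group_by(.data$pair_id) |>
    summarise(n_A = sum(.data$mating_type == "A"),
              n_a = sum(.data$mating_type == "a"), .groups = "drop") |>
    filter(.data$n_A != 1L | .data$n_a != 1L)
  if (nrow(bad_pairs) > 0) {
    stop_tetmat(
      sprintf("pair(s) without exactly one A and one a strain: %s",
              paste(bad_pairs$pair_id, collapse = ", ")),
      "tetmat_validation_error"
    )
  }
  class(df) <- c("tet_manifest", class(df))
  df
}

#' Read and validate a chromosome layout
#'
#' The layout gives the assumed left-to-right gene order along the mat
#' chromosome (gene order taken to parallel *N. crassa*), the position of the
#' mat locus and the centromere, and a coarse region hint per gene.
#'
#' @param path Tab-separated file with columns `gene`, `region_hint`
#'   (`left_flank`/`central`/`right_flank`) and logical `mat_locus_follows`
#'   and `centromere_follows` marking the gene *preceding* each landmark.
#'   Optional integer columns `coding_bp` and `intron_bp` are carried along
#'   (the simulator uses them as gene lengths).
#' @return A tibble with one row per gene in order, 0-based `order` column
#'   (class `tet_layout`).
#' @export
read_chromosome_layout <- function(path) {
  if (!file.exists(path)) {
    stop_tetmat(sprintf("layout file not found: %s", path), "tetmat_format_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  as_tet_layout(df)
}

#' Validate a chromosome layout data frame
#' @param df Data frame as described in [read_chromosome_layout()].
#' @return Tibble classed `tet_layout`.
#' @export
as_tet_layout <- function(df) {
  needed <- c("gene", "region_hint", "mat_locus_follows", "centromere_follows")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0 || nrow(df) == 0) {
    stop_tetmat(sprintf("layout must contain columns %s and at least one row",
                        paste(needed, collapse = ", ")),
                "tetmat_format_error")
  }
  df <- as_tibble(df)
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene)) {
    stop_tetmat("duplicated gene names in layout", "tetmat_validation_error")
  }
  check_values(df$region_hint, c("left_flank", "central", "right_flank"), "region_hint")
  if (sum(df$mat_locus_follows) > 1 || sum(df$centromere_follows) > 1) {
    stop_tetmat("at most one gene may precede each landmark", "tetmat_validation_error")
  }
  df$order <- seq_len(nrow(df)) - 1L
  class(df) <- c("tet_layout", class(df))
  df
}

#' Path to a packaged example/reference data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
tetmat_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "tetmat"))
  } else {
    f <- system.file("extdata", file, package = "tetmat")
    if (!nzchar(f)) stop_tetmat(sprintf("no packaged file '%s'", file), "tetmat_format_error")
    f
  }
}

#' Reference strain set of the N. tetrasperma species complex
#'
#' Twenty single mating-type component strains forming ten heterokaryon pairs
#' across the nine phylogenetic lineages (lineage 8 represented twice).
#'
#' @return A `tet_manifest` tibble.
#' @export
tetrasperma_strains <- function() {
  read_strain_manifest(tetmat_example("tetrasperma_strains.tsv"))
}

#' Reference mat-chromosome gene layout
#'
#' The 24 surveyed genes in assumed *N. crassa* order, with the mat locus
#' placed after *un-3* and the centromere after *eth-1*, plus per-gene coding
#' and intron lengths used as simulator defaults.
#'
#' @return A `tet_layout` tibble.
#' @export
tetrasperma_layout <- function() {
  read_chromosome_layout(tetmat_example("tetrasperma_layout.tsv"))
}

#' Curated gene-conversion event summary for the N. tetrasperma complex
#'
#' The eight conversion events recognised across the ten chromosome pairs of
#' the species complex in the published gene-genealogy survey this pipeline
#' reproduces: affected gene, affected pairs, template direction, and whether
#' the event traces back to a common ancestor of several lineages.
#'
#' @return A tibble with one row per event.
#' @export
tetrasperma_conversion_events <- function() {
  readr::read_tsv(tetmat_example("tetrasperma_conversion_events.tsv"),
                  col_types = readr::cols(
                    event_id = readr::col_integer(),
                    gene = readr::col_character(),
                    pairs = readr::col_character(),
                    lineages = readr::col_character(),
                    template = readr::col_character(),
                    ancestral = readr::col_logical()
                  ), progress = FALSE)
}

# pair table: pair_id, strain_A, strain_a, lineage
pair_table <- function(manifest) {
  manifest |>
    group_by(.data$pair_id) |>
    summarise(strain_A = .data$strain_id[.data$mating_type == "A"],
              strain_a = .data$strain_id[.data$mating_type == "a"],
              lineage = .data$lineage[1], .groups = "drop")
}
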