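#' Classify allelic divergence records
#'
#' Deterministic counting rule on the raw number of differing columns
#' (coding + intron): `diverged` at `min_diffs` or more differences,
#' `homoallelic_flagged` at exactly one (the single-SNP exceptions expected
#' from rare outcrossing), `homoallelic` at zero, `missing` when undefined.
#'
#' @param div A [divergence_table()] tibble (or any tibble with `raw_diffs`).
#' @param min_diffs Difference count from which a gene counts as diverged.
#' @return The input with a `class` column added.
#' @export
classify_allele_pairs <- function(div, min_diffs = 2L) {
  stopifnot(min_diffs >= 2)
  mutate(div, class = dplyr::case_when(
    is.na(.data$raw_diffs) ~ "missing",
    .data$raw_diffs >= min_diffs ~ "diverged",
    .data$raw_diffs == 1L ~ "homoallelic_flagged",
    TRUE ~ "homoallelic"
  ))
}

#' Demarcate the recombinationally suppressed region for one pair
#'
#' The region is the span from the leftmost to the rightmost diverged gene in
#' layout order (flagged single-SNP genes do not set bounds). Homoallelic
#' genes strictly inside the span stay inside it and are listed separately:
#' they are gene-conversion candidates, not interruptions of the region.
#'
#' @param classes Tibble with `gene` and `class` for one pair (one row per
#'   layout gene).
#' @param layout A `tet_layout`.
#' @param pair_id Pair label carried into the result.
#' @return A list of class `suppression_map`: `pair_id`, `classes` (tibble in
#'   layout order), `region_start_gene`, `region_end_gene` (NA when no gene is
#'   diverged), `internal_homoallelic_genes`.
#' @export
demarcate_region <- function(classes, layout, pair_id = NA_character_) {
  df <- left_join(layout[, c("gene", "order")], classes[, c("gene", "class")],
                  by = "gene")
  df$class[is.na(df$class)] <- "missing"
  div_ord <- df$order[df$class == "diverged"]
  if (length(div_ord) == 0) {
    res <- list(pair_id = pair_id, classes = df,
                region_start_gene = NA_character_, region_end_gene = NA_character_,
                internal_homoallelic_genes = character(0))
  } else {
    lo <- min(div_ord); hi <- max(div_ord)
    inside <- df$order > lo & df$order < hi
    res <- list(
      pair_id = pair_id, classes = df,
      region_start_gene = df$gene[df$order == lo],
      region_end_gene = df$gene[df$order == hi],
      internal_homoallelic_genes =
        df$gene[inside & df$class %in% c("homoallelic", "homoallelic_flagged")]
    )
  }
  structure(res, class = "suppression_map")
}

#' @export
print.suppression_map <- function(x, ...) {
  cat(sprintf("<suppression_map> %s: region %s..%s (%d internal homoallelic)\n",
              x$pair_id, x$region_start_gene %||% "-", x$region_end_gene %||% "-",
              length(x$internal_homoallelic_genes)))
  invisible(x)
}

# order span (integer vector lo:hi) of a suppression map, or NULL
region_span <- function(map, layout) {
  if (is.na(map$region_start_gene)) return(NULL)
  lo <- layout$order[layout$gene == map$region_start_gene]
  hi <- layout$order[layout$gene == map$region_end_gene]
  lo:hi
}

#' Suppression maps for all pairs
#'
#' @param div_classes Output of [classify_allele_pairs()] over all pairs.
#' @param layout A `tet_layout`.
#' @return Named list of [demarcate_region()] maps, one per pair.
#' @export
suppression_maps <- function(div_classes, layout) {
  ids <- unique(div_classes$pair_id)
  setNames(
    purrr::map(ids, function(p) {
      demarcate_region(filter(div_classes, .data$pair_id == p), layout, pair_id = p)
    }),
    ids
  )
}

#' Compare suppressed-region boundaries across pairs
#'
#' Summarises the left and right boundary gene per pair and flags pairs whose
#' boundary deviates from the majority (ties: no majority, everyone flagged
#' whose boundary differs from the modal value).
#'
#' @param maps List of suppression maps (from [suppression_maps()]).
#' @param layout A `tet_layout`.
#' @return A tibble: `pair_id`, `left_gene`, `right_gene`, `left_differs`,
#'   `right_differs`.
#' @export
compare_boundaries <- function(maps, layout) {
  if (length(maps) < 2) {
    stop_tetmat("boundary comparison needs at least 2 maps", "tetmat_validation_error")
  }
  df <- tibble(
    pair_id = unname(map_chr(maps, "pair_id")),
    left_gene = unname(map_chr(maps, function(m) m$region_start_gene %||% NA_character_)),
    right_gene = unname(map_chr(maps, function(m) m$region_end_gene %||% NA_character_))
  )
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_character_)
    tab <- sort(table(x), decreasing = TRUE)
    names(tab)[1]
  }
  ml <- modal(df$left_gene); mr <- modal(df$right_gene)
  df$left_differs <- !is.na(df$left_gene) & !identical(ml, NA_character_) & df$left_gene != ml
  df$right_differs <- !is.na(df$right_gene) & !identical(mr, NA_character_) & df$right_gene != mr
  df
}

#' @rdname tetmat-generics
#' @param x A `suppression_map`.
#' @param ... Unused.
#' @exportS3Method
tidy.suppression_map <- function(x, ...) {
  span <- if (is.na(x$region_start_gene)) integer(0) else {
    x$classes$order[x$classes$gene == x$region_start_gene][1]:
      x$classes$order[x$classes$gene == x$region_end_gene][1]
  }
  mutate(x$classes, pair_id = x$pair_id, in_region = .data$order %in% span)
}

#' @rdname tetmat-generics
#' @exportS3Method
glance.suppression_map <- function(x, ...) {
  tibble(pair_id = x$pair_id,
         region_start_gene = x$region_start_gene,
         region_end_gene = x$region_end_gene,
         n_region_genes = if (is.na(x$region_start_gene)) 0L else {
           abs(x$classes$order[x$classes$gene == x$region_end_gene] -
                 x$classes$order[x$classes$gene == x$region_start_gene]) + 1L
         },
         n_internal_homoallelic = length(x$internal_homoallelic_genes))
}

#' Write per-pair suppression maps and boundary table
#' @param maps List of suppression maps.
#' @param layout A `tet_layout`.
#' @param class_path,boundary_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_suppression_maps <- function(maps, layout, class_path, boundary_path) {
  classes <- purrr::map_dfr(maps, tidy)
  readr::write_tsv(classes, class_path, progress = FALSE)
  readr::write_tsv(compare_boundaries(maps, layout), boundary_path, progress = FALSE)
  invisible(list(class_path, boundary_path))
}
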