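#' Detect gene-conversion events from a phase matrix
#'
#' Applies the three-genealogy window rule along the chromosome: a conversion
#' is called at gene *g* for a pair when the pair's alleles are *together* at
#' *g* but *separated* at the flanking genealogies on both sides, with the
#' separation significantly supported on at least one flank. By default an
#' unresolved neighbour extends the window to the next informative gene;
#' `strict = TRUE` restricts windows to immediately adjacent genes. Genes
#' lacking an informative neighbour on either side (in particular terminal
#' genes) never yield an event.
#'
#' @param phases A [phase_matrix()] tibble.
#' @param maps Suppression maps from [suppression_maps()] (used to annotate
#'   events as inside/outside the pair's suppressed span).
#' @param layout A `tet_layout`.
#' @param strict Use only immediately adjacent genes as window flanks.
#' @return A tibble of per-pair conversion events, classed `tet_conversions`:
#'   `gene`, `pair_id`, `left_gene`, `right_gene`, `left_supported`,
#'   `right_supported`, `in_region`.
#' @export
detect_conversions <- function(phases, maps, layout, strict = FALSE) {
  if (!all(layout$gene %in% unique(phases$gene))) {
    stop_tetmat("phase matrix does not cover every layout gene",
                "tetmat_validation_error")
  }
  empty <- tibble(gene = character(0), pair_id = character(0),
                  left_gene = character(0), right_gene = character(0),
                  left_supported = logical(0), right_supported = logical(0),
                  in_region = logical(0))
  out <- purrr::map_dfr(unique(phases$pair_id), function(p) {
    ph <- phases |> filter(.data$pair_id == p) |> arrange(.data$order)
    informative <- which(ph$phase %in% c("together", "separated"))
    span <- if (!is.null(maps[[p]])) region_span(maps[[p]], layout) else integer(0)
    rows <- purrr::map_dfr(informative[ph$phase[informative] == "together"], function(j) {
      left <- informative[informative < j]
      right <- informative[informative > j]
      if (strict) {
        left <- left[left == j - 1L]
        right <- right[right == j + 1L]
      }
      if (length(left) == 0 || length(right) == 0) return(empty[0, ])
      l <- max(left); r <- min(right)
      if (ph$phase[l] != "separated" || ph$phase[r] != "separated") return(empty[0, ])
      if (!ph$separation_supported[l] && !ph$separation_supported[r]) return(empty[0, ])
      tibble(gene = ph$gene[j], pair_id = p,
             left_gene = ph$gene[l], right_gene = ph$gene[r],
             left_supported = ph$separation_supported[l],
             right_supported = ph$separation_supported[r],
             in_region = ph$order[j] %in% span)
    })
    rows
  })
  if (nrow(out) == 0) out <- empty
  class(out) <- c("tet_conversions", class(out))
  out
}

# supported unrooted clades (tip-label sets) of a tree, smallest first
supported_sides <- function(tree, thresholds) {
  phy <- tree$phy
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  nodes <- ape::Ntip(phy) + seq_along(pp)
  sides <- list()
  for (i in seq_along(pp)) {
    s <- tree$supports[tree$supports$node == nodes[i], ]
    if (nrow(s) == 0) next
    ok <- (!is.na(s$bootstrap) && s$bootstrap >= thresholds$bootstrap_min) ||
      (!is.na(s$posterior) && s$posterior >= thresholds$posterior_min)
    if (!ok) next
    inside <- labs[pp[[i]]]
    sides <- c(sides, list(inside), list(setdiff(labs, inside)))
  }
  sides[order(map_int(sides, length))]
}

#' Infer the conversion template direction from the focal genealogy
#'
#' The template is the mating type whose alleles the converted pair nests
#' among: the smallest significantly supported clade containing both of the
#' pair's alleles is located, and if the clade's other resolved members are
#' (at least `direction_majority` of them) mat a-linked alleles of other
#' pairs, the template is `mat_a` (symmetrically `mat_A`); otherwise
#' `unknown`.
#'
#' @param tree The focal gene's [supported_tree()].
#' @param pair_id Converted pair, or a vector of pairs for a merged ancestral
#'   event (all their alleles are then treated as the converted unit, so
#'   co-converted alleles cannot masquerade as clade context).
#' @param manifest A `tet_manifest`.
#' @param thresholds A [support_thresholds()].
#' @param direction_majority Minimum fraction of clade members of one mating
#'   type (default 1 = unanimity).
#' @param exclude_pairs Pairs whose alleles are dropped from the clade
#'   context (e.g. other pairs independently converted at the same gene).
#' @return `"mat_A"`, `"mat_a"` or `"unknown"`.
#' @export
infer_template_direction <- function(tree, pair_id, manifest,
                                     thresholds = support_thresholds(),
                                     direction_majority = 1,
                                     exclude_pairs = character(0)) {
  pairs <- pair_table(manifest)
  i <- match(pair_id, pairs$pair_id)
  if (anyNA(i)) return("unknown")
  focal <- c(pairs$strain_A[i], pairs$strain_a[i])
  if (!all(focal %in% tree$phy$tip.label)) return("unknown")
  j <- match(setdiff(exclude_pairs, pair_id), pairs$pair_id)
  j <- j[!is.na(j)]
  excluded <- c(focal, pairs$strain_A[j], pairs$strain_a[j])
  mt <- setNames(manifest$mating_type, manifest$strain_id)
  for (side in supported_sides(tree, thresholds)) {
    if (!all(focal %in% side)) next
    others <- setdiff(side, excluded)
    others <- others[!is.na(mt[others])]
    if (length(others) == 0) next
    frac_a <- mean(mt[others] == "a")
    if (frac_a >= direction_majority) return("mat_a")
    if ((1 - frac_a) >= direction_majority) return("mat_A")
    return("unknown")
  }
  "unknown"
}

# column-wise SNP distance between two aligned sequences (non-ACGT columns
# dropped pairwise); returns c(diffs, compared)
aligned_snp_distance <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  c(diffs = sum(a[ok] != b[ok]), compared = sum(ok))
}

#' Merge per-pair conversion events into ancestral events
#'
#' Events at the same gene in different pairs are merged into a single
#' ancestral event when the converted alleles are identical across those
#' pairs (at most `max_diffs` SNPs, or at most a fraction `max_prop` of
#' compared columns when given): identity across lineages places the
#' conversion before their split. Unmerged events stay per-pair.
#'
#' @param events A [detect_conversions()] tibble, optionally with a
#'   `template` column.
#' @param alignments Named list of [gene_alignment()] objects.
#' @param manifest A `tet_manifest`.
#' @param max_diffs Maximum SNP count for "identical" converted alleles.
#' @param max_prop Optional proportional threshold overriding `max_diffs`.
#' @return A tibble of merged events, classed `tet_conversions_merged`:
#'   `event_id`, `gene`, `pairs` (comma-joined), `lineages` (comma-joined),
#'   `n_pairs`, `ancestral`, `template`, `in_region`.
#' @export
merge_ancestral_events <- function(events, alignments, manifest,
                                   max_diffs = 0L, max_prop = NULL) {
  if (nrow(events) == 0) {
    out <- tibble(event_id = integer(0), gene = character(0),
                  pairs = character(0), lineages = character(0),
                  n_pairs = integer(0), ancestral = logical(0),
                  template = character(0), in_region = logical(0))
    class(out) <- c("tet_conversions_merged", class(out))
    return(out)
  }
  pairs <- pair_table(manifest)
  groups <- split(seq_len(nrow(events)), events$gene)
  out <- purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    aln <- alignments[[g]]
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (k > 1 && !is.null(aln)) {
      rep_seq <- map_chr(events$pair_id[idx], function(p) {
        sa <- pairs$strain_A[match(p, pairs$pair_id)]
        aln$seqs[[sa]] %||% NA_character_
      })
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          if (is.na(rep_seq[i]) || is.na(rep_seq[j])) next
          d <- aligned_snp_distance(rep_seq[i], rep_seq[j])
          same <- if (!is.null(max_prop)) {
            d[["compared"]] > 0 && d[["diffs"]] / d[["compared"]] <= max_prop
          } else {
            d[["diffs"]] <= max_diffs
          }
          if (same) parent[find(i)] <- find(j)
        }
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    purrr::map_dfr(unique(comp), function(cc) {
      members <- idx[comp == cc]
      pr <- sort(unique(events$pair_id[members]))
      lin <- sort(unique(pairs$lineage[match(pr, pairs$pair_id)]))
      tmpl <- unique(events$template[members]) %||% "unknown"
      tibble(
        gene = g,
        pairs = paste(pr, collapse = ","),
        lineages = paste(lin, collapse = ","),
        n_pairs = length(pr),
        ancestral = length(pr) > 1,
        template = if (length(tmpl) == 1 && !is.null(tmpl)) tmpl else "unknown",
        in_region = any(events$in_region[members])
      )
    })
  })
  out <- arrange(out, .data$gene, .data$pairs)
  out$event_id <- seq_len(nrow(out))
  out <- select(out, "event_id", dplyr::everything())
  class(out) <- c("tet_conversions_merged", class(out))
  out
}

# clade affiliation of one allele: mating type of the smallest supported
# clade of other pairs' alleles it nests within, or NA. Mixed sides are
# skipped rather than terminal: the complement of an unrelated clade is
# mixed by construction and carries no affiliation signal, so the walk
# continues outward until a pure context (or nothing) is found. `sides` is
# the precomputed supported_sides() list for the gene's tree.
clade_affiliation <- function(sides, strain, focal_pair, mt,
                              direction_majority = 1) {
  for (side in sides) {
    if (!strain %in% side) next
    others <- setdiff(side, focal_pair)
    others <- others[!is.na(mt[others])]
    if (length(others) == 0) next
    frac_a <- mean(mt[others] == "a")
    if (frac_a >= direction_majority) return("a")
    if ((1 - frac_a) >= direction_majority) return("A")
  }
  NA_character_
}

#' Detect crossovers from persistent allele-phase swaps along the chromosome
#'
#' For each pair and gene, each allele is assigned the mating-type identity of
#' the supported allele clade of *other* pairs it nests within. A gene is in
#' the *swapped* state when the mat A-linked allele sits in the a-affiliated
#' clade and vice versa, and *normal* in the opposite configuration. A
#' crossover is called between two consecutive informative genes where the
#' state flips, provided the runs on both sides of the flip persist for at
#' least `persistence` informative genes or are anchored at a chromosome end
#' (guarding against single-tree noise).
#'
#' @param trees Named list of [supported_tree()] objects.
#' @param manifest A `tet_manifest`.
#' @param layout A `tet_layout`.
#' @param thresholds A [support_thresholds()].
#' @param persistence Minimum run length of the new state.
#' @param direction_majority Clade purity required for an affiliation call.
#' @return A tibble of crossover events: `pair_id`, `left_gene`, `right_gene`,
#'   `state_before`, `state_after`, `run_length`.
#' @export
detect_crossovers <- function(trees, manifest, layout,
                              thresholds = support_thresholds(),
                              persistence = 2L, direction_majority = 1) {
  pairs <- pair_table(manifest)
  mt <- setNames(manifest$mating_type, manifest$strain_id)
  sides_of <- purrr::map(setNames(layout$gene, layout$gene), function(g) {
    if (is.null(trees[[g]])) NULL else supported_sides(trees[[g]], thresholds)
  })
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    p <- pairs$pair_id[i]
    focal <- c(pairs$strain_A[i], pairs$strain_a[i])
    states <- purrr::map_chr(layout$gene, function(g) {
      sides <- sides_of[[g]]
      tr <- trees[[g]]
      if (is.null(tr) || !all(focal %in% tr$phy$tip.label)) return(NA_character_)
      affA <- clade_affiliation(sides, pairs$strain_A[i], focal, mt,
                                direction_majority)
      affa <- clade_affiliation(sides, pairs$strain_a[i], focal, mt,
                                direction_majority)
      if (is.na(affA) || is.na(affa)) return(NA_character_)
      if (affA == "A" && affa == "a") return("normal")
      if (affA == "a" && affa == "A") return("swapped")
      NA_character_
    })
    inf <- which(!is.na(states))
    if (length(inf) < 2) return(tibble())
    s <- states[inf]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # a run is credible when long enough or anchored at a chromosome end;
    # both sides of a transition must be credible (guards against blips)
    qualifies <- r$lengths >= persistence | starts == 1L | ends == length(s)
    purrr::map_dfr(seq_along(r$values)[-1], function(k) {
      if (!qualifies[k] || !qualifies[k - 1L]) return(tibble())
      tibble(pair_id = p,
             left_gene = layout$gene[inf[ends[k - 1L]]],
             right_gene = layout$gene[inf[starts[k]]],
             state_before = r$values[k - 1L],
             state_after = r$values[k],
             run_length = r$lengths[k])
    })
  })
}

#' Per-site homogenization rate from conversion events
#'
#' Implements `r = K / (2T)` with `K = event_count / n_lineages`: the per-site
#' rate at which gene conversion homogenizes the two alleles, analogous to a
#' substitution rate between two taxa separated for time `T`.
#'
#' @param event_count Number of conversion events at the gene.
#' @param n_lineages Number of lineages surveyed.
#' @param T Divergence time of the lineages from their common ancestor, in
#'   million years.
#' @param gene Optional gene label.
#' @return A one-row tibble: `gene`, `event_count`, `n_lineages`, `T`, `K`,
#'   `r` (full precision) and `r_rounded` (3 decimals, the reporting
#'   convention).
#' @export
#' @examples
#' homogenization_rate(1, 9, 4.6)
homogenization_rate <- function(event_count, n_lineages, T, gene = NA_character_) {
  if (n_lineages < 1 || T <= 0) {
    stop_tetmat("homogenization rate needs n_lineages >= 1 and T > 0",
                "tetmat_domain_error")
  }
  if (event_count < 0) {
    stop_tetmat("event_count must be non-negative", "tetmat_domain_error")
  }
  K <- event_count / n_lineages
  r <- K / (2 * T)
  tibble(gene = gene, event_count = event_count, n_lineages = n_lineages,
         T = T, K = K, r = r, r_rounded = round(r, 3))
}

#' Per-gene homogenization rate table
#'
#' Computes per-gene K and r under both event-counting conventions: counting
#' each merged (possibly ancestral) event once (`r_per_event`, the headline
#' rate) and counting one event per affected chromosome pair (`r_per_pair`).
#'
#' @param merged A [merge_ancestral_events()] tibble.
#' @param n_lineages Number of lineages surveyed.
#' @param T Lineage divergence time, million years.
#' @param inside_region_only Count only events inside the suppressed span.
#' @return A tibble: `gene`, `events`, `events_per_pair`, `K`, `r_per_event`,
#'   `r_per_pair` (and 3-decimal rounded columns).
#' @export
rate_table <- function(merged, n_lineages, T, inside_region_only = TRUE) {
  ev <- if (inside_region_only) filter(merged, .data$in_region) else merged
  ev |>
    group_by(.data$gene) |>
    summarise(events = dplyr::n(), events_per_pair = sum(.data$n_pairs),
              .groups = "drop") |>
    mutate(
      K = .data$events / n_lineages,
      r_per_event = .data$K / (2 * T),
      r_per_pair = (.data$events_per_pair / n_lineages) / (2 * T),
      r_per_event_rounded = round(.data$r_per_event, 3),
      r_per_pair_rounded = round(.data$r_per_pair, 3)
    )
}

#' Write the JSON event report
#'
#' @param merged Merged conversion events.
#' @param crossovers Crossover events.
#' @param rates A [rate_table()] tibble.
#' @param path Output JSON path.
#' @param signals Optional per-pair conversion signals (the
#'   [detect_conversions()] tibble) carrying the three-genealogy evidence
#'   windows.
#' @param boundaries Optional [compare_boundaries()] summary.
#' @return `path`, invisibly.
#' @export
write_event_report <- function(merged, crossovers, rates, path,
                               signals = NULL, boundaries = NULL) {
  report <- list(conversions = merged, crossovers = crossovers, rates = rates)
  if (!is.null(signals)) report$conversion_signals <- signals
  if (!is.null(boundaries)) report$region_boundaries <- boundaries
  jsonlite::write_json(
    report, path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}
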