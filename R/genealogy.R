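#' Support thresholds and tree-building settings
#'
#' Defaults follow common practice for genealogy-based event calling: a branch
#' is treated as significantly supported when its bootstrap percentage is at
#' least 70 (roughly a 95% confidence level) or its Bayesian posterior
#' probability is at least 0.95; bootstrap resampling uses 1000 replicates.
#'
#' @param bootstrap_min Minimum bootstrap percent for a supported branch.
#' @param posterior_min Minimum posterior probability for a supported branch.
#' @param bootstrap_reps Bootstrap replicate count.
#' @param together_max_dist Maximum patristic distance (substitutions/site)
#'   between a pair's two alleles for a "together" call; tolerates residual
#'   1-2 bp differences after incomplete homogenization.
#' @param seed RNG seed governing bootstrap resampling.
#' @return A list of class `support_thresholds`.
#' @export
support_thresholds <- function(bootstrap_min = 70, posterior_min = 0.95,
                               bootstrap_reps = 1000L, together_max_dist = 0.005,
                               seed = 1L) {
  stopifnot(bootstrap_min >= 0, bootstrap_min <= 100,
            posterior_min >= 0, posterior_min <= 1,
            bootstrap_reps >= 1, together_max_dist >= 0)
  structure(list(bootstrap_min = bootstrap_min, posterior_min = posterior_min,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 together_max_dist = together_max_dist, seed = as.integer(seed)),
            class = "support_thresholds")
}

# gene_alignment -> ape DNAbin matrix
as_dnabin <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  ape::as.DNAbin(m)
}

#' Jukes-Cantor pairwise distance matrix for a gene alignment
#'
#' JC69-corrected distances with pairwise deletion of gap/ambiguous columns.
#'
#' @param aln A [gene_alignment()] with at least 3 sequences.
#' @return A symmetric distance matrix (substitutions/site, zero diagonal).
#' @export
jc_distance_matrix <- function(aln) {
  if (length(aln$seqs) < 3) {
    stop_tetmat(sprintf("gene %s: neighbor-joining needs at least 3 sequences",
                        aln$gene), "tetmat_validation_error")
  }
  d <- as.matrix(ape::dist.dna(as_dnabin(aln), model = "JC69",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop_tetmat(
      sprintf("gene %s: JC distance undefined for pair (%s, %s): difference proportion >= 0.75",
              aln$gene, rownames(d)[bad[1]], colnames(d)[bad[2]]),
      "tetmat_correction_error"
    )
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Produces an unrooted tree; on an exactly additive matrix the tree's path
#' lengths reproduce the input distances.
#'
#' @param d Symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @param gene Optional gene name attached to the result.
#' @param collapse_tol Branches no longer than this are collapsed into
#'   polytomies. NJ resolves ties among (near-)identical sequences
#'   arbitrarily, producing spurious short branches; sequence-based callers
#'   set this to a fraction of one substitution per site (0.1/alignment
#'   length) so that no real substitution is ever collapsed.
#' @return A [supported_tree()] without supports.
#' @export
nj_gene_tree <- function(d, gene = NA_character_, collapse_tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
    stop_tetmat("distance matrix must be symmetric with a zero diagonal",
                "tetmat_validation_error")
  }
  if (nrow(d) < 3) {
    stop_tetmat("neighbor-joining needs at least 3 taxa", "tetmat_validation_error")
  }
  # collapse (near-)zero branches into polytomies: NJ resolves ties between
  # identical sequences arbitrarily, and such branches carry no signal
  phy <- ape::di2multi(ape::nj(d), tol = collapse_tol)
  supported_tree(phy, gene = gene,
                 supports = tibble(node = ape::Ntip(phy) + seq_len(phy$Nnode),
                                   bootstrap = NA_real_, posterior = NA_real_))
}

# Canonical bipartition keys of all internal edges of an unrooted tree:
# for each internal edge, the tip-label set of the side not containing the
# lexicographically first label, sorted and collapsed. Invariant to rooting
# and rotation.
tree_bipartitions <- function(phy) {
  ntip <- ape::Ntip(phy)
  ref <- sort(phy$tip.label)[1]
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- map_chr(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  })
  # node numbers corresponding to prop.part entries are ntip+1 .. ntip+Nnode
  names(keys) <- as.character(ntip + seq_along(keys))
  # drop trivial splits (whole tree / single tip)
  keys[map_int(strsplit(keys, "|", fixed = TRUE), length) >= 2 &
         map_int(strsplit(keys, "|", fixed = TRUE), length) <= ntip - 2]
}

# Fast bipartition keys over tip indices (valid when all trees share the same
# tip-index -> taxon mapping, as NJ trees over one distance matrix do):
# canonical side is the one not containing tip 1.
biparts_index_keys <- function(phy, canon_labels) {
  ntip <- length(phy$tip.label)
  remap <- match(phy$tip.label, canon_labels)
  pp <- ape::prop.part(phy)
  keys <- character(length(pp))
  sizes <- integer(length(pp))
  for (i in seq_along(pp)) {
    idx <- sort(remap[pp[[i]]])
    if (1L %in% idx) idx <- setdiff(seq_len(ntip), idx)
    keys[i] <- paste(idx, collapse = ",")
    sizes[i] <- length(idx)
  }
  names(keys) <- as.character(ntip + seq_along(pp))
  keys[sizes >= 2L & sizes <= ntip - 2L]
}

#' Nonparametric bootstrap supports for a neighbor-joining genealogy
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from JC
#' distances for each replicate, and scores every internal branch of the
#' reference tree by the percentage of replicates containing the same
#' unrooted bipartition. Replicates whose resampled distances are undefined
#' (difference proportion >= 0.75) are dropped from the denominator.
#'
#' @param aln A [gene_alignment()].
#' @param reps Number of bootstrap replicates.
#' @param seed RNG seed (resampling is deterministic given the seed).
#' @return A [supported_tree()] whose `bootstrap` supports are percentages.
#' @export
bootstrap_supports <- function(aln, reps = 1000L, seed = 1L) {
  tol <- 0.1 / length(aln$coding_mask)   # a tenth of one substitution/site
  ref <- nj_gene_tree(jc_distance_matrix(aln), gene = aln$gene,
                      collapse_tol = tol)
  canon <- names(aln$seqs)
  ref_keys <- biparts_index_keys(ref$phy, canon)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  L <- length(aln$coding_mask)
  mat <- do.call(rbind, strsplit(tolower(aln$seqs), ""))
  rownames(mat) <- names(aln$seqs)
  db_full <- ape::as.DNAbin(mat)
  n_ok <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      db <- db_full[, cols]
      d <- suppressWarnings(as.matrix(ape::dist.dna(db, model = "JC69",
                                                    pairwise.deletion = TRUE)))
      if (any(!is.finite(d))) next
      # no need to collapse zero branches here: the reference tree's keys
      # already exclude them, so artifactual replicate splits never match
      keys <- biparts_index_keys(ape::nj(d), canon)
      n_ok <- n_ok + 1L
      hit <- ref_keys %in% keys
      counts[hit] <- counts[hit] + 1
    }
  })
  if (n_ok == 0L) {
    stop_tetmat(sprintf("gene %s: no usable bootstrap replicates", aln$gene),
                "tetmat_correction_error")
  }
  pct <- 100 * counts / n_ok
  sup <- ref$supports
  node_of_key <- as.integer(names(ref_keys))
  sup$bootstrap[match(node_of_key, sup$node)] <- unname(pct)
  supported_tree(ref$phy, gene = aln$gene, supports = sup)
}

# --- phase calling ----------------------------------------------------------

# node sequence along the path between two nodes (plain BFS on the edge list)
tree_path_nodes <- function(phy, from, to) {
  n_nodes <- max(phy$edge)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  prev <- rep(NA_integer_, n_nodes)
  seen <- rep(FALSE, n_nodes)
  queue <- from
  seen[from] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) break
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[to]) return(integer(0))
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# edges (rows of phy$edge) along the path between two tips
path_edges <- function(phy, tip1, tip2) {
  nodes <- tree_path_nodes(phy, tip1, tip2)
  m <- cbind(nodes[-length(nodes)], nodes[-1])
  apply(m, 1, function(uv) {
    w <- which((phy$edge[, 1] == uv[1] & phy$edge[, 2] == uv[2]) |
                 (phy$edge[, 1] == uv[2] & phy$edge[, 2] == uv[1]))
    w[1]
  })
}

edge_is_supported <- function(tree, edge_idx, thresholds) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  map_lgl(edge_idx, function(e) {
    child <- phy$edge[e, 2]
    parent <- phy$edge[e, 1]
    node <- if (child > ntip) child else parent
    if (node <= ntip) return(FALSE)
    s <- tree$supports[tree$supports$node == node, ]
    if (nrow(s) == 0) return(FALSE)
    (!is.na(s$bootstrap) && s$bootstrap >= thresholds$bootstrap_min) ||
      (!is.na(s$posterior) && s$posterior >= thresholds$posterior_min)
  })
}

# an internal edge separates >=2 tips on each side
edge_is_internal <- function(phy, edge_idx) {
  ntip <- ape::Ntip(phy)
  map_lgl(edge_idx, function(e) all(phy$edge[e, ] > ntip))
}

#' Call the allele phase of one chromosome pair on one genealogy
#'
#' A pair's alleles are *together* when no internal branch on the path
#' between them is significantly supported and their patristic distance is at
#' most `together_max_dist`; *separated* when at least one branch on the path
#' meets the support threshold; otherwise *unresolved* (including pairs with
#' a missing strain or trees without the pair's leaves).
#'
#' @param tree A [supported_tree()].
#' @param pair_id Pair label.
#' @param strain_A,strain_a The pair's two strain ids.
#' @param thresholds A [support_thresholds()].
#' @return A one-row tibble: `pair_id`, `gene`, `phase`,
#'   `separation_supported`, `max_support_on_path`, `patristic`.
#' @export
pair_phase <- function(tree, pair_id, strain_A, strain_a, thresholds = support_thresholds()) {
  phy <- tree$phy
  out <- tibble(pair_id = pair_id, gene = tree$gene, phase = "unresolved",
                separation_supported = FALSE, max_support_on_path = NA_real_,
                patristic = NA_real_)
  t1 <- match(strain_A, phy$tip.label)
  t2 <- match(strain_a, phy$tip.label)
  if (is.na(t1) || is.na(t2)) return(out)
  eidx <- path_edges(phy, t1, t2)
  internal <- eidx[edge_is_internal(phy, eidx)]
  supported <- internal[edge_is_supported(tree, internal, thresholds)]
  patristic <- if (is.null(phy$edge.length)) NA_real_ else
    sum(pmax(phy$edge.length[eidx], 0))
  max_sup <- if (length(internal) == 0) NA_real_ else {
    vals <- map_dbl(internal, function(e) {
      child <- phy$edge[e, 2]
      node <- if (child > ape::Ntip(phy)) child else phy$edge[e, 1]
      s <- tree$supports[tree$supports$node == node, ]
      v <- c(s$bootstrap, 100 * s$posterior)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  out$patristic <- patristic
  out$max_support_on_path <- max_sup
  if (length(supported) > 0) {
    out$phase <- "separated"
    out$separation_supported <- TRUE
  } else if (!is.na(patristic) && patristic <= thresholds$together_max_dist) {
    out$phase <- "together"
  } else if (is.na(patristic)) {
    # trees without branch lengths: fall back on the support criterion alone
    out$phase <- "together"
  }
  out
}

#' Phase matrix over all genes and pairs
#'
#' @param trees Named list of [supported_tree()] objects (names = genes), in
#'   any order; genes are reported in layout order. Genes without a tree are
#'   marked unresolved.
#' @param manifest A `tet_manifest`.
#' @param layout A `tet_layout`.
#' @param thresholds A [support_thresholds()].
#' @return A long tibble (gene x pair) of phase calls, classed `tet_phases`.
#' @export
phase_matrix <- function(trees, manifest, layout, thresholds = support_thresholds()) {
  pairs <- pair_table(manifest)
  rows <- purrr::map_dfr(layout$gene, function(g) {
    tr <- trees[[g]]
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      if (is.null(tr)) {
        tibble(pair_id = pairs$pair_id[i], gene = g, phase = "unresolved",
               separation_supported = FALSE, max_support_on_path = NA_real_,
               patristic = NA_real_)
      } else {
        pair_phase(tr, pairs$pair_id[i], pairs$strain_A[i], pairs$strain_a[i],
                   thresholds)
      }
    })
  })
  rows <- left_join(rows, layout[, c("gene", "order")], by = "gene")
  class(rows) <- c("tet_phases", class(rows))
  rows
}

#' Write a phase matrix as TSV (genes as rows in layout order)
#'
#' Supported separation is marked with a dagger suffix (`separated+`).
#'
#' @param phases A [phase_matrix()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phase_matrix <- function(phases, path) {
  wide <- phases |>
    mutate(cell = ifelse(.data$phase == "separated" & .data$separation_supported,
                         "separated+", .data$phase)) |>
    select("gene", "order", "pair_id", "cell") |>
    tidyr::pivot_wider(names_from = "pair_id", values_from = "cell") |>
    arrange(.data$order)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
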