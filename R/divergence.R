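#' Jukes-Cantor correction of a raw difference proportion
#'
#' Converts an observed proportion of differing sites into an estimated number
#' of substitutions per site, `d = -(3/4) * log(1 - 4p/3)`, correcting for
#' multiple hits under equal base exchangeabilities.
#'
#' @param p Proportion of differing sites, in `[0, 0.75)`.
#' @return Corrected distance `d >= p` (vectorised).
#' @export
#' @examples
#' jc_correct(0.3)
jc_correct <- function(p) {
  if (any(!is.na(p) & (p < 0 | p >= 0.75))) {
    stop_tetmat(
      sprintf("proportion %s outside [0, 0.75): Jukes-Cantor correction undefined",
              paste(format(p[!is.na(p) & (p < 0 | p >= 0.75)]), collapse = ", ")),
      "tetmat_correction_error"
    )
  }
  -0.75 * log(1 - 4 * p / 3) + 0  # + 0 normalises IEEE negative zero
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' Each codon position contributes `(# synonymous single-base neighbours)/3`
#' synonymous sites; the remainder is nonsynonymous, so the two fractions sum
#' to 3. Mutations to stop codons count as nonsynonymous.
#'
#' @param codon Three-letter string over `A,C,G,T`; must not be a stop codon.
#' @return Named numeric vector `c(syn = , nonsyn = )`.
#' @export
#' @examples
#' ng86_site_counts("GGG")
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop_tetmat(sprintf("'%s' is not an unambiguous codon", codon),
                "tetmat_validation_error")
  }
  if (is_stop_codon(codon)) {
    stop_tetmat(sprintf("stop codon '%s' has no NG86 site counts", codon),
                "tetmat_validation_error")
  }
  syn <- syn_sites_lookup()[[codon]]
  c(syn = syn, nonsyn = 3 - syn)
}

# synonymous site fraction for every non-stop codon, computed once
syn_sites_lookup <- function() {
  if (is.null(.tetmat$syn_sites)) {
    code <- genetic_code()
    codons <- names(code)[code != "*"]
    syn <- vapply(codons, function(codon) {
      aa <- code[[codon]]
      nt <- strsplit(codon, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        for (b in setdiff(DNA_BASES, nt[pos])) {
          alt <- nt
          alt[pos] <- b
          if (code[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .tetmat$syn_sites <- syn
  }
  .tetmat$syn_sites
}

# Average syn/nonsyn difference counts between two codons over all minimal
# mutational pathways (equal weights). Pathways passing through a stop codon
# are excluded unless every pathway does.
codon_path_counts <- function(c1, c2) {
  key <- paste0("path_", c1, c2)
  cached <- .tetmat[[key]]
  if (!is.null(cached)) return(cached)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) {
    out <- c(syn = 0, nonsyn = 0)
  } else {
    orders <- switch(k,
      list(pos),
      list(pos, rev(pos)),
      {
        p <- pos
        list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
             p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
      }
    )
    target <- strsplit(c2, "")[[1]]
    paths <- purrr::map(orders, function(ord) {
      cur <- strsplit(c1, "")[[1]]
      syn <- 0; nonsyn <- 0; through_stop <- FALSE
      for (p in ord) {
        prev_cod <- paste(cur, collapse = "")
        cur[p] <- target[p]
        next_cod <- paste(cur, collapse = "")
        if (is_stop_codon(next_cod) && next_cod != c2) through_stop <- TRUE
        if (is_stop_codon(prev_cod) || is_stop_codon(next_cod)) {
          nonsyn <- nonsyn + 1          # changes to/from stops: nonsynonymous
        } else if (translate_codon(prev_cod) == translate_codon(next_cod)) {
          syn <- syn + 1
        } else {
          nonsyn <- nonsyn + 1
        }
      }
      c(syn = syn, nonsyn = nonsyn, stop = as.numeric(through_stop))
    })
    m <- do.call(rbind, paths)
    use <- if (all(m[, "stop"] == 1)) rep(TRUE, nrow(m)) else m[, "stop"] == 0
    out <- c(syn = mean(m[use, "syn"]), nonsyn = mean(m[use, "nonsyn"]))
  }
  assign(key, out, envir = .tetmat)
  out
}

#' Nei-Gojobori pairwise dN and dS with Jukes-Cantor correction
#'
#' Codons containing a gap, an ambiguous base, or a stop codon in either
#' sequence are removed (pairwise deletion at codon granularity). Synonymous
#' and nonsynonymous sites are averaged over the two sequences; differences in
#' multi-hit codons are averaged over all minimal mutational pathways with
#' equal weights (pathways through stop codons excluded when an alternative
#' exists). The proportions `pN = Nd/N` and `pS = Sd/S` are Jukes-Cantor
#' corrected separately.
#'
#' @param seq_a,seq_b Equal-length in-frame coding sequences (characters) or
#'   codon vectors.
#' @return A one-row tibble with `dN`, `dS`, `N`, `S`, `Nd`, `Sd` and
#'   `sites_used` (retained coding sites). `dN`/`dS` are `NA` when the
#'   corresponding site class is empty.
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  cod_a <- if (length(seq_a) == 1L) split_codons(seq_a) else toupper(seq_a)
  cod_b <- if (length(seq_b) == 1L) split_codons(seq_b) else toupper(seq_b)
  if (length(cod_a) != length(cod_b)) {
    stop_tetmat("coding sequences differ in codon count", "tetmat_alignment_error")
  }
  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  clean <- clean & !(cod_a %in% STOP_CODONS) & !(cod_b %in% STOP_CODONS)
  cod_a <- cod_a[clean]; cod_b <- cod_b[clean]
  n_cod <- length(cod_a)
  if (n_cod == 0) {
    return(tibble(dN = NA_real_, dS = NA_real_, N = 0, S = 0,
                  Nd = 0, Sd = 0, sites_used = 0L))
  }
  syn <- syn_sites_lookup()
  S <- sum(syn[cod_a] + syn[cod_b]) / 2
  N <- 3 * n_cod - S
  Sd <- 0; Nd <- 0
  diff_idx <- which(cod_a != cod_b)
  for (i in diff_idx) {
    cnt <- codon_path_counts(cod_a[i], cod_b[i])
    Sd <- Sd + cnt[["syn"]]
    Nd <- Nd + cnt[["nonsyn"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  for (p in c(pS, pN)) {
    if (!is.na(p) && p >= 0.75) {
      stop_tetmat(
        sprintf("difference proportion %.4f >= 0.75: Jukes-Cantor correction undefined", p),
        "tetmat_correction_error", proportion = p
      )
    }
  }
  tibble(
    dN = if (is.na(pN)) NA_real_ else jc_correct(pN),
    dS = if (is.na(pS)) NA_real_ else jc_correct(pS),
    N = N, S = S, Nd = Nd, Sd = Sd, sites_used = 3L * n_cod
  )
}

split_codons <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3 != 0) {
    stop_tetmat(sprintf("coding sequence length %d is not a multiple of 3", n),
                "tetmat_validation_error")
  }
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Count intron SNP differences between two aligned sequences
#'
#' Counts noncoding columns at which both strains carry an unambiguous,
#' non-gap base and the bases differ. Indel and ambiguous columns are
#' excluded, so the count is SNPs only.
#'
#' @param aln A [gene_alignment()].
#' @param strain_a,strain_b Strain ids present in `aln`.
#' @return Integer count, or `NA` when the gene has no noncoding columns.
#' @export
intron_diff_count <- function(aln, strain_a, strain_b) {
  if (!any(!aln$coding_mask)) return(NA_integer_)
  cols <- intron_columns(aln, strain_a, strain_b)
  ok <- cols[1, ] %in% DNA_BASES & cols[2, ] %in% DNA_BASES
  sum(cols[1, ok] != cols[2, ok])
}

# raw differing columns (coding + noncoding), SNPs only
raw_diff_count <- function(aln, strain_a, strain_b) {
  a <- strsplit(aln$seqs[[strain_a]], "")[[1]]
  b <- strsplit(aln$seqs[[strain_b]], "")[[1]]
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  sum(a[ok] != b[ok])
}

#' Per-pair, per-gene allelic divergence table
#'
#' For every heterokaryon pair and every gene, computes NG86 `dN`/`dS` between
#' the mat A- and mat a-linked alleles, the intron SNP count, and the raw
#' count of differing columns. Pairs missing a strain at a gene yield a row of
#' `NA`s (and a warning), so downstream stages can mark them unresolved.
#'
#' @param alignments Named list of [gene_alignment()] objects (names = genes).
#' @param manifest A `tet_manifest`.
#' @param layout A `tet_layout`; genes are reported in layout order.
#' @return A tibble with columns `pair_id`, `gene`, `dN`, `dS`, `intron_diffs`,
#'   `raw_diffs`, `sites_used`, classed `tet_divergence`.
#' @export
divergence_table <- function(alignments, manifest, layout) {
  pairs <- pair_table(manifest)
  genes <- intersect(layout$gene, names(alignments))
  rows <- purrr::map_dfr(genes, function(g) {
    aln <- alignments[[g]]
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      sa <- pairs$strain_A[i]; sb <- pairs$strain_a[i]
      if (!sa %in% names(aln$seqs) || !sb %in% names(aln$seqs)) {
        warn(sprintf("pair %s missing a strain at gene %s; divergence undefined",
                     pairs$pair_id[i], g))
        return(tibble(pair_id = pairs$pair_id[i], gene = g,
                      dN = NA_real_, dS = NA_real_, intron_diffs = NA_integer_,
                      raw_diffs = NA_integer_, sites_used = NA_integer_))
      }
      ng <- ng86_pairwise(coding_codons(aln, sa), coding_codons(aln, sb))
      tibble(
        pair_id = pairs$pair_id[i], gene = g,
        dN = ng$dN, dS = ng$dS,
        intron_diffs = intron_diff_count(aln, sa, sb),
        raw_diffs = raw_diff_count(aln, sa, sb),
        sites_used = ng$sites_used
      )
    })
  })
  rows$gene <- factor(rows$gene, levels = layout$gene)
  rows <- arrange(rows, .data$gene, .data$pair_id)
  rows$gene <- as.character(rows$gene)
  class(rows) <- c("tet_divergence", class(rows))
  rows
}

#' Write a divergence table as TSV
#'
#' Values are printed at 3 decimals, with `-` for absent intron counts,
#' mirroring the conventional published layout.
#'
#' @param div A [divergence_table()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_divergence_table <- function(div, path) {
  out <- div |>
    mutate(
      dN = ifelse(is.na(.data$dN), "NA", sprintf("%.3f", .data$dN)),
      dS = ifelse(is.na(.data$dS), "NA", sprintf("%.3f", .data$dS)),
      intron_diffs = ifelse(is.na(.data$intron_diffs), "-",
                            as.character(.data$intron_diffs))
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
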