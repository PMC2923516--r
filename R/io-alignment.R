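#' Construct a per-gene allele alignment
#'
#' The central sequence container: one pre-aligned nucleotide alignment per
#' gene, keyed by strain id, with a per-column coding/noncoding partition.
#' Columns are 0-based in all mask coordinates; intervals are half-open.
#'
#' @param gene Gene name.
#' @param seqs Named character vector of equal-length aligned sequences over
#'   `A,C,G,T,N,-` (case-insensitive); names are strain ids.
#' @param coding_mask Logical vector, one flag per alignment column (`TRUE` =
#'   coding). Default: all columns coding.
#' @param frame_offset Codon phase (0, 1 or 2) of the first coding column.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, seqs, coding_mask = NULL, frame_offset = 0L) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_tetmat("sequences must be named by strain id", "tetmat_validation_error")
  }
  if (anyDuplicated(names(seqs))) {
    stop_tetmat(sprintf("gene %s: duplicated strain ids in alignment", gene),
                "tetmat_validation_error")
  }
  seqs <- toupper(seqs)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop_tetmat(sprintf("gene %s: aligned sequences differ in length (%s)",
                        gene, paste(sort(lens), collapse = ", ")),
                "tetmat_alignment_error")
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(DNA_BASES, "N", "-"))
  if (length(bad) > 0) {
    stop_tetmat(sprintf("gene %s: invalid characters in alignment: %s",
                        gene, paste(bad, collapse = " ")),
                "tetmat_alignment_error")
  }
  if (is.null(coding_mask)) coding_mask <- rep(TRUE, lens)
  coding_mask <- as.logical(coding_mask)
  if (length(coding_mask) != lens || anyNA(coding_mask)) {
    stop_tetmat(sprintf("gene %s: coding mask must be one non-missing flag per column", gene),
                "tetmat_validation_error")
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) {
    stop_tetmat("frame_offset must be 0, 1 or 2", "tetmat_validation_error")
  }
  usable <- sum(coding_mask) - (3L - frame_offset) %% 3L
  if (sum(coding_mask) > 0 && usable %% 3L != 0L) {
    stop_tetmat(
      sprintf("gene %s: %d coding columns at frame offset %d is not a whole number of codons",
              gene, sum(coding_mask), frame_offset),
      "tetmat_validation_error"
    )
  }
  structure(
    list(gene = gene, seqs = seqs, coding_mask = coding_mask,
         frame_offset = frame_offset),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d strains x %d columns (%d coding)\n",
              x$gene, length(x$seqs), length(x$coding_mask), sum(x$coding_mask)))
  invisible(x)
}

#' Read a per-gene FASTA alignment
#'
#' @param path FASTA file of pre-aligned sequences; headers are strain ids.
#' @param mask Either a coding-mask tibble from [read_coding_mask()], a
#'   logical per-column vector, or `NULL` (all columns coding).
#' @param gene Gene name; defaults to the file name without extension.
#' @param manifest Optional `tet_manifest`; if given, headers must be known
#'   strain ids.
#' @param frame_offset Codon phase of the first coding column.
#' @return A [gene_alignment()].
#' @export
read_gene_alignment <- function(path, mask = NULL, gene = NULL, manifest = NULL,
                                frame_offset = 0L) {
  if (!file.exists(path)) {
    stop_tetmat(sprintf("alignment file not found: %s", path), "tetmat_format_error")
  }
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) {
    stop_tetmat(sprintf("no sequences in %s", path), "tetmat_format_error")
  }
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  if (!is.null(manifest)) {
    unknown <- setdiff(names(seqs), manifest$strain_id)
    if (length(unknown) > 0) {
      stop_tetmat(sprintf("gene %s: unknown strain id(s): %s", gene,
                          paste(unknown, collapse = ", ")),
                  "tetmat_validation_error")
    }
  }
  if (is.data.frame(mask)) mask <- mask_vector(mask, gene, nchar(seqs[[1]]))
  gene_alignment(gene, seqs, coding_mask = mask, frame_offset = frame_offset)
}

#' Write a gene alignment as FASTA (plus optional mask rows)
#'
#' @param aln A [gene_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_gene_alignment <- function(aln, path) {
  out <- character(2L * length(aln$seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(aln$seqs))
  out[c(FALSE, TRUE)] <- unname(aln$seqs)
  writeLines(out, path)
  invisible(path)
}

#' Read a BED-like coding mask table
#'
#' Columns `gene`, `start`, `end` (0-based, half-open) and `label`
#' (`coding` or `intron`/`noncoding`). Unlisted columns of a gene default to
#' noncoding.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_coding_mask <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), label = readr::col_character()
  ), progress = FALSE)
  check_values(df$label, c("coding", "intron", "noncoding"), "mask label")
  if (any(df$start < 0 | df$end < df$start)) {
    stop_tetmat("mask intervals must satisfy 0 <= start <= end", "tetmat_validation_error")
  }
  df
}

#' Write a coding mask table for a set of alignments
#' @param alignments List of [gene_alignment()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coding_mask <- function(alignments, path) {
  rows <- purrr::map_dfr(alignments, function(a) {
    r <- rle(a$coding_mask)
    ends <- cumsum(r$lengths)
    tibble(gene = a$gene, start = ends - r$lengths, end = ends,
           label = ifelse(r$values, "coding", "intron"))
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

# expand mask tibble rows for one gene into a logical per-column vector
mask_vector <- function(mask_df, gene, len) {
  rows <- mask_df[mask_df$gene == gene & mask_df$label == "coding", , drop = FALSE]
  if (any(mask_df$gene == gene & mask_df$end > len)) {
    stop_tetmat(sprintf("gene %s: mask interval beyond alignment length %d", gene, len),
                "tetmat_validation_error")
  }
  v <- rep(FALSE, len)
  for (i in seq_len(nrow(rows))) {
    if (rows$end[i] > rows$start[i]) v[(rows$start[i] + 1L):rows$end[i]] <- TRUE
  }
  v
}

# Extract the in-frame codon vector of one strain (coding columns only,
# leading partial codon trimmed, trailing complete codons kept).
coding_codons <- function(aln, strain) {
  s <- aln$seqs[[strain]]
  if (is.null(s)) return(NULL)
  cod_cols <- strsplit(s, "")[[1]][aln$coding_mask]
  skip <- (3L - aln$frame_offset) %% 3L
  if (skip > 0) cod_cols <- cod_cols[-seq_len(skip)]
  n <- length(cod_cols) %/% 3L
  if (n == 0) return(character(0))
  apply(matrix(cod_cols[seq_len(3L * n)], nrow = 3L), 2, paste, collapse = "")
}

# Per-column character matrix of the noncoding (intron) columns for two strains.
intron_columns <- function(aln, strain_a, strain_b) {
  a <- strsplit(aln$seqs[[strain_a]], "")[[1]][!aln$coding_mask]
  b <- strsplit(aln$seqs[[strain_b]], "")[[1]][!aln$coding_mask]
  rbind(a, b)
}
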