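# Standard genetic code lookup, built once from seqinr's translation table.

genetic_code <- function() {
  if (is.null(.tetmat$code)) {
    bases <- c("A", "C", "G", "T")
    cods <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                        stringsAsFactors = FALSE)
    codons <- paste0(cods$p1, cods$p2, cods$p3)
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]])
    }, character(1))
    .tetmat$code <- setNames(aa, codons)
  }
  .tetmat$code
}

translate_codon <- function(codon) {
  unname(genetic_code()[codon])
}

is_stop_codon <- function(codon) {
  !is.na(genetic_code()[codon]) & genetic_code()[codon] == "*"
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")
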