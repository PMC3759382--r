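# Amber-suppressed translation of 27-nt HCDR3 sequences. The display host is
# a supE/Sup44-type strain whose Gln-tRNA reads the amber stop (TAG) as
# glutamine, so TAG-containing library members are translated; ochre (TAA)
# and opal (TGA) have no suppressor and invalidate the sequence.

amber_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      gc[["TAG"]] <- "Q"
      tab <<- gc
    }
    tab
  }
})

#' Translate 27-nt HCDR3 sequences with amber suppression
#'
#' Standard genetic code except that TAG is read as glutamine (amber
#' suppression by the host's Gln-tRNA). Sequences containing an unsuppressed
#' stop (TAA or TGA) or any non-ACGT base are biologically invalid and return
#' `NA`. A sequence of the wrong length is a caller error, not an invalid
#' read, and aborts.
#'
#' @param hcdr3_nt Character vector of 27-nt sequences (A/C/G/T; any N makes
#'   the sequence invalid).
#' @return Character vector of 9-residue peptides, `NA` where invalid.
#' @examples
#' translate_hcdr3(strrep("TAT", 9)) # "YYYYYYYYY"
#' translate_hcdr3(paste0(strrep("TAT", 4), "TAG", strrep("TAT", 4))) # Q at 5
#' @export
translate_hcdr3 <- function(hcdr3_nt) {
  if (length(hcdr3_nt) == 0) return(character(0))
  len <- nchar(hcdr3_nt)
  if (any(!is.na(hcdr3_nt) & len != 27)) {
    abort("translate_hcdr3() requires 27-nt sequences; extraction should have enforced this.")
  }
  out <- rep(NA_character_, length(hcdr3_nt))
  ok <- !is.na(hcdr3_nt) & !stringr::str_detect(hcdr3_nt, "[^ACGT]")
  if (!any(ok)) return(out)
  seqs <- hcdr3_nt[ok]
  tab <- amber_codon_table()
  # 9 codons per sequence, columns are sequences
  starts <- seq(1, 25, by = 3)
  codons <- vapply(starts, function(s) substr(seqs, s, s + 2), character(length(seqs)))
  if (length(seqs) == 1) codons <- matrix(codons, nrow = 1)
  aas <- matrix(tab[codons], nrow = nrow(codons))
  pep <- apply(aas, 1, paste0, collapse = "")
  pep[stringr::str_detect(pep, stringr::fixed("*"))] <- NA_character_
  out[ok] <- pep
  out
}

# Codons within one template codon's IUPAC expansion that encode `residue`
# (amber-suppressed). Used by the simulator to draw synonymous encodings.
codons_for_residue <- function(template, residue) {
  sets <- expand_iupac(strsplit(template, "")[[1]])
  codons <- as.vector(outer(
    as.vector(outer(sets[[1]], sets[[2]], paste0)),
    sets[[3]], paste0
  ))
  tab <- amber_codon_table()
  codons[tab[codons] == residue]
}
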