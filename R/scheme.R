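# Degenerate codon scheme describing the synthetic HCDR3 library:
# six fully variable NNS codons followed by the partially restricted
# KBG HTK GMT codons, flanked by fixed vector sequence used as
# extraction anchors.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

# 20 standard residues; amber-suppressed TAG is folded into Q.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Character vector of single IUPAC nucleotide codes.
#' @return A list (one element per input code) of base character vectors.
#' @examples
#' expand_iupac(c("N", "S", "K"))
#' @export
expand_iupac <- function(code) {
  bad <- setdiff(unique(code), names(IUPAC_DNA))
  if (length(bad) > 0) {
    abort(paste0("Invalid IUPAC nucleotide code(s): ", paste(bad, collapse = ", ")))
  }
  unname(IUPAC_DNA[code])
}

#' Define a degenerate HCDR3 codon scheme
#'
#' A scheme is the positional codon template of the randomized HCDR3 plus the
#' two fixed flanking sequences used as extraction anchors. The default is the
#' library design used throughout the package: complete variability at codons
#' 1-6 (NNS) and partial restriction at codons 7-9 (KBG, HTK, GMT); the
#' upstream flank carries the Val-Arg-Glu codons with the BsiWI site (CGTACG)
#' and the downstream flank the fixed Tyr codon plus the WGQGT framework-4
#' consensus.
#'
#' @param codon_templates Character vector of 9 three-letter IUPAC codon
#'   templates.
#' @param flank_upstream,flank_downstream Unambiguous (A/C/G/T only) anchor
#'   sequences immediately flanking the 27-nt HCDR3 in the amplicon.
#' @return An object of class `hcdr3_scheme`.
#' @examples
#' sc <- hcdr3_scheme()
#' sc
#' @export
hcdr3_scheme <- function(codon_templates = c(rep("NNS", 6), "KBG", "HTK", "GMT"),
                         flank_upstream = "GCAGCTTCTCCGTACGTGAA",
                         flank_downstream = "TATTGGGGTCAAGGAACCTCTAGA") {
  if (length(codon_templates) != 9) {
    abort("A scheme requires exactly 9 codon templates.")
  }
  if (any(nchar(codon_templates) != 3)) {
    abort("Every codon template must be 3 characters long.")
  }
  chars <- strsplit(paste(codon_templates, collapse = ""), "")[[1]]
  expand_iupac(chars) # errors on invalid codes
  for (fl in c(flank_upstream, flank_downstream)) {
    if (nchar(fl) < 1 || grepl("[^ACGT]", fl)) {
      abort("Flanks must be non-empty literal A/C/G/T strings (anchors are matched exactly).")
    }
  }
  structure(
    list(
      codon_templates = toupper(codon_templates),
      flank_upstream = toupper(flank_upstream),
      flank_downstream = toupper(flank_downstream)
    ),
    class = "hcdr3_scheme"
  )
}

#' @export
print.hcdr3_scheme <- function(x, ...) {
  cat("<hcdr3_scheme>\n")
  cat("  codons:  ", paste(x$codon_templates, collapse = " "), "\n")
  cat("  upstream anchor:  ", x$flank_upstream, "\n")
  cat("  downstream anchor:", x$flank_downstream, "\n")
  invisible(x)
}

# Per-nucleotide-position template characters (length 27).
scheme_position_codes <- function(scheme) {
  strsplit(paste(scheme$codon_templates, collapse = ""), "")[[1]]
}

# Allowed bases at each of the 27 positions.
scheme_allowed_bases <- function(scheme) {
  expand_iupac(scheme_position_codes(scheme))
}

#' Does a 27-nt sequence conform to a scheme?
#'
#' @param hcdr3_nt Character vector of 27-nt sequences.
#' @param scheme An [hcdr3_scheme()].
#' @return Logical vector.
#' @export
matches_scheme <- function(hcdr3_nt, scheme = hcdr3_scheme()) {
  allowed <- scheme_allowed_bases(scheme)
  vapply(hcdr3_nt, function(s) {
    if (is.na(s) || nchar(s) != 27) return(FALSE)
    b <- strsplit(s, "")[[1]]
    all(mapply(function(base, ok) base %in% ok, b, allowed))
  }, logical(1), USE.NAMES = FALSE)
}

#' Theoretical position frequency matrix of a codon scheme
#'
#' Each nucleotide position gets the uniform distribution over the IUPAC
#' expansion of its template character; this is the null profile of the
#' unselected library against which observed profiles are compared.
#'
#' @param scheme An [hcdr3_scheme()].
#' @return A `pfm` object (see [build_pfm()]), 27 positions x 4 bases.
#' @examples
#' pfm <- theoretical_pfm()
#' tidy(pfm)
#' @export
theoretical_pfm <- function(scheme = hcdr3_scheme()) {
  allowed <- scheme_allowed_bases(scheme)
  freqs <- t(vapply(allowed, function(bases) {
    p <- setNames(numeric(4), DNA_BASES)
    p[bases] <- 1 / length(bases)
    p
  }, numeric(4)))
  rownames(freqs) <- NULL
  new_pfm(freqs,
    alphabet = "dna", n_sequences = NA_integer_,
    weighting = "theoretical"
  )
}
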