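# Shared fixtures: everything is generated in code at test time.

# independent IUPAC expansion used by oracle computations (kept separate from
# the package's own table on purpose)
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

default_template_chars <- function() {
  strsplit(paste(c(rep("NNS", 6), "KBG", "HTK", "GMT"), collapse = ""), "")[[1]]
}

# amber-suppressed translation oracle built on Biostrings, independent of the
# package's codon table
oracle_translate <- function(nt27) {
  vapply(nt27, function(s) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(s),
      no.init.codon = TRUE, # internal CDR3 codons, no alternative initiation
      if.fuzzy.codon = "error"
    ))
    aa <- gsub("\\*", "#", aa) # mark stops
    codons <- substring(s, seq(1, 25, 3), seq(3, 27, 3))
    res <- strsplit(aa, "")[[1]]
    res[codons == "TAG"] <- "Q" # amber suppression
    if (any(res == "#")) NA_character_ else paste(res, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# build a 27-nt sequence from a single test codon at a given position, TAT
# elsewhere
codon_at <- function(codon, pos) {
  codons <- rep("TAT", 9)
  codons[pos] <- codon
  paste(codons, collapse = "")
}

# deterministic multinomial read-count draw from a pool composition, at the
# peptide level (for enrichment tests that do not need full FASTQ emission)
draw_peptide_counts <- function(pool, depth, seed) {
  cnt <- withr::with_seed(seed, {
    as.vector(rmultinom(1, size = depth, prob = pool$freq))
  })
  tb <- dplyr::tibble(peptide = pool$peptide, n = cnt) |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(n = sum(n), .groups = "drop") |>
    dplyr::filter(n > 0) |>
    dplyr::arrange(peptide)
  tb
}

# a small classified-read tibble built by hand for counting tests
manual_classified <- function(rows) {
  dplyr::tibble(
    read_id = sprintf("r%03d", seq_len(nrow(rows))),
    pool_id = rows$pool_id,
    status = "ok",
    source_mate = rows$source_mate,
    hcdr3_nt = rows$hcdr3_nt,
    peptide = phanner::translate_hcdr3(rows$hcdr3_nt),
    valid = TRUE
  )
}
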