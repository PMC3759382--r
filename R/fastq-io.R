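# Paired FASTQ input/output and read-level quality filtering.
# Parsing and writing go through Biostrings; the pipeline works on plain
# tibbles of character columns.

#' Write a tibble of read pairs to a pair of FASTQ files
#'
#' @param reads A tibble with columns `read_id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual` (as produced by [emit_reads()]).
#' @param r1_path,r2_path Output paths; a `.gz` suffix gzips the file.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path,
      format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path)
    )
  }
  write_one(reads$r1_seq, reads$r1_qual, reads$read_id, r1_path)
  write_one(reads$r2_seq, reads$r2_qual, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

read_fastq_one <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(sprintf("Malformed FASTQ in '%s': %s", path, conditionMessage(e)))
    }
  )
  tibble(
    read_id = unname(names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read a pair of lockstep FASTQ files into a read-pair tibble
#'
#' R1 and R2 must contain the same number of records in the same order with
#' matching identifiers (up to the first whitespace). Gzipped input is read
#' transparently.
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return A tibble with `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  for (p in c(r1_path, r2_path)) {
    if (!file.exists(p)) abort(sprintf("FASTQ file not found: '%s'", p))
  }
  r1 <- read_fastq_one(r1_path)
  r2 <- read_fastq_one(r2_path)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf(
      "R1 has %d records but R2 has %d; files are not a lockstep pair (first unmatched pair index: %d).",
      nrow(r1), nrow(r2), min(nrow(r1), nrow(r2)) + 1L
    ))
  }
  id1 <- sub("\\s.*$", "", r1$read_id)
  id2 <- sub("\\s.*$", "", r2$read_id)
  bad <- which(id1 != id2)
  if (length(bad) > 0) {
    abort(sprintf(
      "Read ID mismatch at pair index %d: '%s' vs '%s'.",
      bad[1], id1[bad[1]], id2[bad[1]]
    ))
  }
  tibble(
    read_id = r1$read_id,
    r1_seq = r1$seq, r1_qual = r1$qual,
    r2_seq = r2$seq, r2_qual = r2$qual
  )
}

#' Quality-filtering policy
#'
#' A read (or its HCDR3 window, depending on `region`) passes when its mean
#' Phred score is at least `min_mean_phred` **and** every base is at least
#' `min_base_phred`; both boundaries are inclusive. An N base counts as
#' Phred 0.
#'
#' @param min_mean_phred,min_base_phred Non-negative Phred thresholds.
#' @param region Where the policy is evaluated: over the whole read
#'   (`"whole-read"`, the default) or over the extracted 27-nt window only
#'   (`"hcdr3-only"`).
#' @return A `quality_policy` list.
#' @export
quality_policy <- function(min_mean_phred = 20, min_base_phred = 10,
                           region = c("whole-read", "hcdr3-only")) {
  region <- match.arg(region)
  if (min_mean_phred < 0 || min_base_phred < 0) {
    abort("Quality thresholds must be >= 0.")
  }
  structure(
    list(
      min_mean_phred = min_mean_phred, min_base_phred = min_base_phred,
      region = region
    ),
    class = "quality_policy"
  )
}

# Phred scores (+33 offset) for equal-length quality strings, as a matrix
# (reads x cycles). N bases in `seqs` are forced to Phred 0. Errors on
# characters outside the Phred+33 printable range (Phred+64 data).
phred_matrix <- function(quals, seqs = NULL) {
  width <- nchar(quals[1])
  codes <- utf8ToInt(paste(quals, collapse = ""))
  if (any(codes > 75L)) {
    abort("Quality characters out of Phred+33 range; input looks Phred+64 encoded, which is not supported.")
  }
  m <- matrix(codes - 33L, ncol = width, byrow = TRUE)
  if (!is.null(seqs)) {
    n_pos <- stringr::str_locate_all(seqs, stringr::fixed("N"))
    has_n <- which(vapply(n_pos, nrow, integer(1)) > 0)
    for (i in has_n) m[i, n_pos[[i]][, 1]] <- 0L
  }
  m
}

row_mins <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Does each read pass a quality policy?
#'
#' Vectorised over reads of equal length. Empty sequences fail (with a
#' warning) rather than erroring.
#'
#' @param seq,qual Character vectors of sequences and aligned Phred+33
#'   quality strings.
#' @param policy A [quality_policy()]; evaluated over the strings as given
#'   (callers choose the region by passing whole reads or extracted windows).
#' @return Logical vector.
#' @export
passes_quality <- function(seq, qual, policy = quality_policy()) {
  stopifnot(length(seq) == length(qual))
  if (length(seq) == 0) return(logical(0))
  if (any(nchar(seq) != nchar(qual))) {
    abort("Sequence and quality lengths differ.")
  }
  out <- logical(length(seq))
  empty <- nchar(seq) == 0
  if (any(empty)) {
    warn(sprintf("%d empty sequence(s) failed quality filtering.", sum(empty)))
  }
  widths <- nchar(seq)
  for (w in unique(widths[!empty])) {
    i <- which(widths == w)
    m <- phred_matrix(qual[i], seq[i])
    out[i] <- rowMeans(m) >= policy$min_mean_phred &
      row_mins(m) >= policy$min_base_phred
  }
  out
}
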