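# Demultiplexing by barcode prefix, anchored HCDR3 extraction with the
# R1-then-R2 fallback rule, and assembly of the per-read classification table.

#' Barcode table for pool demultiplexing
#'
#' Barcodes are the amplicon's leading sequence, so comparison is
#' prefix-anchored. Unambiguous assignment requires pairwise Hamming distance
#' greater than `2 * max_mismatch`, which the constructor enforces.
#'
#' @param barcodes Named character vector: `pool_id = barcode`.
#' @param max_mismatch Maximum Hamming distance for an assignment (default 0,
#'   exact prefix match).
#' @return A `barcode_table` tibble with columns `pool_id`, `barcode`.
#' @examples
#' default_barcodes()
#' barcode_table(c(a = "ACGTAC", b = "TGACTA"), max_mismatch = 1)
#' @export
barcode_table <- function(barcodes, max_mismatch = 0) {
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    abort("barcodes must be a named character vector (pool_id = barcode).")
  }
  if (anyDuplicated(barcodes)) abort("Barcodes must be unique.")
  if (length(unique(nchar(barcodes))) != 1) {
    abort("All barcodes must have the same length.")
  }
  if (length(barcodes) > 1) {
    d <- utils::combn(length(barcodes), 2, function(i) {
      hamming(barcodes[i[1]], barcodes[i[2]])
    })
    if (any(d <= 2 * max_mismatch)) {
      abort(sprintf(
        "Minimum pairwise barcode Hamming distance (%d) must exceed 2*max_mismatch (%d) for unambiguous assignment.",
        min(d), 2 * max_mismatch
      ))
    }
  }
  structure(
    tibble(pool_id = names(barcodes), barcode = unname(barcodes)),
    max_mismatch = as.integer(max_mismatch),
    class = c("barcode_table", class(tibble()))
  )
}

#' Default four-pool barcode set
#'
#' Two V-gene contexts (VH4, VH10) crossed with rounds 0 and 3; 6-nt barcodes
#' with pairwise Hamming distance >= 5.
#'
#' @param max_mismatch Passed to [barcode_table()].
#' @return A `barcode_table`.
#' @export
default_barcodes <- function(max_mismatch = 0) {
  barcode_table(
    c(
      vh4_r0 = "ACGTAC", vh4_r3 = "CATACG",
      vh10_r0 = "GTCAGT", vh10_r3 = "TGACTA"
    ),
    max_mismatch = max_mismatch
  )
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Assign read pairs to pools by barcode prefix
#'
#' Compares the read's leading bases against every barcode and returns the
#' unique pool within `max_mismatch`; `NA` (unclassified) when no barcode
#' qualifies or two or more tie at the minimum distance.
#'
#' @param read_seq Character vector of read sequences in amplicon orientation.
#' @param table A [barcode_table()].
#' @return Character vector of pool ids, `NA` where unclassified.
#' @export
assign_pool <- function(read_seq, table = default_barcodes()) {
  n <- length(read_seq)
  if (n == 0) return(character(0))
  width <- nchar(table$barcode[1])
  prefix <- substr(read_seq, 1, width)
  dist <- vapply(table$barcode, function(b) {
    raw_b <- rep(charToRaw(b), times = n)
    short <- nchar(prefix) < width
    pr <- prefix
    pr[short] <- strrep(" ", width) # too-short reads can never match
    colSums(matrix(charToRaw(paste(pr, collapse = "")) != raw_b, nrow = width))
  }, numeric(n))
  if (n == 1) dist <- matrix(dist, nrow = 1)
  best <- apply(dist, 1, min)
  n_best <- rowSums(dist == best)
  hit <- max.col(-dist, ties.method = "first")
  out <- table$pool_id[hit]
  out[best > attr(table, "max_mismatch") | n_best > 1] <- NA_character_
  out
}

#' Extract the 27-nt HCDR3 by exact anchor match
#'
#' Locates the scheme's upstream and downstream flanks as exact literal
#' substrings ("perfect match"). Extraction succeeds only when both anchors
#' occur exactly once, in order, separated by exactly 27 nt; otherwise the
#' specific failure is reported (`no_anchor` for missing, duplicated or
#' out-of-order anchors, `bad_length` for a gap other than 27 nt,
#' `low_quality` when an `hcdr3-only` policy rejects the window).
#'
#' @param read_seq Character vector of reads in amplicon orientation.
#' @param read_qual Optional aligned quality strings (required for
#'   `hcdr3-only` policies).
#' @param scheme An [hcdr3_scheme()] supplying the anchors.
#' @param policy Optional [quality_policy()]; only a policy with
#'   `region = "hcdr3-only"` is applied here (whole-read filtering happens
#'   before extraction).
#' @return A tibble with columns `status` (`ok`, `no_anchor`, `bad_length`,
#'   `low_quality`) and `hcdr3_nt` (27 nt when `ok`, otherwise `NA`).
#' @export
extract_hcdr3 <- function(read_seq, read_qual = NULL, scheme = hcdr3_scheme(),
                          policy = NULL) {
  n <- length(read_seq)
  if (n == 0) return(tibble(status = character(0), hcdr3_nt = character(0)))
  up <- scheme$flank_upstream
  down <- scheme$flank_downstream
  up_first <- stringi::stri_locate_first_fixed(read_seq, up)[, 1]
  up_last <- stringi::stri_locate_last_fixed(read_seq, up)[, 1]
  down_first <- stringi::stri_locate_first_fixed(read_seq, down)[, 1]
  down_last <- stringi::stri_locate_last_fixed(read_seq, down)[, 1]

  status <- rep("ok", n)
  no_anchor <- is.na(up_first) | is.na(down_first) |
    up_first != up_last | down_first != down_last |
    (!is.na(up_first) & !is.na(down_first) & down_first <= up_first)
  no_anchor[is.na(no_anchor)] <- TRUE
  status[no_anchor] <- "no_anchor"

  gap <- down_first - (up_first + nchar(up))
  bad_len <- !no_anchor & gap != 27
  status[bad_len] <- "bad_length"

  hcdr3 <- rep(NA_character_, n)
  ok <- status == "ok"
  hcdr3[ok] <- substr(read_seq[ok], up_first[ok] + nchar(up),
    up_first[ok] + nchar(up) + 26)

  if (!is.null(policy) && policy$region == "hcdr3-only") {
    if (is.null(read_qual)) {
      abort("read_qual is required for an hcdr3-only quality policy.")
    }
    win_qual <- rep(NA_character_, n)
    win_qual[ok] <- substr(read_qual[ok], up_first[ok] + nchar(up),
      up_first[ok] + nchar(up) + 26)
    pass <- ok
    pass[ok] <- passes_quality(hcdr3[ok], win_qual[ok], policy)
    status[ok & !pass] <- "low_quality"
    hcdr3[ok & !pass] <- NA_character_
  }
  tibble(status = status, hcdr3_nt = hcdr3)
}

#' Resolve paired extraction results with the R2 fallback rule
#'
#' R2 is considered only when R1 was discarded (low quality or HCDR3 match
#' failure): the R1 result wins whenever it is `ok`; otherwise an `ok` R2
#' result is used and flagged as rescued; when both fail, the pair is
#' discarded with the R1 failure status.
#'
#' @param r1_result,r2_result Tibbles from [extract_hcdr3()] (R2 extraction
#'   must have been run on the reverse complement of the R2 read, so both are
#'   in amplicon orientation).
#' @return A tibble with `status`, `hcdr3_nt` and `source_mate` (`"R1"`,
#'   `"R2"`, or `NA` for discarded pairs).
#' @export
resolve_pairs <- function(r1_result, r2_result) {
  stopifnot(nrow(r1_result) == nrow(r2_result))
  r1_ok <- r1_result$status == "ok"
  r2_ok <- r2_result$status == "ok"
  status <- r1_result$status
  hcdr3 <- r1_result$hcdr3_nt
  source_mate <- rep(NA_character_, nrow(r1_result))
  source_mate[r1_ok] <- "R1"
  rescue <- !r1_ok & r2_ok
  status[rescue] <- "ok"
  hcdr3[rescue] <- r2_result$hcdr3_nt[rescue]
  source_mate[rescue] <- "R2"
  tibble(status = status, hcdr3_nt = hcdr3, source_mate = source_mate)
}

#' Classify, extract and translate a table of read pairs
#'
#' The full per-read stage of the pipeline: whole-read quality filtering,
#' anchored HCDR3 extraction from R1 with R2 fallback (R2 is
#' reverse-complemented first), barcode demultiplexing on the mate actually
#' consulted, and amber-suppressed translation.
#'
#' @param reads Tibble with `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (from [read_fastq_pairs()] or [emit_reads()]).
#' @param barcodes A [barcode_table()].
#' @param scheme An [hcdr3_scheme()].
#' @param policy A [quality_policy()]; with region `"whole-read"` a failing
#'   mate is discarded before extraction, with `"hcdr3-only"` only the
#'   extracted window is checked.
#' @return A tibble with one row per read pair: `read_id`, `pool_id` (`NA` =
#'   unclassified), `status`, `source_mate`, `hcdr3_nt`, `peptide` (`NA` when
#'   extraction failed or translation hit an unsuppressed stop), and `valid`
#'   (classified + extracted + translatable).
#' @export
classify_reads <- function(reads, barcodes = default_barcodes(),
                           scheme = hcdr3_scheme(),
                           policy = quality_policy()) {
  n <- nrow(reads)
  whole_read <- policy$region == "whole-read"

  r1_res <- tibble(status = rep("low_quality", n), hcdr3_nt = NA_character_)
  r1_pass <- if (whole_read) {
    passes_quality(reads$r1_seq, reads$r1_qual, policy)
  } else {
    rep(TRUE, n)
  }
  r1_res[r1_pass, ] <- extract_hcdr3(
    reads$r1_seq[r1_pass], reads$r1_qual[r1_pass], scheme, policy
  )

  # R2 is consulted only for pairs R1 could not resolve
  need_r2 <- r1_res$status != "ok"
  r2_res <- tibble(status = rep("low_quality", n), hcdr3_nt = NA_character_)
  r2_amp <- rep(NA_character_, n)
  r2_amp_qual <- rep(NA_character_, n)
  if (any(need_r2)) {
    r2_amp[need_r2] <- reverse_complement(reads$r2_seq[need_r2])
    r2_amp_qual[need_r2] <- stringi::stri_reverse(reads$r2_qual[need_r2])
    r2_pass <- need_r2
    if (whole_read) {
      r2_pass[need_r2] <- passes_quality(
        r2_amp[need_r2], r2_amp_qual[need_r2], policy
      )
    }
    r2_res[r2_pass, ] <- extract_hcdr3(
      r2_amp[r2_pass], r2_amp_qual[r2_pass], scheme, policy
    )
  }

  resolved <- resolve_pairs(r1_res, r2_res)

  # demultiplex on the mate actually consulted (R1 unless rescued by R2)
  demux_seq <- reads$r1_seq
  from_r2 <- !is.na(resolved$source_mate) & resolved$source_mate == "R2"
  demux_seq[from_r2] <- r2_amp[from_r2]
  pool_id <- assign_pool(demux_seq, barcodes)

  peptide <- rep(NA_character_, n)
  ok <- resolved$status == "ok"
  peptide[ok] <- translate_hcdr3(resolved$hcdr3_nt[ok])

  tibble(
    read_id = reads$read_id,
    pool_id = pool_id,
    status = resolved$status,
    source_mate = resolved$source_mate,
    hcdr3_nt = resolved$hcdr3_nt,
    peptide = peptide,
    valid = ok & !is.na(pool_id) & !is.na(peptide)
  )
}
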