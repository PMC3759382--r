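# Aggregation of valid HCDR3s into unique nucleotide / peptide count tables
# per pool, and the frequency tables derived from them.

#' Accumulate classified reads into per-pool unique-sequence counts
#'
#' Exact multiset counting of valid HCDR3s at the nucleotide level; peptide
#' counts are obtained by folding synonymous encodings. Records which unique
#' nucleotide sequences were only ever observed through the R2 rescue path
#' (the "uniques to R2" accounting).
#'
#' @param classified Tibble from [classify_reads()] (only rows with
#'   `valid == TRUE` are counted).
#' @return A `pool_counts` tibble with one row per (pool, unique nucleotide
#'   sequence): `pool_id`, `hcdr3_nt`, `peptide`, `n` (reads), `n_r2`
#'   (reads observed via R2 rescue) and `r2_only` (every observation was
#'   rescued).
#' @export
count_pools <- function(classified) {
  valid <- classified[classified$valid, ]
  out <- valid |>
    group_by(.data$pool_id, .data$hcdr3_nt, .data$peptide) |>
    summarise(
      n = n(),
      n_r2 = sum(.data$source_mate == "R2"),
      .groups = "drop"
    ) |>
    mutate(r2_only = .data$n_r2 == .data$n) |>
    arrange(.data$pool_id, .data$hcdr3_nt)
  structure(out, class = c("pool_counts", class(out)))
}

#' Per-pool summary of a counts table
#'
#' One row per pool: valid reads, unique nucleotide and peptide sequences,
#' rescued reads and R2-only uniques — the machine-readable analogue of the
#' classified/unique-sequence summary tables of a panning report.
#'
#' @param x A `pool_counts` tibble from [count_pools()].
#' @param ... Unused.
#' @return A tibble with `pool_id`, `n_reads_valid`, `n_unique_nt`,
#'   `n_unique_pep`, `n_rescued_r2`, `n_unique_r2_only`.
#' @exportS3Method generics::glance
glance.pool_counts <- function(x, ...) {
  x |>
    group_by(.data$pool_id) |>
    summarise(
      n_reads_valid = sum(.data$n),
      n_unique_nt = n(),
      n_unique_pep = dplyr::n_distinct(.data$peptide),
      n_rescued_r2 = sum(.data$n_r2),
      n_unique_r2_only = sum(.data$r2_only),
      .groups = "drop"
    )
}

#' Peptide-level counts for one pool
#'
#' @param counts A `pool_counts` tibble.
#' @param pool One pool id present in `counts`.
#' @return A tibble with `peptide`, `n`, sorted by peptide.
#' @export
peptide_counts <- function(counts, pool) {
  sel <- counts[counts$pool_id == pool, ]
  if (nrow(sel) == 0) abort(sprintf("Pool '%s' has no counted sequences.", pool))
  sel |>
    group_by(.data$peptide) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    arrange(.data$peptide)
}

#' Observed frequency table for one pool
#'
#' With `weighting = "counts"` each sequence's frequency is its read count
#' over the pool total; with `weighting = "unique"` every observed sequence
#' gets equal weight `1 / n_unique` (sequences are not weighted by their
#' frequency, the convention used for diversity statistics).
#'
#' @param counts A `pool_counts` tibble from [count_pools()].
#' @param pool One pool id.
#' @param level `"nt"` (27-nt sequences) or `"peptide"` (9-mers).
#' @param weighting `"counts"` or `"unique"`.
#' @return A tibble with columns `sequence` and `freq` (sums to 1).
#' @export
frequency_table <- function(counts, pool, level = c("nt", "peptide"),
                            weighting = c("counts", "unique")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  sel <- counts[counts$pool_id == pool, ]
  if (nrow(sel) == 0) abort(sprintf("Pool '%s' has no counted sequences.", pool))
  tbl <- if (level == "nt") {
    tibble(sequence = sel$hcdr3_nt, n = sel$n)
  } else {
    sel |>
      group_by(sequence = .data$peptide) |>
      summarise(n = sum(.data$n), .groups = "drop")
  }
  freq <- if (weighting == "counts") tbl$n / sum(tbl$n) else rep(1 / nrow(tbl), nrow(tbl))
  tibble(sequence = tbl$sequence, freq = freq) |> arrange(.data$sequence)
}

#' Write per-pool two-column counts tables
#'
#' One TSV per pool and level, with the raw sequence in the first column and
#' its count in the second.
#'
#' @param counts A `pool_counts` tibble.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_counts_tables <- function(counts, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pool in unique(counts$pool_id)) {
    nt_tbl <- counts[counts$pool_id == pool, c("hcdr3_nt", "n")] |>
      arrange(.data$hcdr3_nt)
    pep_tbl <- peptide_counts(counts, pool)
    p1 <- file.path(dir, sprintf("%s_%s_nt.tsv", prefix, pool))
    p2 <- file.path(dir, sprintf("%s_%s_peptide.tsv", prefix, pool))
    readr::write_tsv(nt_tbl, p1)
    readr::write_tsv(pep_tbl, p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
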