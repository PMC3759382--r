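# Round-over-round enrichment: per-peptide fold change between the unselected
# (round 0) and selected (round 3) pools, stratification into selected /
# counter-selected bands, and the ordered fold-change series.

#' Per-peptide fold-change table between two selection rounds
#'
#' The ratio of round-3 to round-0 abundance for each HCDR3 peptide. With
#' `normalize = TRUE` (default) counts are converted to within-pool
#' frequencies first, `FC = ((c3+psi)/N3) / ((c0+psi)/N0)`, which is robust to
#' unequal pool depths; `normalize = FALSE` uses the raw count ratio
#' `(c3+psi)/(c0+psi)`. With `pseudocount = 0`, peptides absent from round 0
#' are set aside in a `novel` side-list (no finite ratio) and peptides absent
#' from round 3 get `FC = 0` and appear in the `lost` list.
#'
#' @param counts_r0,counts_r3 Peptide count tibbles with columns `peptide`,
#'   `n` (see [peptide_counts()]).
#' @param normalize Use frequency normalisation (default `TRUE`).
#' @param pseudocount Added to both counts (default 0).
#' @param min_count_r0 Minimum round-0 count for a peptide to receive a fold
#'   change (guards ratio blow-up on singletons); filtered peptides are
#'   dropped from the table. Default 1 (no filtering beyond presence).
#' @return An `enrichment_tbl` tibble with `peptide`, `count_r0`, `count_r3`,
#'   `freq_r0`, `freq_r3`, `fold_change`; attributes `novel` and `lost` hold
#'   the side lists, `normalize`/`pseudocount` record the options.
#' @export
fold_change_table <- function(counts_r0, counts_r3, normalize = TRUE,
                              pseudocount = 0, min_count_r0 = 1) {
  if (nrow(counts_r0) == 0 || sum(counts_r0$n) == 0) {
    abort("Round-0 pool is empty; fold changes are undefined.")
  }
  n0 <- sum(counts_r0$n)
  n3 <- sum(counts_r3$n)
  merged <- dplyr::full_join(
    rename(counts_r0, count_r0 = "n"),
    rename(counts_r3, count_r3 = "n"),
    by = "peptide"
  ) |>
    mutate(
      count_r0 = dplyr::coalesce(.data$count_r0, 0L),
      count_r3 = dplyr::coalesce(.data$count_r3, 0L),
      freq_r0 = .data$count_r0 / n0,
      freq_r3 = .data$count_r3 / n3
    ) |>
    arrange(.data$peptide)

  # with no pseudocount, round-0 absentees have no finite ratio: side-list them
  if (pseudocount == 0) {
    novel <- merged |>
      filter(.data$count_r0 == 0) |>
      select("peptide", "count_r0", "count_r3")
    tab <- merged |> filter(.data$count_r0 > 0)
  } else {
    novel <- merged[0, c("peptide", "count_r0", "count_r3")]
    tab <- merged
  }
  if (min_count_r0 > 1) {
    tab <- tab |> filter(.data$count_r0 >= min_count_r0)
  }

  fc <- if (normalize) {
    ((tab$count_r3 + pseudocount) / n3) / ((tab$count_r0 + pseudocount) / n0)
  } else {
    (tab$count_r3 + pseudocount) / (tab$count_r0 + pseudocount)
  }
  tab <- tab |> mutate(fold_change = fc)
  lost <- tab |>
    filter(.data$fold_change == 0) |>
    select("peptide", "count_r0", "count_r3")
  structure(
    tab,
    novel = novel, lost = lost,
    normalize = normalize, pseudocount = pseudocount,
    min_count_r0 = min_count_r0,
    class = c("enrichment_tbl", class(tibble()))
  )
}

#' Novel / lost side-lists of an enrichment table
#'
#' @param x An `enrichment_tbl`.
#' @return A tibble of peptides absent from round 0 (`novel_peptides()`) or
#'   depleted to zero in round 3 (`lost_peptides()`).
#' @export
novel_peptides <- function(x) attr(x, "novel")

#' @rdname novel_peptides
#' @export
lost_peptides <- function(x) attr(x, "lost")

STRATA_UP <- c("mild", "moderate", "high")
STRATA_DOWN <- c("mild_counter", "moderate_counter", "high_counter")

#' Stratify fold changes into selected / counter-selected bands
#'
#' Default thresholds follow the usual three-band convention: mildly
#' (fold change >= 4 or <= 0.25), moderately (>= 7 or <= 0.143) and highly
#' (>= 10 or <= 0.1) selected. In `exclusive` mode each record gets exactly
#' one band (`[4,7)`, `[7,10)`, `[10,Inf)` and mirrored counter-bands;
#' everything in `(0.25, 4)` is `neutral`). In `cumulative` mode a record
#' belongs to every stratum whose threshold it passes (a 22-fold enriched
#' peptide is mild, moderate and high at once); the per-stratum sets are
#' attached as the `strata_sets` attribute and returned by [strata_sets()].
#'
#' @param records An `enrichment_tbl` (or any tibble with `peptide` and
#'   `fold_change`).
#' @param thresholds_up Increasing positive thresholds for selection.
#' @param thresholds_down Decreasing thresholds for counter-selection.
#' @param mode `"exclusive"` (default) or `"cumulative"`.
#' @return The input with a `stratum` column (exclusive band) and a
#'   `strata_sets` attribute (named list of peptide vectors for the requested
#'   mode).
#' @export
stratify <- function(records, thresholds_up = c(4, 7, 10),
                     thresholds_down = c(0.25, 0.143, 0.1),
                     mode = c("exclusive", "cumulative")) {
  mode <- match.arg(mode)
  if (is.unsorted(thresholds_up, strictly = TRUE) ||
    is.unsorted(rev(thresholds_down), strictly = TRUE)) {
    abort("thresholds_up must be strictly increasing and thresholds_down strictly decreasing.")
  }
  fc <- records$fold_change
  stratum <- rep("neutral", nrow(records))
  stratum[fc >= thresholds_up[1]] <- STRATA_UP[1]
  stratum[fc >= thresholds_up[2]] <- STRATA_UP[2]
  stratum[fc >= thresholds_up[3]] <- STRATA_UP[3]
  stratum[fc <= thresholds_down[1]] <- STRATA_DOWN[1]
  stratum[fc <= thresholds_down[2]] <- STRATA_DOWN[2]
  stratum[fc <= thresholds_down[3]] <- STRATA_DOWN[3]
  out <- records |> mutate(stratum = stratum)

  sets <- if (mode == "exclusive") {
    split(records$peptide, factor(stratum, levels = c(STRATA_UP, "neutral", STRATA_DOWN)))
  } else {
    c(
      setNames(
        lapply(thresholds_up, function(t) records$peptide[fc >= t]),
        STRATA_UP
      ),
      list(neutral = records$peptide[fc > thresholds_down[1] & fc < thresholds_up[1]]),
      setNames(
        lapply(thresholds_down, function(t) records$peptide[fc <= t]),
        STRATA_DOWN
      )
    )
  }
  attr(out, "strata_sets") <- sets
  attr(out, "strata_mode") <- mode
  class(out) <- unique(c("enrichment_tbl", class(out)))
  out
}

#' Per-stratum peptide sets attached by [stratify()]
#'
#' @param x A stratified `enrichment_tbl`.
#' @return Named list of peptide character vectors.
#' @export
strata_sets <- function(x) attr(x, "strata_sets")

#' Ordered fold-change series
#'
#' Fold changes sorted in non-increasing order with ranks; ties are broken by
#' lexicographic peptide order so output is deterministic. This is the series
#' conventionally plotted sequentially on a log scale.
#'
#' @param records Tibble with `peptide` and defined `fold_change`.
#' @return A tibble with `rank`, `peptide`, `fold_change`.
#' @export
ordered_series <- function(records) {
  defined <- records |> filter(!is.na(.data$fold_change))
  defined |>
    arrange(desc(.data$fold_change), .data$peptide) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "peptide", "fold_change")
}

#' @exportS3Method generics::tidy
tidy.enrichment_tbl <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an enrichment table
#'
#' @param x An `enrichment_tbl`.
#' @param ... Unused.
#' @return A tibble with peptide counts, median fold change, numbers selected
#'   (`FC >= 4`) and counter-selected (`FC <= 0.25`), and novel/lost sizes.
#' @exportS3Method generics::glance
glance.enrichment_tbl <- function(x, ...) {
  tibble(
    n_peptides = nrow(x),
    median_fc = stats::median(x$fold_change),
    n_selected = sum(x$fold_change >= 4),
    n_counter_selected = sum(x$fold_change <= 0.25),
    n_novel = nrow(attr(x, "novel") %||% tibble()),
    n_lost = nrow(attr(x, "lost") %||% tibble())
  )
}

#' Plot an ordered fold-change series
#'
#' Fold change against rank on a log10 y-scale, the conventional display of
#' a panning enrichment series.
#'
#' @param object An `enrichment_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_tbl <- function(object, ...) {
  series <- ordered_series(object)
  series <- series[series$fold_change > 0, ]
  ggplot2::ggplot(series, ggplot2::aes(x = .data$rank, y = .data$fold_change)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Peptide rank", y = "Fold change (round 3 / round 0)",
      title = "Ordered HCDR3 fold-change series"
    ) +
    ggplot2::theme_minimal()
}
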