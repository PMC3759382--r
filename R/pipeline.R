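# End-to-end orchestration: simulate (optional) -> quality filter ->
# classify/extract -> count -> enrichment -> diversity, with TSV outputs and
# a run report. Stages are plain functions over tibbles; this file only wires
# them together and writes files.

#' Simulate a complete four-pool panning experiment
#'
#' Builds one unselected (round 0) library per V-gene context with the two
#' dominant peptides at high mass, applies per-peptide selection for `rounds`
#' rounds under a context-specific fitness landscape, and emits barcoded
#' paired-end reads for all four pools. The two dominant clones are selected
#' in opposite directions in the two contexts, mirroring the behaviour of
#' dominant clones under antigen selection.
#'
#' @param scheme An [hcdr3_scheme()].
#' @param barcodes A [barcode_table()] with pools `<ctx>_r0` / `<ctx>_r3` for
#'   two contexts.
#' @param n_variants Background variants per library.
#' @param dominant_peptides Two peptides planted at high initial frequency.
#' @param dominant_mass Their combined initial mass (default 0.967).
#' @param rounds Selection rounds (default 3).
#' @param depth Read pairs per pool.
#' @param error_rate Per-base substitution rate.
#' @param fitness_sdlog Log-normal sd of background peptide fitness.
#' @param dominant_fitness Selection weight of the favoured dominant peptide
#'   in each context (the other dominant gets its reciprocal).
#' @param seed Integer seed; all sub-seeds derive from it.
#' @return A list with `reads` (one tibble, all pools interleaved
#'   deterministically), `truth` (tibble of per-pool ground-truth
#'   compositions), `landscapes` (per context) and `pools` (the
#'   `pool_composition` objects).
#' @export
simulate_experiment <- function(scheme = hcdr3_scheme(),
                                barcodes = default_barcodes(),
                                n_variants = 2000,
                                dominant_peptides = c("YLLSPLLLA", "VQQVNNALA"),
                                dominant_mass = 0.967,
                                rounds = 3,
                                depth = 25000,
                                error_rate = 0.001,
                                fitness_sdlog = 0.5,
                                dominant_fitness = 3,
                                seed = 1) {
  seed <- as.integer(seed)
  ids <- barcodes$pool_id
  ctx <- unique(sub("_r[03]$", "", ids))
  if (length(ctx) != 2 || !all(c(paste0(ctx, "_r0"), paste0(ctx, "_r3")) %in% ids)) {
    abort("simulate_experiment expects pools '<ctx>_r0' and '<ctx>_r3' for two contexts.")
  }
  pools <- list()
  landscapes <- list()
  reads <- list()
  truth <- list()
  for (i in seq_along(ctx)) {
    cx <- ctx[i]
    p0 <- make_initial_pool(
      scheme,
      n_variants = n_variants,
      dominant_peptides = dominant_peptides,
      dominant_mass = dominant_mass,
      pool_id = paste0(cx, "_r0"),
      seed = seed + 101L * i
    )
    # context-specific landscape: one dominant favoured, the other depleted,
    # background drawn log-normally around neutrality
    bg_pep <- setdiff(unique(p0$peptide), dominant_peptides)
    bg_fit <- with_seed_if(
      seed + 211L * i,
      exp(stats::rnorm(length(bg_pep), 0, fitness_sdlog))
    )
    fav <- dominant_peptides[((i - 1) %% 2) + 1]
    dis <- setdiff(dominant_peptides, fav)
    ls <- fitness_landscape(
      c(fav, dis, bg_pep),
      c(dominant_fitness, 1 / dominant_fitness, bg_fit)
    )
    p3 <- apply_selection(p0, ls,
      rounds = rounds,
      pool_id = paste0(cx, "_r3"), seed = seed + 307L * i
    )
    for (p in list(p0, p3)) {
      pid <- attr(p, "pool_id")
      cfg <- emission_config(
        barcode = barcodes$barcode[barcodes$pool_id == pid],
        depth = depth, error_rate = error_rate,
        seed = seed + 1009L * match(pid, ids)
      )
      reads[[pid]] <- emit_reads(p, cfg, scheme)
      truth[[pid]] <- tidy(p)
      pools[[pid]] <- p
    }
    landscapes[[cx]] <- ls
  }
  list(
    reads = bind_rows(reads),
    truth = bind_rows(truth),
    landscapes = landscapes,
    pools = pools
  )
}

#' Pipeline run configuration
#'
#' Either paths to a multiplexed R1/R2 FASTQ pair, or a simulation
#' specification (a list of [simulate_experiment()] arguments) from which the
#' input is generated at run time.
#'
#' @param r1_path,r2_path Input FASTQ paths (ignored when `simulate` given).
#' @param simulate Optional named list of [simulate_experiment()] arguments.
#' @param barcodes A [barcode_table()].
#' @param scheme An [hcdr3_scheme()].
#' @param policy A [quality_policy()].
#' @param contrasts Named list of `c(round0_pool, round3_pool)` pairs for
#'   enrichment; default derives `<ctx>_r0` vs `<ctx>_r3` from the barcode
#'   table.
#' @param normalize,pseudocount,min_count_r0 Passed to [fold_change_table()].
#' @param strata_mode Passed to [stratify()].
#' @param kl_pseudocount,diversity_weighting Passed to the diversity stage.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in every output and used for simulation.
#' @return A `run_config` list.
#' @export
run_config <- function(r1_path = NULL, r2_path = NULL, simulate = NULL,
                       barcodes = default_barcodes(),
                       scheme = hcdr3_scheme(),
                       policy = quality_policy(),
                       contrasts = NULL,
                       normalize = TRUE, pseudocount = 0, min_count_r0 = 1,
                       strata_mode = "exclusive",
                       kl_pseudocount = 0.5,
                       diversity_weighting = "unique",
                       out_dir = "phanner_out", seed = 1) {
  if (is.null(simulate)) {
    if (is.null(r1_path) || is.null(r2_path)) {
      abort("Provide r1_path and r2_path, or a `simulate` specification.")
    }
    for (p in c(r1_path, r2_path)) {
      if (!file.exists(p)) abort(sprintf("Input file not found: '%s'", p))
    }
  }
  if (is.null(contrasts)) {
    ctx <- unique(sub("_r[03]$", "", barcodes$pool_id))
    contrasts <- setNames(
      lapply(ctx, function(cx) c(paste0(cx, "_r0"), paste0(cx, "_r3"))),
      ctx
    )
    contrasts <- contrasts[vapply(
      contrasts, function(x) all(x %in% barcodes$pool_id), logical(1)
    )]
  }
  structure(
    list(
      r1_path = r1_path, r2_path = r2_path, simulate = simulate,
      barcodes = barcodes, scheme = scheme, policy = policy,
      contrasts = contrasts,
      normalize = normalize, pseudocount = pseudocount,
      min_count_r0 = min_count_r0, strata_mode = strata_mode,
      kl_pseudocount = kl_pseudocount,
      diversity_weighting = diversity_weighting,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

write_tsv_meta <- function(df, path, meta) {
  writeLines(meta, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> filter -> classify -> count -> enrich ->
#' diversity, writing every stage's tables as TSV under `config$out_dir`
#' (each file headed by a comment recording the config hash and seed) and
#' returning a run report. Re-running with an identical configuration
#' reproduces every output byte for byte.
#'
#' @param config A [run_config()].
#' @return A `phanner_report` list: `classification` (per-pool read counts
#'   and percentages), `uniques` (per-pool unique-sequence summary),
#'   `enrichment` (per contrast: table, strata sizes, series), `diversity`
#'   (per pool entropy profiles; per contrast KL profiles), `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  meta <- sprintf(
    "# phanner run  seed=%d  config_hash=%s", config$seed,
    rlang::hash(cfg_for_hash)
  )

  # -- input stage ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$scheme <- sim_args$scheme %||% config$scheme
    sim_args$barcodes <- sim_args$barcodes %||% config$barcodes
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- do.call(simulate_experiment, sim_args)
    r1 <- file.path(out_dir, "simulated_R1.fastq")
    r2 <- file.path(out_dir, "simulated_R2.fastq")
    write_fastq_pair(sim$reads, r1, r2)
    write_tsv_meta(sim$truth, file.path(out_dir, "ground_truth.tsv"), meta)
    reads <- read_fastq_pairs(r1, r2)
  } else {
    reads <- read_fastq_pairs(config$r1_path, config$r2_path)
  }
  n_total <- nrow(reads)

  # -- filter + classify + extract + translate ------------------------------
  classified <- classify_reads(
    reads, config$barcodes, config$scheme, config$policy
  )
  classification <- classified |>
    mutate(pool = ifelse(is.na(.data$pool_id), "unclassified", .data$pool_id)) |>
    group_by(.data$pool) |>
    summarise(
      n_pairs = n(),
      n_valid = sum(.data$valid),
      n_rescued_r2 = sum(.data$valid & .data$source_mate == "R2"),
      .groups = "drop"
    ) |>
    mutate(pct_pairs = 100 * .data$n_pairs / n_total) |>
    arrange(.data$pool)
  write_tsv_meta(
    classification, file.path(out_dir, "classification.tsv"), meta
  )

  # -- count ---------------------------------------------------------------
  counts <- count_pools(classified)
  uniques <- glance(counts)
  write_tsv_meta(uniques, file.path(out_dir, "unique_summary.tsv"), meta)
  write_counts_tables(counts, out_dir)

  # -- enrichment ----------------------------------------------------------
  enrichment <- list()
  for (nm in names(config$contrasts)) {
    pair <- config$contrasts[[nm]]
    fc <- fold_change_table(
      peptide_counts(counts, pair[1]), peptide_counts(counts, pair[2]),
      normalize = config$normalize, pseudocount = config$pseudocount,
      min_count_r0 = config$min_count_r0
    )
    fc <- stratify(fc, mode = config$strata_mode)
    series <- ordered_series(fc)
    strata_n <- tibble(
      stratum = names(strata_sets(fc)),
      n_peptides = lengths(strata_sets(fc)),
      mode = attr(fc, "strata_mode")
    )
    write_tsv_meta(
      as_tibble(fc), file.path(out_dir, sprintf("enrichment_%s.tsv", nm)), meta
    )
    write_tsv_meta(
      series, file.path(out_dir, sprintf("fc_series_%s.tsv", nm)), meta
    )
    write_tsv_meta(
      novel_peptides(fc), file.path(out_dir, sprintf("novel_%s.tsv", nm)), meta
    )
    write_tsv_meta(
      lost_peptides(fc), file.path(out_dir, sprintf("lost_%s.tsv", nm)), meta
    )
    enrichment[[nm]] <- list(
      table = fc, series = series, strata = strata_n,
      glance = glance(fc)
    )
  }

  # -- diversity -----------------------------------------------------------
  diversity <- list(entropy = list(), kl = list())
  for (pool in unique(counts$pool_id)) {
    for (level in c("nt", "peptide")) {
      pfm <- pool_pfm(counts, pool, level, config$diversity_weighting)
      prof <- information_content(pfm)
      key <- paste(pool, level, sep = "_")
      diversity$entropy[[key]] <- prof
      write_tsv_meta(
        as_tibble(prof),
        file.path(out_dir, sprintf("entropy_%s.tsv", key)), meta
      )
    }
  }
  for (nm in names(config$contrasts)) {
    pair <- config$contrasts[[nm]]
    for (level in c("nt", "peptide")) {
      kl <- kl_profile(
        pool_pfm(counts, pair[2], level, config$diversity_weighting),
        pool_pfm(counts, pair[1], level, config$diversity_weighting),
        pseudocount = config$kl_pseudocount
      )
      key <- paste(nm, level, sep = "_")
      diversity$kl[[key]] <- kl
      write_tsv_meta(
        as_tibble(kl), file.path(out_dir, sprintf("kl_%s.tsv", key)), meta
      )
    }
  }

  report <- structure(
    list(
      n_total_pairs = n_total,
      classification = classification,
      uniques = uniques,
      counts = counts,
      enrichment = enrichment,
      diversity = diversity,
      seed = config$seed,
      config_hash = rlang::hash(cfg_for_hash),
      out_dir = out_dir
    ),
    class = "phanner_report"
  )
  report
}

#' @export
print.phanner_report <- function(x, ...) {
  cat("<phanner_report>  seed", x$seed, " hash", x$config_hash, "\n")
  cat("Read pairs:", x$n_total_pairs, "\n\nClassification:\n")
  print(as.data.frame(x$classification), row.names = FALSE)
  cat("\nUnique sequences:\n")
  print(as.data.frame(x$uniques), row.names = FALSE)
  for (nm in names(x$enrichment)) {
    cat("\nEnrichment [", nm, "]:\n", sep = "")
    print(as.data.frame(x$enrichment[[nm]]$glance), row.names = FALSE)
  }
  for (nm in names(x$diversity$kl)) {
    cat(sprintf(
      "Summed KL [%s]: %.4f bits\n", nm, sum(x$diversity$kl[[nm]]$kl)
    ))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.phanner_report <- function(x, ...) {
  tibble(
    n_total_pairs = x$n_total_pairs,
    n_pools = sum(x$classification$pool != "unclassified"),
    pct_classified = 100 * sum(
      x$classification$n_pairs[x$classification$pool != "unclassified"]
    ) / x$n_total_pairs,
    n_contrasts = length(x$enrichment)
  )
}
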