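# Synthetic-data generator: ground-truth library compositions, multinomial
# selection across panning rounds, and barcoded paired-end read emission.
# Every downstream stage of the pipeline can be checked exactly against the
# compositions produced here.

#' Sample random HCDR3 nucleotide sequences from a codon scheme
#'
#' Each of the 27 positions is drawn uniformly from the IUPAC expansion of its
#' template character, so e.g. an S position is G or C with probability 1/2.
#'
#' @param scheme An [hcdr3_scheme()].
#' @param n Number of sequences to draw.
#' @param seed Optional integer seed (draws are made in a local RNG scope).
#' @return Character vector of `n` 27-nt sequences.
#' @examples
#' sample_hcdr3(n = 3, seed = 1)
#' @export
sample_hcdr3 <- function(scheme = hcdr3_scheme(), n = 1, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  draw <- function() {
    allowed <- scheme_allowed_bases(scheme)
    m <- vapply(allowed, function(bases) {
      if (length(bases) == 1) rep(bases, n) else sample(bases, n, replace = TRUE)
    }, character(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    apply(m, 1, paste0, collapse = "")
  }
  with_seed_if(seed, draw())
}

# Run expr under a fixed seed when seed is non-NULL, leaving the global RNG
# state untouched; otherwise use the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

new_pool_composition <- function(variants, pool_id) {
  total <- sum(variants$freq)
  if (abs(total - 1) > 1e-9) {
    abort("Pool frequencies must sum to 1.")
  }
  if (any(variants$freq <= 0)) {
    abort("Pool frequencies must be strictly positive.")
  }
  structure(
    as_tibble(variants[c("variant", "peptide", "freq")]),
    pool_id = pool_id,
    class = c("pool_composition", class(tibble()))
  )
}

#' Build a ground-truth initial (round-0) pool composition
#'
#' Emulates an unselected degenerate library: `n_variants` distinct random
#' 27-nt variants share `1 - dominant_mass` uniformly, while each dominant
#' peptide is represented by several distinct synonymous nucleotide encodings
#' (as observed for dominant clones in real libraries, which are carried by
#' many codon variants rather than one expanded clone); all dominant encodings
#' together carry `dominant_mass`, split equally.
#'
#' @param scheme An [hcdr3_scheme()].
#' @param n_variants Number of background variants.
#' @param dominant_peptides Character vector of 9-residue peptides to plant at
#'   high frequency (may be empty).
#' @param dominant_mass Total frequency mass of all dominant encodings
#'   combined, in `[0, 1)`.
#' @param encodings_per_dominant Number of synonymous nucleotide encodings
#'   drawn per dominant peptide.
#' @param pool_id Pool label.
#' @param seed Optional integer seed.
#' @return A `pool_composition`: a tibble with columns `variant` (27 nt),
#'   `peptide` (9 aa) and `freq`, with a `pool_id` attribute.
#' @examples
#' make_initial_pool(n_variants = 5, seed = 1)
#' @export
make_initial_pool <- function(scheme = hcdr3_scheme(),
                              n_variants = 1000,
                              dominant_peptides = character(),
                              dominant_mass = 0,
                              encodings_per_dominant = 20,
                              pool_id = "pool",
                              seed = NULL) {
  if (dominant_mass < 0 || dominant_mass >= 1) {
    abort("dominant_mass must lie in [0, 1).")
  }
  if (dominant_mass > 0 && length(dominant_peptides) == 0) {
    abort("dominant_mass > 0 requires at least one dominant peptide.")
  }
  if (n_variants < 1) abort("n_variants must be >= 1.")
  with_seed_if(seed, {
    dom <- NULL
    if (dominant_mass > 0) {
      enc <- purrr::map(dominant_peptides, function(pep) {
        sample_dominant_encodings(scheme, pep, encodings_per_dominant)
      })
      enc_nt <- unlist(enc)
      dom <- tibble(
        variant = enc_nt,
        peptide = rep(dominant_peptides, vapply(enc, length, integer(1))),
        freq = dominant_mass / length(enc_nt)
      )
    }
    # draw distinct background variants, avoiding collisions with dominants
    taken <- if (is.null(dom)) character(0) else dom$variant
    bg <- character(0)
    while (length(bg) < n_variants) {
      cand <- sample_hcdr3(scheme, n = n_variants - length(bg) + 10L)
      cand <- setdiff(unique(cand), c(taken, bg))
      bg <- c(bg, head(cand, n_variants - length(bg)))
    }
    bg_tbl <- tibble(
      variant = bg,
      peptide = translate_hcdr3(bg),
      freq = (1 - dominant_mass) / n_variants
    )
    new_pool_composition(bind_rows(dom, bg_tbl), pool_id = pool_id)
  })
}

# Draw n distinct synonymous 27-nt encodings of a 9-residue peptide under the
# scheme's codon constraints; errors if a residue is not encodable at its
# position.
sample_dominant_encodings <- function(scheme, peptide, n) {
  res <- strsplit(peptide, "")[[1]]
  if (length(res) != 9) abort("Dominant peptides must be 9 residues long.")
  choices <- purrr::map2(scheme$codon_templates, seq_along(res), function(tmpl, i) {
    cods <- codons_for_residue(tmpl, res[i])
    if (length(cods) == 0) {
      abort(sprintf(
        "Residue '%s' at HCDR3 position %d is not encodable by template %s.",
        res[i], i, tmpl
      ))
    }
    cods
  })
  n_possible <- prod(vapply(choices, length, numeric(1)))
  n <- min(n, n_possible)
  enc <- character(0)
  while (length(enc) < n) {
    draw <- vapply(choices, function(c) sample(c, 1), character(1))
    enc <- unique(c(enc, paste0(draw, collapse = "")))
  }
  enc
}

#' Define a fitness landscape over HCDR3 peptides
#'
#' Selection weights multiply a variant's frequency each panning round; a
#' peptide absent from the table gets `default_fitness`. Weights are relative:
#' only ratios matter.
#'
#' @param peptides Character vector of 9-residue peptides.
#' @param fitness Positive weights, recycled against `peptides`.
#' @param default_fitness Positive weight for unlisted peptides.
#' @return A `fitness_landscape` tibble with attribute `default_fitness`.
#' @export
fitness_landscape <- function(peptides = character(), fitness = numeric(),
                              default_fitness = 1) {
  if (length(fitness) == 1 && length(peptides) > 1) {
    fitness <- rep(fitness, length(peptides))
  }
  if (any(fitness <= 0) || default_fitness <= 0) {
    abort("Fitness weights must be strictly positive.")
  }
  structure(
    tibble(peptide = peptides, fitness = fitness),
    default_fitness = default_fitness,
    class = c("fitness_landscape", class(tibble()))
  )
}

landscape_weights <- function(landscape, peptides) {
  w <- landscape$fitness[match(peptides, landscape$peptide)]
  w[is.na(w)] <- attr(landscape, "default_fitness")
  w
}

#' Apply rounds of selection to a pool composition
#'
#' One round multiplies each variant's frequency by its peptide's fitness and
#' renormalises. With a `bottleneck`, frequencies are then replaced by the
#' proportions of a multinomial resample of that many phage (variants drawn
#' zero times are lost), emulating the finite phage population carried between
#' panning rounds.
#'
#' @param pool A `pool_composition`.
#' @param landscape A [fitness_landscape()].
#' @param rounds Number of selection rounds (>= 0).
#' @param bottleneck Integer number of phage sampled between rounds, or `NULL`
#'   for deterministic (infinite-population) selection.
#' @param pool_id Label for the output pool; default appends `_r<rounds>`.
#' @param seed Optional integer seed (used only when `bottleneck` is set).
#' @return A `pool_composition`.
#' @export
apply_selection <- function(pool, landscape, rounds = 3, bottleneck = NULL,
                            pool_id = NULL, seed = NULL) {
  stopifnot(rounds >= 0)
  if (!is.null(bottleneck) && bottleneck < 1) {
    abort("bottleneck must be >= 1 (or NULL for no bottleneck).")
  }
  out_id <- pool_id %||% paste0(attr(pool, "pool_id"), "_r", rounds)
  df <- tibble(variant = pool$variant, peptide = pool$peptide, freq = pool$freq)
  with_seed_if(seed, {
    for (r in seq_len(rounds)) {
      w <- landscape_weights(landscape, df$peptide)
      f <- df$freq * w
      df$freq <- f / sum(f)
      if (!is.null(bottleneck)) {
        draws <- as.vector(rmultinom(1, size = bottleneck, prob = df$freq))
        keep <- draws > 0
        df <- df[keep, ]
        df$freq <- draws[keep] / bottleneck
      }
    }
    new_pool_composition(df, pool_id = out_id)
  })
}

#' Read-emission settings for one pool
#'
#' @param barcode Pool barcode (>= 4 nt), the amplicon's leading sequence.
#' @param depth Number of read pairs to emit.
#' @param error_rate Per-base substitution probability, in `[0, 0.5)`.
#' @param quality_high,quality_low Phred scores written for correct and
#'   erroneous bases respectively (two-level model, so extraction failures are
#'   attributable to injected errors).
#' @param seed Optional integer seed.
#' @return An `emission_config` list.
#' @export
emission_config <- function(barcode, depth, error_rate = 0.001,
                            quality_high = 37, quality_low = 2, seed = NULL) {
  if (nchar(barcode) < 4 || grepl("[^ACGT]", barcode)) {
    abort("barcode must be an A/C/G/T string of length >= 4.")
  }
  if (depth < 1) abort("depth must be >= 1.")
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must lie in [0, 0.5).")
  }
  structure(
    list(
      barcode = barcode, depth = as.integer(depth), error_rate = error_rate,
      quality_high = as.integer(quality_high),
      quality_low = as.integer(quality_low), seed = seed
    ),
    class = "emission_config"
  )
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

# Substitute bases at random positions of equal-length sequences, raw-byte
# implementation so full-depth emission stays fast. Returns list(seq, qual).
inject_errors <- function(seqs, error_rate, q_high, q_low) {
  width <- nchar(seqs[1])
  n <- length(seqs)
  total <- n * width
  raw_seq <- charToRaw(paste(seqs, collapse = ""))
  qual_hi <- as.raw(q_high + 33L)
  raw_qual <- rep(qual_hi, total)
  if (error_rate > 0) {
    n_err <- rbinom(1, total, error_rate)
    if (n_err > 0) {
      pos <- sample.int(total, n_err)
      cur <- rawToChar(raw_seq[pos], multiple = TRUE)
      # substitute with one of the three other bases, uniformly
      sub <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
        character(1),
        USE.NAMES = FALSE
      )
      raw_seq[pos] <- charToRaw(paste(sub, collapse = ""))
      raw_qual[pos] <- as.raw(q_low + 33L)
    }
  }
  starts <- seq(1L, total, by = width)
  big_seq <- rawToChar(raw_seq)
  big_qual <- rawToChar(raw_qual)
  list(
    seq = substring(big_seq, starts, starts + width - 1L),
    qual = substring(big_qual, starts, starts + width - 1L)
  )
}

#' Emit barcoded paired-end reads from a pool composition
#'
#' For each read pair a variant is drawn by frequency; the amplicon is
#' `barcode + flank_upstream + variant + flank_downstream` (77 bp with the
#' default scheme and 6-nt barcodes). R1 is the amplicon with independent
#' per-base substitution errors; R2 is the reverse complement of the amplicon
#' with its own independent errors. Quality strings carry `quality_high`
#' except at injected errors (`quality_low`). Read IDs pair the mates and
#' record the ground-truth variant for auditing.
#'
#' @param pool A `pool_composition`.
#' @param config An [emission_config()].
#' @param scheme The [hcdr3_scheme()] supplying the flanks.
#' @return A tibble with columns `read_id`, `variant` (ground truth),
#'   `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @export
emit_reads <- function(pool, config, scheme = hcdr3_scheme()) {
  stopifnot(inherits(config, "emission_config"))
  pool_id <- attr(pool, "pool_id")
  with_seed_if(config$seed, {
    idx <- sample.int(nrow(pool), config$depth, replace = TRUE, prob = pool$freq)
    variant <- pool$variant[idx]
    amplicon <- paste0(
      config$barcode, scheme$flank_upstream, variant, scheme$flank_downstream
    )
    r1 <- inject_errors(amplicon, config$error_rate,
      config$quality_high, config$quality_low)
    r2 <- inject_errors(reverse_complement(amplicon), config$error_rate,
      config$quality_high, config$quality_low)
    tibble(
      read_id = sprintf("%s:%07d v=%s", pool_id, seq_along(variant), variant),
      variant = variant,
      r1_seq = r1$seq, r1_qual = r1$qual,
      r2_seq = r2$seq, r2_qual = r2$qual
    )
  })
}

#' Tidy a pool composition into its ground-truth table
#'
#' @param x A `pool_composition`.
#' @param ... Unused.
#' @return A tibble with `pool_id`, `variant`, `peptide`, `freq`.
#' @exportS3Method generics::tidy
tidy.pool_composition <- function(x, ...) {
  tibble(
    pool_id = attr(x, "pool_id"),
    variant = x$variant, peptide = x$peptide, freq = x$freq
  )
}

#' @exportS3Method generics::glance
glance.pool_composition <- function(x, ...) {
  tibble(
    pool_id = attr(x, "pool_id"),
    n_variants = nrow(x),
    n_peptides = dplyr::n_distinct(x$peptide),
    max_freq = max(x$freq)
  )
}
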