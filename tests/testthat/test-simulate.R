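test_that("sample_hcdr3 respects positional templates", {
  sc <- hcdr3_scheme()
  seqs <- sample_hcdr3(sc, n = 200, seed = 5)
  expect_true(all(nchar(seqs) == 27))
  # third base of codon 1 is S = G/C
  expect_true(all(substr(seqs, 3, 3) %in% c("G", "C")))
  # codon 7 (positions 19-21) matches K, B, G
  expect_true(all(substr(seqs, 19, 19) %in% c("G", "T")))
  expect_true(all(substr(seqs, 20, 20) %in% c("C", "G", "T")))
  expect_true(all(substr(seqs, 21, 21) == "G"))
  # degenerate-to-single-outcome case
  mono <- hcdr3_scheme(codon_templates = rep("AAA", 9))
  expect_equal(sample_hcdr3(mono, n = 2, seed = 1), rep(strrep("A", 27), 2))
})

test_that("sample_hcdr3 per-position base frequencies match theory within 3 SE", {
  sc <- hcdr3_scheme()
  n <- 10000
  seqs <- sample_hcdr3(sc, n = n, seed = 99)
  theo <- unclass(theoretical_pfm(sc))
  chars <- matrix(unlist(strsplit(seqs, "")), ncol = 27, byrow = TRUE)
  for (pos in seq_len(27)) {
    obs <- table(factor(chars[, pos], levels = c("A", "C", "G", "T"))) / n
    p <- theo[pos, ]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(as.numeric(obs) - p) <= 3 * se + 1e-12),
      label = sprintf("position %d within 3 SE", pos)
    )
  }
})

test_that("make_initial_pool constructs the stated compositions", {
  # uniform case
  p <- make_initial_pool(n_variants = 100, seed = 1)
  expect_equal(nrow(p), 100)
  expect_equal(p$freq, rep(0.01, 100))
  expect_equal(sum(p$freq), 1, tolerance = 1e-12)
  # single variant
  p1 <- make_initial_pool(n_variants = 1, seed = 2)
  expect_equal(p1$freq, 1)
  # dominant mass: encodings jointly carry 0.967
  pd <- make_initial_pool(
    n_variants = 50,
    dominant_peptides = c("YLLSPLLLA", "VQQVNNALA"),
    dominant_mass = 0.967, seed = 3
  )
  dom_mass <- sum(pd$freq[pd$peptide %in% c("YLLSPLLLA", "VQQVNNALA")])
  expect_equal(dom_mass, 0.967, tolerance = 1e-9)
  # several synonymous encodings per dominant peptide
  expect_gt(sum(pd$peptide == "YLLSPLLLA"), 1)
  expect_true(all(translate_hcdr3(pd$variant) == pd$peptide))
  expect_false(anyDuplicated(pd$variant) > 0)
})

test_that("unencodable dominant peptides fail with a residue-naming error", {
  # proline is not encodable by GMT (Asp/Ala only) at position 9
  expect_error(
    make_initial_pool(
      n_variants = 5, dominant_peptides = "YLLSPLLLP",
      dominant_mass = 0.5, seed = 1
    ),
    "position 9"
  )
})

test_that("apply_selection follows the one-round update and its closed form", {
  sc <- hcdr3_scheme(codon_templates = rep("AAA", 9)) # fixed peptide KKKKKKKKK
  # hand-built two-variant pool: use distinct variants with distinct peptides
  pool <- make_initial_pool(n_variants = 2, seed = 4)
  ls <- fitness_landscape(pool$peptide, c(2, 1))
  r1 <- apply_selection(pool, ls, rounds = 1)
  expect_equal(sort(r1$freq, decreasing = TRUE), c(2 / 3, 1 / 3), tolerance = 1e-12)
  r3 <- apply_selection(pool, ls, rounds = 3)
  expect_equal(sort(r3$freq, decreasing = TRUE), c(8 / 9, 1 / 9), tolerance = 1e-12)
  # neutral selection leaves frequencies unchanged
  neutral <- fitness_landscape(default_fitness = 1)
  r <- apply_selection(pool, neutral, rounds = 5)
  expect_equal(r$freq, pool$freq, tolerance = 1e-12)
})

test_that("multi-round selection equals closed form f * w^r on random pools", {
  for (seed in 1:5) {
    pool <- make_initial_pool(n_variants = 30, seed = seed)
    w <- withr::with_seed(seed * 7L, exp(stats::rnorm(30, 0, 0.6)))
    ls <- fitness_landscape(pool$peptide, w)
    # the landscape keys on peptides; duplicated peptides would get the first
    # weight, so compute the oracle with the same peptide-keyed lookup
    wv <- w[match(pool$peptide, pool$peptide)]
    for (r in c(1, 2, 4)) {
      got <- apply_selection(pool, ls, rounds = r)
      expected <- pool$freq * wv^r
      expected <- expected / sum(expected)
      expect_equal(got$freq, expected, tolerance = 1e-10)
      expect_equal(sum(got$freq), 1, tolerance = 1e-9)
    }
  }
})

test_that("bottleneck resampling keeps frequencies normalized and drops zeros", {
  pool <- make_initial_pool(n_variants = 200, seed = 8)
  ls <- fitness_landscape(default_fitness = 1)
  b <- apply_selection(pool, ls, rounds = 2, bottleneck = 100, seed = 9)
  expect_lte(nrow(b), 100)
  expect_equal(sum(b$freq), 1, tolerance = 1e-12)
  expect_true(all(b$freq > 0))
  expect_error(apply_selection(pool, ls, rounds = 1, bottleneck = 0), "bottleneck")
})

test_that("noiseless emission is exact and reproducible", {
  pool <- make_initial_pool(n_variants = 20, pool_id = "vh4_r0", seed = 10)
  cfg <- emission_config("ACGTAC", depth = 1000, error_rate = 0, seed = 11)
  reads <- emit_reads(pool, cfg)
  sc <- hcdr3_scheme()
  expect_true(all(startsWith(reads$r1_seq, "ACGTAC")))
  expect_true(all(nchar(reads$r1_seq) == 77))
  # R2 is the exact reverse complement of R1 when no errors are injected
  expect_equal(reads$r2_seq, reverse_complement(reads$r1_seq))
  # the embedded HCDR3 matches the scheme
  ins <- substr(reads$r1_seq, 6 + nchar(sc$flank_upstream) + 1,
    6 + nchar(sc$flank_upstream) + 27)
  expect_true(all(matches_scheme(ins, sc)))
  expect_equal(ins, reads$variant)
  # seeded determinism
  reads2 <- emit_reads(pool, cfg)
  expect_identical(reads, reads2)
})

test_that("emitted variant frequencies converge to pool frequencies (chi-square)", {
  pool <- make_initial_pool(n_variants = 40, pool_id = "p", seed = 12)
  cfg <- emission_config("ACGTAC", depth = 1e5, error_rate = 0, seed = 13)
  reads <- emit_reads(pool, cfg)
  obs <- table(factor(reads$variant, levels = pool$variant))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pool$freq))
  expect_gt(gof$p.value, 0.001)
})

test_that("error injection marks erroneous bases with the low quality score", {
  pool <- make_initial_pool(n_variants = 10, pool_id = "p", seed = 14)
  cfg <- emission_config("ACGTAC", depth = 500, error_rate = 0.02,
    quality_high = 37, quality_low = 2, seed = 15)
  reads <- emit_reads(pool, cfg)
  truth <- paste0("ACGTAC", hcdr3_scheme()$flank_upstream, reads$variant,
    hcdr3_scheme()$flank_downstream)
  for (i in c(1, 50, 200)) {
    mism <- which(strsplit(reads$r1_seq[i], "")[[1]] != strsplit(truth[i], "")[[1]])
    quals <- utf8ToInt(reads$r1_qual[i]) - 33L
    expect_true(all(quals[mism] == 2))
    expect_true(all(quals[-mism] == 37) || length(mism) == 0)
  }
  # overall error rate is near nominal
  n_mm <- sum(vapply(seq_len(nrow(reads)), function(i) {
    sum(strsplit(reads$r1_seq[i], "")[[1]] != strsplit(truth[i], "")[[1]])
  }, numeric(1)))
  expect_equal(n_mm / (500 * 77), 0.02, tolerance = 0.25)
})
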