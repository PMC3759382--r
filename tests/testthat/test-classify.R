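test_that("barcode table enforces unambiguous spacing", {
  expect_error(barcode_table(c(a = "AAAA", b = "AAAT"), max_mismatch = 1), "Hamming")
  expect_silent(barcode_table(c(a = "AAAA", b = "TTTT"), max_mismatch = 1))
  expect_error(barcode_table(c("ACGT", "TTTT")), "named")
  expect_error(barcode_table(c(a = "ACGT", b = "ACGT")), "unique")
})

test_that("assign_pool handles exact matches, mismatch budgets and ties", {
  tb <- default_barcodes() # max_mismatch = 0
  sc <- hcdr3_scheme()
  read <- paste0("ACGTAC", sc$flank_upstream, strrep("A", 27), sc$flank_downstream)
  expect_equal(assign_pool(read, tb), "vh4_r0")
  # one substitution with max_mismatch = 0 -> unclassified
  read1 <- sub("^ACGTAC", "TCGTAC", read)
  expect_true(is.na(assign_pool(read1, tb)))
  # with max_mismatch = 1 it is recovered
  tb1 <- default_barcodes(max_mismatch = 1)
  expect_equal(assign_pool(read1, tb1), "vh4_r0")
  # equidistant tie at the minimum distance -> unclassified, even within the
  # mismatch budget (table built directly to place barcodes 2 apart)
  tie_tb <- structure(
    tibble::tibble(pool_id = c("a", "b"), barcode = c("AAAA", "AATT")),
    max_mismatch = 1L,
    class = c("barcode_table", class(tibble::tibble()))
  )
  expect_true(is.na(assign_pool(paste0("AAAT", strrep("G", 20)), tie_tb)))
  # an unambiguous distance-1 read still assigns
  expect_equal(assign_pool(paste0("CAAA", strrep("G", 20)), tie_tb), "a")
})

test_that("extract_hcdr3 requires a perfect single in-order anchor pair", {
  sc <- hcdr3_scheme()
  insert <- sample_hcdr3(sc, seed = 21)
  read <- paste0("ACGTAC", sc$flank_upstream, insert, sc$flank_downstream)
  res <- extract_hcdr3(read, scheme = sc)
  expect_equal(res$status, "ok")
  expect_equal(res$hcdr3_nt, insert)
  # 26-nt insert -> bad_length
  short <- paste0("ACGTAC", sc$flank_upstream, substr(insert, 1, 26), sc$flank_downstream)
  expect_equal(extract_hcdr3(short, scheme = sc)$status, "bad_length")
  # one substitution in the upstream anchor -> no_anchor (perfect match only)
  mut <- read
  substr(mut, 8, 8) <- if (substr(mut, 8, 8) == "A") "C" else "A"
  expect_equal(extract_hcdr3(mut, scheme = sc)$status, "no_anchor")
  # duplicated downstream anchor -> ambiguous -> no_anchor
  dup <- paste0(read, sc$flank_downstream)
  expect_equal(extract_hcdr3(dup, scheme = sc)$status, "no_anchor")
  # missing both anchors
  expect_equal(extract_hcdr3(strrep("A", 77), scheme = sc)$status, "no_anchor")
})

test_that("hcdr3-only policies reject low-quality windows as low_quality", {
  sc <- hcdr3_scheme()
  insert <- sample_hcdr3(sc, seed = 22)
  read <- paste0("ACGTAC", sc$flank_upstream, insert, sc$flank_downstream)
  qual_good <- strrep(intToUtf8(37 + 33), nchar(read))
  pol <- quality_policy(min_mean_phred = 20, min_base_phred = 10, region = "hcdr3-only")
  expect_equal(extract_hcdr3(read, qual_good, sc, pol)$status, "ok")
  # poison one base inside the window
  qual_bad <- qual_good
  substr(qual_bad, 6 + nchar(sc$flank_upstream) + 5, 6 + nchar(sc$flank_upstream) + 5) <-
    intToUtf8(2 + 33)
  expect_equal(extract_hcdr3(read, qual_bad, sc, pol)$status, "low_quality")
})

test_that("resolve_pairs prefers R1 and rescues from R2 only on R1 failure", {
  ok1 <- tibble::tibble(status = "ok", hcdr3_nt = strrep("A", 27))
  ok2 <- tibble::tibble(status = "ok", hcdr3_nt = strrep("C", 27))
  fail <- tibble::tibble(status = "no_anchor", hcdr3_nt = NA_character_)
  both_ok <- resolve_pairs(ok1, ok2)
  expect_equal(both_ok$hcdr3_nt, strrep("A", 27))
  expect_equal(both_ok$source_mate, "R1")
  rescued <- resolve_pairs(fail, ok2)
  expect_equal(rescued$status, "ok")
  expect_equal(rescued$hcdr3_nt, strrep("C", 27))
  expect_equal(rescued$source_mate, "R2")
  dead <- resolve_pairs(fail, fail)
  expect_equal(dead$status, "no_anchor")
  expect_true(is.na(dead$source_mate))
})

test_that("amber-suppressed translation matches the genetic code", {
  expect_equal(translate_hcdr3(strrep("TAT", 9)), "YYYYYYYYY")
  expect_equal(translate_hcdr3(codon_at("TAG", 5)), "YYYYQYYYY")
  expect_true(is.na(translate_hcdr3(codon_at("TAA", 3))))
  expect_true(is.na(translate_hcdr3(codon_at("TGA", 9))))
  expect_true(is.na(translate_hcdr3(paste0("N", strrep("A", 26)))))
  expect_error(translate_hcdr3("ACGACG"), "27")
})

test_that("translation agrees with an independent Biostrings oracle on random codons", {
  sc <- hcdr3_scheme()
  seqs <- sample_hcdr3(sc, n = 300, seed = 23)
  expect_equal(translate_hcdr3(seqs), oracle_translate(seqs))
})

test_that("classification conserves reads and recovers noiseless ground truth", {
  sim <- simulate_experiment(n_variants = 40, depth = 1500, error_rate = 0, seed = 31)
  cl <- classify_reads(sim$reads)
  # conservation: classified + unclassified == total
  expect_equal(sum(!is.na(cl$pool_id)) + sum(is.na(cl$pool_id)), nrow(sim$reads))
  # noiseless: every read classified to its true pool with its planted HCDR3
  true_pool <- sub(":.*$", "", sim$reads$read_id)
  expect_equal(cl$pool_id, true_pool)
  expect_equal(cl$hcdr3_nt, sim$reads$variant)
  expect_true(all(cl$valid))
  expect_true(all(cl$source_mate == "R1"))
})

test_that("resolve_pairs never returns R2 when R1 succeeded (property)", {
  sim <- simulate_experiment(n_variants = 30, depth = 800, error_rate = 0.01, seed = 32)
  cl <- classify_reads(sim$reads)
  # recompute R1-only extraction to find which R1s succeeded
  pol <- quality_policy()
  r1_pass <- passes_quality(sim$reads$r1_seq, sim$reads$r1_qual, pol)
  r1_ext <- extract_hcdr3(sim$reads$r1_seq, sim$reads$r1_qual)
  r1_ok <- r1_pass & r1_ext$status == "ok"
  expect_true(all(cl$source_mate[r1_ok] == "R1"))
})
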