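test_that("PFMs are correct under both weightings", {
  p <- build_pfm(c("AAA", "AAC"), alphabet = "dna")
  expect_equal(unname(unclass(p)[3, "A"]), 0.5)
  expect_equal(unname(unclass(p)[3, "C"]), 0.5)
  pc <- build_pfm(c("AAA", "AAC"), counts = c(3, 1), alphabet = "dna",
    weighting = "counts")
  expect_equal(unname(unclass(pc)[3, "A"]), 0.75)
  expect_equal(unname(unclass(pc)[3, "C"]), 0.25)
  # unique weighting ignores counts and duplicates
  pu <- build_pfm(c("AAA", "AAA", "AAC"), counts = c(5, 5, 1),
    alphabet = "dna", weighting = "unique")
  expect_equal(unname(unclass(pu)[3, "A"]), 0.5)
  expect_equal(unname(rowSums(unclass(pu))), rep(1, 3))
  expect_error(build_pfm(character(0)), "zero")
  expect_error(build_pfm(c("AA", "AAA")), "same length")
  expect_error(build_pfm("AXA", alphabet = "dna"), "alphabet")
})

test_that("shannon entropy evaluates the defining sum", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0)), 1) # 0 log 0 = 0
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("entropy and KL match a brute-force oracle on random distributions", {
  brute_entropy <- function(p) {
    s <- 0
    for (x in p) if (x > 0) s <- s - x * log2(x)
    s
  }
  brute_kl <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
    s
  }
  withr::with_seed(61, {
    for (rep in 1:200) {
      k <- sample(c(2, 4, 20), 1)
      p <- runif(k)
      p <- p / sum(p)
      q <- runif(k) + 1e-6
      q <- q / sum(q)
      expect_equal(shannon_entropy(p), brute_entropy(p), tolerance = 1e-12)
      d <- kl_divergence(p, q)
      expect_equal(d, brute_kl(p, q), tolerance = 1e-12)
      expect_gte(d, 0) # Gibbs inequality
      expect_equal(kl_divergence(p, p), 0)
    }
  })
})

test_that("information content of the theoretical scheme matches enumeration", {
  prof <- information_content(theoretical_pfm())
  # oracle: IC = 2 - log2(#bases in the template's expansion), enumerated
  expected <- vapply(default_template_chars(), function(ch) {
    2 - log2(length(oracle_iupac[[ch]]))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(prof$ic, expected, tolerance = 1e-12)
  expect_equal(prof$entropy + prof$ic, rep(2, 27), tolerance = 1e-12)
})

test_that("IC spans 0 (uniform) to log2(k) (invariant)", {
  u <- build_pfm(c("A", "C", "G", "T"), alphabet = "dna")
  expect_equal(information_content(u)$ic, 0)
  inv <- build_pfm(c("A", "A"), alphabet = "dna")
  expect_equal(information_content(inv)$ic, 2)
  s_pos <- build_pfm(c("G", "C"), alphabet = "dna")
  expect_equal(information_content(s_pos)$ic, 1)
  # protein alphabet uses S_max = log2(20)
  pp <- build_pfm("YYYYYYYYY", alphabet = "protein")
  expect_equal(information_content(pp)$ic, rep(log2(20), 9))
})

test_that("kl_profile evaluates the positional divergence with smoothing rules", {
  p1 <- build_pfm(c("A", "A"), alphabet = "dna") # P = (1,0,0,0)
  q1 <- build_pfm(c("A", "C"), alphabet = "dna") # Q = (.5,.5,0,0)
  expect_equal(kl_profile(p1, q1, pseudocount = 0)$kl, 1)
  # P == Q -> 0 everywhere
  expect_equal(kl_profile(q1, q1, pseudocount = 0)$kl, 0)
  # hand-evaluated asymmetric case: P=(.75,.25), Q=(.25,.75) over {A,C}
  p2 <- build_pfm(c("A", "C"), counts = c(3, 1), alphabet = "dna",
    weighting = "counts")
  q2 <- build_pfm(c("A", "C"), counts = c(1, 3), alphabet = "dna",
    weighting = "counts")
  expect_equal(kl_profile(p2, q2, pseudocount = 0)$kl, 0.5 * log2(3),
    tolerance = 1e-12)
  # pseudocount = 0 with a needed zero in Q errors
  r <- build_pfm(c("G"), alphabet = "dna")
  expect_error(kl_profile(r, q1, pseudocount = 0), "pseudocount")
  # positive pseudocount smooths it to a finite value
  expect_true(is.finite(kl_profile(r, q1, pseudocount = 0.5)$kl))
  expect_error(kl_profile(p1, build_pfm("Y", alphabet = "protein")), "alphabet")
})

test_that("restrictive selection increases summed KL over permissive selection", {
  one_rep <- function(seed, frac_fit) {
    pool <- make_initial_pool(n_variants = 200, pool_id = "p", seed = seed)
    peps <- unique(pool$peptide)
    n_fit <- max(1, round(frac_fit * length(peps)))
    fit_set <- withr::with_seed(seed + 1L, sample(peps, n_fit))
    ls <- fitness_landscape(fit_set, rep(4, n_fit), default_fitness = 0.25)
    sel <- apply_selection(pool, ls, rounds = 3)
    c0 <- draw_peptide_counts(pool, 2e4, seed = seed + 2L)
    c3 <- draw_peptide_counts(sel, 2e4, seed = seed + 3L)
    kl <- kl_profile(
      build_pfm(c3$peptide, alphabet = "protein"),
      build_pfm(c0$peptide, alphabet = "protein")
    )
    sum(kl$kl)
  }
  wins <- vapply(1:20, function(s) {
    one_rep(1000L + s, 0.05) > one_rep(2000L + s, 0.60)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
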