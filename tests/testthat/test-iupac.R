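test_that("IUPAC to PSSM translation follows the smoothing rule", {
  expect_equal(unclass(iupac_to_pssm("A", delta = 0))[, 1],
               c(A = 1, C = 0, G = 0, T = 0))
  # full four-base set is uniform regardless of smoothing
  expect_equal(unclass(iupac_to_pssm("N", delta = 0.1))[, 1],
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(unclass(iupac_to_pssm("R", delta = 0.04))[, 1],
               c(A = 0.48, C = 0.02, G = 0.48, T = 0.02))
  expect_error(iupac_to_pssm("AXG"), "invalid IUPAC")
  expect_error(iupac_to_pssm("A", delta = 1), "delta")
})

test_that("PSSM columns are stochastic for all symbols across deltas", {
  for (delta in c(0, 1e-6, 0.04, 0.1, 0.5, 0.9)) {
    p <- iupac_to_pssm(paste(IUPAC_ALPHABET, collapse = ""), delta = delta)
    expect_equal(colSums(unclass(p)), rep(1, 15), tolerance = 1e-12)
    expect_true(all(unclass(p) >= 0))
    if (delta > 0) expect_true(all(unclass(p) > 0))
  }
})

test_that("word scoring is the sum of column log probabilities", {
  expect_identical(score_word(iupac_to_pssm("ACGT", delta = 0), "ACGT"), 0)
  expect_equal(score_word(iupac_to_pssm("NN", delta = 0.3), "GT"),
               2 * log(0.25))
  expect_equal(score_word(iupac_to_pssm("RC", delta = 0.04), "GC"),
               log(0.48) + log(0.96))
  expect_error(score_word(iupac_to_pssm("ACG"), "AC"), "width")
  expect_error(score_word(iupac_to_pssm("AC"), "AN"), "masked")
})

test_that("word scores are non-positive, zero only for certain matches", {
  set.seed(11)
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    m <- random_motif(k)
    delta <- sample(c(0, 0.1, 0.4), 1)
    p <- iupac_to_pssm(m, delta)
    w <- random_motif(k, alphabet = c("A", "C", "G", "T"))
    sc <- score_word(p, w)
    expect_lte(sc, 0)
    cols <- unclass(p)[cbind(match(strsplit(w, "")[[1]], c("A", "C", "G", "T")),
                             seq_len(k))]
    expect_identical(sc == 0, all(cols == 1))
  }
})

test_that("substitution replaces exactly one position", {
  expect_identical(motif_substitute("ACGT", 0, "R"), "RCGT")
  expect_identical(motif_substitute("ACGT", 3, "T"), "ACGT")
  expect_identical(motif_substitute("AAAA", 2, "N"), "AANA")
  expect_error(motif_substitute("ACGT", 4, "A"), "out of range")
  # involution: substituting back restores the original
  set.seed(5)
  for (rep in 1:20) {
    m <- random_motif(sample(2:6, 1))
    i <- sample(seq_len(nchar(m)), 1) - 1
    a <- sample(IUPAC_ALPHABET, 1)
    old <- substr(m, i + 1, i + 1)
    expect_identical(motif_substitute(motif_substitute(m, i, a), i, old), m)
    expect_identical(motif_substitute(m, i, old), m)
  }
})

test_that("degenerate positions are counted over the non-ACGT symbols", {
  expect_identical(degenerate_count("ACGT"), 0L)
  expect_identical(degenerate_count("ARGTN"), 2L)
  expect_identical(degenerate_count("N"), 1L)
})

test_that("PSSM distance is a scaled pseudometric", {
  pA <- iupac_to_pssm("A", 0)
  expect_identical(pssm_distance(pA, pA), 0)
  expect_equal(pssm_distance(pA, iupac_to_pssm("C", 0)), 1)
  expect_equal(pssm_distance(pA, iupac_to_pssm("R", 0)), 0.5)
  set.seed(21)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    p <- iupac_to_pssm(random_motif(k), runif(1, 0, 0.5))
    q <- iupac_to_pssm(random_motif(k), runif(1, 0, 0.5))
    r <- iupac_to_pssm(random_motif(k), runif(1, 0, 0.5))
    dpq <- pssm_distance(p, q)
    expect_gte(dpq, 0)
    expect_lte(dpq, 1)
    expect_equal(dpq, pssm_distance(q, p))
    expect_lte(dpq, pssm_distance(p, r) + pssm_distance(r, q) + 1e-12)
  }
})

test_that("unequal widths slide to the best full-overlap offset", {
  inner <- iupac_to_pssm("ACG", 0)
  outer <- iupac_to_pssm("TACGT", 0)
  expect_equal(pssm_distance(inner, outer), 0)
  expect_equal(pssm_distance(outer, inner), 0)
  # reverse complement found only with both_strands
  rc <- iupac_to_pssm("CGT", 0)   # revcomp of ACG
  mism <- pssm_distance(rc, iupac_to_pssm("ACG", 0))
  expect_gt(mism, 0)
  expect_equal(pssm_distance(rc, iupac_to_pssm("ACG", 0),
                             both_strands = TRUE), 0)
})

test_that("the empty motif loses every strict score comparison", {
  s <- seq_set(c("ACGT", "AGGT"))
  expect_identical(bis_of(empty_motif()), -Inf)
  real <- bis_of("AN", seqs = s)
  expect_true(real > bis_of(empty_motif()))
  expect_false(bis_of(empty_motif()) > bis_of(empty_motif()))
  # ordering of real motifs is preserved
  set.seed(3)
  for (rep in 1:10) {
    m1 <- random_motif(2)
    m2 <- random_motif(2)
    expect_identical(bis_of(m1, seqs = s) > bis_of(m2, seqs = s),
                     bis_score(s, m1) > bis_score(s, m2))
  }
})
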