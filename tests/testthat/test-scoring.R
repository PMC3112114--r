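test_that("annotation picks the best-scoring admissible start", {
  s <- seq_set("CCCCACCC")
  a <- annotate_motif(s, "A", delta = 0.1)
  expect_identical(a$start, 4L)
  expect_identical(a$word, "A")
  expect_equal(a$contribution, log(0.9))
})

test_that("ties resolve to the smallest start", {
  s <- seq_set("ACCA")
  a <- annotate_motif(s, "A", delta = 0.1)
  expect_identical(a$start, 0L)
})

test_that("windows overlapping masked bases are never annotated", {
  s <- seq_set(c("NNACGTNN", "ACNNNNGT"))
  a <- annotate_motif(s, "AC", delta = 0.1)
  expect_identical(a$start, c(2L, 0L))
  expect_error(annotate_motif(seq_set(c("ACGT", "ANNT")), "AC", delta = 0),
               "seq_2 has no admissible window")
})

test_that("a hand-computed prior-weighted score is reproduced", {
  s <- seq_set("AC")
  p <- as_psp(data.frame(id = s$id, start = 0:1, prob = c(0.8, 0.2)),
              s, k = 1)
  a <- annotate_motif(s, "A", priors = list(p), lambda = 0.5, delta = 0.1)
  expect_identical(a$start, 0L)
  expect_equal(bis_score(s, "A", priors = list(p), lambda = 0.5,
                         delta = 0.1),
               0.5 * log(0.9) + 0.5 * log(0.8))
})

test_that("a probability-1 motif scores exactly zero without priors", {
  s <- seq_set(c("TTACGTTT", "ACGTGGGG", "GGGGACGT"))
  expect_identical(bis_score(s, "ACGT", delta = 0), 0)
  a <- annotate_motif(s, "ACGT", delta = 0)
  expect_identical(a$start, c(2L, 0L, 4L))
})

test_that("annotation equals the exhaustive window-scan oracle", {
  set.seed(61)
  for (rep in 1:25) {
    k <- sample(1:4, 1)
    seqs <- random_seqs(sample(1:5, 1), 30, k)
    ell <- sample(0:2, 1)
    priors <- if (ell) lapply(seq_len(ell), function(.) random_psp(seqs, k))
              else list()
    weights <- if (ell) runif(ell, 0.1, 1) else NULL
    lambda <- if (ell) runif(1, 0.1, 1) else NULL
    delta <- runif(1, 0.01, 0.5)
    m <- random_motif(k)
    a <- annotate_motif(seqs, m, priors, weights, lambda, delta)
    o <- oracle_annotate(seqs, m, priors, weights, lambda, delta)
    expect_identical(as.integer(a$start), as.integer(o$start))
    expect_equal(a$contribution, o$contribution, tolerance = 1e-9)
    expect_equal(bis_score(seqs, m, priors, weights, lambda, delta),
                 sum(o$contribution), tolerance = 1e-9)
  }
})

test_that("a uniform prior changes scores affinely but decisions not at all", {
  set.seed(71)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    seqs <- random_seqs(4, 25, k)
    unif <- uniform_psp(seqs, k)
    for (lambda in c(0.25, 0.5, 1)) {
      motifs <- replicate(5, random_motif(k))
      free <- vapply(motifs, function(m) bis_score(seqs, m), numeric(1))
      withu <- vapply(motifs, function(m)
        bis_score(seqs, m, priors = list(unif), lambda = lambda),
        numeric(1))
      # motif-independent offset after the lambda scaling
      offs <- withu - lambda * free
      expect_equal(max(offs) - min(offs), 0, tolerance = 1e-9)
      a_free <- annotate_motif(seqs, motifs[1])
      a_unif <- annotate_motif(seqs, motifs[1], priors = list(unif),
                               lambda = lambda)
      expect_identical(a_free$start, a_unif$start)
      expect_identical(a_free$strand, a_unif$strand)
    }
  }
})

test_that("raising the prior at the annotated position never lowers the score", {
  set.seed(81)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    seqs <- random_seqs(3, 20, k)
    p <- random_psp(seqs, k)
    m <- random_motif(k)
    lambda <- runif(1, 0.1, 0.9)
    a <- annotate_motif(seqs, m, list(p), lambda = lambda)
    b0 <- bis_score(seqs, m, list(p), lambda = lambda)
    p2 <- p
    i <- sample(nrow(seqs), 1)
    sel <- p2$id == seqs$id[i] & p2$start == a$start[i]
    p2$prob[sel] <- min(1, p2$prob[sel] * 1.5)
    expect_gte(bis_score(seqs, m, list(p2), lambda = lambda), b0 - 1e-12)
  }
})

test_that("both-strand scoring annotates the better orientation", {
  # CCCC-free sequence where only the reverse complement of the motif occurs
  s <- seq_set("CCCCCATTCC")   # revcomp of ATG = CAT at start 4
  fwd <- annotate_motif(s, "ATG", delta = 0.01)
  both <- annotate_motif(s, "ATG", delta = 0.01, both_strands = TRUE)
  expect_identical(both$strand, "-")
  expect_identical(both$start, 4L)
  expect_gt(both$contribution, fwd$contribution)
  # palindromic tie goes to the forward strand
  pal <- annotate_motif(seq_set("GGCATGCC"), "CATG", delta = 0.1,
                        both_strands = TRUE)
  expect_identical(pal$strand, "+")
})

test_that("annotation export writes TSV and BED6", {
  s <- seq_set(c("TTACGTTT", "ACGTGGGG"))
  a <- annotate_motif(s, "ACGT", delta = 0.1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation(a, tsv, "tsv")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$start, a$start)
  write_annotation(a, bed, "bed")
  b <- utils::read.table(bed, sep = "\t")
  expect_equal(b$V3 - b$V2, rep(4, 2))
  expect_true(all(b$V5 >= 0 & b$V5 <= 1000))
})
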