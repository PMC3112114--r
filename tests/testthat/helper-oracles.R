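# Independent brute-force oracles and small random-instance generators.
# The oracles deliberately avoid the package's vectorised scoring engine:
# they loop over windows explicitly, using only the elementary exported
# operations (iupac_to_pssm / score_word) and plain arithmetic.

oracle_balance <- function(priors, weights, lambda) {
  ell <- length(priors)
  if (ell == 0L) return(list(lambda = 1, w = numeric(0)))
  w <- if (is.null(weights)) rep(1, ell) else weights
  list(lambda = if (is.null(lambda)) 0.5 else lambda, w = w / sum(w))
}

# exhaustive per-sequence window scan; ties to the smallest start
oracle_annotate <- function(seqs, motif, priors = list(), weights = NULL,
                            lambda = NULL, delta = 0.1) {
  k <- nchar(motif)
  bal <- oracle_balance(priors, weights, lambda)
  p <- iupac_to_pssm(motif, delta)
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs$seq[i]
    best <- NULL
    for (j in 0:(nchar(s) - k)) {
      word <- substr(s, j + 1, j + k)
      if (grepl("N", word, fixed = TRUE)) next
      term <- bal$lambda * score_word(p, word)
      for (pi in seq_along(priors)) {
        pr <- priors[[pi]]
        v <- pr$prob[pr$id == seqs$id[i] & pr$start == j]
        term <- term + (1 - bal$lambda) * bal$w[pi] * log(v)
      }
      if (is.null(best) || term > best$term) {
        best <- list(start = j, term = term, word = word)
      }
    }
    best
  })
  data.frame(id = seqs$id,
             start = vapply(out, `[[`, numeric(1), "start"),
             word = vapply(out, `[[`, character(1), "word"),
             contribution = vapply(out, `[[`, numeric(1), "term"))
}

oracle_bis <- function(seqs, motif, priors = list(), weights = NULL,
                       lambda = NULL, delta = 0.1) {
  sum(oracle_annotate(seqs, motif, priors, weights, lambda,
                      delta)$contribution)
}

random_seqs <- function(N, n_max, k, masked = FALSE) {
  letters_pool <- if (masked) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  n <- sample(k:n_max, N, replace = TRUE)
  seq_set(vapply(n, function(len)
    paste(sample(letters_pool, len, replace = TRUE,
                 prob = if (masked) c(rep(0.23, 4), 0.08) else NULL),
          collapse = ""), character(1)))
}

random_motif <- function(k, alphabet = IUPAC_ALPHABET) {
  paste(sample(alphabet, k, replace = TRUE), collapse = "")
}

random_psp <- function(seqs, k) {
  nwin <- nchar(seqs$seq) - k + 1L
  long <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i)
    data.frame(id = seqs$id[i], start = 0:(nwin[i] - 1L),
               prob = runif(nwin[i], 0.05, 1))))
  as_psp(long, seqs, k, name = "random")
}

all_dna_words <- function(k) {
  grids <- rep(list(c("A", "C", "G", "T")), k)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

# exact substring-free support count by scanning every admissible window
oracle_support <- function(seqs, word, e) {
  k <- nchar(word)
  sum(vapply(seqs$seq, function(s) {
    for (j in 0:(nchar(s) - k)) {
      win <- substr(s, j + 1, j + k)
      if (grepl("N", win, fixed = TRUE)) next
      if (hamming_distance(win, word) <= e) return(TRUE)
    }
    FALSE
  }, logical(1)))
}

# full 4^k enumeration with the package's quorum-relaxation contract
oracle_seeds <- function(seqs, k, e, quorum) {
  words <- all_dna_words(k)
  support <- vapply(words, oracle_support, integer(1), seqs = seqs, e = e)
  keep <- support >= quorum
  data.frame(word = words[keep], support = support[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

expect_no_improving_substitution <- function(seqs, motif, priors = list(),
                                             weights = NULL, lambda = NULL,
                                             delta = 0.1) {
  base <- oracle_bis(seqs, motif, priors, weights, lambda, delta)
  k <- nchar(motif)
  for (i in 0:(k - 1)) {
    for (a in IUPAC_ALPHABET) {
      cand <- motif_substitute(motif, i, a)
      if (cand == motif) next
      expect_lte(oracle_bis(seqs, cand, priors, weights, lambda, delta),
                 base + 1e-9)
    }
  }
}
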