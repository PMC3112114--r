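#' Hamming distance between two equal-length DNA words
#'
#' The minimum number of substitutions required to change one word into the
#' other; the occurrence semantics of the seed enumerator ("a sequence
#' contains word w" means some window lies within distance `e` of `w`).
#'
#' @param a,b Equal-length character strings.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming_distance("ACGT", "ACGA")  # 1
#' @export
hamming_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) {
    stop("words must have equal length", call. = FALSE)
  }
  sum(x != y)
}

# windows of the admissible forward strand, stacked over sequences
seed_windows <- function(seqs, k) {
  seqs <- validate_seq_set(seqs, k = k)
  Ws <- vector("list", nrow(seqs))
  seqidx <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    wm <- window_matrix(encode_dna(seqs$seq[i]), k)
    Ws[[i]] <- wm$W
    seqidx[[i]] <- rep(i, nrow(wm$W))
  }
  list(W = do.call(rbind, Ws),
       seq_of = unlist(seqidx, use.names = FALSE),
       n_windows = vapply(Ws, nrow, integer(1)))
}

#' Over-representation significance of a seed word
#'
#' Ranks candidate words by the z-score of their observed support (number
#' of sequences with at least one window within Hamming distance `e`)
#' against a null in which bases are i.i.d. uniform and windows are treated
#' as independent: a word with neighbourhood size
#' `V = sum_{d<=e} choose(k,d) 3^d` hits a single window with probability
#' `V / 4^k`, and a sequence with `w_i` admissible windows with probability
#' `1 - (1 - V/4^k)^{w_i}`. The independence treatment of overlapping
#' windows is an approximation (exact for `w_i = 1`); the statistic is a
#' documented stand-in for published consensus-ranking tests and is only
#' used to order seeds.
#'
#' @param support Integer vector of observed supports.
#' @param n_windows Integer vector of admissible window counts per sequence.
#' @param k Word width.
#' @param e Maximum Hamming distance for an occurrence.
#' @return A numeric z-score per support value; higher means more
#'   over-represented.
#' @export
seed_significance <- function(support, n_windows, k, e) {
  V <- sum(choose(k, 0:e) * 3^(0:e))
  q <- V / 4^k
  p_i <- 1 - (1 - q)^n_windows
  mu <- sum(p_i)
  v <- sum(p_i * (1 - p_i))
  if (v <= 0) {
    return(ifelse(support == mu, 0, sign(support - mu) * Inf))
  }
  (support - mu) / sqrt(v)
}

#' Enumerate over-represented candidate consensus words
#'
#' Exhaustive extension-based enumeration over `{A,C,G,T}`: candidate
#' prefixes grow letter by letter and a prefix is abandoned as soon as the
#' number of sequences containing it (within Hamming distance `e`, on the
#' prefix) drops below the quorum. Pruning on prefix distance is an
#' admissible relaxation of the full-word distance, so every width-`k` word
#' meeting the quorum is found. Full-length survivors are ranked by
#' [seed_significance()], ties by support then lexicographically. If fewer
#' than `z_min` candidates survive, the quorum is relaxed by
#' `ceiling(0.05 * N)` and enumeration repeats (down to a quorum of 1); the
#' ranked list is truncated at `z_max`.
#'
#' @param seqs A sequence-set tibble.
#' @param k Word width; must not exceed the shortest sequence.
#' @param e Maximum Hamming distance for an occurrence (default 2).
#' @param quorum Minimum number of sequences that must contain an
#'   occurrence; default `ceiling(0.8 * N)`.
#' @param z_min,z_max Minimum / maximum number of candidates to return.
#' @return A tibble of candidates ordered best-first: `word`, `support`,
#'   `significance`, plus the effective `quorum` as an attribute.
#' @export
enumerate_seeds <- function(seqs, k = 8, e = 2, quorum = NULL,
                            z_min = 10, z_max = 50) {
  seqs <- validate_seq_set(seqs, k = k)
  if (e < 0) stop("e must be >= 0", call. = FALSE)
  N <- nrow(seqs)
  quorum <- as.integer(quorum %||% ceiling(0.8 * N))
  quorum <- max(1L, min(quorum, N))
  if (z_min > z_max) stop("z_min must be <= z_max", call. = FALSE)
  sw <- seed_windows(seqs, k)
  if (nrow(sw$W) == 0L) {
    stop("no admissible windows: every sequence is shorter than k = ", k,
         " or fully masked", call. = FALSE)
  }
  repeat {
    res <- enumerate_words_cpp(sw$W, sw$seq_of, as.integer(k),
                               as.integer(e), quorum)
    if (length(res$support) >= z_min || quorum == 1L) break
    quorum <- max(1L, quorum - as.integer(ceiling(0.05 * N)))
  }
  if (length(res$support) == 0L) {
    return(structure(tibble(word = character(0), support = integer(0),
                            significance = numeric(0)),
                     quorum = quorum))
  }
  words <- apply(res$words, 1L, decode_dna)
  sig <- seed_significance(res$support, sw$n_windows, k, e)
  out <- tibble(word = words, support = res$support, significance = sig) |>
    dplyr::arrange(dplyr::desc(.data$significance),
                   dplyr::desc(.data$support), .data$word) |>
    head(z_max)
  structure(out, quorum = quorum)
}

#' Read a seeds file
#'
#' One width-`k` DNA word per line; blank lines and `#` comments are
#' ignored. A seeds file bypasses enumeration entirely, so any external
#' consensus-finding tool can supply the starting points of the greedy
#' refinement.
#'
#' @param path Path to the seeds file.
#' @param k Required word width.
#' @return A character vector of seed words.
#' @export
read_seeds <- function(path, k) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- toupper(x[nzchar(x) & !grepl("^#", x)])
  bad <- nchar(x) != k | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("seeds file: line(s) that are not width-", k, " DNA words: ",
         paste(head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  x
}
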