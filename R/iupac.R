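#' The IUPAC nucleotide alphabet
#'
#' The 15 IUPAC nucleotide symbols in the canonical order used throughout the
#' package: the four bases first, then the degenerate symbols. The greedy
#' refinement scans substitution candidates in exactly this order, which makes
#' every search deterministic.
#'
#' @format A character vector of length 15.
#' @export
IUPAC_ALPHABET <- c("A", "C", "G", "T",
                    "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

# base sets of each symbol, as indices into c(A, C, G, T)
IUPAC_SETS <- list(
  A = 1L, C = 2L, G = 3L, T = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
  K = c(3L, 4L), M = c(1L, 2L),
  B = c(2L, 3L, 4L), D = c(1L, 3L, 4L), H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
  N = c(1L, 2L, 3L, 4L)
)

DNA_BASES <- c("A", "C", "G", "T")

iupac_codes <- function(symbols) {
  idx <- match(symbols, IUPAC_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

motif_symbols <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif) ||
      nchar(motif) < 1L) {
    stop("a motif must be a single non-empty IUPAC string", call. = FALSE)
  }
  strsplit(toupper(motif), "", fixed = TRUE)[[1]]
}

#' Validate an IUPAC motif string
#'
#' A motif is a single string of width `k >= 1` over the 15-letter IUPAC
#' nucleotide alphabet. Degenerate symbols (everything outside `A`, `C`, `G`,
#' `T`) encode sets of admissible bases, e.g. `R = {A, G}`.
#'
#' @param motif A single character string.
#' @return The validated motif (uppercased), invisibly usable as input to the
#'   other motif operations.
#' @examples
#' check_motif("ACGTRYN")
#' @export
check_motif <- function(motif) {
  syms <- motif_symbols(motif)
  iupac_codes(syms)
  paste(syms, collapse = "")
}

#' Number of degenerate positions in a motif
#'
#' Counts motif positions holding a symbol outside `A`, `C`, `G`, `T`. The
#' ChIP-seq search preset caps this count at 2 so that reported consensus
#' strings stay interpretable on very large sequence-sets.
#'
#' @param motif An IUPAC motif string.
#' @return Integer count of degenerate positions.
#' @examples
#' degenerate_count("ACGT")   # 0
#' degenerate_count("ARGTN")  # 2
#' @export
degenerate_count <- function(motif) {
  sum(iupac_codes(motif_symbols(motif)) > 4L)
}

#' Substitute one motif position
#'
#' Returns a copy of `motif` whose position `i` (0-based, as everywhere in
#' this package's internals) is replaced by the IUPAC symbol `alpha`. This is
#' the elementary move of the greedy refinement.
#'
#' @param motif An IUPAC motif string.
#' @param i 0-based position, `0 <= i < width`.
#' @param alpha A single IUPAC symbol.
#' @return The substituted motif string; the input is unchanged.
#' @examples
#' motif_substitute("ACGT", 0, "R")  # "RCGT"
#' @export
motif_substitute <- function(motif, i, alpha) {
  syms <- motif_symbols(motif)
  if (length(i) != 1L || is.na(i) || i < 0 || i >= length(syms)) {
    stop("position i out of range [0, ", length(syms) - 1L, "]", call. = FALSE)
  }
  alpha <- toupper(alpha)
  iupac_codes(alpha)
  syms[i + 1L] <- alpha
  paste(syms, collapse = "")
}

#' Translate an IUPAC motif into a position-specific scoring matrix
#'
#' Each motif column becomes a probability vector over `A,C,G,T`: the bases in
#' the symbol's set share probability `1 - delta` uniformly and the remaining
#' bases share `delta` uniformly (a full four-base set such as `N` is uniform
#' 1/4 regardless of `delta`). Smoothing with `delta > 0` keeps every word's
#' log-probability finite, so a motif without an exact-compatible occurrence
#' in some sequence still scores; `delta = 0` gives exact-match semantics.
#'
#' @param motif An IUPAC motif string.
#' @param delta Off-consensus smoothing mass in `[0, 1)`; default 0.1.
#' @return A `pssm` object: a 4 x k column-stochastic matrix with rownames
#'   `A,C,G,T` and attributes `motif` and `delta`.
#' @examples
#' iupac_to_pssm("R", delta = 0.04)
#' @export
iupac_to_pssm <- function(motif, delta = 0.1) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta >= 1) {
    stop("delta must be a single value in [0, 1)", call. = FALSE)
  }
  codes <- iupac_codes(motif_symbols(motif))
  mat <- vapply(codes, function(code) {
    set <- IUPAC_SETS[[code]]
    col <- numeric(4)
    if (length(set) == 4L) {
      col[] <- 0.25
    } else {
      col[set] <- (1 - delta) / length(set)
      col[-set] <- delta / (4 - length(set))
    }
    col
  }, numeric(4))
  mat <- matrix(mat, nrow = 4, dimnames = list(DNA_BASES, NULL))
  structure(mat, class = c("pssm", "matrix"),
            motif = paste(IUPAC_ALPHABET[codes], collapse = ""),
            delta = delta)
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM induced from motif ", attr(x, "motif"),
      " (delta = ", attr(x, "delta"), ")\n", sep = "")
  m <- unclass(x)
  attr(m, "motif") <- NULL
  attr(m, "delta") <- NULL
  colnames(m) <- seq_len(ncol(m))
  print(round(m, 4), ...)
  invisible(x)
}

pssm_width <- function(p) ncol(p)

#' Log-probability of a DNA word under a PSSM
#'
#' Scores a word of the matrix's width as the sum of per-column log
#' probabilities, `sum_j log p_j(w_j)`. The result is always `<= 0`, with 0
#' attained only when every column assigns probability 1 to the corresponding
#' base; `-Inf` can occur only for unsmoothed matrices (`delta = 0`).
#'
#' @param pssm A `pssm` (see [iupac_to_pssm()]).
#' @param word A DNA word over `A,C,G,T` with `nchar(word) == ncol(pssm)`.
#' @return A single non-positive number (possibly `-Inf`).
#' @examples
#' score_word(iupac_to_pssm("ACGT", delta = 0), "ACGT")  # 0
#' @export
score_word <- function(pssm, word) {
  chars <- motif_symbols(word)
  if (length(chars) != pssm_width(pssm)) {
    stop("word length ", length(chars), " does not match PSSM width ",
         pssm_width(pssm), call. = FALSE)
  }
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    stop("word must be over A,C,G,T; masked or ambiguous bases (",
         paste(unique(chars[is.na(idx)]), collapse = ","),
         ") are not scoreable", call. = FALSE)
  }
  sum(log(unclass(pssm)[cbind(idx, seq_along(idx))]))
}

revcomp_pssm <- function(p) {
  m <- unclass(p)[4:1, rev(seq_len(ncol(p))), drop = FALSE]
  rownames(m) <- DNA_BASES
  structure(m, class = class(p), motif = attr(p, "motif"),
            delta = attr(p, "delta"))
}

pssm_distance_aligned <- function(p, q) {
  d <- unclass(p) - unclass(q)
  mean(sqrt(colSums(d * d))) / sqrt(2)
}

#' Scaled Euclidean distance between two PSSMs
#'
#' The per-column Euclidean distance between the two probability vectors,
#' averaged over columns and divided by `sqrt(2)`, so that identical matrices
#' score 0 and maximally distinct point-mass matrices score 1. For unequal
#' widths the shorter matrix is slid over the longer one and the minimum over
#' all full-overlap offsets is reported; with `both_strands` the reverse
#' complement of `q` is also tried. Used as the success metric of the
#' recovery benchmark (reported motif vs planted consensus).
#'
#' @param p,q `pssm` objects.
#' @param both_strands Also compare against the reverse complement of `q`?
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pssm_distance(iupac_to_pssm("A", 0), iupac_to_pssm("R", 0))  # 0.5
#' @export
pssm_distance <- function(p, q, both_strands = FALSE) {
  stopifnot(inherits(p, "pssm"), inherits(q, "pssm"))
  slide_min <- function(a, b) {
    # width(a) <= width(b): minimum over full-overlap offsets
    wa <- pssm_width(a); wb <- pssm_width(b)
    offs <- 0:(wb - wa)
    min(vapply(offs, function(o) {
      pssm_distance_aligned(a, structure(unclass(b)[, (o + 1):(o + wa),
                                                    drop = FALSE],
                                         class = class(b)))
    }, numeric(1)))
  }
  one <- function(p, q) {
    if (pssm_width(p) == pssm_width(q)) pssm_distance_aligned(p, q)
    else if (pssm_width(p) < pssm_width(q)) slide_min(p, q)
    else slide_min(q, p)
  }
  d <- one(p, q)
  if (both_strands) d <- min(d, one(p, revcomp_pssm(q)))
  d
}

#' The empty motif sentinel
#'
#' The search driver initialises its running best with the empty motif, whose
#' score compares strictly less than any real motif's score, so the first
#' refined seed always replaces it. It is never returned to the user.
#'
#' @return An object of class `empty_motif`.
#' @export
empty_motif <- function() {
  structure(list(), class = "empty_motif")
}

#' @export
print.empty_motif <- function(x, ...) {
  cat("<empty motif: score -Inf>\n")
  invisible(x)
}

is_empty_motif <- function(x) inherits(x, "empty_motif")
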