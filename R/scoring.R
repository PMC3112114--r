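#' Annotate the best-scoring motif occurrence in every sequence
#'
#' For each sequence the annotation is the admissible start position
#' maximising the balanced per-sequence term
#' `lambda * log P_m(window) + (1 - lambda) * sum_p alpha_p * log S_p[i, j]`,
#' where `P_m` is the probability of the window under the PSSM induced from
#' the motif and `S_p` are the position-specific priors. Windows overlapping
#' a masked base (`N`) are never candidates. Ties resolve to the smallest
#' start, then the forward strand.
#'
#' @param seqs A sequence-set tibble (columns `id`, `seq`).
#' @param motif An IUPAC motif string.
#' @param priors A list of `psp` objects (possibly empty).
#' @param weights Raw non-negative prior weights, normalised to a convex
#'   combination; default uniform.
#' @param lambda Balance between sequence over-representation and prior
#'   information, in `(0, 1]`. Defaults to 0.5 with priors and is fixed at 1
#'   without (it then plays no role).
#' @param delta PSSM smoothing (see [iupac_to_pssm()]).
#' @param both_strands Score each window on both orientations and annotate
#'   the better one? The prior value is always taken at the forward start.
#' @return A tibble with one row per sequence: `id`, `start` (0-based),
#'   `strand`, `word` (the matched window as scored), and `contribution`
#'   (the per-sequence balanced term, always `<= 0`).
#' @examples
#' s <- seq_set(c("CCCCACCC", "ACCCCCCC"))
#' annotate_motif(s, "A")
#' @export
annotate_motif <- function(seqs, motif, priors = list(), weights = NULL,
                           lambda = NULL, delta = 0.1,
                           both_strands = FALSE) {
  engine <- bis_engine(seqs, nchar(check_motif(motif)), priors, weights,
                       lambda, delta, both_strands)
  engine_annotate(engine, motif)
}

#' Balanced Information Score of a motif on a sequence set
#'
#' The (sign-flipped) balanced self-information of observing the motif at
#' its annotated positions in every sequence and, when priors are supplied,
#' of the priors at those same positions:
#' `sum_i max_j [ lambda * log P_m(f_i[j..j+k-1]) +
#' (1 - lambda) * sum_p alpha_p * log S_p[i, j] ]`.
#' The score is always non-positive; it reaches 0 exactly when the motif
#' occurs with probability 1 at every annotated position (prior-free,
#' unsmoothed case). The discovery search maximises this quantity.
#'
#' @inheritParams annotate_motif
#' @return A single number `<= 0` (possibly `-Inf` when `delta = 0`).
#' @examples
#' bis_score(seq_set(c("ACGT", "TACG")), "ACG", delta = 0)
#' @export
bis_score <- function(seqs, motif, priors = list(), weights = NULL,
                      lambda = NULL, delta = 0.1, both_strands = FALSE) {
  engine <- bis_engine(seqs, nchar(check_motif(motif)), priors, weights,
                       lambda, delta, both_strands)
  engine_bis(engine, motif)
}

#' Score a motif or the empty-motif sentinel
#'
#' The empty motif (see [empty_motif()]) scores `-Inf`, strictly below any
#' real motif, so it loses every comparison against a refined candidate.
#'
#' @param x A motif string or an `empty_motif`.
#' @param ... Passed to [bis_score()] for real motifs.
#' @return `-Inf` for the empty motif, otherwise [bis_score()].
#' @export
bis_of <- function(x, ...) {
  if (is_empty_motif(x)) return(-Inf)
  bis_score(motif = x, ...)
}

#' Write an annotation table as TSV or BED6
#'
#' The TSV mirrors the annotation tibble (sequence id, 0-based start,
#' strand, matched word, per-sequence contribution). BED6 uses 0-based
#' half-open intervals; the BED score column compresses the contribution
#' into 0-1000 as `round(1000 * exp(contribution / k))`, i.e. the per-column
#' geometric-mean probability of the annotated window.
#'
#' @param annotation An annotation tibble from [annotate_motif()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  k <- nchar(annotation$word[1])
  if (format == "tsv") {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = annotation$id,
                      chromStart = annotation$start,
                      chromEnd = annotation$start + k,
                      name = annotation$word,
                      score = pmin(1000, pmax(0, round(
                        1000 * exp(annotation$contribution / k)))),
                      strand = annotation$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
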