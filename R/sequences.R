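#' Build a sequence-set tibble
#'
#' A sequence set is an ordinary tibble with columns `id` (unique character
#' identifiers) and `seq` (uppercase DNA over `A,C,G,T,N`). `N` marks masked
#' bases (e.g. repeat-masked ChIP-seq preprocessing); windows overlapping a
#' masked base are excluded from all scoring and enumeration.
#'
#' @param seqs A character vector of DNA sequences.
#' @param ids Optional identifiers; defaults to `seq_1`, `seq_2`, ...
#' @return A tibble with columns `id`, `seq`.
#' @examples
#' seq_set(c("ACGTACGT", "TTTTACGT"))
#' @export
seq_set <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  out <- tibble(id = as.character(ids), seq = toupper(as.character(seqs)))
  validate_seq_set(out)
}

validate_seq_set <- function(seqs, k = NULL) {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("a sequence set must be a data frame with columns 'id' and 'seq'",
         call. = FALSE)
  }
  if (nrow(seqs) < 1L) stop("sequence set is empty", call. = FALSE)
  if (anyDuplicated(seqs$id)) {
    stop("duplicated sequence id(s): ",
         paste(unique(seqs$id[duplicated(seqs$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs$seq)
  if (any(bad)) {
    stop("sequence(s) with characters outside A,C,G,T,N: ",
         paste(head(seqs$id[bad], 3), collapse = ", "), call. = FALSE)
  }
  if (!is.null(k)) {
    short <- nchar(seqs$seq) < k
    if (any(short)) {
      stop("sequence(s) shorter than the motif width k = ", k, ": ",
           paste(head(seqs$id[short], 3), collapse = ", "), call. = FALSE)
    }
  }
  as_tibble(seqs)
}

#' Read a FASTA file into a sequence-set tibble
#'
#' Standard FASTA dialect (multi-line sequences, `>` headers); the identifier
#' is the first whitespace-delimited token of the header. Lowercase bases are
#' uppercased and any IUPAC ambiguity code other than `A,C,G,T` is treated as
#' a masked base (`N`).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  sq <- toupper(as.character(x))
  sq <- gsub("[^ACGT]", "N", sq)
  seq_set(sq, ids)
}

#' Write a sequence-set tibble to FASTA
#'
#' @param seqs A sequence-set tibble (columns `id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_seq_set(seqs)
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# integer encoding: A,C,G,T -> 1..4, N (mask) -> 0
encode_dna <- function(s) {
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  unname(codes[strsplit(s, "", fixed = TRUE)[[1]]])
}

decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")
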