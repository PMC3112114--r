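#' Position-specific priors (PSPs)
#'
#' A PSP stores, for every sequence in a set, one prior probability per
#' candidate motif start position (so row `i` holds `n_i - k + 1` values for
#' a width-`k` search). Inside this package a PSP is a long tibble with
#' columns `id`, `start` (0-based), `prob`, carrying the motif width as
#' attribute `k` and a human-readable attribute `name`. Entries enter the
#' score only through their logarithm, so every value is floored at
#' `prob_floor` on construction; rows are deliberately not renormalised after
#' flooring, preserving the semantics of externally supplied prior files.
#'
#' @param x A data frame with columns `id`, `start`, `prob`.
#' @param seqs The sequence-set tibble the prior belongs to.
#' @param k Motif width the prior was computed for.
#' @param name Prior name used in reports.
#' @param prob_floor Minimum admissible entry (default `1e-10`); smaller
#'   values are raised to the floor so `log` stays finite.
#' @return A `psp` tibble.
#' @export
as_psp <- function(x, seqs, k, name = "psp", prob_floor = 1e-10) {
  seqs <- validate_seq_set(seqs, k = k)
  if (!is.data.frame(x) || !all(c("id", "start", "prob") %in% names(x))) {
    stop("a PSP needs columns 'id', 'start', 'prob'", call. = FALSE)
  }
  if (nrow(x) == 0L) stop("empty PSP (0 rows)", call. = FALSE)
  if (any(x$prob < 0)) {
    stop("PSP format error: negative prior probability for sequence ",
         x$id[which(x$prob < 0)[1]], call. = FALSE)
  }
  if (any(x$prob > 1)) {
    stop("PSP format error: prior probability > 1 for sequence ",
         x$id[which(x$prob > 1)[1]], call. = FALSE)
  }
  extra <- setdiff(unique(x$id), seqs$id)
  if (length(extra)) {
    stop("PSP alignment error: unknown sequence id(s): ",
         paste(head(extra, 3), collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(seqs$id, unique(x$id))
  if (length(missing_ids)) {
    stop("PSP alignment error: no prior row for sequence id(s): ",
         paste(head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  nwin <- setNames(nchar(seqs$seq) - k + 1L, seqs$id)
  cnt <- table(x$id)
  bad <- names(cnt)[cnt != nwin[names(cnt)]]
  if (length(bad)) {
    stop("PSP format error: sequence ", bad[1], " has ", cnt[[bad[1]]],
         " prior values, expected n - k + 1 = ", nwin[[bad[1]]],
         call. = FALSE)
  }
  out <- x |>
    dplyr::mutate(id = as.character(.data$id),
                  start = as.integer(.data$start),
                  prob = pmax(.data$prob, prob_floor)) |>
    dplyr::arrange(match(.data$id, seqs$id), .data$start)
  expected <- unlist(lapply(nwin, function(w) seq_len(w) - 1L),
                     use.names = FALSE)
  if (!identical(as.integer(out$start), as.integer(expected))) {
    stop("PSP format error: start positions must cover 0 .. n - k ",
         "exactly once per sequence", call. = FALSE)
  }
  structure(as_tibble(out),
            class = c("psp", class(as_tibble(out))),
            k = as.integer(k), name = name, prob_floor = prob_floor)
}

psp_name <- function(p) attr(p, "name") %||% "psp"

#' Read a PSP file
#'
#' The PSP dialect is FASTA-like: a first comment line declaring the width
#' (`#k=8`), then for each sequence a header line `>` + sequence id followed
#' by whitespace/newline-separated decimal probabilities — exactly
#' `n_i - k + 1` values in 0-based start order. Row lengths, ids, and the
#' declared width are all validated against the sequence set, so a file
#' computed for a different width or sequence-set fails loudly instead of
#' silently misaligning.
#'
#' @param path Path to a PSP file.
#' @inheritParams as_psp
#' @return A `psp` tibble.
#' @export
read_psp <- function(path, seqs, k, name = NULL, prob_floor = 1e-10) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PSP file: ", path, call. = FALSE)
  kline <- grep("^#\\s*k\\s*=", lines, value = TRUE)
  if (length(kline) < 1L) {
    stop("PSP format error: missing width declaration line '#k=<int>' in ",
         path, call. = FALSE)
  }
  k_file <- as.integer(sub("^#\\s*k\\s*=\\s*", "", kline[1]))
  if (is.na(k_file) || k_file != k) {
    stop("PSP format error: file declares k=", k_file,
         " but the configured width is k=", k, call. = FALSE)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    stop("PSP format error: expected '>' sequence headers in ", path,
         call. = FALSE)
  }
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", trimws(lines[hdr]))
  rows <- lapply(split(lines[!hdr], grp[!hdr]), function(v) {
    vals <- suppressWarnings(as.numeric(unlist(strsplit(paste(v, collapse = " "),
                                                        "\\s+"))))
    vals[!is.na(vals)]
  })
  # headers with no value lines at all
  if (length(rows) != length(ids)) {
    present <- as.integer(names(rows))
    empty_hdr <- setdiff(seq_along(ids), present)
    stop("PSP format error: sequence ", ids[empty_hdr[1]],
         " has 0 prior values", call. = FALSE)
  }
  long <- tibble(
    id = rep(ids, lengths(rows)),
    start = unlist(lapply(rows, function(v) seq_along(v) - 1L),
                   use.names = FALSE),
    prob = unlist(rows, use.names = FALSE)
  )
  as_psp(long, seqs, k,
         name = name %||% tools::file_path_sans_ext(basename(path)),
         prob_floor = prob_floor)
}

#' Write a PSP file
#'
#' Inverse of [read_psp()]: values are written with enough digits that a
#' read/write round trip reproduces every entry to better than `1e-9`.
#'
#' @param psp A `psp` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psp <- function(psp, path) {
  if (!inherits(psp, "psp")) stop("not a psp object", call. = FALSE)
  if (nrow(psp) == 0L) stop("refusing to write an empty PSP", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#k=", attr(psp, "k")), con)
  for (chunk in split(psp, factor(psp$id, levels = unique(psp$id)))) {
    writeLines(paste0(">", chunk$id[1]), con)
    writeLines(paste(format(chunk$prob, digits = 15, scientific = TRUE,
                            trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Uniform position-specific prior
#'
#' Row `i` is constant `1/(n_i - k + 1)`: any position is equally likely to
#' hold the motif. Because a uniform prior contributes the same additive
#' constant to every candidate position of a sequence, adding it never
#' changes annotations, greedy trajectories, or the reported motif relative
#' to a prior-free run — a useful null arm for benchmarking.
#'
#' @inheritParams as_psp
#' @return A `psp` tibble.
#' @export
uniform_psp <- function(seqs, k, prob_floor = 1e-10) {
  seqs <- validate_seq_set(seqs, k = k)
  nwin <- nchar(seqs$seq) - k + 1L
  long <- tibble(
    id = rep(seqs$id, nwin),
    start = unlist(lapply(nwin, function(w) seq_len(w) - 1L),
                   use.names = FALSE),
    prob = rep(1 / nwin, nwin)
  )
  as_psp(long, seqs, k, name = "uniform", prob_floor = prob_floor)
}

#' Read a peak-summit table
#'
#' Two-column TSV: sequence id and 0-based summit offset within that
#' sequence (the highest-coverage position of the ChIP-seq binding peak).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `summit`.
#' @export
read_peaks <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("id", "summit"),
                         colClasses = c("character", "integer"))
  as_tibble(x)
}

#' Binding-peak position-specific prior
#'
#' Builds the coverage-style prior used for ChIP-seq data: prior mass is
#' proportional to a Student-t density (default 3 degrees of freedom)
#' of the distance between a window's centre and the peak summit, discretised
#' into fixed-size steps (default 25 bp) so the row forms a step function,
#' symmetric about the summit. All window starts whose centre falls in the
#' same step share one value (the t density at the step's midpoint distance);
#' each row is normalised to sum to 1.
#'
#' @param peaks A tibble with columns `id` and `summit` (0-based offset of
#'   the peak summit within the sequence), one row per sequence.
#' @inheritParams as_psp
#' @param step Step size in bp (default 25).
#' @param df Degrees of freedom of the t density (default 3).
#' @return A `psp` tibble.
#' @export
peak_psp <- function(peaks, seqs, k, step = 25, df = 3, prob_floor = 1e-10) {
  seqs <- validate_seq_set(seqs, k = k)
  if (!all(c("id", "summit") %in% names(peaks))) {
    stop("peaks needs columns 'id' and 'summit'", call. = FALSE)
  }
  if (step <= 0 || df <= 0) {
    stop("config error: step and df must be positive", call. = FALSE)
  }
  summit <- setNames(as.numeric(peaks$summit), peaks$id)
  missing_ids <- setdiff(seqs$id, names(summit))
  if (length(missing_ids)) {
    stop("no summit for sequence id(s): ",
         paste(head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    n <- nchar(seqs$seq[i])
    s <- summit[[seqs$id[i]]]
    if (is.na(s) || s < 0 || s >= n) {
      stop("summit offset ", s, " out of bounds for sequence ", seqs$id[i],
           call. = FALSE)
    }
    starts <- 0:(n - k)
    centre <- starts + k %/% 2
    step_idx <- floor(abs(centre - s) / step)
    raw <- stats::dt((step_idx + 0.5) * step, df = df)
    raw <- pmax(raw, prob_floor)
    tibble(id = seqs$id[i], start = starts, prob = raw / sum(raw))
  })
  as_psp(dplyr::bind_rows(rows), seqs, k, name = "peak",
         prob_floor = prob_floor)
}

#' Normalise prior weights into a convex combination
#'
#' Scales non-negative raw weights so they sum to 1; equal raw weights give
#' the uniform `1/l` default. The convex combination keeps the combined
#' prior self-information on the same scale as each component.
#'
#' @param raw Numeric vector of non-negative raw weights, at least one
#'   positive.
#' @return Numeric weights summing to 1.
#' @examples
#' normalize_weights(c(2, 1, 1))  # 0.5 0.25 0.25
#' @export
normalize_weights <- function(raw) {
  if (length(raw) == 0L) stop("no weights given", call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  s <- sum(raw)
  if (s <= 0) stop("all prior weights are zero", call. = FALSE)
  raw / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
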