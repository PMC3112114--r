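#' Greedy IUPAC refinement of a motif
#'
#' Hill-climbs the Balanced Information Score by single-position IUPAC
#' substitutions. Positions are visited cyclically starting at 0; at each
#' position every symbol of the canonical alphabet order
#' (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`) is tried and a substitution is accepted
#' only if it strictly increases the score (the inner loop then continues,
#' comparing the remaining symbols against the already-improved motif). The
#' search stops once `k` consecutive positions admit no accepted
#' substitution, which certifies the result locally optimal under
#' single-position moves. Convergence is guaranteed because the score is
#' upper-bounded by 0 and strictly increases on every accepted move over a
#' finite motif space.
#'
#' @inheritParams annotate_motif
#' @param max_degenerate Maximum number of degenerate (non-`A,C,G,T`)
#'   positions the refined motif may hold; `Inf` (default) for no limit, 2
#'   for the ChIP-seq preset that keeps consensus strings readable on very
#'   large sequence-sets.
#' @return A list with elements `motif` (the refined IUPAC string), `bis`
#'   (its score), `trace` (a tibble of accepted moves: 0-based `position`,
#'   `old`, `new`, `bis_before`, `bis_after`), and `iterations` (number of
#'   candidate evaluations).
#' @examples
#' s <- seq_set(c("GGACGTGG", "TTACGTTT", "CCACGTCC"))
#' refine_motif(s, "AAAA")$motif
#' @export
refine_motif <- function(seqs, motif, priors = list(), weights = NULL,
                         lambda = NULL, delta = 0.1, max_degenerate = Inf,
                         both_strands = FALSE) {
  motif <- check_motif(motif)
  engine <- bis_engine(seqs, nchar(motif), priors, weights, lambda, delta,
                       both_strands)
  out <- engine_ggp(engine, motif, max_degenerate)
  out
}

engine_ggp <- function(engine, motif, max_degenerate = Inf) {
  sym0 <- iupac_codes(motif_symbols(motif))
  if (length(sym0) != engine$k) {
    stop("seed width ", length(sym0), " does not match k = ", engine$k,
         call. = FALSE)
  }
  md <- if (is.infinite(max_degenerate)) -1L else as.integer(max_degenerate)
  if (md >= 0L && sum(sym0 > 4L) > md) {
    stop("starting motif already exceeds max_degenerate = ", md,
         call. = FALSE)
  }
  pv <- if (engine$n_priors > 0L) engine$priorvec else numeric(0)
  res <- ggp_cpp(sym0, engine$W, engine$symlogp, pv,
                 engine$first, engine$last, md)
  list(
    motif = paste(IUPAC_ALPHABET[res$sym], collapse = ""),
    bis = res$bis,
    trace = tibble(position = res$move_pos,
                   old = IUPAC_ALPHABET[res$move_old],
                   new = IUPAC_ALPHABET[res$move_new],
                   bis_before = res$move_before,
                   bis_after = res$move_after),
    iterations = res$iterations
  )
}

#' Discover a motif in a set of co-regulated sequences
#'
#' The full discovery pipeline: enumerate over-represented width-`k`
#' consensus words (see [enumerate_seeds()]), take the top `z` as seeds,
#' greedily refine each over the IUPAC alphabet to maximise the Balanced
#' Information Score (see [refine_motif()]), and report the refined motif
#' with the strictly highest score (the first one found is kept on ties).
#' The running best is initialised with the empty-motif sentinel, which any
#' real motif beats; if enumeration yields no seeds even after quorum
#' relaxation, the run aborts with a "no seeds" error rather than returning
#' the sentinel.
#'
#' @inheritParams refine_motif
#' @inheritParams enumerate_seeds
#' @param z Number of top-ranked seeds to refine (default 10).
#' @param seeds Optional character vector (or file read via [read_seeds()])
#'   of width-`k` DNA words that bypasses enumeration entirely.
#' @return A `motif_fit` object; see [tidy.motif_fit()], [glance.motif_fit()]
#'   and [autoplot.motif_fit()].
#' @examples
#' s <- seq_set(c("GGGTGACTCAGG", "TTTGACTCATTT", "CCTGACTCATCC"))
#' fit <- discover_motif(s, k = 6, e = 1, z = 3)
#' glance(fit)
#' @export
discover_motif <- function(seqs, priors = list(), weights = NULL, k = 8,
                           lambda = NULL, delta = 0.1, seeds = NULL,
                           z = 10, e = 2, quorum = NULL,
                           z_min = 10, z_max = 50,
                           max_degenerate = Inf, both_strands = FALSE) {
  seqs <- validate_seq_set(seqs, k = k)
  if (inherits(priors, "psp")) priors <- list(priors)
  if (z < 1) stop("z must be >= 1", call. = FALSE)

  if (is.null(seeds)) {
    cand <- enumerate_seeds(seqs, k = k, e = e, quorum = quorum,
                            z_min = z_min, z_max = z_max)
    seed_tbl <- head(cand, z)
    effective_quorum <- attr(cand, "quorum")
  } else {
    bad <- nchar(seeds) != k | grepl("[^ACGT]", toupper(seeds))
    if (any(bad)) {
      stop("seeds must be width-", k, " DNA words; offending: ",
           paste(head(seeds[bad], 3), collapse = ", "), call. = FALSE)
    }
    seed_tbl <- tibble(word = toupper(seeds), support = NA_integer_,
                       significance = NA_real_) |> head(z)
    effective_quorum <- NA_integer_
  }
  if (nrow(seed_tbl) == 0L) {
    stop("no seeds: enumeration found no over-represented word even at ",
         "quorum 1; try a larger Hamming distance e or smaller k",
         call. = FALSE)
  }

  engine <- bis_engine(seqs, k, priors, weights, lambda, delta, both_strands)

  best <- empty_motif()
  best_bis <- -Inf
  refined <- character(nrow(seed_tbl))
  refined_bis <- numeric(nrow(seed_tbl))
  traces <- vector("list", nrow(seed_tbl))
  for (s in seq_len(nrow(seed_tbl))) {
    g <- engine_ggp(engine, seed_tbl$word[s], max_degenerate)
    refined[s] <- g$motif
    refined_bis[s] <- g$bis
    traces[[s]] <- g$trace
    if (g$bis > best_bis) {   # strict: first motif wins ties
      best <- g$motif
      best_bis <- g$bis
    }
  }

  annotation <- engine_annotate(engine, best)
  structure(list(
    motif = best,
    bis = best_bis,
    pssm = iupac_to_pssm(best, delta),
    annotation = annotation,
    seeds = dplyr::mutate(seed_tbl, refined = refined,
                          refined_bis = refined_bis),
    traces = traces,
    config = list(k = k, lambda = engine$lambda, delta = delta,
                  n_priors = engine$n_priors,
                  weights = if (engine$n_priors)
                    normalize_weights(weights %||% rep(1, engine$n_priors))
                  else numeric(0),
                  prior_names = vapply(priors, psp_name, character(1)),
                  z = z, e = e, quorum = effective_quorum,
                  z_min = z_min, z_max = z_max,
                  max_degenerate = max_degenerate,
                  both_strands = both_strands,
                  n_sequences = nrow(seqs))
  ), class = "motif_fit")
}

#' @export
print.motif_fit <- function(x, ...) {
  cfg <- x$config
  cat("Motif discovery fit\n")
  cat("  motif: ", x$motif, "  (", degenerate_count(x$motif),
      " degenerate position(s))\n", sep = "")
  cat("  balanced information score: ", format(x$bis), "\n", sep = "")
  cat("  sequences: ", cfg$n_sequences, ", k = ", cfg$k,
      ", lambda = ", cfg$lambda, ", priors = ", cfg$n_priors,
      "\n", sep = "")
  cat("  seeds refined: ", nrow(x$seeds), "\n", sep = "")
  invisible(x)
}

#' Tidy the per-sequence annotations of a motif fit
#'
#' @param x A `motif_fit`.
#' @param ... Unused.
#' @return The annotation tibble: one row per sequence with `id`, `start`
#'   (0-based), `strand`, `word`, `contribution`.
#' @export
tidy.motif_fit <- function(x, ...) {
  x$annotation
}

#' One-row summary of a motif fit
#'
#' @param x A `motif_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `motif`, `bis`, `k`, `n_sequences`,
#'   `degenerate_positions`, `lambda`, `n_priors`, `seeds_refined`.
#' @export
glance.motif_fit <- function(x, ...) {
  tibble(motif = x$motif,
         bis = x$bis,
         k = x$config$k,
         n_sequences = x$config$n_sequences,
         degenerate_positions = degenerate_count(x$motif),
         lambda = x$config$lambda,
         n_priors = x$config$n_priors,
         seeds_refined = nrow(x$seeds))
}

#' Plot the PSSM of a discovered motif
#'
#' Tile heat map of the 4 x k column-stochastic matrix induced from the
#' reported IUPAC motif, with the consensus symbols on the x axis.
#'
#' @param object A `motif_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_fit <- function(object, ...) {
  m <- unclass(object$pssm)
  df <- tidyr::expand_grid(base = factor(DNA_BASES, levels = rev(DNA_BASES)),
                           position = seq_len(ncol(m))) |>
    dplyr::mutate(prob = as.vector(m[cbind(as.integer(5L) -
                                             as.integer(.data$base),
                                           .data$position)]))
  syms <- motif_symbols(object$motif)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$base,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1), name = "prob") +
    ggplot2::scale_x_continuous(breaks = seq_along(syms), labels = syms) +
    ggplot2::labs(x = "motif position (consensus symbol)", y = NULL,
                  title = paste("PSSM of", object$motif)) +
    ggplot2::theme_minimal()
}

#' Write a motif report
#'
#' Plain-text and JSON reports of a discovery run: the IUPAC motif, its
#' PSSM (also emitted in a minimal motif-matrix text block for
#' interoperability), the score, per-sequence annotations, the seed table,
#' and, when `verbose`, the full accepted-move trace of every seed.
#'
#' @param fit A `motif_fit`.
#' @param path Output path stem; `.txt` and `.json` are appended.
#' @param verbose Include the search traces?
#' @return The two paths, invisibly.
#' @export
write_report <- function(fit, path, verbose = FALSE) {
  txt <- paste0(path, ".txt")
  jsn <- paste0(path, ".json")
  m <- unclass(fit$pssm)
  con <- file(txt, "w")
  writeLines(c(
    paste0("motif\t", fit$motif),
    paste0("bis\t", format(fit$bis, digits = 12)),
    paste0("k\t", fit$config$k),
    paste0("lambda\t", fit$config$lambda),
    "",
    "# PSSM (rows A C G T, columns = motif positions)",
    vapply(seq_len(4), function(r)
      paste(c(DNA_BASES[r], format(m[r, ], digits = 6)), collapse = "\t"),
      character(1)),
    "",
    "# annotations: id, start (0-based), strand, word, contribution",
    vapply(seq_len(nrow(fit$annotation)), function(i)
      paste(unlist(fit$annotation[i, ]), collapse = "\t"), character(1))
  ), con)
  close(con)
  payload <- list(
    motif = fit$motif,
    bis = fit$bis,
    pssm = unname(apply(m, 2, identity, simplify = FALSE)),
    config = fit$config,
    annotation = fit$annotation,
    seeds = fit$seeds
  )
  if (verbose) payload$traces <- fit$traces
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(txt, jsn))
}
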