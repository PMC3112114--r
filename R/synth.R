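#' Specification of a planted-motif synthetic dataset
#'
#' Describes one simulated study: `N` background sequences of length `n`
#' with one mutated occurrence of a width-`k` consensus planted per sequence
#' (the one-occurrence-per-sequence regime the scoring model annotates), and
#' zero or more position-specific priors whose mass is concentrated, to a
#' controllable degree, at the planted starts. Defaults emulate the yeast
#' ChIP-chip benchmark scale: around 200 sequences of 500 bp, a width-8
#' consensus with 2 substitutions per occurrence, and a prior that puts half
#' of each row's mass on the planted start.
#'
#' @param consensus Planted DNA consensus word (default `TGACTCAT`, a
#'   classic yeast bZIP-family site).
#' @param N Number of sequences (default 200).
#' @param n Length of every sequence in bp (default 500).
#' @param mutations Exact number of substitutions applied to each planted
#'   occurrence (default 2).
#' @param background Base composition of the background, probabilities for
#'   `A,C,G,T` (default uniform).
#' @param prior_concentration Fraction of each prior row's mass placed on
#'   the (jittered) planted start, in `[0, 1]`; the remainder is spread
#'   uniformly (default 0.5).
#' @param prior_noise_sd Gaussian jitter (bp, sd) of the prior peak around
#'   the planted start (default 0: perfectly informative placement).
#' @param n_priors Number of priors to generate (default 1).
#' @param prob_floor Flooring applied to prior entries (see [as_psp()]).
#' @param seed RNG seed; every dataset is fully reproducible from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(consensus = "TGACTCAT", N = 200, n = 500,
                       mutations = 2, background = c(.25, .25, .25, .25),
                       prior_concentration = 0.5, prior_noise_sd = 0,
                       n_priors = 1, prob_floor = 1e-10, seed = 1) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus must be a plain DNA word", call. = FALSE)
  }
  k <- nchar(consensus)
  if (n < k) stop("sequence length n must be >= motif width", call. = FALSE)
  if (mutations < 0 || mutations > k) {
    stop("mutations must lie in [0, k]", call. = FALSE)
  }
  if (length(background) != 4 || any(background < 0) ||
      sum(background) <= 0) {
    stop("background must be 4 non-negative proportions", call. = FALSE)
  }
  if (prior_concentration < 0 || prior_concentration > 1) {
    stop("prior_concentration must lie in [0, 1]", call. = FALSE)
  }
  structure(list(consensus = consensus, k = k, N = as.integer(N),
                 n = as.integer(n), mutations = as.integer(mutations),
                 background = background / sum(background),
                 prior_concentration = prior_concentration,
                 prior_noise_sd = prior_noise_sd,
                 n_priors = as.integer(n_priors),
                 prob_floor = prob_floor, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a planted-motif dataset with priors and ground truth
#'
#' Draws i.i.d. background sequences, plants one occurrence of the consensus
#' (with exactly `mutations` random substitutions) at a uniform random
#' admissible start in each, and builds the requested priors: each prior row
#' mixes a point mass at the (jittered) planted start, weight
#' `prior_concentration`, with a uniform remainder. Identical seeds give
#' byte-identical outputs.
#'
#' @param spec A [synth_spec()].
#' @return A list with `seqs` (sequence-set tibble), `priors` (list of
#'   `psp`), `truth` (tibble: `id`, `start`, `occurrence`), `consensus`, and
#'   `consensus_pssm` (the unsmoothed PSSM of the planted consensus).
#' @export
synth_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  k <- spec$k
  withr::local_seed(spec$seed)

  cons_codes <- encode_dna(spec$consensus)
  seqs_chr <- character(spec$N)
  starts <- integer(spec$N)
  occ <- character(spec$N)
  for (i in seq_len(spec$N)) {
    codes <- sample.int(4L, spec$n, replace = TRUE, prob = spec$background)
    word <- cons_codes
    if (spec$mutations > 0) {
      pos <- sample.int(k, spec$mutations)
      for (p in pos) word[p] <- sample(setdiff(1:4, word[p]), 1L)
    }
    j <- sample.int(spec$n - k + 1L, 1L) - 1L  # 0-based start
    codes[(j + 1):(j + k)] <- word
    seqs_chr[i] <- decode_dna(codes)
    starts[i] <- j
    occ[i] <- decode_dna(word)
  }
  seqs <- seq_set(seqs_chr)
  truth <- tibble(id = seqs$id, start = starts, occurrence = occ)

  nwin <- spec$n - k + 1L
  priors <- lapply(seq_len(spec$n_priors), function(p) {
    rows <- lapply(seq_len(spec$N), function(i) {
      js <- starts[i]
      if (spec$prior_noise_sd > 0) {
        js <- as.integer(round(js + rnorm(1, 0, spec$prior_noise_sd)))
        js <- max(0L, min(nwin - 1L, js))
      }
      prob <- rep((1 - spec$prior_concentration) / nwin, nwin)
      prob[js + 1L] <- prob[js + 1L] + spec$prior_concentration
      tibble(id = seqs$id[i], start = 0:(nwin - 1L), prob = prob)
    })
    as_psp(dplyr::bind_rows(rows), seqs, k,
           name = paste0("planted_", p), prob_floor = spec$prob_floor)
  })

  list(seqs = seqs, priors = priors, truth = truth,
       consensus = spec$consensus,
       consensus_pssm = iupac_to_pssm(spec$consensus, delta = 0))
}

#' Write a synthetic dataset to disk
#'
#' Standard FASTA for the sequences, the package's PSP dialect for each
#' prior, and a ground-truth TSV (`id`, 0-based `start`, planted
#' `occurrence`).
#'
#' @param data A dataset from [synth_dataset()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem (default `"synth"`).
#' @return A character vector of the written paths, invisibly.
#' @export
write_synth_dataset <- function(data, dir, stem = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  write_fasta(data$seqs, fa)
  psps <- character(0)
  for (p in seq_along(data$priors)) {
    pp <- file.path(dir, paste0(stem, "_prior", p, ".psp"))
    write_psp(data$priors[[p]], pp)
    psps <- c(psps, pp)
  }
  tr <- file.path(dir, paste0(stem, "_truth.tsv"))
  utils::write.table(data$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, psps, tr))
}

#' Planted-motif recovery benchmark
#'
#' Runs the full discovery pipeline over a grid of dataset specifications
#' and configuration arms, replicated with derived seeds, and scores every
#' run by the scaled Euclidean distance between the reported motif's PSSM
#' and the planted consensus PSSM. A run is a success when that distance is
#' at most `threshold`.
#'
#' Each configuration is a named list understood by [discover_motif()]
#' (`lambda`, `z`, `e`, `max_degenerate`, ...), plus a `prior_mode` entry
#' selecting the prior arm: `"none"` (no priors), `"uniform"` (the uniform
#' prior), `"first"` / `"second"` (one generated prior alone), or `"all"`
#' (all generated priors combined with uniform weights).
#'
#' @param spec_grid A list of [synth_spec()] objects (or named lists of
#'   overrides applied to the default spec).
#' @param config_grid A list of named configuration lists; an empty list
#'   means one default arm (`prior_mode = "all"`).
#' @param replicates Replicates per (spec, config) cell.
#' @param seed Master seed; replicate `r` of spec `s` runs on a seed derived
#'   deterministically from it.
#' @param threshold Success distance threshold (default 0.25).
#' @return A tibble of class `recovery_benchmark`, one row per run:
#'   `spec_id`, `config_id`, `prior_mode`, `replicate`, `seed`, `motif`,
#'   `distance`, `success`, `bis`, `seconds`.
#' @export
recovery_benchmark <- function(spec_grid = list(synth_spec()),
                               config_grid = list(),
                               replicates = 1, seed = 1, threshold = 0.25) {
  if (length(spec_grid) == 0L || is.null(config_grid)) {
    stop("spec_grid and config_grid must be non-empty", call. = FALSE)
  }
  if (length(config_grid) == 0L) config_grid <- list(list())
  spec_grid <- lapply(spec_grid, function(s) {
    if (inherits(s, "synth_spec")) s
    else do.call(synth_spec, s)
  })
  rows <- list()
  run <- 0L
  for (si in seq_along(spec_grid)) {
    for (r in seq_len(replicates)) {
      data_seed <- (seed + 7919L * si + r) %% .Machine$integer.max
      sp <- spec_grid[[si]]
      sp$seed <- as.integer(data_seed)
      data <- synth_dataset(sp)
      for (ci in seq_along(config_grid)) {
        run <- run + 1L
        cfg <- config_grid[[ci]]
        mode <- cfg$prior_mode %||% "all"
        cfg$prior_mode <- NULL
        priors <- switch(mode,
          none = list(),
          uniform = list(uniform_psp(data$seqs, sp$k,
                                     prob_floor = sp$prob_floor)),
          first = data$priors[1],
          second = data$priors[2],
          all = data$priors,
          stop("unknown prior_mode: ", mode, call. = FALSE))
        args <- c(list(seqs = data$seqs, priors = priors, k = sp$k), cfg)
        t0 <- proc.time()[["elapsed"]]
        fit <- do.call(discover_motif, args)
        secs <- proc.time()[["elapsed"]] - t0
        d <- pssm_distance(iupac_to_pssm(fit$motif, fit$config$delta),
                           data$consensus_pssm)
        rows[[run]] <- tibble(
          spec_id = si, config_id = ci, prior_mode = mode, replicate = r,
          seed = data_seed, motif = fit$motif, distance = d,
          success = d <= threshold, bis = fit$bis, seconds = secs)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_benchmark", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Plot recovery rates of a benchmark run
#'
#' Success proportion per (spec, prior arm) with binomial standard-error
#' bars.
#'
#' @param object A `recovery_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_benchmark <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$spec_id, .data$prior_mode) |>
    dplyr::summarise(rate = mean(.data$success), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(se = sqrt(.data$rate * (1 - .data$rate) / .data$n))
  ggplot2::ggplot(df, ggplot2::aes(.data$prior_mode, .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$rate - .data$se),
                                        ymax = pmin(1, .data$rate + .data$se)),
                           width = 0.2) +
    ggplot2::facet_wrap(~spec_id, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "prior arm", y = "recovery rate",
                  title = "Planted-motif recovery") +
    ggplot2::theme_minimal()
}
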