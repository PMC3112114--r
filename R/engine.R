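# Internal scoring context.
#
# All scoring (annotation, BIS, greedy refinement) runs against a
# precomputed engine: the admissible windows of every sequence as an integer
# matrix, the per-window weighted prior log term, and the 15 x 4 table of
# weighted per-symbol log probabilities. Building it once per (sequences,
# priors, lambda, delta, k) makes repeated motif evaluations cheap.

symbol_logprob_table <- function(delta, lambda = 1) {
  tab <- matrix(NA_real_, 15, 4, dimnames = list(IUPAC_ALPHABET, DNA_BASES))
  for (s in seq_len(15)) {
    set <- IUPAC_SETS[[s]]
    col <- numeric(4)
    if (length(set) == 4L) col[] <- 0.25
    else {
      col[set] <- (1 - delta) / length(set)
      col[-set] <- delta / (4 - length(set))
    }
    tab[s, ] <- log(col)
  }
  lambda * tab
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0 || lambda > 1) {
    stop("lambda must lie in (0, 1]", call. = FALSE)
  }
  lambda
}

resolve_lambda_weights <- function(priors, weights, lambda) {
  ell <- length(priors)
  if (ell == 0L) {
    # lambda plays no role without priors; the score is the plain
    # self-information of the annotated occurrences
    return(list(lambda = 1, weights = numeric(0)))
  }
  if (is.null(weights)) weights <- rep(1, ell)
  if (length(weights) != ell) {
    stop("need one weight per prior (", ell, ")", call. = FALSE)
  }
  list(lambda = check_lambda(lambda %||% 0.5),
       weights = normalize_weights(weights))
}

# forward-strand admissible windows of one encoded sequence
window_matrix <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(matrix(integer(0), 0, k))
  W <- vapply(seq_len(k), function(d) codes[d:(d + n - k)],
              integer(n - k + 1L))
  W <- matrix(W, ncol = k)
  ok <- rowSums(W == 0L) == 0L
  list(W = W[ok, , drop = FALSE], starts = which(ok) - 1L)
}

prior_lookup <- function(prior, seqs, k) {
  if (!inherits(prior, "psp")) {
    stop("priors must be psp objects (see as_psp/read_psp)", call. = FALSE)
  }
  if (attr(prior, "k") != k) {
    stop("prior '", psp_name(prior), "' was built for k = ", attr(prior, "k"),
         ", not k = ", k, call. = FALSE)
  }
  miss <- setdiff(seqs$id, unique(prior$id))
  if (length(miss)) {
    stop("prior '", psp_name(prior), "' lacks sequence id(s): ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  split(prior$prob, factor(prior$id, levels = seqs$id))
}

bis_engine <- function(seqs, k, priors = list(), weights = NULL,
                       lambda = NULL, delta = 0.1, both_strands = FALSE) {
  seqs <- validate_seq_set(seqs, k = k)
  if (inherits(priors, "psp")) priors <- list(priors)
  lw <- resolve_lambda_weights(priors, weights, lambda)
  lam <- lw$lambda

  plook <- lapply(priors, prior_lookup, seqs = seqs, k = k)

  Ws <- vector("list", nrow(seqs))
  starts <- strand <- seqidx <- pv <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    wm <- window_matrix(encode_dna(seqs$seq[i]), k)
    if (nrow(wm$W) == 0L) {
      stop("sequence ", seqs$id[i],
           " has no admissible window (too short or fully masked) for k = ",
           k, call. = FALSE)
    }
    W <- wm$W
    st <- wm$starts
    sd <- rep("+", nrow(W))
    if (both_strands) {
      # interleave forward/reverse rows per start so that ties resolve to
      # the smallest start and then the '+' strand
      Wrc <- 5L - W[, rev(seq_len(k)), drop = FALSE]
      ord <- rep(seq_len(nrow(W)), each = 2L)
      pick <- rep(c(TRUE, FALSE), nrow(W))
      W2 <- matrix(0L, 2L * nrow(W), k)
      W2[pick, ] <- W
      W2[!pick, ] <- Wrc
      W <- W2
      st <- st[ord]
      sd <- rep(c("+", "-"), nrow(Wrc))
    }
    prior_term <- numeric(nrow(W))
    if (length(priors)) {
      for (p in seq_along(priors)) {
        prior_term <- prior_term +
          lw$weights[p] * log(plook[[p]][[i]][st + 1L])
      }
      prior_term <- (1 - lam) * prior_term
    }
    Ws[[i]] <- W
    starts[[i]] <- st
    strand[[i]] <- sd
    seqidx[[i]] <- rep(i, nrow(W))
    pv[[i]] <- prior_term
  }
  W <- do.call(rbind, Ws)
  nper <- vapply(Ws, nrow, integer(1))
  last <- cumsum(nper)
  first <- c(1L, head(last, -1L) + 1L)
  list(W = W,
       start = unlist(starts, use.names = FALSE),
       strand = unlist(strand, use.names = FALSE),
       seq_idx = unlist(seqidx, use.names = FALSE),
       priorvec = unlist(pv, use.names = FALSE),
       first = as.integer(first), last = as.integer(last),
       symlogp = symbol_logprob_table(delta, lam),
       lambda = lam, delta = delta, k = as.integer(k),
       n_priors = length(priors), seqs = seqs,
       both_strands = both_strands)
}

engine_total <- function(engine, motif) {
  sym <- iupac_codes(motif_symbols(motif))
  if (length(sym) != engine$k) {
    stop("motif width ", length(sym), " does not match engine k = ",
         engine$k, call. = FALSE)
  }
  sc <- window_scores_cpp(engine$W, sym, engine$symlogp)
  if (engine$n_priors > 0L) sc <- sc + engine$priorvec
  sc
}

engine_annotate <- function(engine, motif) {
  total <- engine_total(engine, motif)
  a <- annotate_best_cpp(total, engine$first, engine$last)
  idx <- a$idx
  words <- apply(engine$W[idx, , drop = FALSE], 1L, decode_dna)
  tibble(id = engine$seqs$id,
         start = engine$start[idx],
         strand = engine$strand[idx],
         word = words,
         contribution = a$value)
}

engine_bis <- function(engine, motif) {
  total <- engine_total(engine, motif)
  annotate_best_cpp(total, engine$first, engine$last)$bis
}
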