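#' Train a dual-corpus skip-gram embedding
#'
#' Trains one skip-gram-with-negative-sampling model over the concatenation
#' of a benign and an underground corpus, with the input layer doubled: each
#' center token updates the input vector belonging to its corpus (benign rows
#' or underground rows) while the output/context vectors are shared across
#' corpora. Every vocabulary word therefore ends up with two vectors — its
#' benign-context and underground-context embedding — living in one
#' comparable space, which is what makes the cross-corpus jargon query
#' meaningful.
#'
#' Training is single-threaded with an internal deterministic RNG, so the
#' same inputs and seed reproduce the vectors exactly.
#'
#' @param benign,underground Character vectors of sentences (tokens separated
#'   by whitespace).
#' @param d Embedding dimension (default 100).
#' @param window Maximum context window; per-position windows are reduced
#'   uniformly as in standard skip-gram training (default 5).
#' @param negative Negative samples per context pair (default 5), drawn from
#'   the unigram distribution raised to 0.75.
#' @param epochs Training epochs (default 5).
#' @param min_count Words below this total count are dropped (default 5).
#' @param alpha Initial learning rate, linearly decayed (default 0.025).
#' @param seed Integer seed for initialization and sampling.
#' @return A `dual_embedding` object: `vocab`, matrices `V_benign`,
#'   `V_underground`, `output` (one row per word), per-corpus occurrence
#'   counts, mean per-pair training loss by epoch, and the parameters.
#' @export
train_dual_skipgram <- function(benign, underground, d = 100L, window = 5L,
                                negative = 5L, epochs = 5L, min_count = 5L,
                                alpha = 0.025, seed = 1L) {
  if (length(benign) == 0 || length(underground) == 0) {
    abort("both corpora must be nonempty")
  }
  if (d <= 0) abort("embedding dimension d must be positive")
  toks_b <- strsplit(benign, "[[:space:]]+")
  toks_u <- strsplit(underground, "[[:space:]]+")
  all_tok <- c(unlist(toks_b), unlist(toks_u))
  all_tok <- all_tok[nzchar(all_tok)]
  cnt <- table(all_tok)
  # deterministic vocabulary order: frequency desc, then term
  cnt <- cnt[order(-as.integer(cnt), names(cnt))]
  vocab <- names(cnt)[as.integer(cnt) >= min_count]
  if (length(vocab) == 0) abort("no word reaches min_count")
  vidx <- seq_along(vocab)
  names(vidx) <- vocab

  encode <- function(sent_tokens) {
    lapply(sent_tokens, function(t) {
      ids <- vidx[t[nzchar(t)]]
      as.integer(ids[!is.na(ids)]) - 1L
    })
  }
  enc_b <- encode(toks_b)
  enc_u <- encode(toks_u)
  enc <- c(enc_b, enc_u)
  keep <- lengths(enc) > 0
  enc <- enc[keep]
  corp <- c(rep(0L, length(enc_b)), rep(1L, length(enc_u)))[keep]

  counts <- as.integer(cnt[vocab])
  uni <- counts^0.75
  cdf <- cumsum(uni) / sum(uni)

  fit <- sgns_train_dual_cpp(unlist(enc), corp, lengths(enc),
                             length(vocab), as.integer(d),
                             as.integer(window), as.integer(negative),
                             as.integer(epochs), alpha, cdf,
                             as.integer(seed))
  V <- length(vocab)
  cb <- table(factor(unlist(enc[corp == 0]) + 1L, levels = vidx))
  cu <- table(factor(unlist(enc[corp == 1]) + 1L, levels = vidx))
  V_benign <- fit$input[seq_len(V), , drop = FALSE]
  V_underground <- fit$input[V + seq_len(V), , drop = FALSE]
  rownames(V_benign) <- rownames(V_underground) <-
    rownames(fit$output) <- vocab
  structure(list(vocab = vocab, V_benign = V_benign,
                 V_underground = V_underground, output = fit$output,
                 count_benign = as.integer(cb),
                 count_underground = as.integer(cu),
                 epoch_loss = as.numeric(fit$epoch_loss),
                 params = list(d = d, window = window, negative = negative,
                               epochs = epochs, min_count = min_count,
                               alpha = alpha, seed = seed)),
            class = "dual_embedding")
}

#' @exportS3Method base::print
print.dual_embedding <- function(x, ...) {
  cat(sprintf("<dual_embedding> %d words, d = %d (window %d, %d negatives, %d epochs, seed %d)\n",
              length(x$vocab), x$params$d, x$params$window,
              x$params$negative, x$params$epochs, x$params$seed))
  invisible(x)
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Rank underground words by proximity to seed keywords
#'
#' The jargon query: every eligible vocabulary word is scored by the maximum
#' cosine similarity between its underground-context vector and the
#' benign-context vectors of the seed opioid keywords, and the top `k`
#' candidates are returned in descending score order (ties broken
#' lexicographically). Words never observed in the underground corpus are
#' excluded (their underground vector is untrained), as are the seeds
#' themselves. With `pos_filter = TRUE` the ranking is restricted to
#' `proper_nouns` — a POS tagger's proper-noun set for natural text, or the
#' token-class marker of the synthetic generator.
#'
#' @param emb A [train_dual_skipgram()] fit.
#' @param seeds Character vector of seed keywords; seeds missing from the
#'   vocabulary (or unseen in the benign corpus) are skipped with a warning.
#' @param k Number of candidates (default 100, the conventional shortlist
#'   size for manual validation).
#' @param pos_filter Restrict candidates to `proper_nouns`?
#' @param proper_nouns Character vector of proper-noun tokens (required when
#'   `pos_filter` is `TRUE`; still annotated on the output otherwise).
#' @return Tibble of `JargonCandidate`s: `term`, `score`, `nearest_seed`,
#'   `is_proper_noun`, sorted by descending score.
#' @export
query_jargon <- function(emb, seeds, k = 100L, pos_filter = FALSE,
                         proper_nouns = NULL) {
  stopifnot(inherits(emb, "dual_embedding"), k >= 1)
  seeds <- normalize_term(seeds)
  ok <- seeds %in% emb$vocab & emb$count_benign[match(seeds, emb$vocab)] > 0
  if (any(!ok)) {
    warn(sprintf("skipping %d seed(s) absent from the benign vocabulary: %s",
                 sum(!ok), paste(head(seeds[!ok], 5), collapse = ", ")))
  }
  seeds_in <- seeds[ok]
  if (length(seeds_in) == 0) abort("no seed keyword found in the vocabulary")
  eligible <- emb$vocab[emb$count_underground > 0]
  eligible <- setdiff(eligible, seeds)
  if (pos_filter) {
    if (is.null(proper_nouns)) {
      abort("pos_filter = TRUE requires `proper_nouns`")
    }
    eligible <- intersect(eligible, proper_nouns)
  }
  if (length(eligible) == 0) abort("no eligible candidate word")
  if (k > length(eligible)) {
    warn(sprintf("k = %d exceeds the %d eligible words; returning all", k,
                 length(eligible)))
    k <- length(eligible)
  }
  U <- row_normalize(emb$V_underground[eligible, , drop = FALSE])
  B <- row_normalize(emb$V_benign[seeds_in, , drop = FALSE])
  S <- U %*% t(B)
  best <- max.col(S, ties.method = "first")
  score <- S[cbind(seq_len(nrow(S)), best)]
  out <- tibble::tibble(term = eligible, score = as.numeric(score),
                        nearest_seed = seeds_in[best],
                        is_proper_noun = if (is.null(proper_nouns)) NA else
                          eligible %in% proper_nouns)
  out <- out[order(-out$score, out$term), ]
  out[seq_len(k), ]
}
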