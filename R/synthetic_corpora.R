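# Zipf-like weights over the background vocabulary (Mandelbrot shift 2.7).
zipf_weights <- function(n) {
  w <- 1 / (seq_len(n) + 2.7)
  w / sum(w)
}

# Seed keywords for the corpus generator: deterministic single-token terms
# from the packaged lexicon, so seeds are genuine opioid keywords whose
# benign-context vectors anchor the jargon query.
corpus_seed_terms <- function(n) {
  lex <- load_opioid_lexicon()
  single <- lex[!grepl(" ", lex$term) & grepl("^[a-z]+$", lex$term), ]
  if (n > nrow(single)) abort("not enough single-token lexicon terms for seeds")
  single <- dplyr::arrange(single, .data$term)
  idx <- round(seq(1, nrow(single), length.out = n))
  single[idx, c("term", "category")]
}

#' Generate paired benign/underground corpora with planted jargon
#'
#' Emulates the two-register setting of dual-corpus jargon discovery with a
#' topic-mixture language model. Each seed keyword owns a "topic": a disjoint
#' block of context words with geometric weights. In the benign register the
#' seed keywords appear surrounded by draws from their topic; in the
#' underground register each planted jargon term shadows one seed keyword and
#' draws its context from a mixture `overlap * topic + (1 - overlap) *
#' background`, while decoy proper nouns carry their own unrelated topics.
#' Both registers share a large Zipf-distributed background so output vectors
#' train on common ground.
#'
#' @param config A [generator_config()].
#' @return List with `benign` and `underground` (character vectors, one
#'   sentence per element, tokens space-separated) and `truth`: `planted`
#'   (term, shadowed seed, category), `decoys`, and `proper_nouns` (the
#'   token-class marker the generator emits in place of a POS tagger).
#' @export
gen_dual_corpora <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    V <- config$vocab_size
    vocab <- sprintf("w%04d", seq_len(V))
    wz <- zipf_weights(V)
    seeds <- corpus_seed_terms(config$n_seeds)
    planted <- tibble::tibble(
      term = sprintf("jarg%02d", seq_len(config$n_planted)),
      seed = seeds$term[seq_len(config$n_planted)],
      category = seeds$category[seq_len(config$n_planted)])
    decoys <- sprintf("decoy%02d", seq_len(config$n_decoys))

    # seed topics get disjoint word blocks; decoy topics draw from the
    # remaining vocabulary (mutually overlapping is fine — they only need to
    # be unrelated to every seed topic)
    need <- config$n_seeds * config$topic_words
    if (need >= V) abort("vocab too small for the requested topic blocks")
    shuffled <- sample(vocab)
    blocks <- split(shuffled[seq_len(need)],
                    rep(seq_len(config$n_seeds), each = config$topic_words))
    rest <- shuffled[(need + 1):V]
    for (d in seq_len(config$n_decoys)) {
      blocks[[config$n_seeds + d]] <-
        sample(rest, min(config$topic_words, length(rest)))
    }
    tw <- 0.9^(seq_len(config$topic_words) - 1)
    tw <- tw / sum(tw)

    bg_sentence <- function() {
      paste(sample(vocab, config$sentence_length, replace = TRUE, prob = wz),
            collapse = " ")
    }
    focal_sentence <- function(term, topic, a) {
      k <- config$context_size
      from_topic <- runif(k) < a
      ctx <- character(k)
      ctx[from_topic] <- sample(blocks[[topic]], sum(from_topic),
                                replace = TRUE, prob = tw)
      ctx[!from_topic] <- sample(vocab, sum(!from_topic), replace = TRUE,
                                 prob = wz)
      mid <- k %/% 2
      paste(c(ctx[seq_len(mid)], term, ctx[(mid + 1):k]), collapse = " ")
    }

    benign <- c(
      vapply(seq_len(config$background_sentences), function(i) bg_sentence(),
             character(1)),
      unlist(lapply(seq_len(config$n_seeds), function(s) {
        vapply(seq_len(config$focal_sentences), function(i) {
          focal_sentence(seeds$term[[s]], s, 0.95)
        }, character(1))
      }))
    )
    benign <- sample(benign)

    underground <- c(
      vapply(seq_len(config$background_sentences), function(i) bg_sentence(),
             character(1)),
      unlist(lapply(seq_len(config$n_planted), function(p) {
        vapply(seq_len(config$focal_sentences), function(i) {
          focal_sentence(planted$term[[p]], p, config$overlap)
        }, character(1))
      })),
      unlist(lapply(seq_len(config$n_decoys), function(d) {
        vapply(seq_len(config$decoy_sentences), function(i) {
          focal_sentence(decoys[[d]], config$n_seeds + d, 0.9)
        }, character(1))
      }))
    )
    underground <- sample(underground)

    list(benign = benign, underground = underground,
         truth = list(planted = planted,
                      decoys = tibble::tibble(term = decoys),
                      proper_nouns = c(planted$term, decoys),
                      seeds = seeds))
  })
}
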