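# Register-specific word pools for the forum-post generator. Tiny by design:
# posts are bags of register words, not fluent prose.
.pool <- list(
  promo = c("sale", "bulk", "stealth", "shipping", "discount", "grade",
            "quality", "pure", "uncut", "fresh", "stock", "order", "listing",
            "price", "gram", "deal", "free", "express", "vacuum", "sealed",
            "lab", "tested", "supply", "wholesale", "reship", "tracking",
            "dispatch", "premium", "batch", "direct", "restock", "promo",
            "intro", "offer", "samples", "finest", "potent", "pressed",
            "capsules", "powder", "crystals", "resin", "import", "domestic",
            "overnight", "priority", "decoy", "moneyback", "refund",
            "guarantee", "unbeatable", "cheapest", "kilo", "ounce", "qp",
            "zip", "eighth", "fire", "loud", "gas"),
  review_common = c("ordered", "vendor", "package", "delivery", "days",
                    "review", "received", "product", "experience",
                    "customer", "communication", "packaging", "weight",
                    "reorder", "feedback", "rating", "transaction", "parcel",
                    "envelope", "postmark"),
  review_pos = c("great", "good", "fast", "legit", "perfect", "smooth",
                 "arrived", "recommend", "excellent", "quick", "trusted",
                 "awesome", "happy", "clean", "solid", "flawless", "superb",
                 "generous", "professional", "responsive", "accurate",
                 "reliable", "stellar", "impressed", "satisfied"),
  review_neg = c("scam", "fake", "slow", "bad", "never", "late", "selective",
                 "ripoff", "warning", "avoid", "junk", "weak", "bunk",
                 "disappointed", "missing", "shorted", "ignored", "stale",
                 "cut", "garbage", "useless", "unresponsive", "blacklist",
                 "dispute", "refused"),
  qa = c("question", "how", "what", "anyone", "help", "advice", "thread",
         "forum", "account", "wallet", "bitcoin", "login", "mirror", "link",
         "guide", "newbie", "safety", "tor", "pgp", "market", "answer",
         "thanks", "info", "tips", "please", "tutorial", "verify", "monero",
         "address", "deposit", "withdraw", "vpn", "tails", "opsec", "dox",
         "phishing", "captcha", "registration", "username", "password",
         "multisig", "finalize", "dispute", "mod", "admin", "banned",
         "rules", "sticky", "faq", "search"),
  background = c("the", "a", "and", "to", "of", "in", "for", "on", "with",
                 "is", "it", "this", "that", "was", "but", "not", "have",
                 "you", "my", "me", "so", "at", "just", "all", "from")
)

.geo_phrase_countries <- c("usa", "uk", "germany", "netherlands", "canada",
                           "france", "australia")

# One synthetic post body. `register` controls the vocabulary; `noise`
# replaces register draws with background words and `confusion` with draws
# from the other registers, making the desk-scale task imperfectly
# separable; price and ship-from phrases appear with register-dependent
# probability rather than deterministically.
synth_post_body <- function(register = c("promotion", "review", "other"),
                            noise, lexicon_terms, length_range = c(10, 20),
                            sentiment = NA_character_,
                            vendor = NA_character_,
                            term_prob = 1, confusion = 0) {
  register <- match.arg(register)
  n <- sample(length_range[[1]]:length_range[[2]], 1)
  words <- switch(register,
    promotion = .pool$promo,
    review = c(.pool$review_common,
               if (identical(sentiment, "positive")) .pool$review_pos
               else if (identical(sentiment, "negative")) .pool$review_neg
               else c(.pool$review_pos, .pool$review_neg)),
    other = .pool$qa)
  other_words <- switch(register,
    promotion = c(.pool$review_common, .pool$qa),
    review = c(.pool$promo, .pool$qa),
    other = c(.pool$promo, .pool$review_common))
  toks <- sample(words, n, replace = TRUE)
  mixed <- runif(n) < confusion
  toks[mixed] <- sample(other_words, sum(mixed), replace = TRUE)
  noisy <- runif(n) < noise
  toks[noisy] <- sample(.pool$background, sum(noisy), replace = TRUE)
  if (runif(1) < term_prob) {
    toks <- append(toks, sample(lexicon_terms, 1), after = sample(n, 1) - 1)
  }
  p_ship <- switch(register, promotion = 0.6, review = 0.1, other = 0.05)
  p_price <- switch(register, promotion = 0.6, review = 0.15, other = 0.05)
  if (runif(1) < p_ship) {
    toks <- append(toks, c("ships", "from", sample(.geo_phrase_countries, 1)),
                   after = sample(length(toks), 1) - 1)
  }
  if (runif(1) < p_price) {
    toks <- append(toks, c(sprintf("$%d", sample(10:900, 1)), "per", "gram"))
  }
  if (register == "review" && !is.na(vendor)) {
    toks <- append(toks, c("ordered", "from", vendor), after = 0)
  }
  paste(toks, collapse = " ")
}

#' Generate synthetic forum posts with topic and sentiment ground truth
#'
#' Emits three disjoint sets mirroring the three training stages of the topic
#' classifier: (1) proxy-initialization corpora — promotion-like listing
#' descriptions vs review-like vs Q&A-like text at roughly 1% of full-scale
#' sizes; (2) a small labeled transfer set, by default 800 positive and 800
#' negative posts per topic; (3) an unlabeled evaluation pool whose class mix
#' follows `config$topic_mix` (heavily imbalanced toward "other" by default).
#' Promotion and review posts embed opioid lexicon terms, prices and
#' ship-from phrases; review posts carry a latent positive/negative sentiment
#' expressed through register vocabulary and name the vendor they review.
#'
#' @param config A [generator_config()].
#' @return List with `proxy_promotion`, `proxy_review` (each `list(pos, neg)`
#'   of plain documents), `labeled` (`list(promotion, review)` tibbles with
#'   `post_id`, `body`, `label`), `pool` (tibble of unlabeled forum posts),
#'   and `truth` (`topic_labels`, `sentiment_labels`, `review_vendor`).
#' @export
gen_posts <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lex <- load_opioid_lexicon()
  forums <- dplyr::filter(load_markets(), .data$kind == "forum")
  with_seed(config$seed + 101L, {
    terms <- lex$term
    vendors <- sprintf("vendor_%03d", seq_len(config$n_vendors))

    proxy_doc <- function(register, sentiment = NA_character_) {
      synth_post_body(register, config$proxy_noise, terms,
                      length_range = c(20, 40), sentiment = sentiment,
                      term_prob = if (register == "other") 0.1 else 1,
                      confusion = config$proxy_confusion)
    }
    proxy_promotion <- list(
      pos = vapply(seq_len(config$proxy_promotion_pos),
                   function(i) proxy_doc("promotion"), character(1)),
      neg = vapply(seq_len(config$proxy_promotion_neg), function(i) {
        proxy_doc(if (i %% 2 == 0) "review" else "other")
      }, character(1)))
    proxy_review <- list(
      pos = vapply(seq_len(config$proxy_review_pos),
                   function(i) proxy_doc("review"), character(1)),
      neg = vapply(seq_len(config$proxy_review_neg),
                   function(i) proxy_doc("other"), character(1)))

    make_posts <- function(registers, prefix) {
      n <- length(registers)
      sentiments <- ifelse(
        registers == "review",
        ifelse(runif(n) < config$sentiment_positive_share, "positive",
               "negative"),
        NA_character_)
      vendor <- ifelse(registers == "review", sample(vendors, n, TRUE),
                       NA_character_)
      body <- vapply(seq_len(n), function(i) {
        synth_post_body(registers[[i]], config$post_noise, terms,
                        length_range = c(8, 16),
                        sentiment = sentiments[[i]], vendor = vendor[[i]],
                        term_prob = switch(registers[[i]], promotion = 1,
                                           review = 0.9, other = 0.15),
                        confusion = config$post_confusion)
      }, character(1))
      fi <- sample(nrow(forums), n, replace = TRUE)
      span <- as.integer(forums$measurement_end[fi] -
                           forums$measurement_start[fi])
      tibble::tibble(
        post_id = sprintf("%s%05d", prefix, seq_len(n)),
        forum = forums$name[fi],
        author = sprintf("buyer_%04d", sample(500, n, TRUE)),
        body = body,
        posted_at = forums$measurement_start[fi] +
          floor(runif(n) * (span + 1)),
        topic_label = registers,
        sentiment_label = sentiments,
        vendor = vendor)
    }

    labeled <- list()
    for (topic in c("promotion", "review")) {
      neg_regs <- setdiff(c("promotion", "review", "other"), topic)
      regs <- c(rep(topic, config$labeled_pos),
                sample(neg_regs, config$labeled_neg, replace = TRUE))
      posts <- make_posts(regs, paste0("lab_", substr(topic, 1, 4), "_"))
      posts$label <- as.integer(posts$topic_label == topic)
      labeled[[topic]] <- posts
    }

    pool_regs <- sample(names(config$topic_mix), config$pool_size,
                        replace = TRUE, prob = config$topic_mix)
    pool <- make_posts(pool_regs, "pool_")

    truth_posts <- dplyr::bind_rows(labeled$promotion, labeled$review, pool)
    truth <- list(
      topic_labels = truth_posts[, c("post_id", "topic_label")],
      sentiment_labels = truth_posts[!is.na(truth_posts$sentiment_label),
                                     c("post_id", "sentiment_label")],
      review_vendor = truth_posts[!is.na(truth_posts$vendor),
                                  c("post_id", "vendor")])
    pool$topic_label <- NULL
    pool$sentiment_label <- NULL
    pool$vendor <- NULL
    labeled <- lapply(labeled, function(df) {
      df[, c("post_id", "forum", "author", "body", "posted_at", "label")]
    })
    list(proxy_promotion = proxy_promotion, proxy_review = proxy_review,
         labeled = labeled, pool = pool, truth = truth)
  })
}
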