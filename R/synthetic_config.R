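#' Configuration for the synthetic-data generator
#'
#' One seeded configuration object drives every generator stage. Defaults are
#' the package's desk-scale study conditions: paired ~250k-token corpora over
#' a 5000-word vocabulary with 10 planted jargon terms at context-overlap 0.8;
#' forum-post sets with an 800 + 800 labeled transfer set per topic and proxy
#' corpora at about 1% of the full-scale initialization sets; 2000 marketplace
#' listings over the packaged market lifespans with a 5% injected price
#' outlier rate; and 12 planted supplier migrations.
#'
#' @param seed Integer seed; every stage derives its randomness from it.
#' @param ... Named overrides of the defaults listed below; unknown names
#'   error.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # dual corpora
    vocab_size = 5000L,
    n_seeds = 20L,
    n_planted = 10L,
    n_decoys = 200L,
    overlap = 0.8,
    background_sentences = 13000L,
    sentence_length = 12L,
    focal_sentences = 250L,
    decoy_sentences = 60L,
    context_size = 10L,
    topic_words = 40L,
    # forum posts
    proxy_promotion_pos = 600L,
    proxy_promotion_neg = 600L,
    proxy_review_pos = 1000L,
    proxy_review_neg = 1000L,
    labeled_pos = 800L,
    labeled_neg = 800L,
    pool_size = 1500L,
    topic_mix = c(promotion = 0.1, review = 0.1, other = 0.8),
    proxy_noise = 0.15,
    proxy_confusion = 0.1,
    post_noise = 0.5,
    post_confusion = 0.25,
    sentiment_positive_share = 0.6,
    # listings / vendors
    n_listings = 2000L,
    n_vendors = 150L,
    outlier_rate = 0.05,
    amount_unparseable_rate = 0.03,
    jargon_term_share = 0.25,
    n_duplicate_groups = 25L,
    cross_market_rate = 0.2,
    n_migrations = 12L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown generator_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$overlap < 0 || cfg$overlap > 1) {
    abort("context-overlap strength must lie in [0, 1]")
  }
  if (cfg$outlier_rate >= 0.5) {
    abort("outlier_rate must be < 0.5 (the clean mass must own the median)")
  }
  if (cfg$outlier_rate < 0) abort("outlier_rate must be nonnegative")
  if (abs(sum(cfg$topic_mix) - 1) > 1e-8) {
    abort("topic_mix proportions must sum to 1")
  }
  counts <- c("vocab_size", "n_seeds", "n_planted", "n_decoys",
              "background_sentences", "sentence_length", "focal_sentences",
              "decoy_sentences", "context_size", "topic_words",
              "proxy_promotion_pos", "proxy_promotion_neg",
              "proxy_review_pos", "proxy_review_neg", "labeled_pos",
              "labeled_neg", "pool_size", "n_listings", "n_vendors")
  for (nm in counts) {
    if (cfg[[nm]] <= 0) abort(sprintf("%s must be positive", nm))
  }
  if (cfg$n_planted > cfg$n_seeds) {
    abort("n_planted cannot exceed n_seeds (each planted term shadows a seed)")
  }
  structure(cfg, class = "generator_config")
}
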