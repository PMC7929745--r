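# Small generator configurations for fast unit tests; acceptance tests use
# the package defaults.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    vocab_size = 400L, n_seeds = 5L, n_planted = 3L, n_decoys = 5L,
    background_sentences = 300L, focal_sentences = 40L, decoy_sentences = 20L,
    proxy_promotion_pos = 60L, proxy_promotion_neg = 60L,
    proxy_review_pos = 60L, proxy_review_neg = 60L,
    labeled_pos = 60L, labeled_neg = 60L, pool_size = 120L,
    n_listings = 400L, n_vendors = 40L, n_duplicate_groups = 5L,
    n_migrations = 4L)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(generator_config, c(list(seed = seed), defaults))
}

tiny_topic_params <- function(seed = 1L, ...) {
  defaults <- list(hidden = c(16, 8, 4), vocab_size = 1500L, epochs = 10L,
                   lr = 0.5, seed = seed)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(topic_params, defaults)
}
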