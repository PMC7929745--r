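# Reproducible study-scale experiments: each runs the full protocol for one
# pipeline claim and returns the measured quantities. These back the
# package's acceptance checks and the worked examples in the documentation.

#' Planted-jargon recovery at study scale
#'
#' For each seed, generates the paired corpora at the configured conditions
#' (by default a 5000-word vocabulary, ~500k tokens, context-overlap 0.8),
#' trains the dual-corpus skip-gram at its defaults, queries the top
#' `k` proper-noun candidates against the seed keywords, and measures the
#' fraction of planted jargon terms recovered.
#'
#' @param seeds Integer vector of generator/training seeds.
#' @param k Candidate-list size (default 100).
#' @param config_args Named overrides for [generator_config()].
#' @param d,epochs Skip-gram dimension and epochs (defaults 100 and 5).
#' @return Tibble with one row per seed (`seed`, `recovery`) plus the mean
#'   recovery as attribute `mean_recovery`.
#' @export
evaluate_jargon_recovery <- function(seeds = 1:5, k = 100L,
                                     config_args = list(), d = 100L,
                                     epochs = 5L) {
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(generator_config, c(list(seed = s), config_args))
    co <- gen_dual_corpora(cfg)
    emb <- train_dual_skipgram(co$benign, co$underground, d = d,
                               epochs = epochs, seed = s)
    cand <- query_jargon(emb, co$truth$seeds$term, k = k, pos_filter = TRUE,
                         proper_nouns = co$truth$proper_nouns)
    tibble::tibble(seed = s,
                   recovery = mean(co$truth$planted$term %in% cand$term))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_recovery") <- mean(out$recovery)
  out
}

#' Transfer-learning benefit under cross-validation
#'
#' The model-comparison protocol of the topic classifier: per seed, posts
#' are generated at the configured conditions, the network is initialized on
#' the proxy corpora once, and stratified 10-fold cross-validation on the
#' labeled transfer set compares (a) the refined transfer model (transfer
#' stage plus two audit-refinement iterations against the unlabeled pool)
#' with (b) the no-transfer baseline — the identical architecture trained
#' directly on the labeled folds with the same total epoch budget. Reported
#' as mean precision and recall per arm.
#'
#' @param seeds Integer vector of seeds.
#' @param topic `"promotion"` (default) or `"review"`.
#' @param folds Cross-validation folds (default 10).
#' @param config_args Named overrides for [generator_config()].
#' @param hidden,vocab_size Network width and feature cap for the desk-scale
#'   run.
#' @param transfer_epochs,refine_epochs,refine_iterations,init_epochs Stage
#'   epoch budgets; the baseline gets
#'   `transfer_epochs + refine_iterations * refine_epochs` epochs.
#' @return Tibble with one row per seed and arm
#'   (`seed`, `model`, `precision`, `recall`); the across-seed means are in
#'   attribute `means`.
#' @export
evaluate_transfer_benefit <- function(seeds = 1:5, topic = "promotion",
                                      folds = 10L, config_args = list(),
                                      hidden = c(48, 24, 12),
                                      vocab_size = 4000L,
                                      transfer_epochs = 10L,
                                      refine_epochs = 3L,
                                      refine_iterations = 2L,
                                      init_epochs = 10L) {
  topic <- match.arg(topic, c("promotion", "review"))
  base_epochs <- transfer_epochs + refine_iterations * refine_epochs
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(generator_config, c(list(seed = s), config_args))
    po <- gen_posts(cfg)
    lab <- po$labeled[[topic]]
    truth <- po$truth$topic_labels
    pool_lab <- truth$topic_label[match(po$pool$post_id, truth$post_id)]
    proxy <- po[[paste0("proxy_", topic)]]
    init <- train_initial(proxy$pos, proxy$neg,
                          topic_params(hidden = hidden,
                                       vocab_size = vocab_size,
                                       epochs = init_epochs, seed = s))
    ours <- function(d, l) {
      st <- transfer(init, d[l == 1], d[l == 0], epochs = transfer_epochs)
      st <- refine(st, po$pool$body,
                   function(idx) pool_lab[idx] == topic,
                   iterations = refine_iterations, epochs = refine_epochs)
      function(nd) predict_topic(st, nd)
    }
    baseline <- function(d, l) {
      st <- train_initial(d[l == 1], d[l == 0],
                          topic_params(hidden = hidden,
                                       vocab_size = vocab_size,
                                       epochs = base_epochs, seed = s))
      function(nd) predict_topic(st, nd)
    }
    cv_o <- evaluate_cv(ours, lab$body, lab$label, folds = folds, seed = s)
    cv_b <- evaluate_cv(baseline, lab$body, lab$label, folds = folds,
                        seed = s)
    take <- function(cv, model) {
      tibble::tibble(
        seed = s, model = model,
        precision = cv$summary$mean[cv$summary$metric == "precision"],
        recall = cv$summary$mean[cv$summary$metric == "recall"])
    }
    dplyr::bind_rows(take(cv_o, "transfer_refined"),
                     take(cv_b, "baseline"))
  })
  out <- dplyr::bind_rows(rows)
  means <- out |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(precision = mean(.data$precision),
                     recall = mean(.data$recall), .groups = "drop")
  attr(out, "means") <- means
  out
}

#' Exact recovery of injected price outliers
#'
#' Generates seeded listing sets at a given injection rate and checks that
#' the 5x / 0.25x median filter removes exactly the injected outlier set in
#' every category-year group.
#'
#' @param seeds Integer vector of seeds.
#' @param outlier_rate Injection rate (default 0.3).
#' @param config_args Extra overrides for [generator_config()].
#' @return Tibble per seed: number of injected and removed outliers and
#'   whether the sets match exactly.
#' @export
evaluate_outlier_recovery <- function(seeds = 1:20, outlier_rate = 0.3,
                                      config_args = list()) {
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(generator_config,
                   c(list(seed = s, outlier_rate = outlier_rate),
                     config_args))
    li <- gen_listings(cfg)
    tr <- li$truth$listings
    rec <- tr[!is.na(tr$grams), ]
    yr <- format(li$listings$first_seen[match(rec$listing_id,
                                              li$listings$listing_id)],
                 "%Y")
    f <- filter_price_outliers(rec$per_gram, paste(rec$category, yr))
    tibble::tibble(seed = s, n_injected = sum(rec$outlier),
                   n_removed = sum(!f$kept),
                   exact = identical(!f$kept, rec$outlier))
  })
  dplyr::bind_rows(rows)
}

#' Per-property extraction accuracy at study scale
#'
#' Generates a listing set, runs the full property extractors and scores
#' them against ground truth, mirroring the manual-annotation accuracy
#' protocol (default 1000 sampled listings per property).
#'
#' @param seed Generator seed.
#' @param n_listings Listings generated (default 2000).
#' @param n_sample Records sampled per property (default 1000).
#' @return The accuracy tibble of [evaluate_extraction()].
#' @export
evaluate_extraction_at_scale <- function(seed = 1L, n_listings = 2000L,
                                         n_sample = 1000L) {
  cfg <- generator_config(seed = seed, n_listings = n_listings)
  li <- gen_listings(cfg)
  rec <- extract_records(li$listings, load_opioid_lexicon())
  evaluate_extraction(rec, li$truth$listings, n_sample = n_sample,
                      seed = seed)
}
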