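# End-to-end orchestration: synthetic data -> jargon discovery -> topic
# classification -> information extraction -> supply-chain analytics, all
# driven by one seeded configuration.

#' Pipeline configuration
#'
#' Desk-scale defaults chosen so the full demonstration run finishes in a
#' few minutes on one CPU; every stage can be toggled and every module
#' parameter overridden. Unknown keys error by name.
#'
#' @param seed Master seed, propagated to every stochastic stage.
#' @param out_dir Optional directory for stage outputs (JSON-lines records,
#'   TSV reports); nothing is written when `NULL`.
#' @param stages Character subset of
#'   `c("synth", "jargon", "topic", "extract", "analyze")`.
#' @param generator Named overrides for [generator_config()].
#' @param jargon Named overrides: `d`, `window`, `negative`, `epochs`,
#'   `min_count`, `k`.
#' @param topic Named overrides for [topic_params()] plus `transfer_epochs`,
#'   `refine_epochs`, `refine_iterations`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            stages = c("synth", "jargon", "topic", "extract",
                                       "analyze"),
                            generator = list(), jargon = list(),
                            topic = list()) {
  known <- c("synth", "jargon", "topic", "extract", "analyze")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  jargon_defaults <- list(d = 50L, window = 5L, negative = 5L, epochs = 3L,
                          min_count = 5L, k = 50L)
  bad <- setdiff(names(jargon), names(jargon_defaults))
  if (length(bad)) {
    abort(sprintf("unknown jargon key(s): %s", paste(bad, collapse = ", ")))
  }
  jargon_defaults[names(jargon)] <- jargon
  topic_defaults <- list(hidden = c(32, 16, 8), vocab_size = 4000L,
                         ngram_max = 2L, epochs = 15L, batch = 64L,
                         lr = 0.5, lambda = 1e-4, tol = 1e-4,
                         transfer_epochs = 15L, refine_epochs = 5L,
                         refine_iterations = 2L)
  bad <- setdiff(names(topic), names(topic_defaults))
  if (length(bad)) {
    abort(sprintf("unknown topic key(s): %s", paste(bad, collapse = ", ")))
  }
  topic_defaults[names(topic)] <- topic
  gen_scaled <- list(vocab_size = 1500L, n_seeds = 12L, n_planted = 6L,
                     n_decoys = 60L, background_sentences = 3000L,
                     focal_sentences = 120L, decoy_sentences = 40L,
                     proxy_promotion_pos = 300L, proxy_promotion_neg = 300L,
                     proxy_review_pos = 300L, proxy_review_neg = 300L,
                     labeled_pos = 250L, labeled_neg = 250L,
                     pool_size = 600L, n_listings = 1200L)
  gen_scaled[names(generator)] <- generator
  # validate generator overrides eagerly (unknown keys, invalid rates)
  do.call(generator_config, c(list(seed = as.integer(seed)), gen_scaled))
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 generator = gen_scaled, jargon = jargon_defaults,
                 topic = topic_defaults),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_pipeline_config()`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order and returns a run
#' manifest: per-stage outputs, counters and seeds, sufficient to re-run any
#' stage identically. Stage outputs are additionally written under
#' `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_manifest` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  gen <- do.call(generator_config, c(list(seed = config$seed),
                                     config$generator))
  lexicon <- load_opioid_lexicon()
  manifest <- list(seed = config$seed, stages = list(),
                   config = unclass(config))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  data <- NULL
  if ("synth" %in% config$stages) {
    data <- run_stage("synth", function() {
      corpora <- gen_dual_corpora(gen)
      posts <- gen_posts(gen)
      listings <- gen_listings(gen)
      if (!is.null(out)) {
        write_listings(listings$listings, file.path(out, "listings.jsonl"))
        write_posts(posts$pool, file.path(out, "posts.jsonl"))
        writeLines(corpora$benign, file.path(out, "corpus_benign.txt"))
        writeLines(corpora$underground,
                   file.path(out, "corpus_underground.txt"))
      }
      list(corpora = corpora, posts = posts, listings = listings)
    })
    manifest$stages$synth <- list(
      n_benign_sentences = length(data$corpora$benign),
      n_underground_sentences = length(data$corpora$underground),
      n_listings = nrow(data$listings$listings),
      n_pool_posts = nrow(data$posts$pool))
  }

  if ("jargon" %in% config$stages) {
    if (is.null(data)) abort("jargon stage requires the synth stage")
    jg <- config$jargon
    res <- run_stage("jargon", function() {
      emb <- train_dual_skipgram(data$corpora$benign,
                                 data$corpora$underground,
                                 d = jg$d, window = jg$window,
                                 negative = jg$negative, epochs = jg$epochs,
                                 min_count = jg$min_count,
                                 seed = config$seed)
      seeds <- data$corpora$truth$seeds$term
      cand <- query_jargon(emb, seeds, k = jg$k, pos_filter = TRUE,
                           proper_nouns = data$corpora$truth$proper_nouns)
      planted <- data$corpora$truth$planted
      recovered <- cand$term[cand$term %in% planted$term]
      accepted <- tibble::tibble(
        term = recovered,
        category = planted$category[match(recovered, planted$term)])
      list(embedding = emb, candidates = cand,
           lexicon = expand_lexicon(lexicon, accepted),
           recovery_rate = nrow(accepted) / nrow(planted))
    })
    if (!is.null(out)) {
      write.table(res$candidates, file.path(out, "jargon_candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$jargon <- list(
      vocab = length(res$embedding$vocab),
      recovery_rate = res$recovery_rate,
      n_candidates = nrow(res$candidates))
    data$jargon <- res
  }

  if ("topic" %in% config$stages) {
    if (is.null(data)) abort("topic stage requires the synth stage")
    tp <- config$topic
    res <- run_stage("topic", function() {
      params <- topic_params(hidden = tp$hidden, vocab_size = tp$vocab_size,
                             ngram_max = tp$ngram_max, epochs = tp$epochs,
                             batch = tp$batch, lr = tp$lr,
                             lambda = tp$lambda, tol = tp$tol,
                             seed = config$seed)
      truth <- data$posts$truth$topic_labels
      states <- list()
      for (topic_name in c("promotion", "review")) {
        proxy <- data$posts[[paste0("proxy_", topic_name)]]
        lab <- data$posts$labeled[[topic_name]]
        st <- train_initial(proxy$pos, proxy$neg, params)
        st <- transfer(st, lab$body[lab$label == 1],
                       lab$body[lab$label == 0],
                       epochs = tp$transfer_epochs)
        pool_truth <- truth$topic_label[match(data$posts$pool$post_id,
                                              truth$post_id)]
        oracle <- function(idx) pool_truth[idx] == topic_name
        st <- refine(st, data$posts$pool$body, oracle,
                     iterations = tp$refine_iterations,
                     epochs = tp$refine_epochs)
        states[[topic_name]] <- st
      }
      labeled_pool <- classify_posts(states, data$posts$pool, lexicon)
      acc <- mean(labeled_pool$topic ==
                    truth$topic_label[match(labeled_pool$post_id,
                                            truth$post_id)])
      list(states = states, pool_labeled = labeled_pool,
           pool_accuracy = acc)
    })
    manifest$stages$topic <- list(
      pool_accuracy = res$pool_accuracy,
      n_promotion = sum(res$pool_labeled$topic == "promotion"),
      n_review = sum(res$pool_labeled$topic == "review"))
    data$topic <- res
  }

  if ("extract" %in% config$stages) {
    if (is.null(data)) abort("extract stage requires the synth stage")
    res <- run_stage("extract", function() {
      lex_use <- if (!is.null(data$jargon)) data$jargon$lexicon else lexicon
      records <- extract_records(data$listings$listings, lex_use)
      flt <- filter_price_outliers(records$per_gram,
                                   paste(records$category, records$year))
      records$kept <- flt$kept
      accuracy <- evaluate_extraction(records, data$listings$truth$listings,
                                      seed = config$seed)
      list(records = records, accuracy = accuracy,
           n_price_outliers = sum(!flt$kept & flt$reason != "no amount",
                                  na.rm = TRUE))
    })
    if (!is.null(out)) {
      write.table(res$accuracy, file.path(out, "extraction_accuracy.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$extract <- list(
      n_records = nrow(res$records),
      accuracy = res$accuracy,
      n_price_outliers = res$n_price_outliers)
    data$extract <- res
  }

  if ("analyze" %in% config$stages) {
    if (is.null(data$extract)) abort("analyze stage requires extract")
    res <- run_stage("analyze", function() {
      listings <- data$listings$listings
      records <- data$extract$records
      lifespans <- load_markets()
      landscape <- landscape_counts(listings, data$posts$pool, lexicon)
      dup <- match_identical_listings(listings)
      jac <- supplier_jaccard(listings)
      activity <- tibble::tibble(vendor = listings$vendor,
                                 market = listings$market,
                                 date = listings$first_seen)
      mig <- detect_migrations(activity,
                               lifespans[lifespans$kind == "marketplace", ])
      commodities <- commodity_tables(records)
      geo <- geo_distribution(records)
      list(landscape = landscape, duplicates = dup, jaccard = jac,
           migrations = mig, commodities = commodities, geo = geo)
    })
    if (!is.null(out)) {
      write.table(res$jaccard$pairs, file.path(out, "jaccard.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$geo$origins, file.path(out, "origins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$analyze <- list(
      totals = res$landscape$totals,
      n_duplicate_groups = nrow(res$duplicates$groups),
      n_migrations = nrow(res$migrations))
    data$analyze <- res
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(manifest = manifest, data = data),
            class = "pipeline_run")
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, stages: %s (%.1f s)\n",
              x$manifest$seed, paste(names(x$manifest$stages),
                                     collapse = ", "),
              x$manifest$elapsed_s))
  invisible(x)
}
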