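test_that("generator configuration validates its inputs", {
  expect_error(generator_config(overlap = 1.5), "overlap")
  expect_error(generator_config(outlier_rate = 0.5), "outlier_rate")
  expect_error(generator_config(topic_mix = c(promotion = 0.5, review = 0.2,
                                              other = 0.2)), "sum to 1")
  expect_error(generator_config(nonsense = 1), "unknown")
  expect_error(generator_config(n_listings = 0), "positive")
})

test_that("all generator stages are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- gen_dual_corpora(cfg)
  b <- gen_dual_corpora(cfg)
  expect_identical(a, b)
  expect_identical(gen_posts(cfg)$pool$body, gen_posts(cfg)$pool$body)
  expect_identical(gen_listings(cfg)$listings, gen_listings(cfg)$listings)
  # a different seed changes the streams
  expect_false(identical(gen_dual_corpora(tiny_config(seed = 12))$benign,
                         a$benign))
})

test_that("planted jargon contexts match their seed keyword contexts", {
  context_dist <- function(sentences, focal) {
    toks <- strsplit(sentences, " ")
    ctx <- unlist(lapply(toks, function(t) {
      i <- which(t == focal)
      if (!length(i)) return(NULL)
      t[-i]
    }))
    table(ctx) / length(ctx)
  }
  # overlap 1: the planted term's context distribution equals its seed's
  cfg1 <- tiny_config(seed = 5, overlap = 1)
  co <- gen_dual_corpora(cfg1)
  planted <- co$truth$planted[1, ]
  d_seed <- context_dist(co$benign, planted$seed)
  d_jarg <- context_dist(co$underground, planted$term)
  shared <- union(names(d_seed), names(d_jarg))
  tv <- sum(abs(replace(setNames(numeric(length(shared)), shared),
                        names(d_seed), d_seed)[shared] -
                replace(setNames(numeric(length(shared)), shared),
                        names(d_jarg), d_jarg)[shared])) / 2
  # same topic block with geometric weights; sampling noise only
  expect_lt(tv, 0.25)
  # the planted term's context words live inside the seed's topic support
  # (finite sampling leaves a small tail of rarely drawn topic words)
  expect_gt(mean(names(d_jarg) %in% names(d_seed)), 0.8)

  # overlap 0: contexts are background draws, mostly outside the topic block
  co0 <- gen_dual_corpora(tiny_config(seed = 5, overlap = 0))
  p0 <- co0$truth$planted[1, ]
  d0 <- context_dist(co0$underground, p0$term)
  ds <- context_dist(co0$benign, p0$seed)
  expect_lt(mean(names(d0) %in% names(ds)), 0.5)
  # planted terms never leak into the benign register
  expect_false(any(grepl("jarg", co0$benign)))
})

test_that("post generator respects set sizes, imbalance and labels", {
  cfg <- tiny_config(seed = 7)
  po <- gen_posts(cfg)
  expect_equal(nrow(po$labeled$promotion), 120)  # 60 + 60
  expect_equal(sum(po$labeled$promotion$label), 60)
  expect_equal(length(po$proxy_review$pos), 60)
  expect_equal(nrow(po$pool), 120)
  # every pool post has a ground-truth topic label
  expect_true(all(po$pool$post_id %in% po$truth$topic_labels$post_id))
  # sentiment labels exist only for review posts
  senti <- po$truth$sentiment_labels
  topics <- po$truth$topic_labels
  expect_true(all(
    topics$topic_label[match(senti$post_id, topics$post_id)] == "review"))

  # heavy imbalance in the pool matches the configured mixture
  cfg2 <- tiny_config(seed = 8, pool_size = 1000L,
                      topic_mix = c(promotion = 1 / 11, review = 0,
                                    other = 10 / 11))
  po2 <- gen_posts(cfg2)
  lab <- po2$truth$topic_labels
  pool_lab <- lab$topic_label[match(po2$pool$post_id, lab$post_id)]
  p_hat <- mean(pool_lab == "promotion")
  expect_lt(abs(p_hat - 1 / 11), 3 * sqrt((1 / 11) * (10 / 11) / 1000))
  expect_equal(sum(pool_lab == "review"), 0)
})

test_that("listing generator plants outliers, duplicates and geography", {
  cfg <- tiny_config(seed = 9, outlier_rate = 0.2)
  li <- gen_listings(cfg)
  tr <- li$truth$listings
  expect_equal(nrow(li$listings), cfg$n_listings)
  expect_equal(nrow(tr), nrow(li$listings))          # label conservation
  expect_false(any(is.na(tr$outlier)))
  expect_gt(sum(tr$outlier), 0)
  # injected outliers sit strictly beyond the 5x / 0.25x band of their group
  expect_true(all(is.na(tr$grams[tr$outlier]) == FALSE))

  # zero rate -> no outliers
  li0 <- gen_listings(tiny_config(seed = 9, outlier_rate = 0))
  expect_false(any(li0$truth$listings$outlier))

  # duplicate groups equal on (title, description, vendor), across markets
  expect_equal(length(li$truth$duplicate_groups), cfg$n_duplicate_groups)
  for (g in li$truth$duplicate_groups) {
    rows <- li$listings[match(g, li$listings$listing_id), ]
    expect_equal(dplyr::n_distinct(rows$title), 1)
    expect_equal(dplyr::n_distinct(rows$description), 1)
    expect_equal(dplyr::n_distinct(rows$vendor), 1)
    expect_gte(dplyr::n_distinct(rows$market), 2)
  }
  expect_true(all(li$listings$price > 0))
  expect_true(all(li$listings$first_seen <= li$listings$last_seen))
})

test_that("clean per-gram prices follow the configured log-normal", {
  cfg <- tiny_config(seed = 21, n_listings = 4000L, n_vendors = 60L,
                     outlier_rate = 0.05)
  tr <- gen_listings(cfg)$truth$listings
  clean <- tr[!tr$outlier & !is.na(tr$grams), ]
  meds <- c(Heroin = 130, Oxycodone = 600)
  for (cat in names(meds)) {
    r <- clean$per_gram[clean$category == cat] / meds[[cat]]
    expect_gt(length(r), 500)
    ks <- suppressWarnings(stats::ks.test(log(r), "pnorm", 0, 0.25))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("vendor timelines honor lifespans and plant exact migrations", {
  cfg <- tiny_config(seed = 13)
  tl <- gen_vendor_timelines(cfg)
  mk <- load_markets()
  mk <- mk[mk$kind == "marketplace", ]
  win <- match(tl$timeline$market, mk$name)
  expect_true(all(tl$timeline$first_date >= mk$measurement_start[win]))
  expect_true(all(tl$timeline$last_date <= mk$measurement_end[win]))
  expect_equal(nrow(tl$migrations), cfg$n_migrations)
  for (i in seq_len(nrow(tl$migrations))) {
    ev <- tl$migrations[i, ]
    expect_gt(ev$first_date_in_destination, ev$close_date)
    dst <- tl$timeline[tl$timeline$vendor == ev$vendor &
                         tl$timeline$market == ev$to_market, ]
    expect_equal(dst$first_date, ev$first_date_in_destination)
  }
  # no migrations requested -> none planted
  expect_equal(nrow(gen_vendor_timelines(
    tiny_config(seed = 13, n_migrations = 0L))$migrations), 0)
  # expected Jaccard agrees with direct set computation on the timeline
  sets <- lapply(split(tl$timeline$vendor, tl$timeline$market), unique)
  for (i in seq_len(nrow(tl$jaccard_expected))) {
    row <- tl$jaccard_expected[i, ]
    a <- sets[[row$market_a]]
    b <- sets[[row$market_b]]
    expect_equal(row$jaccard,
                 length(intersect(a, b)) / length(union(a, b)))
  }
})
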