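test_that("landscape counts split opioid records and jargon-only hits", {
  lex <- load_opioid_lexicon()
  listings <- tibble::tibble(
    listing_id = sprintf("L%d", 1:4), market = "Agora",
    vendor = c("v1", "v1", "v2", "v3"),
    title = c("roxy stock", "oxycontin deal", "laptop", "lean syrup"),
    description = "", price = 1, currency = "USD", amount_raw = "",
    origin = "", destinations = list(character(0), character(0),
                                     character(0), character(0)),
    escrow = "unknown", sold_count = NA_integer_,
    first_seen = as.Date("2014-01-01"), last_seen = as.Date("2014-02-01"))
  posts <- tibble::tibble(
    post_id = c("p1", "p2"), forum = "The Hub", author = c("a1", "a2"),
    body = c("where to buy percocet", "how to use tor"),
    posted_at = as.Date("2014-05-01"))
  out <- landscape_counts(listings, posts, lex)
  # 3 opioid listings (roxy, oxycontin, lean) + 1 opioid post (percocet)
  expect_equal(out$totals$n_opioid_listings, 3)
  expect_equal(out$totals$n_opioid_posts, 1)
  expect_equal(out$totals$n_opioid_records, 4)
  # exactly half of the opioid records hit only jargon terms (roxy, lean)
  expect_equal(out$totals$n_jargon_only, 2)
  expect_equal(out$totals$jargon_share_pct, 50)
  expect_equal(out$totals$n_supplier_ids, 2)  # v1 and v3 (v2 sells laptops)
  expect_equal(out$totals$n_buyer_ids, 1)
  # empty input gives an all-zero summary
  zero <- landscape_counts(listings[0, ], posts[0, ], lex)
  expect_equal(zero$totals$n_opioid_records, 0)
  expect_equal(zero$totals$n_supplier_ids, 0)
})

test_that("monthly churn follows the first-seen / month-after-last-seen rule", {
  listings <- tibble::tibble(
    listing_id = "L1", market = "Agora", vendor = "v", title = "t",
    description = "", price = 1, currency = "USD", amount_raw = "",
    origin = "", destinations = list(character(0)), escrow = "unknown",
    sold_count = NA_integer_,
    first_seen = as.Date("2014-01-15"), last_seen = as.Date("2014-03-20"))
  ch <- monthly_churn(listings, "Agora")
  expect_equal(ch$newly_appeared[ch$month == as.Date("2014-01-01")], 1L)
  expect_equal(sum(ch$disappeared), 0L)  # disappears in April, after series
  expect_equal(nrow(monthly_churn(listings, "Evolution")), 0)

  # churn conservation on generator output
  li <- gen_listings(tiny_config(seed = 61))
  for (mkt in c("Agora", "Evolution")) {
    ch <- monthly_churn(li$listings, mkt)
    x <- li$listings[li$listings$market == mkt, ]
    final <- max(ch$month)
    alive_final <- sum(format(x$last_seen, "%Y-%m") == format(final, "%Y-%m"))
    expect_equal(sum(ch$newly_appeared), nrow(x))
    expect_equal(sum(ch$newly_appeared) - sum(ch$disappeared), alive_final)
  }
})

test_that("identical-listing matching recovers planted duplicate groups", {
  li <- gen_listings(tiny_config(seed = 62))
  got <- match_identical_listings(li$listings)
  expect_equal(nrow(got$groups), length(li$truth$duplicate_groups))
  got_sets <- lapply(got$groups$listing_ids, sort)
  true_sets <- lapply(li$truth$duplicate_groups, sort)
  expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                  vapply(true_sets, paste, character(1), collapse = ","))
  expect_true(all(got$groups$cross_market))

  # same triple in the same market groups but is not cross-market
  same <- li$listings[c(1, 1), ]
  same$listing_id <- c("A", "B")
  g <- match_identical_listings(same)
  expect_equal(nrow(g$groups), 1)
  expect_false(g$groups$cross_market)
})

test_that("supplier Jaccard matches hand values and a brute-force oracle", {
  listings <- tibble::tibble(
    listing_id = sprintf("L%d", 1:6),
    market = rep(c("M1", "M2"), each = 3),
    vendor = c("a", "b", "c", "b", "c", "d"),
    title = "t", description = "", price = 1, currency = "USD",
    amount_raw = "", origin = "",
    destinations = replicate(6, character(0), simplify = FALSE),
    escrow = "unknown", sold_count = NA_integer_,
    first_seen = as.Date("2014-01-01"), last_seen = as.Date("2014-02-01"))
  out <- supplier_jaccard(listings)
  expect_equal(out$pairs$jaccard, 0.5)  # {a,b,c} vs {b,c,d} -> 2/4
  expect_equal(out$matrix["M1", "M2"], 0.5)
  expect_equal(diag(out$matrix), c(M1 = 1, M2 = 1))

  # identical and disjoint sets
  listings2 <- listings
  listings2$vendor <- c("a", "b", "c", "a", "b", "c")
  expect_equal(supplier_jaccard(listings2)$pairs$jaccard, 1)
  listings2$vendor <- c("a", "b", "c", "d", "e", "f")
  expect_equal(supplier_jaccard(listings2)$pairs$jaccard, 0)

  # brute-force oracle over the generator's 10 markets
  li <- gen_listings(tiny_config(seed = 63))
  got <- supplier_jaccard(li$listings)
  sets <- lapply(split(li$listings$vendor, li$listings$market), unique)
  for (i in seq_len(nrow(got$pairs))) {
    row <- got$pairs[i, ]
    a <- sets[[row$market_a]]
    b <- sets[[row$market_b]]
    expect_equal(row$jaccard, length(intersect(a, b)) / length(union(a, b)))
  }
  # construction-time expectation matches the measured matrix
  je <- li$truth$jaccard_expected
  for (i in seq_len(nrow(je))) {
    expect_equal(got$matrix[je$market_a[i], je$market_b[i]], je$jaccard[i])
  }
})

test_that("migration detection is exact against planted ground truth", {
  lifespans <- load_markets()
  lifespans <- lifespans[lifespans$kind == "marketplace", ]
  for (s in 1:3) {
    li <- gen_listings(tiny_config(seed = 70 + s))
    activity <- tibble::tibble(vendor = li$listings$vendor,
                               market = li$listings$market,
                               date = li$listings$first_seen)
    got <- detect_migrations(activity, lifespans)
    tr <- li$truth$migrations
    key <- function(df) sort(paste(df$vendor, df$from_market, df$to_market,
                                   df$first_date_in_destination))
    expect_equal(key(got), key(tr))
  }

  # concurrent cross-market activity is not a migration
  act <- tibble::tibble(
    vendor = "v", market = c("Evolution", "Agora", "Agora"),
    date = as.Date(c("2014-06-01", "2014-07-01", "2015-05-01")))
  expect_equal(nrow(detect_migrations(act, lifespans)), 0)
  # activity only in the destination is not a migration
  act2 <- tibble::tibble(vendor = "v", market = "Agora",
                         date = as.Date("2015-05-01"))
  expect_equal(nrow(detect_migrations(act2, lifespans)), 0)
  # a vendor leaving a closed market for a later one is
  act3 <- tibble::tibble(
    vendor = "v", market = c("Evolution", "Agora"),
    date = as.Date(c("2014-06-01", "2015-05-01")))
  got <- detect_migrations(act3, lifespans)
  expect_equal(got$from_market, "Evolution")
  expect_equal(got$first_date_in_destination, as.Date("2015-05-01"))
})

test_that("commodity tables rank, price and difference categories by year", {
  rec <- tibble::tibble(
    category = c(rep("Heroin", 100), rep("Codeine", 50),
                 rep("Heroin", 40), rep("Codeine", 66)),
    year = c(rep("2014", 150), rep("2019", 106)),
    per_gram = 50, kept = TRUE)
  out <- commodity_tables(rec)
  h <- out$change[out$change$category == "Heroin", ]
  expect_equal(h$pct_change, -60)
  expect_equal(out$by_year$rank[out$by_year$year == "2014" &
                                  out$by_year$category == "Heroin"], 1L)
  # single kept listing: mean equals the price, sd is 0
  one <- commodity_tables(tibble::tibble(category = "Heroin", year = "2020",
                                         per_gram = 50, kept = TRUE))
  expect_equal(one$by_year$mean_per_gram, 50)
  expect_equal(one$by_year$sd_per_gram, 0)
})

test_that("geography shares reproduce printed-ratio rounding", {
  # 5654 worldwide of 15546 destination-bearing records -> 36.37%
  n_ww <- 5654
  n_rest <- 15546 - n_ww
  rec <- tibble::tibble(
    origin = NA_character_,
    destinations = c(replicate(n_ww, "worldwide", simplify = FALSE),
                     replicate(n_rest, "Canada", simplify = FALSE)))
  out <- geo_distribution(rec)
  expect_equal(out$destination_denominator, 15546)
  expect_equal(out$destination_class$pct[
    out$destination_class$class == "worldwide"], 36.37)
  # single-origin records give 100%
  rec2 <- tibble::tibble(origin = rep("Germany", 8),
                         destinations = replicate(8, character(0),
                                                  simplify = FALSE))
  out2 <- geo_distribution(rec2)
  expect_equal(out2$origins$pct, 100)
  # percentages never exceed 100 and recompute from their own counts
  li <- gen_listings(tiny_config(seed = 64))
  rec3 <- extract_records(li$listings, load_opioid_lexicon())
  out3 <- geo_distribution(rec3)
  expect_true(all(out3$origins$pct <= 100))
  expect_equal(out3$origins$pct,
               pct(out3$origins$n, out3$origin_denominator))
  expect_lte(sum(out3$destination_class$n), out3$destination_denominator +
               1e-9)
})

test_that("supplier sentiment aggregates to satisfaction shares", {
  reviews <- tibble::tibble(
    supplier = c(rep("v1", 4), rep("v2", 2), NA),
    sentiment = c("positive", "positive", "positive", "negative",
                  "positive", "positive", "negative"))
  out <- supplier_sentiment(reviews)
  expect_equal(out$table$satisfaction_pct[out$table$supplier == "v1"], 75)
  expect_equal(out$table$satisfaction_pct[out$table$supplier == "v2"], 100)
  expect_equal(out$n_unlinked, 1)
  empty <- supplier_sentiment(reviews[0, ])
  expect_equal(nrow(empty$table), 0)
})
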