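# Median per-gram USD price assumed for each opioid category (order of
# magnitude guided by observed darknet price tables).
category_price_table <- c(
  Heroin = 130, Fentanyl = 1100, Buprenorphine = 2700, Oxycodone = 600,
  Dihydrocodeine = 40, Oxymorphone = 700, Morphine = 150, Methadone = 120,
  Hydromorphone = 900, Hydrocodone = 1100, Tramadol = 21, Codeine = 80,
  Others = 100)

# Listing-count mixture over categories (heroin and oxycodone dominate).
category_mix <- c(
  Heroin = 0.30, Oxycodone = 0.22, Fentanyl = 0.12, Buprenorphine = 0.07,
  Tramadol = 0.07, Codeine = 0.06, Morphine = 0.05, Hydrocodone = 0.04,
  Methadone = 0.02, Hydromorphone = 0.02, Oxymorphone = 0.01,
  Dihydrocodeine = 0.01, Others = 0.01)

# Clean per-gram prices are log-normal around the category median, truncated
# to the ratio band [0.55, 1.9]; injected outliers sit at >= 10x or <= 0.12x
# the category median. Under the 5x / 0.25x median rule this guarantees the
# filter recovers exactly the injected set for any group outlier share < 1/2.
price_ratio_band <- c(0.55, 1.9)

rtrunc_ratio <- function(n, sdlog = 0.25) {
  out <- numeric(0)
  while (length(out) < n) {
    r <- exp(rnorm(n, 0, sdlog))
    out <- c(out, r[r >= price_ratio_band[[1]] & r <= price_ratio_band[[2]]])
  }
  out[seq_len(n)]
}

rand_date <- function(n, from, to) {
  span <- as.integer(as.Date(to) - as.Date(from))
  as.Date(from) + floor(runif(n) * (span + 1))
}

#' Generate vendor activity timelines with planted migrations
#'
#' Assigns each synthetic vendor an activity interval in a home marketplace
#' (drawn over the packaged market lifespans), makes a configurable fraction
#' concurrently active in a second marketplace, and plants
#' `config$n_migrations` supplier migrations: the migrating vendor's activity
#' in the source market ends by its closure and their first activity in the
#' destination market falls strictly after it, with no earlier presence
#' there. Expected cross-market Jaccard coefficients are computed from the
#' constructed supplier sets.
#'
#' @param config A [generator_config()].
#' @return List with `timeline` (vendor, market, first_date, last_date),
#'   `migrations` (ground-truth events), and `jaccard_expected`.
#' @export
gen_vendor_timelines <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  markets <- dplyr::filter(load_markets(), .data$kind == "marketplace")
  with_seed(config$seed + 202L, {
    vendors <- sprintf("vendor_%03d", seq_len(config$n_vendors))
    mw <- markets$n_opioid / sum(markets$n_opioid)

    # viable (source, destination) pairs: source closed while destination's
    # measurement window still runs
    pairs <- list()
    for (i in seq_len(nrow(markets))) {
      if (is.na(markets$close_date[[i]])) next
      for (j in seq_len(nrow(markets))) {
        if (i == j) next
        if (markets$measurement_end[[j]] > markets$close_date[[i]] + 7) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
    if (config$n_migrations > 0 && length(pairs) == 0) {
      abort("market lifespans admit no migration pair")
    }

    n_mig <- min(config$n_migrations, config$n_vendors %/% 4)
    mig_vendors <- vendors[seq_len(n_mig)]
    rows <- list()
    migs <- list()
    for (k in seq_len(n_mig)) {
      p <- pairs[[(k - 1L) %% length(pairs) + 1L]]
      src <- markets[p[[1]], ]
      dst <- markets[p[[2]], ]
      close <- src$close_date
      end_src <- min(close, src$measurement_end)
      start_src <- rand_date(1, src$measurement_start,
                             max(src$measurement_start, end_src - 60))
      arrive <- max(close + sample(7:90, 1), dst$measurement_start)
      arrive <- min(arrive, dst$measurement_end)
      if (arrive <= close) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vendor = mig_vendors[[k]], market = src$name,
        first_date = start_src, last_date = end_src)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vendor = mig_vendors[[k]], market = dst$name,
        first_date = arrive, last_date = dst$measurement_end)
      migs[[length(migs) + 1L]] <- tibble::tibble(
        vendor = mig_vendors[[k]], from_market = src$name,
        to_market = dst$name, close_date = close,
        first_date_in_destination = arrive)
    }

    for (v in setdiff(vendors, mig_vendors)) {
      hi <- sample(nrow(markets), 1, prob = mw)
      home <- markets[hi, ]
      a <- rand_date(1, home$measurement_start,
                     max(home$measurement_start, home$measurement_end - 30))
      b <- rand_date(1, a, home$measurement_end)
      if (runif(1) < config$cross_market_rate) {
        # second market concurrently active: both intervals open at a common
        # anchor date inside the measurement-window intersection
        cand <- which(markets$measurement_start <= b &
                        markets$measurement_end >= a &
                        seq_len(nrow(markets)) != hi)
        if (length(cand)) {
          si <- cand[[sample(length(cand), 1)]]
          sec <- markets[si, ]
          lo <- max(a, sec$measurement_start)
          hi2 <- min(b, sec$measurement_end)
          anchor <- rand_date(1, lo, hi2)
          b2 <- rand_date(1, anchor, sec$measurement_end)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            vendor = v, market = home$name, first_date = anchor,
            last_date = b)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            vendor = v, market = sec$name, first_date = anchor,
            last_date = b2)
          next
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vendor = v, market = home$name, first_date = a, last_date = b)
    }

    timeline <- dplyr::bind_rows(rows)
    migrations <- if (length(migs)) dplyr::bind_rows(migs) else
      tibble::tibble(vendor = character(), from_market = character(),
                     to_market = character(), close_date = as.Date(character()),
                     first_date_in_destination = as.Date(character()))
    sets <- split(timeline$vendor, timeline$market)
    mk <- names(sets)
    jac <- list()
    for (i in seq_along(mk)) {
      for (j in seq_along(mk)) {
        if (j <= i) next
        a <- unique(sets[[i]]); b <- unique(sets[[j]])
        u <- length(union(a, b))
        jac[[length(jac) + 1L]] <- tibble::tibble(
          market_a = mk[[i]], market_b = mk[[j]],
          jaccard = if (u == 0) 0 else length(intersect(a, b)) / u)
      }
    }
    list(timeline = timeline, migrations = migrations,
         jaccard_expected = dplyr::bind_rows(jac))
  })
}

amount_string <- function(mg, n_units, grams, form) {
  switch(form,
         sprintf("%g mg x %d pills", mg, n_units),
         sprintf("%d x %g mg", n_units, mg),
         sprintf("%g g", grams),
         sprintf("%g grams", grams),
         sprintf("%d pills %g mg", n_units, mg))
}

#' Generate marketplace listings with full ground truth
#'
#' Builds a seeded set of opioid listings over the packaged market lifespans:
#' vendor activity follows [gen_vendor_timelines()] (one guaranteed listing
#' at the start of every vendor-market interval, so supplier sets and
#' migration events are recoverable exactly); quantity strings are drawn from
#' a small grammar ("20 mg x 80 pills", "1.5 g", ...) with a configurable
#' unparseable share; per-gram prices are log-normal around category medians
#' with outliers injected per category-year group, strictly beyond the
#' 5x / 0.25x median bounds; identical cross-market listings (same title,
#' description and vendor) are planted as `n_duplicate_groups`; origins and
#' destinations are drawn over the packaged country dictionary with a
#' worldwide mass.
#'
#' @param config A [generator_config()].
#' @return List with `listings` (interchange-schema tibble), and `truth`:
#'   per-listing tibble (category, grams, per-gram price, `outlier` flag,
#'   canonical geography, escrow, sold count, vendor), `duplicate_groups`
#'   (list of listing-id groups), plus the timeline, migration and Jaccard
#'   ground truth of the underlying vendor model.
#' @export
gen_listings <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  lex <- load_opioid_lexicon()
  markets <- dplyr::filter(load_markets(), .data$kind == "marketplace")
  countries <- load_country_dictionary()
  tl <- gen_vendor_timelines(config)
  with_seed(config$seed + 303L, {
    timeline <- tl$timeline
    mandatory <- nrow(timeline)
    dup_sizes <- integer(0)

    # duplicate groups ride on multi-market vendors
    multi <- timeline |>
      dplyr::count(.data$vendor) |>
      dplyr::filter(.data$n >= 2)
    mig_v <- tl$migrations$vendor
    dup_candidates <- setdiff(multi$vendor, mig_v)
    n_dup <- min(config$n_duplicate_groups, length(dup_candidates))
    dup_vendors <- if (n_dup > 0) sample(dup_candidates, n_dup) else character(0)

    n_dup_listings <- sum(pmin(
      timeline |> dplyr::count(.data$vendor) |>
        dplyr::filter(.data$vendor %in% dup_vendors) |> dplyr::pull(.data$n),
      3L))
    n_extra <- config$n_listings - mandatory - n_dup_listings
    if (n_extra < 0) {
      abort("n_listings too small for the vendor timeline and duplicates")
    }

    # one mandatory listing per timeline row (at its start date), extras
    # allocated by market weight
    mrow <- timeline
    mrow$date <- mrow$first_date
    if (n_extra > 0) {
      w <- markets$n_opioid[match(timeline$market, markets$name)]
      ridx <- sample(nrow(timeline), n_extra, replace = TRUE, prob = w)
      extra <- timeline[ridx, ]
      extra$date <- as.Date(mapply(function(a, b) rand_date(1, a, b),
                                   extra$first_date, extra$last_date),
                            origin = "1970-01-01")
      base <- dplyr::bind_rows(mrow, extra)
    } else {
      base <- mrow
    }

    # duplicate listings: identical (title, description, vendor) in >= 2 markets
    dup_rows <- list()
    dup_groups <- list()
    for (v in dup_vendors) {
      vm <- timeline[timeline$vendor == v, ]
      vm <- vm[seq_len(min(3L, nrow(vm))), ]
      vm$date <- as.Date(mapply(function(a, b) rand_date(1, a, b),
                                vm$first_date, vm$last_date),
                         origin = "1970-01-01")
      dup_rows[[length(dup_rows) + 1L]] <- vm
      dup_sizes <- c(dup_sizes, nrow(vm))
    }
    dup_block <- if (length(dup_rows)) dplyr::bind_rows(dup_rows) else NULL
    all_rows <- dplyr::bind_rows(base, dup_block)
    n <- nrow(all_rows)

    # duplicate bookkeeping: which rows form which group
    dup_group_id <- rep(NA_integer_, n)
    if (length(dup_sizes)) {
      off <- nrow(base)
      for (g in seq_along(dup_sizes)) {
        dup_group_id[off + seq_len(dup_sizes[[g]])] <- g
        off <- off + dup_sizes[[g]]
      }
    }

    category <- sample(names(category_mix), n, replace = TRUE,
                       prob = category_mix)
    # one shared category/term/amount per duplicate group (titles must match)
    term <- character(n)
    by_cat <- split(seq_len(n), category)
    for (ct in names(by_cat)) {
      pool_k <- lex[lex$category == ct, ]
      use_jargon <- runif(length(by_cat[[ct]])) < config$jargon_term_share
      jt <- pool_k$term[pool_k$kind == "jargon"]
      pt <- pool_k$term[pool_k$kind == "product_name"]
      if (!length(jt)) jt <- pt
      term[by_cat[[ct]]] <- ifelse(use_jargon,
                                   sample(jt, length(by_cat[[ct]]), TRUE),
                                   sample(pt, length(by_cat[[ct]]), TRUE))
    }

    unparseable <- runif(n) < config$amount_unparseable_rate
    mg <- sample(c(5, 10, 15, 20, 30, 40, 50, 80, 100, 200), n, TRUE)
    n_units <- sample(c(10, 20, 30, 50, 80, 100, 120, 200, 250), n, TRUE)
    form <- sample(5, n, TRUE)
    grams <- ifelse(form %in% c(3, 4),
                    round(runif(n, 0.5, 100), 1), mg * n_units / 1000)
    amount_raw <- vapply(seq_len(n), function(i) {
      if (unparseable[[i]]) return("bulk deal - message for details!!")
      amount_string(mg[[i]], n_units[[i]], grams[[i]], form[[i]])
    }, character(1))
    grams[unparseable] <- NA_real_

    # duplicate-group members must agree on everything the shared title and
    # description carry
    dup_ids <- unique(stats::na.omit(dup_group_id))
    for (g in dup_ids) {
      idx <- which(dup_group_id == g)
      f <- idx[[1]]
      category[idx] <- category[[f]]
      term[idx] <- term[[f]]
      amount_raw[idx] <- amount_raw[[f]]
      grams[idx] <- grams[[f]]
      unparseable[idx] <- unparseable[[f]]
    }

    # per-gram prices with per-group outlier injection (category x year)
    med <- unname(category_price_table[category])
    per_gram <- med * rtrunc_ratio(n)
    year <- format(all_rows$date, "%Y")
    outlier <- rep(FALSE, n)
    parseable_idx <- which(!unparseable)
    groups <- split(parseable_idx, paste(category[parseable_idx],
                                         year[parseable_idx]))
    for (g in groups) {
      k <- floor(config$outlier_rate * length(g))
      if (k < 1) next
      pick <- if (length(g) == 1) g else sample(g, k)
      hi <- runif(length(pick)) < 0.5
      per_gram[pick[hi]] <- med[pick[hi]] * runif(sum(hi), 10.5, 25)
      per_gram[pick[!hi]] <- med[pick[!hi]] * runif(sum(!hi), 0.02, 0.12)
      outlier[pick] <- TRUE
    }
    price <- pmax(round(per_gram * dplyr::coalesce(grams, 1), 2), 0.01)

    # geography
    origin_mix <- c("United States" = 0.35, "United Kingdom" = 0.17,
                    Germany = 0.15, Netherlands = 0.09, Canada = 0.06,
                    France = 0.05, Australia = 0.04, India = 0.02,
                    Spain = 0.016, Sweden = 0.008, Japan = 0.007,
                    Italy = 0.006, Belgium = 0.005, Switzerland = 0.005,
                    China = 0.003, Denmark = 0.01)
    origin_mix <- origin_mix / sum(origin_mix)
    origin_true <- sample(names(origin_mix), n, TRUE, prob = origin_mix)
    alias_of <- function(canon) {
      al <- countries$alias[countries$canonical == canon]
      al[[sample(length(al), 1)]]
    }
    origin_field <- vapply(origin_true, function(o) {
      if (runif(1) < 0.3) alias_of(o) else o
    }, character(1))
    dest_kind <- sample(c("worldwide", "us", "europe", "countries"), n, TRUE,
                        prob = c(0.36, 0.19, 0.11, 0.34))
    dest_true <- lapply(seq_len(n), function(i) {
      switch(dest_kind[[i]],
             worldwide = "worldwide",
             us = "United States",
             europe = "Europe",
             countries = sample(setdiff(names(origin_mix), "China"),
                                sample(1:3, 1)))
    })
    dest_field <- lapply(dest_true, function(d) {
      vapply(d, function(x) if (runif(1) < 0.2) alias_of(x) else x,
             character(1), USE.NAMES = FALSE)
    })

    # escrow and sold counts: structured only on the markets that expose them
    escrow_markets <- c("Alphabay", "Apollon", "Empire")
    sold_markets <- c("Alphabay", "The Versus Project", "Apollon", "Empire",
                      "Darkbay")
    escrow_true <- sample(c("yes", "no", "unknown"), n, TRUE,
                          prob = c(0.55, 0.25, 0.2))
    for (g in dup_ids) {   # one escrow status per shared description
      idx <- which(dup_group_id == g)
      escrow_true[idx] <- escrow_true[[idx[[1]]]]
    }
    escrow_field <- ifelse(all_rows$market %in% escrow_markets &
                             escrow_true != "unknown",
                           escrow_true, "unknown")
    # the description carries the escrow phrase wherever no structured field
    # exists; duplicate groups carry it everywhere so the shared text stays
    # consistent with every member's truth
    escrow_phrase <- vapply(seq_len(n), function(i) {
      if (all_rows$market[[i]] %in% escrow_markets &&
          is.na(dup_group_id[[i]])) {
        return("")
      }
      switch(escrow_true[[i]], yes = "escrow accepted for all orders",
             no = "no escrow we ship after payment", "")
    }, character(1))
    sold_count <- ifelse(all_rows$market %in% sold_markets,
                         stats::rnbinom(n, size = 1.2, mu = 25), NA_integer_)

    lot <- sprintf("lot%05d", seq_len(n))
    for (g in unique(stats::na.omit(dup_group_id))) {
      idx <- which(dup_group_id == g)
      lot[idx] <- lot[[idx[[1]]]]
    }
    title <- sprintf("%s %s %s", term, amount_raw, lot)
    description <- vapply(seq_len(n), function(i) {
      paste(c(sprintf("top quality %s stealth shipping", term[[i]]),
              escrow_phrase[[i]], "tracked delivery discreet packaging"),
            collapse = " ")
    }, character(1))
    # duplicates must agree on the full (title, description) pair
    for (g in unique(stats::na.omit(dup_group_id))) {
      idx <- which(dup_group_id == g)
      title[idx] <- title[[idx[[1]]]]
      description[idx] <- description[[idx[[1]]]]
    }

    last_seen <- as.Date(mapply(function(d, b) rand_date(1, d, b),
                                all_rows$date,
                                pmax(all_rows$last_date, all_rows$date)),
                         origin = "1970-01-01")
    listing_id <- sprintf("L%05d", seq_len(n))

    listings <- tibble::tibble(
      listing_id = listing_id, market = all_rows$market,
      vendor = all_rows$vendor, title = title, description = description,
      price = price, currency = "USD", amount_raw = amount_raw,
      origin = origin_field, destinations = dest_field,
      escrow = escrow_field, sold_count = as.integer(sold_count),
      first_seen = all_rows$date, last_seen = last_seen)

    truth_listings <- tibble::tibble(
      listing_id = listing_id, vendor = all_rows$vendor,
      market = all_rows$market, category = category, term = term,
      grams = grams, per_gram = price / grams, outlier = outlier,
      origin = origin_true, destinations = dest_true,
      escrow = escrow_true, sold_count = as.integer(sold_count),
      price = price)

    dup_groups <- lapply(unique(stats::na.omit(dup_group_id)), function(g) {
      listing_id[which(dup_group_id == g)]
    })

    list(listings = listings,
         truth = list(listings = truth_listings,
                      duplicate_groups = dup_groups,
                      timeline = tl$timeline, migrations = tl$migrations,
                      jaccard_expected = tl$jaccard_expected))
  })
}
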