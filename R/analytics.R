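# Supply-chain analytics over extracted records: landscape counts, listing
# churn, duplicate listings, supplier overlap and migration, commodity and
# geography tables, per-supplier sentiment.

#' Landscape summary of listings and forum posts
#'
#' Totals per platform, the opioid-matched subtotal (at least one lexicon
#' hit on title+description or body), the share of opioid records reached
#' only through jargon terms (no product-name hit), and unique supplier /
#' buyer ID counts. ID counts are upper bounds: the same person may hold
#' several IDs and one ID string may denote different people on different
#' platforms.
#'
#' @param listings Listing tibble (may be empty).
#' @param posts Forum-post tibble (may be empty).
#' @param lexicon A `jargon_lexicon`.
#' @return List with `platforms` (per-platform totals) and `totals`.
#' @export
landscape_counts <- function(listings, posts, lexicon) {
  n_l <- nrow(listings)
  n_p <- nrow(posts)
  l_text <- if (n_l) paste(listings$title, listings$description) else character(0)
  p_text <- if (n_p) posts$body else character(0)
  hits <- match_keywords(c(l_text, p_text), lexicon)
  per_doc <- hits |>
    dplyr::group_by(.data$doc) |>
    dplyr::summarise(jargon_only = all(.data$kind == "jargon"),
                     .groups = "drop")
  opioid <- logical(n_l + n_p)
  jargon_only <- logical(n_l + n_p)
  opioid[per_doc$doc] <- TRUE
  jargon_only[per_doc$doc] <- per_doc$jargon_only
  l_op <- opioid[seq_len(n_l)]
  p_op <- if (n_p) opioid[n_l + seq_len(n_p)] else logical(0)

  plat_l <- if (n_l) {
    tibble::tibble(name = listings$market, kind = "marketplace",
                   opioid = l_op)
  } else NULL
  plat_p <- if (n_p) {
    tibble::tibble(name = posts$forum, kind = "forum", opioid = p_op)
  } else NULL
  platforms <- dplyr::bind_rows(plat_l, plat_p)
  platforms <- if (nrow(platforms)) {
    platforms |>
      dplyr::group_by(.data$name, .data$kind) |>
      dplyr::summarise(n_records = dplyr::n(), n_opioid = sum(.data$opioid),
                       .groups = "drop")
  } else {
    tibble::tibble(name = character(), kind = character(),
                   n_records = integer(), n_opioid = integer())
  }
  n_opioid <- sum(opioid)
  n_jargon_only <- sum(jargon_only)
  totals <- list(
    n_listings = n_l, n_posts = n_p,
    n_opioid_listings = sum(l_op), n_opioid_posts = sum(p_op),
    n_opioid_records = n_opioid,
    n_jargon_only = n_jargon_only,
    jargon_share_pct = pct(n_jargon_only, n_opioid),
    n_supplier_ids = if (n_l) dplyr::n_distinct(listings$vendor[l_op]) else 0L,
    n_buyer_ids = if (n_p) dplyr::n_distinct(posts$author[p_op]) else 0L)
  list(platforms = platforms, totals = totals)
}

#' Monthly listing churn for one market
#'
#' A listing newly appears in the calendar month of its `first_seen` and
#' disappears in the month after its `last_seen` month — the only definition
#' computable from first/last sight alone. Months without activity are
#' emitted as zeros.
#'
#' @param listings Listing tibble.
#' @param market Market name.
#' @param window Optional `c(start, end)` dates clamping the series;
#'   defaults to the span of the market's listings.
#' @return Tibble with `month` (first-of-month `Date`), `newly_appeared`,
#'   `disappeared`.
#' @export
monthly_churn <- function(listings, market, window = NULL) {
  x <- listings[listings$market == market, ]
  if (nrow(x) == 0) {
    return(tibble::tibble(month = as.Date(character()),
                          newly_appeared = integer(),
                          disappeared = integer()))
  }
  if (!is.null(window)) {
    out_of <- x$first_seen < window[[1]] | x$last_seen > window[[2]]
    if (any(out_of)) {
      warn(sprintf("%d listing(s) outside the market window; clamped",
                   sum(out_of)))
      x$first_seen <- pmax(x$first_seen, window[[1]])
      x$last_seen <- pmin(x$last_seen, window[[2]])
    }
  }
  first_m <- month_floor(x$first_seen)
  gone_m <- add_months(month_floor(x$last_seen), 1L)
  months <- seq(min(first_m), max(month_floor(x$last_seen)), by = "month")
  tibble::tibble(
    month = months,
    newly_appeared = vapply(months, function(m) sum(first_m == m), integer(1)),
    disappeared = vapply(months, function(m) sum(gone_m == m), integer(1)))
}

#' Identical listings across markets
#'
#' Two listings are identical when they agree exactly on normalized title,
#' description and vendor name. Groups spanning two or more markets are
#' flagged cross-market, and per-market-pair shared-listing counts are
#' reported.
#'
#' @param listings Listing tibble.
#' @return List with `groups` (group id, listing ids, size, markets,
#'   `cross_market`) and `pair_counts` (market pair, shared groups).
#' @export
match_identical_listings <- function(listings) {
  key <- paste(normalize_term(listings$title),
               normalize_term(listings$description),
               normalize_term(listings$vendor), sep = "\r")
  grp <- split(seq_len(nrow(listings)), key)
  grp <- grp[lengths(grp) >= 2]
  if (!length(grp)) {
    return(list(groups = tibble::tibble(group = integer(),
                                        listing_ids = list(),
                                        size = integer(), n_markets = integer(),
                                        cross_market = logical()),
                pair_counts = tibble::tibble(market_a = character(),
                                             market_b = character(),
                                             shared = integer())))
  }
  grp <- grp[order(vapply(grp, min, integer(1)))]
  groups <- tibble::tibble(
    group = seq_along(grp),
    listing_ids = lapply(grp, function(i) listings$listing_id[i]),
    size = lengths(grp),
    n_markets = vapply(grp, function(i) {
      dplyr::n_distinct(listings$market[i])
    }, integer(1)))
  groups$cross_market <- groups$n_markets >= 2
  pairs <- list()
  for (g in grp) {
    mk <- sort(unique(listings$market[g]))
    if (length(mk) < 2) next
    cmb <- utils::combn(mk, 2)
    for (c_ in seq_len(ncol(cmb))) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(market_a = cmb[1, c_],
                                                    market_b = cmb[2, c_])
    }
  }
  pair_counts <- if (length(pairs)) {
    dplyr::bind_rows(pairs) |>
      dplyr::count(.data$market_a, .data$market_b, name = "shared")
  } else {
    tibble::tibble(market_a = character(), market_b = character(),
                   shared = integer())
  }
  list(groups = groups, pair_counts = pair_counts)
}

#' Supplier Jaccard overlap between markets
#'
#' Jaccard coefficient |A intersect B| / |A union B| of the supplier-ID sets
#' of every market pair, from opioid-matched listings. Supplier identity is
#' exact ID-string equality; the caveat that one ID string may not be one
#' person is carried in the output attributes, not resolved.
#'
#' @param listings Listing tibble (already restricted to opioid listings).
#' @return List with `pairs` (market pair, set sizes, intersection, jaccard)
#'   and `matrix` (symmetric, unit diagonal).
#' @export
supplier_jaccard <- function(listings) {
  sets <- lapply(split(listings$vendor, listings$market), unique)
  mk <- sort(names(sets))
  if (any(lengths(sets) == 0)) {
    warn("market with zero suppliers; its coefficients are 0")
  }
  m <- matrix(1, length(mk), length(mk), dimnames = list(mk, mk))
  rows <- list()
  for (i in seq_along(mk)) {
    for (j in seq_along(mk)) {
      if (j <= i) next
      a <- sets[[mk[[i]]]]
      b <- sets[[mk[[j]]]]
      u <- length(union(a, b))
      jac <- if (u == 0) 0 else length(intersect(a, b)) / u
      m[i, j] <- m[j, i] <- jac
      rows[[length(rows) + 1L]] <- tibble::tibble(
        market_a = mk[[i]], market_b = mk[[j]], n_a = length(a),
        n_b = length(b), n_intersection = length(intersect(a, b)),
        jaccard = jac)
    }
  }
  list(pairs = dplyr::bind_rows(rows), matrix = m)
}

#' Detect supplier migrations after market closures
#'
#' A migration event is a vendor whose first activity in a destination
#' market falls strictly after the closure of a source market where they
#' were active, with no destination activity on or before the closure. A
#' deterministic predicate, not an estimator; a vendor may generate several
#' events. Markets without a close date cannot be sources.
#'
#' @param activity Tibble with `vendor`, `market`, `date` (e.g. listing
#'   `first_seen` dates).
#' @param lifespans Market lifespan tibble ([load_markets()]).
#' @return Tibble of events: vendor, source/destination market, close date,
#'   first activity date in the destination. The same-ID-across-markets
#'   caveat is attached as attribute `id_caveat`.
#' @export
detect_migrations <- function(activity, lifespans) {
  close <- setNames(lifespans$close_date, lifespans$name)
  missing <- setdiff(unique(activity$market), lifespans$name)
  if (length(missing)) {
    abort(sprintf("lifespans missing for: %s", paste(missing, collapse = ", ")))
  }
  per <- activity |>
    dplyr::group_by(.data$vendor, .data$market) |>
    dplyr::summarise(first = min(.data$date), last = max(.data$date),
                     .groups = "drop")
  events <- list()
  for (v in unique(per$vendor)) {
    pv <- per[per$vendor == v, ]
    if (nrow(pv) < 2) next
    for (i in seq_len(nrow(pv))) {
      m <- pv$market[[i]]
      cd <- close[[m]]
      if (is.na(cd)) next
      if (pv$first[[i]] > cd) next   # never active in m before its closure
      for (j in seq_len(nrow(pv))) {
        if (i == j) next
        if (pv$first[[j]] > cd) {
          events[[length(events) + 1L]] <- tibble::tibble(
            vendor = v, from_market = m, to_market = pv$market[[j]],
            close_date = cd, first_date_in_destination = pv$first[[j]])
        }
      }
    }
  }
  out <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(vendor = character(), from_market = character(),
                   to_market = character(), close_date = as.Date(character()),
                   first_date_in_destination = as.Date(character()))
  attr(out, "id_caveat") <-
    "vendor identity is exact ID-string equality across markets"
  out
}

#' Top commodities per year with price statistics
#'
#' Ranks opioid categories by listing count within each year (from
#' `first_seen`), with mean and SD per-gram price over the filtered,
#' parseable-amount listings, and the percent change in listing counts
#' between years. Count ties break by mean price, then name.
#'
#' @param records Extraction records with `category`, `year` and a `kept`
#'   logical from the price filter (missing `kept` means all kept).
#' @param top_n Categories per year (default 5).
#' @return List with `by_year` and `change` (category, from, to,
#'   `pct_change`).
#' @export
commodity_tables <- function(records, top_n = 5L) {
  if (!"kept" %in% names(records)) records$kept <- TRUE
  counted <- records |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$year, .data$category) |>
    dplyr::summarise(
      n_listings = dplyr::n(),
      mean_per_gram = mean(.data$per_gram[.data$kept & !is.na(.data$per_gram)]),
      sd_per_gram = {
        p <- .data$per_gram[.data$kept & !is.na(.data$per_gram)]
        if (length(p) <= 1) 0 else sd(p)
      },
      .groups = "drop")
  by_year <- counted |>
    dplyr::group_by(.data$year) |>
    dplyr::arrange(dplyr::desc(.data$n_listings),
                   dplyr::desc(.data$mean_per_gram), .data$category,
                   .by_group = TRUE) |>
    dplyr::slice(seq_len(top_n)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  years <- sort(unique(counted$year))
  change <- list()
  if (length(years) >= 2) {
    for (i in seq_along(years)) {
      for (j in seq_along(years)) {
        if (j <= i) next
        a <- counted[counted$year == years[[i]], ]
        b <- counted[counted$year == years[[j]], ]
        shared <- intersect(a$category, b$category)
        if (!length(shared)) next
        change[[length(change) + 1L]] <- tibble::tibble(
          category = shared, from = years[[i]], to = years[[j]],
          n_from = a$n_listings[match(shared, a$category)],
          n_to = b$n_listings[match(shared, b$category)])
      }
    }
  }
  change <- if (length(change)) {
    dplyr::bind_rows(change) |>
      dplyr::mutate(pct_change = round_half_up(
        100 * (.data$n_to - .data$n_from) / .data$n_from, 2))
  } else {
    tibble::tibble(category = character(), from = character(),
                   to = character(), n_from = integer(), n_to = integer(),
                   pct_change = numeric())
  }
  list(by_year = by_year, change = change)
}

#' Origin and destination distributions
#'
#' Origin shares over records with a known origin, and destination classes
#' (worldwide / single region / named countries) over records with any
#' destination. Denominators are explicit in the output; percentages use
#' two-decimal round-half-up.
#'
#' @param records Extraction records.
#' @return List with `origins`, `origin_denominator`, `destination_class`,
#'   `destinations`, `destination_denominator`.
#' @export
geo_distribution <- function(records) {
  known_o <- records[!is.na(records$origin), ]
  n_o <- nrow(known_o)
  origins <- known_o |>
    dplyr::count(origin = .data$origin, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$origin) |>
    dplyr::mutate(pct = pct(.data$n, n_o))
  has_d <- lengths(records$destinations) > 0
  dsets <- records$destinations[has_d]
  n_d <- length(dsets)
  classify <- function(d) {
    if ("worldwide" %in% d) return("worldwide")
    regions <- d[d %in% "Europe"]
    if (length(regions) == length(d)) return("single region")
    "countries"
  }
  cls <- vapply(dsets, classify, character(1))
  destination_class <- tibble::tibble(class = c("worldwide", "single region",
                                                "countries")) |>
    dplyr::mutate(n = vapply(.data$class, function(k) sum(cls == k),
                             integer(1)),
                  pct = pct(.data$n, n_d))
  dest_tokens <- unlist(dsets)
  destinations <- if (length(dest_tokens)) {
    tibble::tibble(destination = dest_tokens) |>
      dplyr::count(.data$destination, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$destination) |>
      dplyr::mutate(pct = pct(.data$n, n_d))
  } else {
    tibble::tibble(destination = character(), n = integer(), pct = numeric())
  }
  list(origins = origins, origin_denominator = n_o,
       destination_class = destination_class, destinations = destinations,
       destination_denominator = n_d)
}

#' Per-supplier review sentiment
#'
#' @param reviews Tibble with `supplier` and `sentiment`
#'   (`positive`/`negative`); rows without a supplier link are excluded and
#'   counted.
#' @return List with `table` (per-supplier counts and satisfaction percent)
#'   and `n_unlinked`.
#' @export
supplier_sentiment <- function(reviews) {
  unlinked <- is.na(reviews$supplier)
  linked <- reviews[!unlinked, ]
  tab <- if (nrow(linked)) {
    linked |>
      dplyr::group_by(supplier = .data$supplier) |>
      dplyr::summarise(n_positive = sum(.data$sentiment == "positive"),
                       n_negative = sum(.data$sentiment == "negative"),
                       .groups = "drop") |>
      dplyr::mutate(satisfaction_pct = pct(.data$n_positive,
                                           .data$n_positive +
                                             .data$n_negative)) |>
      dplyr::arrange(dplyr::desc(.data$n_positive + .data$n_negative),
                     .data$supplier)
  } else {
    tibble::tibble(supplier = character(), n_positive = integer(),
                   n_negative = integer(), satisfaction_pct = numeric())
  }
  list(table = tab, n_unlinked = sum(unlinked))
}
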