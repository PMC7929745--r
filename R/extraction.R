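# Structured trading-information extraction: quantity strings, per-gram
# prices with the 5x / 0.25x median outlier rule, geography, escrow.

#' Load the country-name dictionary
#'
#' Canonical English short names with common aliases (e.g. "uk" for United
#' Kingdom) plus the region tokens "Europe" and "worldwide".
#'
#' @param path TSV with columns `alias`, `canonical`, `type`; defaults to the
#'   packaged dictionary.
#' @return Tibble of aliases.
#' @export
load_country_dictionary <- function(path = opitrade_file("countries.tsv")) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character")
  tibble::as_tibble(df)
}

.units_pill <- "pills?|tabs?|tablets?|caps?|capsules?|pieces?"
.num <- "([0-9]+(?:\\.[0-9]+)?)"

#' Parse an advertised quantity string
#'
#' Recognizes the small grammar of darknet quantity strings — "20 mg x 80
#' pills", "80 x 20 mg", "80 pills 20 mg", "1.5 g", "2 grams" (the
#' multiplication sign is normalized to "x") — and returns the total mass in
#' grams. Strings outside the grammar, or with nonpositive quantities, give
#' the no-amount marker (`NA`), which excludes the listing from per-gram
#' price statistics.
#'
#' @param amount_raw Character vector of quantity strings.
#' @return Tibble with `amount_raw`, `unit_dose_mg`, `unit_count`, `total_g`.
#' @examples
#' parse_amount("20 mg × 80 pills")$total_g  # 1.6
#' @export
parse_amount <- function(amount_raw) {
  x <- normalize_term(amount_raw)
  n <- length(x)
  mg <- count <- total <- rep(NA_real_, n)
  pat_mg_x_n <- paste0("\\b", .num, "\\s*mg\\s*[x*]\\s*([0-9]+)\\s*(?:",
                       .units_pill, ")?\\b")
  pat_n_x_mg <- paste0("\\b([0-9]+)\\s*[x*]\\s*", .num, "\\s*mg\\b")
  pat_n_pill_mg <- paste0("\\b([0-9]+)\\s*(?:", .units_pill,
                          ")\\s*(?:of\\s*)?", .num, "\\s*mg\\b")
  pat_g <- paste0("\\b", .num, "\\s*(?:g|grams?|gr)\\b")
  pat_mg <- paste0("\\b", .num, "\\s*mg\\b")
  for (i in seq_len(n)) {
    s <- x[[i]]
    m <- regmatches(s, regexec(pat_mg_x_n, s, perl = TRUE))[[1]]
    if (length(m)) {
      mg[i] <- as.numeric(m[[2]])
      count[i] <- as.numeric(m[[3]])
      next
    }
    m <- regmatches(s, regexec(pat_n_x_mg, s, perl = TRUE))[[1]]
    if (length(m)) {
      count[i] <- as.numeric(m[[2]])
      mg[i] <- as.numeric(m[[3]])
      next
    }
    m <- regmatches(s, regexec(pat_n_pill_mg, s, perl = TRUE))[[1]]
    if (length(m)) {
      count[i] <- as.numeric(m[[2]])
      mg[i] <- as.numeric(m[[3]])
      next
    }
    m <- regmatches(s, regexec(pat_g, s, perl = TRUE))[[1]]
    if (length(m)) {
      total[i] <- as.numeric(m[[2]])
      next
    }
    m <- regmatches(s, regexec(pat_mg, s, perl = TRUE))[[1]]
    if (length(m)) total[i] <- as.numeric(m[[2]]) / 1000
  }
  from_units <- !is.na(mg) & !is.na(count)
  total[from_units] <- mg[from_units] * count[from_units] / 1000
  bad <- !is.na(total) & total <= 0
  if (any(bad)) {
    warn(sprintf("%d quantity string(s) with nonpositive mass -> no amount",
                 sum(bad)))
    total[bad] <- NA_real_
    mg[bad] <- count[bad] <- NA_real_
  }
  tibble::tibble(amount_raw = amount_raw, unit_dose_mg = mg,
                 unit_count = count, total_g = total)
}

#' Per-gram price
#'
#' @param price Listing price (USD).
#' @param total_g Total advertised mass in grams (`NA` excludes the listing).
#' @return `price / total_g`, unrounded; `NA` where the mass is unknown or
#'   nonpositive.
#' @export
per_gram_price <- function(price, total_g) {
  ifelse(!is.na(total_g) & total_g > 0, price / total_g, NA_real_)
}

#' Filter abnormal per-gram prices
#'
#' Within each group (by default product category, optionally per year), a
#' price is dismissed when it exceeds 5 times the group median or falls below
#' 25% of it. The rule is applied in a single pass against the full-group
#' median; groups of size 1 are never filtered.
#'
#' @param prices Numeric per-gram prices (`NA`s pass through unkept with
#'   reason `"no amount"`).
#' @param group Grouping vector (same length), e.g. `paste(category, year)`.
#' @return Tibble with `price`, `group`, `kept`, `reason`
#'   (`NA`, `"above 5x median"`, `"below 0.25x median"`, `"no amount"`) and
#'   the group `median` used.
#' @export
filter_price_outliers <- function(prices, group = rep("all", length(prices))) {
  stopifnot(length(prices) == length(group))
  out <- tibble::tibble(price = prices, group = as.character(group),
                        kept = TRUE, reason = NA_character_,
                        median = NA_real_)
  out$kept[is.na(prices)] <- FALSE
  out$reason[is.na(prices)] <- "no amount"
  for (g in unique(out$group)) {
    idx <- which(out$group == g & !is.na(out$price))
    if (length(idx) <= 1) next
    m <- median(out$price[idx])
    out$median[idx] <- m
    hi <- out$price[idx] > 5 * m
    lo <- out$price[idx] < 0.25 * m
    out$kept[idx[hi]] <- FALSE
    out$reason[idx[hi]] <- "above 5x median"
    out$kept[idx[lo]] <- FALSE
    out$reason[idx[lo]] <- "below 0.25x median"
  }
  out
}

country_index <- function(countries) {
  surf <- normalize_term(countries$alias)
  setNames(countries$canonical, surf)
}

canonicalize_geo <- function(x, cidx) {
  unname(cidx[normalize_term(x)])
}

.geo_cues <- c("ship", "ships", "shipped", "shipping", "origin",
               "destination", "destinations", "deliver", "delivers")

# Scan free text for country/region mentions within `window` tokens of a
# shipping cue; "from"-side mentions become the origin, "to"/destination-side
# mentions become destinations. Mentions without a nearby cue are ignored
# (product names like "Vietnamese Heroin" must not set geography).
scan_geo_text <- function(text, countries, window = 6L) {
  cidx <- country_index(countries)
  toks <- tokenize_text(text)[[1]]
  n <- length(toks)
  if (n == 0) return(list(origin = NA_character_, destinations = character(0)))
  cues <- which(toks %in% .geo_cues)
  origin <- NA_character_
  dests <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (L in 3:1) {
      if (i + L - 1L > n) next
      key <- paste(toks[i:(i + L - 1L)], collapse = " ")
      if (!is.na(cidx[key])) {
        hit <- list(canon = unname(cidx[key]), start = i, end = i + L - 1L)
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
      next
    }
    near <- cues[abs(cues - hit$start) <= window]
    if (length(near)) {
      cue <- near[[which.min(abs(near - hit$start))]]
      # the directional marker closest before the mention decides the side
      lo <- max(1L, hit$start - window)
      pre <- toks[seq(lo, max(lo, hit$start - 1L))]
      from_at <- which(pre == "from")
      to_at <- which(pre == "to")
      side <- if (length(from_at) &&
                  (!length(to_at) || max(from_at) > max(to_at))) {
        "origin"
      } else if (length(to_at) ||
                 toks[[cue]] %in% c("destination", "destinations")) {
        "destination"
      } else if (toks[[cue]] == "origin") {
        "origin"
      } else {
        "destination"
      }
      if (side == "origin" && is.na(origin)) origin <- hit$canon
      if (side == "destination") dests <- union(dests, hit$canon)
    }
    i <- hit$end + 1L
  }
  list(origin = origin, destinations = dests)
}

#' Extract origin and shipping destinations
#'
#' Structured fields pass through after canonicalization against the country
#' dictionary; when absent, free text is scanned for country mentions within
#' a fixed token window of the cue words ship/origin/destination, with
#' "from" marking the origin side and "to" the destination side. A
#' structured origin always wins over a conflicting text origin (the
#' conflict is reported).
#'
#' @param origin Structured origin string (may be empty).
#' @param destinations Character vector of structured destination tokens.
#' @param text Free text fallback (title/description/post body).
#' @param countries Country dictionary ([load_country_dictionary()]).
#' @param window Token window around cue words (default 6).
#' @return List with `origin` (canonical or `NA`), `destinations`
#'   (canonical character vector), and `conflict` (logical).
#' @export
extract_geo <- function(origin = "", destinations = character(0), text = "",
                        countries = load_country_dictionary(), window = 6L) {
  cidx <- country_index(countries)
  s_origin <- if (!is.null(origin) && !is.na(origin) && nzchar(origin)) {
    canonicalize_geo(origin, cidx)
  } else {
    NA_character_
  }
  s_dest <- if (length(destinations)) {
    out <- canonicalize_geo(destinations, cidx)
    out[!is.na(out)]
  } else {
    character(0)
  }
  scanned <- if ((is.na(s_origin) || length(s_dest) == 0) && nzchar(text)) {
    scan_geo_text(text, countries, window)
  } else {
    list(origin = NA_character_, destinations = character(0))
  }
  conflict <- !is.na(s_origin) && !is.na(scanned$origin) &&
    s_origin != scanned$origin
  list(origin = if (!is.na(s_origin)) s_origin else scanned$origin,
       destinations = if (length(s_dest)) s_dest else scanned$destinations,
       conflict = conflict)
}

#' Extract escrow support
#'
#' The structured listing field wins when present; otherwise the keyword
#' "escrow" sets yes/no, with a simple negation check ("no", "not",
#' "without", "non") in the 3 preceding tokens; with neither, the value is
#' unknown.
#'
#' @param field Structured escrow field (`"yes"`, `"no"`, `"unknown"`, or
#'   missing).
#' @param text Free text fallback.
#' @return `"yes"`, `"no"` or `"unknown"`.
#' @export
extract_escrow <- function(field = NULL, text = "") {
  if (!is.null(field) && !is.na(field) && field %in% c("yes", "no")) {
    return(field)
  }
  toks <- tokenize_text(text)[[1]]
  pos <- which(toks == "escrow")
  if (!length(pos)) return("unknown")
  p <- pos[[1]]
  pre <- toks[max(1, p - 3):max(1, p - 1)]
  if (p > 1 && any(pre %in% c("no", "not", "without", "non"))) "no" else "yes"
}

#' Extract a price mention from free text
#'
#' Currency-aware regex extraction for `$`/USD, EUR and BTC amounts, with a
#' fixed conversion table to USD.
#'
#' @param text Character vector.
#' @param rates Named conversion rates to USD (defaults: usd 1, eur 1.1,
#'   btc 9000 — a fixed convention, configurable).
#' @return Tibble with `value`, `currency`, `usd`.
#' @export
extract_price <- function(text, rates = c(usd = 1, eur = 1.1, btc = 9000)) {
  x <- normalize_term(text)
  val <- rep(NA_real_, length(x))
  cur <- rep(NA_character_, length(x))
  pats <- c(usd = paste0("(?:\\$|us ?\\$|usd)\\s*", .num),
            usd2 = paste0(.num, "\\s*usd\\b"),
            eur = paste0("(?:€|eur)\\s*", .num),
            eur2 = paste0(.num, "\\s*eur\\b"),
            btc = paste0(.num, "\\s*btc\\b"))
  curr_of <- c(usd = "usd", usd2 = "usd", eur = "eur", eur2 = "eur",
               btc = "btc")
  for (i in seq_along(x)) {
    for (p in names(pats)) {
      m <- regmatches(x[[i]], regexec(pats[[p]], x[[i]], perl = TRUE))[[1]]
      if (length(m)) {
        val[i] <- as.numeric(m[[2]])
        cur[i] <- curr_of[[p]]
        break
      }
    }
  }
  tibble::tibble(value = val, currency = cur,
                 usd = val * unname(rates[cur]))
}

#' Extract the trading properties of every listing
#'
#' Applies the full property extractors to a listing table: vendor (the
#' structured field of the interchange schema), product category via keyword
#' matching on title + description (longest match wins), listing price,
#' advertised quantity and per-gram price, origin and destinations, escrow,
#' and sold count.
#'
#' @param listings Listing tibble (interchange schema).
#' @param lexicon A `jargon_lexicon`.
#' @param countries Country dictionary.
#' @return Tibble of extraction records, one row per listing.
#' @export
extract_records <- function(listings, lexicon,
                            countries = load_country_dictionary()) {
  n <- nrow(listings)
  text <- paste(listings$title, listings$description)
  hits <- match_keywords(text, lexicon)
  prod_term <- rep(NA_character_, n)
  prod_cat <- rep(NA_character_, n)
  if (nrow(hits)) {
    hits$len <- hits$end - hits$start
    best <- hits |>
      dplyr::group_by(.data$doc) |>
      dplyr::arrange(dplyr::desc(.data$len), .data$start,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    prod_term[best$doc] <- best$canonical
    prod_cat[best$doc] <- best$category
  }
  amt <- parse_amount(listings$amount_raw)
  cidx <- country_index(countries)
  geo <- lapply(seq_len(n), function(i) {
    extract_geo(listings$origin[[i]], listings$destinations[[i]],
                listings$description[[i]], countries)
  })
  escrow <- vapply(seq_len(n), function(i) {
    extract_escrow(listings$escrow[[i]], listings$description[[i]])
  }, character(1))
  tibble::tibble(
    listing_id = listings$listing_id,
    market = listings$market,
    vendor = listings$vendor,
    product_term = prod_term,
    category = prod_cat,
    price = listings$price,
    total_g = amt$total_g,
    per_gram = per_gram_price(listings$price, amt$total_g),
    origin = vapply(geo, function(g) g$origin, character(1)),
    destinations = lapply(geo, function(g) g$destinations),
    escrow = escrow,
    sold_count = listings$sold_count,
    year = format(listings$first_seen, "%Y"),
    first_seen = listings$first_seen,
    last_seen = listings$last_seen)
}

#' Per-property extraction accuracy
#'
#' For each trading property, samples up to `n_sample` records and scores
#' the extracted value against ground truth, reported as a count-and-percent
#' table. Destination sets compare as sets; missing values count as correct
#' only when the truth is also missing.
#'
#' @param records Output of [extract_records()].
#' @param truth Ground-truth listing tibble (the generator's
#'   `truth$listings`).
#' @param n_sample Records sampled per property (default 1000).
#' @param seed Sampling seed.
#' @return Tibble with `property`, `n`, `n_correct`, `accuracy_pct`.
#' @export
evaluate_extraction <- function(records, truth, n_sample = 1000L, seed = 1L) {
  if (nrow(records) == 0) abort("empty record set")
  tr <- truth[match(records$listing_id, truth$listing_id), ]
  cmp <- list(
    vendor = records$vendor == tr$vendor,
    product = same_or_both_na(records$category, tr$category),
    price = abs(records$price - tr$price) < 1e-9,
    amount = same_or_both_na(records$total_g, tr$grams),
    origin = same_or_both_na(records$origin, tr$origin),
    destinations = mapply(function(a, b) setequal(a, b),
                          records$destinations, tr$destinations),
    escrow = records$escrow == tr$escrow,
    sold_count = same_or_both_na(records$sold_count, tr$sold_count))
  rows <- list()
  with_seed(seed, {
    for (prop in names(cmp)) {
      ok <- cmp[[prop]]
      idx <- sample(length(ok), min(n_sample, length(ok)))
      rows[[prop]] <- tibble::tibble(
        property = prop, n = length(idx), n_correct = sum(ok[idx]),
        accuracy_pct = pct(sum(ok[idx]), length(idx)))
    }
  })
  dplyr::bind_rows(rows)
}

same_or_both_na <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}
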