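#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
opitrade_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "opitrade")))
  }
  path <- system.file("extdata", file, package = "opitrade")
  if (!nzchar(path)) abort(sprintf("no packaged file '%s'", file))
  path
}

listing_columns <- c("listing_id", "market", "vendor", "title", "description",
                     "price", "currency", "amount_raw", "origin",
                     "destinations", "escrow", "sold_count", "first_seen",
                     "last_seen")

post_columns <- c("post_id", "forum", "author", "body", "posted_at",
                  "topic_label", "sentiment_label")

validate_listing_row <- function(rec) {
  if (is.null(rec$price) || is.na(rec$price) || rec$price <= 0) {
    return("nonpositive price")
  }
  if (is.null(rec$market) || is.na(rec$market) || !nzchar(rec$market)) {
    return("empty market")
  }
  if (is.null(rec$vendor) || is.na(rec$vendor) || !nzchar(rec$vendor)) {
    return("empty vendor")
  }
  fs <- suppressWarnings(as.Date(rec$first_seen))
  ls <- suppressWarnings(as.Date(rec$last_seen))
  if (is.na(fs) || is.na(ls)) return("unparseable date")
  if (fs > ls) return("first_seen after last_seen")
  NA_character_
}

listing_row_tibble <- function(rec) {
  tibble::tibble(
    listing_id = as.character(rec$listing_id),
    market = as.character(rec$market),
    vendor = as.character(rec$vendor),
    title = as.character(rec$title %||% ""),
    description = as.character(rec$description %||% ""),
    price = as.numeric(rec$price),
    currency = as.character(rec$currency %||% "USD"),
    amount_raw = as.character(rec$amount_raw %||% ""),
    origin = as.character(rec$origin %||% ""),
    destinations = list(as.character(unlist(rec$destinations))),
    escrow = as.character(rec$escrow %||% "unknown"),
    sold_count = as.integer(rec$sold_count %||% NA_integer_),
    first_seen = as.Date(rec$first_seen),
    last_seen = as.Date(rec$last_seen)
  )
}

#' Read marketplace listings
#'
#' Reads one listing record per line (JSON-lines, the canonical interchange
#' format) or a CSV with the same columns (`destinations` joined by `|`).
#' Rows violating the record invariants (positive price, nonempty market and
#' vendor, `first_seen <= last_seen`) are rejected, counted and reported
#' rather than silently dropped.
#'
#' @param path Input file.
#' @param dialect `"jsonl"` (default) or `"csv"`.
#' @return A list with `records` (tibble of listings), `rejections` (tibble
#'   with `line` and `reason`) and `n_rejected`.
#' @export
read_listings <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  raw <- if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    df$destinations <- strsplit(ifelse(is.na(df$destinations), "",
                                       df$destinations), "\\|")
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  keep <- list()
  rej <- list()
  for (i in seq_along(raw)) {
    reason <- validate_listing_row(raw[[i]])
    if (is.na(reason)) {
      keep[[length(keep) + 1L]] <- listing_row_tibble(raw[[i]])
    } else {
      rej[[length(rej) + 1L]] <- tibble::tibble(line = i, reason = reason)
    }
  }
  records <- if (length(keep)) dplyr::bind_rows(keep) else empty_listings()
  rejections <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble::tibble(line = integer(), reason = character())
  list(records = records, rejections = rejections,
       n_rejected = nrow(rejections))
}

empty_listings <- function() {
  tibble::tibble(listing_id = character(), market = character(),
                 vendor = character(), title = character(),
                 description = character(), price = numeric(),
                 currency = character(), amount_raw = character(),
                 origin = character(), destinations = list(),
                 escrow = character(), sold_count = integer(),
                 first_seen = as.Date(character()),
                 last_seen = as.Date(character()))
}

#' Write marketplace listings
#'
#' Inverse of [read_listings()]; `write_listings()` then `read_listings()`
#' round-trips the record sequence exactly.
#'
#' @param listings Tibble of listings.
#' @param path Output file.
#' @param dialect `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_listings <- function(listings, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(listings)), function(i) {
      rec <- as.list(listings[i, ])
      rec$destinations <- rec$destinations[[1]]
      rec$first_seen <- format(rec$first_seen)
      rec$last_seen <- format(rec$last_seen)
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                    digits = NA))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- as.data.frame(listings)
    df$destinations <- vapply(listings$destinations, paste, character(1),
                              collapse = "|")
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read and write forum posts
#'
#' Forum posts travel as JSON-lines with fields `post_id`, `forum`, `author`,
#' `body`, `posted_at` and optional `topic_label` / `sentiment_label`.
#' A `sentiment_label` is only valid on review posts; offending rows are
#' rejected. Empty bodies are rejected.
#'
#' @param path File path.
#' @return For `read_posts()`, a list with `records`, `rejections`,
#'   `n_rejected`; for `write_posts()`, `path` invisibly.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  keep <- vector("list", length(lines))
  rej <- list()
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[i]])
    topic <- rec$topic_label %||% NA_character_
    senti <- rec$sentiment_label %||% NA_character_
    reason <- if (is.null(rec$body) || !nzchar(rec$body)) {
      "empty body"
    } else if (!is.na(senti) && (is.na(topic) || topic != "review")) {
      "sentiment on non-review post"
    } else {
      NA_character_
    }
    if (is.na(reason)) {
      keep[[i]] <- tibble::tibble(
        post_id = as.character(rec$post_id),
        forum = as.character(rec$forum),
        author = as.character(rec$author),
        body = as.character(rec$body),
        posted_at = as.Date(rec$posted_at),
        topic_label = topic, sentiment_label = senti)
    } else {
      rej[[length(rej) + 1L]] <- tibble::tibble(line = i, reason = reason)
    }
  }
  records <- dplyr::bind_rows(keep)
  rejections <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble::tibble(line = integer(), reason = character())
  list(records = records, rejections = rejections,
       n_rejected = nrow(rejections))
}

#' @rdname read_posts
#' @param posts Tibble of forum posts.
#' @export
write_posts <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    rec <- as.list(posts[i, ])
    rec$posted_at <- format(rec$posted_at)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load the market and forum summary table
#'
#' Reads the packaged summary of the 16 studied platforms (10 marketplaces, 6
#' forums): lifespan, measurement window, record count and opioid-related
#' record count. Lifetimes are stored as ISO dates at month resolution (open =
#' first day, close = last day of the printed month); a missing `close_date`
#' means the platform was still active at collection end.
#'
#' @param path A TSV; defaults to the packaged table.
#' @return Tibble with one row per platform.
#' @export
load_markets <- function(path = opitrade_file("markets.tsv")) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character")
  tibble::tibble(
    name = df$name,
    kind = df$kind,
    open_date = as.Date(df$open_date),
    close_date = as.Date(ifelse(nzchar(df$close_date), df$close_date, NA)),
    measurement_start = as.Date(df$measurement_start),
    measurement_end = as.Date(df$measurement_end),
    n_records = as.integer(df$n_records),
    n_opioid = as.integer(df$n_opioid)
  )
}
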