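# The 13 opioid categories used throughout: one per substance family plus a
# catch-all. Category labels are fixed vocabulary, not free text.
opioid_categories <- c("Heroin", "Fentanyl", "Buprenorphine", "Oxycodone",
                       "Dihydrocodeine", "Oxymorphone", "Morphine",
                       "Methadone", "Hydromorphone", "Hydrocodone",
                       "Tramadol", "Codeine", "Others")

new_lexicon <- function(df) {
  stopifnot(all(c("term", "category", "kind", "variants", "provenance")
                %in% names(df)))
  class(df) <- c("jargon_lexicon", class(tibble::tibble()))
  df
}

# "K8/K9" style slash codes expand into one term per code; numeric-only parts
# inherit the alphabetic prefix of the first code (M15/30 -> M15, M30).
# Expansion only fires on single-token terms whose first part is an
# alpha-prefixed code, so dose ratios like "percocet 10/325" stay intact.
expand_slash_codes <- function(term) {
  if (grepl(" ", term) || !grepl("/", term)) return(term)
  parts <- strsplit(term, "/", fixed = TRUE)[[1]]
  if (!grepl("^[a-z]+[0-9]+$", parts[[1]])) return(term)
  prefix <- sub("[0-9]+$", "", parts[[1]])
  vapply(parts, function(p) {
    if (grepl("^[0-9]+$", p)) paste0(prefix, p) else p
  }, character(1), USE.NAMES = FALSE)
}

# "chyna (china white)" stores "china white" as a spelling variant of the
# single canonical term "chyna"; variants match in text but do not add terms.
split_paren_variant <- function(term) {
  m <- regmatches(term, regexec("^([^()]+)\\(([^()]+)\\)\\s*$", term))[[1]]
  if (length(m) == 3) {
    list(term = trimws(m[[2]]), variants = trimws(m[[3]]))
  } else {
    list(term = term, variants = character(0))
  }
}

#' Load an opioid keyword lexicon
#'
#' Reads a 3-column TSV (`term`, `category`, `kind`) of opioid keywords.
#' Terms are normalized (lowercase, trimmed, whitespace collapsed),
#' slash-separated pill codes are expanded into individual terms, and
#' parenthesized alternates are kept as spelling variants of one canonical
#' term. Entries with a category outside the 13 opioid categories are dropped
#' with a warning; duplicate terms keep the first occurrence.
#'
#' @param path TSV file with columns `term`, `category`, `kind`
#'   (`jargon` or `product_name`).
#' @param provenance Provenance tag stored on every entry (default `"seed"`).
#' @return A `jargon_lexicon` tibble: one row per canonical term with its
#'   category, kind, spelling `variants` (list-column) and provenance.
#' @examples
#' lex <- load_lexicon(opitrade_file("opioid_jargon.tsv"))
#' nrow(lex)            # 58 jargon terms
#' dplyr::n_distinct(lex$category)  # 13 categories
#' @export
load_lexicon <- function(path, provenance = "seed") {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
               colClasses = "character"),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    warn(sprintf("empty lexicon file '%s'", path))
    return(new_lexicon(tibble::tibble(term = character(),
                                      category = character(),
                                      kind = character(), variants = list(),
                                      provenance = character())))
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    cat_i <- trimws(df$category[[i]])
    if (!cat_i %in% opioid_categories) {
      warn(sprintf("dropping '%s': unknown category '%s'",
                   df$term[[i]], cat_i))
      next
    }
    parsed <- split_paren_variant(normalize_term(df$term[[i]]))
    for (term in expand_slash_codes(parsed$term)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = term, category = cat_i, kind = trimws(df$kind[[i]]),
        variants = list(parsed$variants), provenance = provenance)
    }
  }
  if (!length(rows)) {
    return(new_lexicon(tibble::tibble(term = character(),
                                      category = character(),
                                      kind = character(), variants = list(),
                                      provenance = character())))
  }
  out <- dplyr::bind_rows(rows)
  dup <- duplicated(out$term)
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate term(s): %s", sum(dup),
                 paste(unique(out$term[dup]), collapse = ", ")))
    out <- out[!dup, ]
  }
  new_lexicon(dplyr::arrange(out, .data$term))
}

#' Load the packaged opioid keyword set
#'
#' Combines the packaged jargon table (58 terms discovered from underground
#' corpora) with the packaged product-name list (253 terms; a synthetic
#' stand-in assembled from public opioid nomenclature) into the full
#' 311-keyword, 13-category lexicon used by the pipeline.
#'
#' @return A `jargon_lexicon` tibble with 311 rows.
#' @export
load_opioid_lexicon <- function() {
  merge_lexicons(load_lexicon(opitrade_file("opioid_jargon.tsv")),
                 load_lexicon(opitrade_file("opioid_products_synthetic.tsv")))
}

#' Merge lexicons, keeping first occurrence of each term
#'
#' @param ... `jargon_lexicon` tibbles.
#' @return A merged `jargon_lexicon`.
#' @export
merge_lexicons <- function(...) {
  out <- dplyr::bind_rows(...)
  new_lexicon(dplyr::arrange(out[!duplicated(out$term), ], .data$term))
}

#' Fold accepted jargon candidates into a lexicon
#'
#' Mirrors the manual-validation step of jargon discovery: candidates that a
#' reviewer accepted, each with an assigned opioid category, join the keyword
#' set with provenance `"discovered"`. Terms already present are left
#' untouched; candidates with a category outside the 13 are rejected.
#'
#' @param lexicon A `jargon_lexicon`.
#' @param accepted Tibble with columns `term` and `category`.
#' @return The expanded `jargon_lexicon`.
#' @export
expand_lexicon <- function(lexicon, accepted) {
  if (is.null(accepted) || nrow(accepted) == 0) return(lexicon)
  ok <- accepted$category %in% opioid_categories
  if (any(!ok)) {
    warn(sprintf("rejecting %d candidate(s) with unknown category", sum(!ok)))
    accepted <- accepted[ok, ]
  }
  add <- tibble::tibble(term = normalize_term(accepted$term),
                        category = accepted$category, kind = "jargon",
                        variants = rep(list(character(0)), nrow(accepted)),
                        provenance = "discovered")
  merge_lexicons(lexicon, add)
}

# One row per matchable surface form (terms plus their spelling variants).
lexicon_surfaces <- function(lexicon) {
  base <- tibble::tibble(surface = lexicon$term, canonical = lexicon$term,
                         category = lexicon$category, kind = lexicon$kind)
  vr <- lexicon[lengths(lexicon$variants) > 0, ]
  if (nrow(vr)) {
    extra <- tibble::tibble(
      surface = unlist(vr$variants),
      canonical = rep(vr$term, lengths(vr$variants)),
      category = rep(vr$category, lengths(vr$variants)),
      kind = rep(vr$kind, lengths(vr$variants)))
    base <- dplyr::bind_rows(base, extra)
  }
  base[!duplicated(base$surface), ]
}

#' Match opioid keywords in free text
#'
#' Case-insensitive, whole-token keyword matching with multi-word terms,
#' resolved longest-match-first and non-overlapping, scanning left to right.
#' Spelling variants (e.g. "china white" for "chyna") match and report their
#' canonical term.
#'
#' @param text Character vector of documents.
#' @param lexicon A `jargon_lexicon`.
#' @return Tibble with one row per match: `doc` (index into `text`), `term`
#'   (surface form matched), `canonical`, `category`, `kind`, and the token
#'   span `start`/`end`.
#' @examples
#' lex <- load_opioid_lexicon()
#' match_keywords("selling suboxone strips", lex)
#' @export
match_keywords <- function(text, lexicon) {
  surf <- lexicon_surfaces(lexicon)
  if (nrow(surf) == 0 || length(text) == 0) {
    return(tibble::tibble(doc = integer(), term = character(),
                          canonical = character(), category = character(),
                          kind = character(), start = integer(),
                          end = integer()))
  }
  surf_tokens <- lapply(surf$surface, function(s) tokenize_text(s)[[1]])
  surf$ntok <- lengths(surf_tokens)
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(surf))) {
    assign(paste(surf_tokens[[i]], collapse = " "), i, envir = index)
  }
  max_len <- max(surf$ntok)
  toks_all <- tokenize_text(text)
  out <- list()
  for (d in seq_along(toks_all)) {
    toks <- toks_all[[d]]
    n <- length(toks)
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (L in seq(min(max_len, n - i + 1L), 1L)) {
        key <- paste(toks[i:(i + L - 1L)], collapse = " ")
        idx <- index[[key]]
        if (!is.null(idx)) {
          out[[length(out) + 1L]] <- tibble::tibble(
            doc = d, term = surf$surface[[idx]],
            canonical = surf$canonical[[idx]],
            category = surf$category[[idx]], kind = surf$kind[[idx]],
            start = i, end = i + L - 1L)
          hit <- L
          break
        }
      }
      i <- i + max(hit, 1L)
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(doc = integer(), term = character(),
                   canonical = character(), category = character(),
                   kind = character(), start = integer(), end = integer())
}
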