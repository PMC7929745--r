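#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib opitrade, .registration = TRUE
#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median quantile rbinom rlnorm rnorm runif sd setNames qnorm
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals: exact halves round up in
#' magnitude (`round_half_up(0.125, 2)` is `0.13`), unlike base R's
#' round-half-even. Percentages throughout the package are rounded this way so
#' shares such as 9896/41614 print as 23.78.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s); zero denominators give `NA`.
#' @param digits Decimals kept (round half up, default 2).
#' @return Numeric percentage on the 0-100 scale.
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_up(100 * num / den, digits)
  out[!is.finite(out)] <- NA_real_
  as.numeric(out)
}

# Overflow-safe log(1 + exp(x)).
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  neg <- x < -35
  mid <- !big & !neg
  out[big] <- x[big]
  out[neg] <- exp(x[neg])
  out[mid] <- log1p(exp(x[mid]))
  out
}

# NFKC-style compatibility folding, lowercase, trim, collapse whitespace.
normalize_term <- function(x) {
  x <- enc2utf8(x)
  x <- fold_compat(x)
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# light compatibility folding: the forms that matter for this domain are the
# multiplication sign and typographic quotes/dashes.
fold_compat <- function(x) {
  x <- gsub("×", "x", x)         # multiplication sign -> 'x'
  x <- gsub("[‘’]", "'", x)
  x <- gsub("[“”]", '"', x)
  x <- gsub("[–—]", "-", x)
  x
}

# Tokenizer shared by keyword matching, corpus generation and the classifiers:
# lowercase, keep digits and #/-,./ inside tokens, split elsewhere.
tokenize_text <- function(x) {
  x <- normalize_term(x)
  x <- gsub("[^a-z0-9#/\\.\\$-]+", " ", x)
  strsplit(trimws(x), " +")
}

month_floor <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

add_months <- function(d, n) {
  d <- as.Date(d)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m")) + n
  y <- y + (m - 1) %/% 12
  m <- (m - 1) %% 12 + 1
  as.Date(sprintf("%04d-%02d-01", y, m))
}
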