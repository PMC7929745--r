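# Review sentiment: a linear classifier on binary term-presence features
# selected by the 2x2 chi-square score between term presence and class.

# chi-square statistic (no continuity correction) of the 2x2 contingency
# table [present/absent x positive/negative], one value per term.
chi_square_scores <- function(present_pos, present_neg, n_pos, n_neg) {
  a <- present_pos
  b <- present_neg
  c_ <- n_pos - a
  d <- n_neg - b
  n <- n_pos + n_neg
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  out <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  as.numeric(out)
}

binary_term_matrix <- function(docs, vocab = NULL) {
  toks <- lapply(tokenize_text(docs), unique)
  if (is.null(vocab)) vocab <- sort(unique(unlist(toks)))
  vidx <- seq_along(vocab)
  names(vidx) <- vocab
  ij <- lapply(seq_along(toks), function(i) {
    j <- vidx[toks[[i]]]
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    cbind(i = i, j = as.integer(j))
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = if (is.null(ij)) integer(0) else ij[, "i"],
                       j = if (is.null(ij)) integer(0) else ij[, "j"],
                       x = 1, dims = c(length(docs), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Train the chi-square sentiment classifier
#'
#' Scores every vocabulary term by the 2x2 chi-square statistic between term
#' presence and review class, keeps the top `k` terms, and fits a logistic
#' model on the selected binary features by gradient descent.
#'
#' @param docs Character vector of review documents.
#' @param labels `"positive"` / `"negative"` per document (both classes
#'   required).
#' @param k Number of selected features (default 200; capped at the
#'   vocabulary size with a warning).
#' @return A `sentiment_model`: selected `features` with their chi-square
#'   scores, and the fitted weights.
#' @export
train_sentiment <- function(docs, labels, k = 200L) {
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    abort("labels must be 'positive' or 'negative'")
  }
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) abort("both sentiment classes must be present")
  X <- binary_term_matrix(docs)
  scores <- chi_square_scores(Matrix::colSums(X[pos, , drop = FALSE]),
                              Matrix::colSums(X[!pos, , drop = FALSE]),
                              sum(pos), sum(!pos))
  ord <- order(-scores, colnames(X))
  if (k > ncol(X)) {
    warn(sprintf("k = %d exceeds the %d-term vocabulary; using all", k,
                 ncol(X)))
    k <- ncol(X)
  }
  sel <- ord[seq_len(k)]
  features <- tibble::tibble(term = colnames(X)[sel],
                             chi_square = scores[sel])
  Xs <- as.matrix(X[, sel, drop = FALSE])
  y <- ifelse(pos, 1, 0)
  # full-batch logistic regression, deterministic zero init
  w <- numeric(ncol(Xs))
  b <- 0
  for (it in seq_len(300)) {
    p <- stats::plogis(Xs %*% w + b)
    gw <- crossprod(Xs, p - y) / length(y) + 1e-4 * w
    gb <- mean(p - y)
    w <- w - 0.5 * as.numeric(gw)
    b <- b - 0.5 * gb
  }
  structure(list(features = features, w = w, b = b), class = "sentiment_model")
}

#' Classify review sentiment
#'
#' @param model A [train_sentiment()] fit.
#' @param docs Character vector.
#' @return Character vector `"positive"` / `"negative"`.
#' @export
predict_sentiment <- function(model, docs) {
  X <- as.matrix(binary_term_matrix(docs, model$features$term))
  ifelse(stats::plogis(X %*% model$w + model$b) > 0.5, "positive",
         "negative")[, 1]
}
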