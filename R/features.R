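# TF-IDF unigram+bigram features with a capped vocabulary, shared across the
# classifier's training stages so transfer operates in one feature space.

#' Build a TF-IDF vectorizer
#'
#' @param docs Character vector of documents defining the vocabulary.
#' @param max_vocab Vocabulary cap; the most document-frequent n-grams are
#'   kept (default 20000).
#' @param ngram_max Maximum n-gram order (default 2: unigrams + bigrams).
#' @param min_df Minimum document frequency (default 2).
#' @return A `text_vectorizer` with the vocabulary and smoothed idf weights.
#' @export
text_vectorizer <- function(docs, max_vocab = 20000L, ngram_max = 2L,
                            min_df = 2L) {
  grams <- doc_ngrams(docs, ngram_max)
  df <- table(unlist(lapply(grams, unique)))
  df <- df[as.integer(df) >= min_df]
  if (length(df) == 0) abort("feature vocabulary is empty")
  df <- df[order(-as.integer(df), names(df))]
  df <- df[seq_len(min(max_vocab, length(df)))]
  n <- length(docs)
  structure(list(vocab = names(df),
                 idf = log((1 + n) / (1 + as.integer(df))) + 1,
                 ngram_max = ngram_max),
            class = "text_vectorizer")
}

doc_ngrams <- function(docs, ngram_max) {
  toks <- tokenize_text(docs)
  lapply(toks, function(t) {
    out <- t
    if (ngram_max >= 2 && length(t) >= 2) {
      out <- c(out, paste(t[-length(t)], t[-1]))
    }
    out
  })
}

#' Transform documents to a sparse TF-IDF matrix
#'
#' @param vectorizer A [text_vectorizer()].
#' @param docs Character vector.
#' @return A `dgCMatrix` (documents x features), L2-normalized rows.
#' @export
vectorize_docs <- function(vectorizer, docs) {
  grams <- doc_ngrams(docs, vectorizer$ngram_max)
  vidx <- seq_along(vectorizer$vocab)
  names(vidx) <- vectorizer$vocab
  ij <- lapply(seq_along(grams), function(i) {
    tab <- table(grams[[i]])
    j <- vidx[names(tab)]
    keep <- !is.na(j)
    if (!any(keep)) return(NULL)
    cbind(i = i, j = as.integer(j[keep]), x = as.numeric(tab[keep]))
  })
  ij <- do.call(rbind, ij)
  X <- Matrix::sparseMatrix(
    i = if (is.null(ij)) integer(0) else ij[, "i"],
    j = if (is.null(ij)) integer(0) else ij[, "j"],
    x = if (is.null(ij)) numeric(0) else ij[, "x"],
    dims = c(length(docs), length(vectorizer$vocab)))
  X <- X %*% Matrix::Diagonal(x = vectorizer$idf)
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% X
}
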