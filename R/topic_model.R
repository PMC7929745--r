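# Promotion / review post detection: a feed-forward network with 3 hidden
# layers trained in three stages (proxy initialization, transfer on a small
# labeled set, iterative refinement), under a class-weighted, L1-regularized
# log loss that penalizes misclassified positives more heavily than
# negatives when the labeled classes are imbalanced.

#' Class-weighted loss specification
#'
#' Holds the penalty factors of the imbalance-weighted log-loss objective:
#' `C_plus` (misclassified positive), `C_minus` (misclassified negative) and
#' the L1 regularization coefficient `lambda`. `C_plus` must not be smaller
#' than `C_minus`; equality is the balanced case.
#'
#' @param C_plus,C_minus Positive penalty weights.
#' @param lambda Nonnegative L1 coefficient.
#' @param P,C Optional sizes of the positive/negative labeled sets the spec
#'   was derived from (bookkeeping only).
#' @return A `weighted_loss_spec`.
#' @export
weighted_loss_spec <- function(C_plus = 1, C_minus = 1, lambda = 0,
                               P = NULL, C = NULL) {
  if (C_plus <= 0 || C_minus <= 0) abort("penalty weights must be positive")
  if (lambda < 0) abort("lambda must be nonnegative")
  if (C_plus < C_minus) {
    abort("C_plus must be at least C_minus (positives carry the larger penalty)")
  }
  structure(list(C_plus = C_plus, C_minus = C_minus, lambda = lambda,
                 P = P, C = C), class = "weighted_loss_spec")
}

#' Penalty factors from class counts
#'
#' Inverse-class-frequency weighting: with `P` labeled positives and `C`
#' labeled negatives, the positive penalty is `C / P` (at least 1) and the
#' negative penalty is 1, so the rarer positives weigh proportionally more.
#'
#' @param P,C Positive / negative labeled counts (both at least 1).
#' @param mode Weighting rule; only `"inverse_frequency"` is defined.
#' @param lambda L1 coefficient stored on the returned spec (default 0).
#' @return A [weighted_loss_spec()].
#' @examples
#' set_penalties(100, 400)  # C_plus = 4, C_minus = 1
#' @export
set_penalties <- function(P, C, mode = "inverse_frequency", lambda = 0) {
  mode <- match.arg(mode)
  if (P < 1 || C < 1) abort("class counts must be at least 1")
  weighted_loss_spec(C_plus = max(1, C / P), C_minus = 1, lambda = lambda,
                     P = P, C = C)
}

#' Imbalance-weighted, L1-regularized log loss
#'
#' Computes `C_plus * sum LL(z_i)` over positives plus
#' `C_minus * sum LL(z_i)` over negatives plus `lambda * ||w||_1`, with
#' `LL(z) = log(1 + exp(-z))` evaluated overflow-safely. `margins` are
#' sign-coded scores: `y_i * f(x_i)`, positive when the example is on the
#' correct side.
#'
#' @param margins Numeric vector of sign-coded margins.
#' @param positive Logical vector: is example i a positive?
#' @param spec A [weighted_loss_spec()].
#' @param weights Numeric vector of model weights entering the L1 term
#'   (default none).
#' @return A single nonnegative number.
#' @export
weighted_log_loss <- function(margins, positive, spec = weighted_loss_spec(),
                              weights = numeric(0)) {
  if (length(margins) == 0) abort("empty example set")
  stopifnot(length(positive) == length(margins))
  ll <- log1pexp(-margins)
  spec$C_plus * sum(ll[positive]) + spec$C_minus * sum(ll[!positive]) +
    spec$lambda * sum(abs(weights))
}

#' Training parameters for the topic network
#'
#' @param hidden Hidden layer widths (default `c(256, 64, 16)`, ReLU).
#' @param vocab_size TF-IDF vocabulary cap (default 20000).
#' @param ngram_max Maximum n-gram order (default 2).
#' @param epochs Maximum epochs per training stage (default 200).
#' @param batch Mini-batch size (default 64).
#' @param lr Learning rate of plain mini-batch gradient descent (default 0.5
#'   on the mean-scaled objective).
#' @param lambda L1 coefficient (default 1e-4).
#' @param tol Stop when the relative objective change falls below this
#'   (default 1e-4).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `topic_params` list.
#' @export
topic_params <- function(hidden = c(256, 64, 16), vocab_size = 20000L,
                         ngram_max = 2L, epochs = 200L, batch = 64L,
                         lr = 0.5, lambda = 1e-4, tol = 1e-4, seed = 1L) {
  if (length(hidden) != 3) abort("the network has exactly 3 hidden layers")
  structure(list(hidden = hidden, vocab_size = vocab_size,
                 ngram_max = ngram_max, epochs = epochs, batch = batch,
                 lr = lr, lambda = lambda, tol = tol, seed = seed),
            class = "topic_params")
}

mlp_new <- function(p, hidden, seed) {
  dims <- c(p, hidden, 1L)
  with_seed(seed, {
    W <- lapply(seq_len(length(dims) - 1), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    b <- lapply(dims[-1], function(d) numeric(d))
    list(W = W, b = b)
  })
}

mlp_forward <- function(net, X) {
  A <- vector("list", length(net$W))
  H <- X
  for (l in seq_along(net$W)) {
    Z <- as.matrix(H %*% net$W[[l]])
    Z <- sweep(Z, 2, net$b[[l]], "+")
    if (l < length(net$W)) Z <- pmax(Z, 0)
    A[[l]] <- Z
    H <- Z
  }
  list(score = as.numeric(A[[length(A)]]), A = A)
}

mlp_score <- function(net, X) mlp_forward(net, X)$score

# One stage of mini-batch gradient descent on the mean-scaled weighted
# objective; L1 enters through its subgradient. Returns the updated net and
# the per-epoch objective trace.
mlp_fit <- function(net, X, y, spec, epochs, batch, lr, tol, seed) {
  n <- nrow(X)
  cw <- ifelse(y > 0, spec$C_plus, spec$C_minus)
  nl <- length(net$W)
  obj <- function() {
    s <- mlp_score(net, X)
    weighted_log_loss(y * s, y > 0, spec,
                      weights = unlist(lapply(net$W, as.numeric))) / n
  }
  history <- numeric(0)
  prev <- obj()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- mlp_forward(net, Xb)
        # d(mean weighted LL)/d score
        delta <- matrix(-(cw[idx] / n) * yb * stats::plogis(-yb * fw$score))
        for (l in seq(nl, 1)) {
          Ain <- if (l == 1) Xb else fw$A[[l - 1]]
          gW <- as.matrix(Matrix::crossprod(Ain, delta)) +
            (spec$lambda / n) * sign(net$W[[l]])
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(net$W[[l]])) * (fw$A[[l - 1]] > 0)
          }
          net$W[[l]] <- net$W[[l]] - lr * gW
          net$b[[l]] <- net$b[[l]] - lr * gb
        }
      }
      cur <- obj()
      history <- c(history, cur)
      if (is.finite(prev) && abs(prev - cur) < tol * max(abs(prev), 1e-12)) {
        prev <- cur
        break
      }
      prev <- cur
    }
  })
  list(net = net, history = history)
}

#' Stage 1: initialize the topic network on proxy corpora
#'
#' Trains the 3-hidden-layer network on large proxy sets (e.g. listing
#' descriptions as promotion-like positives against review/Q&A text) with
#' equal class penalties. The TF-IDF feature space is built here and shared
#' by all later stages, which is what makes transfer meaningful.
#'
#' @param proxy_pos,proxy_neg Character vectors of proxy documents.
#' @param params A [topic_params()].
#' @return A `topic_model` state with `stage = "initialized"`.
#' @export
train_initial <- function(proxy_pos, proxy_neg, params = topic_params()) {
  if (length(proxy_pos) == 0 || length(proxy_neg) == 0) {
    abort("both proxy sets must be nonempty")
  }
  vec <- text_vectorizer(c(proxy_pos, proxy_neg), params$vocab_size,
                         params$ngram_max)
  X <- vectorize_docs(vec, c(proxy_pos, proxy_neg))
  y <- c(rep(1, length(proxy_pos)), rep(-1, length(proxy_neg)))
  fit <- mlp_fit(mlp_new(ncol(X), params$hidden, params$seed), X, y,
                 weighted_loss_spec(lambda = params$lambda), params$epochs,
                 params$batch, params$lr, params$tol, params$seed + 1L)
  structure(list(vectorizer = vec, net = fit$net, stage = "initialized",
                 params = params, history = list(initial = fit$history),
                 pos_docs = character(0), neg_docs = character(0)),
            class = "topic_model")
}

#' @exportS3Method base::print
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> stage '%s', %d features, hidden (%s)\n",
              x$stage, length(x$vectorizer$vocab),
              paste(x$params$hidden, collapse = ", ")))
  invisible(x)
}

#' Stage 2: transfer the initialized network to labeled posts
#'
#' Continues optimization on a small manually labeled set under the
#' imbalance-weighted objective; by default the penalties come from
#' [set_penalties()] on the labeled class counts.
#'
#' @param state An initialized `topic_model`.
#' @param D_p,D_c Labeled positive / negative documents.
#' @param spec Optional [weighted_loss_spec()]; default inverse-frequency
#'   penalties with the stage's `lambda`.
#' @param epochs Optional epoch override for this stage.
#' @return The state with `stage = "transferred"`.
#' @export
transfer <- function(state, D_p, D_c, spec = NULL, epochs = NULL) {
  stopifnot(inherits(state, "topic_model"))
  if (state$stage != "initialized") {
    abort("transfer() expects a freshly initialized model")
  }
  if (length(D_p) == 0 || length(D_c) == 0) abort("empty labeled set")
  spec <- spec %||% set_penalties(length(D_p), length(D_c),
                                  lambda = state$params$lambda)
  epochs <- epochs %||% state$params$epochs
  if (epochs > 0) {
    X <- vectorize_docs(state$vectorizer, c(D_p, D_c))
    y <- c(rep(1, length(D_p)), rep(-1, length(D_c)))
    fit <- mlp_fit(state$net, X, y, spec, epochs, state$params$batch,
                   state$params$lr, state$params$tol,
                   state$params$seed + 2L)
    state$net <- fit$net
    state$history$transfer <- fit$history
  }
  state$pos_docs <- D_p
  state$neg_docs <- D_c
  state$spec <- spec
  state$stage <- "transferred"
  state
}

#' Stage 3: iterative refinement with an audit oracle
#'
#' Each iteration scores the unlabeled pool, samples a fraction of the
#' predicted positives for audit, asks the oracle which are genuine (ground
#' truth in tests, a human in production), moves the confirmed false
#' positives into the negative training set and continues training under the
#' same objective.
#'
#' @param state A transferred `topic_model`.
#' @param unlabeled Character vector of unlabeled documents.
#' @param oracle `function(indices)` returning a logical vector: is the
#'   audited document a true positive?
#' @param iterations Number of refinement iterations (default 2).
#' @param audit_fraction Fraction of predicted positives audited per
#'   iteration (default 0.10).
#' @param epochs Optional epoch override per iteration.
#' @return The state with `stage = "refined"` and a `refine_log`.
#' @export
refine <- function(state, unlabeled, oracle, iterations = 2L,
                   audit_fraction = 0.10, epochs = NULL) {
  stopifnot(inherits(state, "topic_model"))
  if (state$stage != "transferred") abort("refine() expects a transferred model")
  if (missing(oracle) || !is.function(oracle)) {
    abort("refine() requires an oracle callback")
  }
  epochs <- epochs %||% state$params$epochs
  log <- list()
  with_seed(state$params$seed + 3L, {
    for (it in seq_len(iterations)) {
      p <- predict_topic(state, unlabeled)
      pred_pos <- which(p > 0.5)
      n_audit <- ceiling(audit_fraction * length(pred_pos))
      audited <- if (n_audit >= length(pred_pos)) pred_pos else
        sort(sample(pred_pos, n_audit))
      truth <- if (length(audited)) oracle(audited) else logical(0)
      fp <- audited[!truth]
      log[[it]] <- tibble::tibble(iteration = it,
                                  n_predicted_positive = length(pred_pos),
                                  n_audited = length(audited),
                                  n_false_positive = length(fp))
      if (length(fp)) {
        state$neg_docs <- c(state$neg_docs, unlabeled[fp])
        # the augmented training set is now imbalanced; refresh the
        # inverse-frequency penalties so positives keep their weight
        state$spec <- set_penalties(length(state$pos_docs),
                                    length(state$neg_docs),
                                    lambda = state$spec$lambda)
      }
      if (epochs > 0) {
        X <- vectorize_docs(state$vectorizer,
                            c(state$pos_docs, state$neg_docs))
        y <- c(rep(1, length(state$pos_docs)),
               rep(-1, length(state$neg_docs)))
        fit <- mlp_fit(state$net, X, y, state$spec, epochs,
                       state$params$batch, state$params$lr,
                       state$params$tol, state$params$seed + 3L + it)
        state$net <- fit$net
      }
    }
  })
  state$refine_log <- dplyr::bind_rows(log)
  state$stage <- "refined"
  state
}

#' Score documents with a topic model
#'
#' @param state A `topic_model`.
#' @param docs Character vector.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_topic <- function(state, docs) {
  if (length(docs) == 0) return(numeric(0))
  stats::plogis(mlp_score(state$net, vectorize_docs(state$vectorizer, docs)))
}

#' Stratified cross-validated precision and recall
#'
#' @param trainer `function(train_docs, train_labels)` returning a function
#'   `function(docs) -> probability` (any model family).
#' @param docs Character vector of labeled documents.
#' @param labels Integer/logical labels (1 = positive).
#' @param folds Number of stratified folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `per_fold` (fold, precision, recall) and `summary`
#'   (mean, sd and normal-approximation 95% CI per metric). Folds whose
#'   held-out part has no positives are excluded from precision/recall with
#'   a warning.
#' @export
evaluate_cv <- function(trainer, docs, labels, folds = 10L, seed = 1L,
                        threshold = 0.5) {
  stopifnot(folds >= 2)
  labels <- as.integer(labels > 0)
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  rows <- list()
  for (f in seq_len(folds)) {
    test <- fold_id == f
    predict_fn <- trainer(docs[!test], labels[!test])
    p <- predict_fn(docs[test])
    pred <- p > threshold
    truth <- labels[test] > 0
    if (!any(truth)) {
      warn(sprintf("fold %d has no positives; excluded", f))
      next
    }
    prec <- if (any(pred)) sum(pred & truth) / sum(pred) else NA_real_
    rec <- sum(pred & truth) / sum(truth)
    rows[[length(rows) + 1L]] <- tibble::tibble(fold = f, precision = prec,
                                                recall = rec)
  }
  per_fold <- dplyr::bind_rows(rows)
  summarize_metric <- function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    s <- sd(x)
    ci <- qnorm(0.975) * s / sqrt(length(x))
    tibble::tibble(mean = m, sd = s, ci_low = m - ci, ci_high = m + ci,
                   n_folds = length(x))
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_metric(per_fold$precision), metric = "precision"),
    dplyr::mutate(summarize_metric(per_fold$recall), metric = "recall"))
  list(per_fold = per_fold,
       summary = summary[, c("metric", "mean", "sd", "ci_low", "ci_high",
                             "n_folds")])
}

#' Label forum posts by topic
#'
#' Posts containing no opioid keyword are labeled `other` without invoking a
#' model; the rest are scored by the promotion and the review model
#' independently at threshold 0.5, with double positives resolved by the
#' higher score.
#'
#' @param states List with elements `promotion` and `review`, each a trained
#'   `topic_model` (refined; a transferred model is accepted with a warning).
#' @param posts Tibble of forum posts (uses `body`).
#' @param lexicon A `jargon_lexicon`.
#' @param threshold Decision threshold (default 0.5).
#' @return `posts` with a `topic` column (`promotion`, `review`, `other`).
#' @export
classify_posts <- function(states, posts, lexicon, threshold = 0.5) {
  stopifnot(all(c("promotion", "review") %in% names(states)))
  for (nm in c("promotion", "review")) {
    st <- states[[nm]]$stage
    if (st == "transferred") {
      warn(sprintf("%s model is only transferred, not refined", nm))
    } else if (st != "refined") {
      abort(sprintf("%s model must be transferred or refined", nm))
    }
  }
  if (nrow(posts) == 0) {
    posts$topic <- character(0)
    return(posts)
  }
  hits <- match_keywords(posts$body, lexicon)
  has_kw <- seq_len(nrow(posts)) %in% hits$doc
  topic <- rep("other", nrow(posts))
  if (any(has_kw)) {
    idx <- which(has_kw)
    pp <- predict_topic(states$promotion, posts$body[idx])
    pr <- predict_topic(states$review, posts$body[idx])
    lab <- rep("other", length(idx))
    lab[pp > threshold & pp >= pr] <- "promotion"
    lab[pr > threshold & pr > pp] <- "review"
    topic[idx] <- lab
  }
  posts$topic <- topic
  posts
}
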