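test_that("weighted log loss matches closed forms and direct summation", {
  # single positive at the decision boundary
  expect_equal(weighted_log_loss(0, TRUE, weighted_loss_spec()), log(2))
  # L1 term alone
  expect_equal(
    weighted_log_loss(1e9, TRUE, weighted_loss_spec(lambda = 1),
                      weights = c(0.5, -0.5)),
    1.0, tolerance = 1e-9)
  # equal penalties reduce to the unweighted logistic loss
  set.seed(42)
  z <- rnorm(50, sd = 3)
  pos <- runif(50) > 0.5
  expect_equal(weighted_log_loss(z, pos, weighted_loss_spec()),
               sum(log(1 + exp(-z))))
  # label-swap symmetry of a balanced (z, -z) pair
  expect_equal(weighted_log_loss(c(1.3, -1.3), c(TRUE, FALSE),
                                 weighted_loss_spec()),
               weighted_log_loss(c(1.3, -1.3), c(FALSE, TRUE),
                                 weighted_loss_spec()))
  # direct-summation oracle on random weighted instances
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:20, 1)
    z <- rnorm(n, sd = 5)
    pos <- runif(n) > 0.3
    w <- rnorm(sample(1:10, 1))
    cp <- runif(1, 1, 5)
    lam <- runif(1, 0, 2)
    direct <- 0
    for (j in seq_len(n)) {
      direct <- direct + (if (pos[j]) cp else 1) * log(1 + exp(-z[j]))
    }
    direct <- direct + lam * sum(abs(w))
    expect_equal(
      weighted_log_loss(z, pos, weighted_loss_spec(cp, 1, lam), w),
      direct, tolerance = 1e-9)
  }
  # overflow safety
  expect_equal(weighted_log_loss(-1000, TRUE, weighted_loss_spec()), 1000)
  expect_equal(weighted_log_loss(1000, TRUE, weighted_loss_spec()), 0)
  expect_error(weighted_log_loss(numeric(0), logical(0)), "empty")
})

test_that("penalty factors follow inverse class frequency", {
  even <- set_penalties(800, 800)
  expect_equal(c(even$C_plus, even$C_minus), c(1, 1))
  skew <- set_penalties(100, 400)
  expect_equal(c(skew$C_plus, skew$C_minus), c(4, 1))
  expect_equal(set_penalties(1, 1)$C_plus, 1)
  # more positives than negatives never drops the positive penalty below 1
  expect_equal(set_penalties(400, 100)$C_plus, 1)
  expect_error(set_penalties(0, 10), "at least 1")
  expect_error(weighted_loss_spec(C_plus = 1, C_minus = 2), "C_plus")
})

test_that("initialization is deterministic and beats chance on proxy data", {
  po <- gen_posts(tiny_config(seed = 31))
  params <- tiny_topic_params(seed = 31)
  a <- train_initial(po$proxy_promotion$pos, po$proxy_promotion$neg, params)
  b <- train_initial(po$proxy_promotion$pos, po$proxy_promotion$neg, params)
  expect_identical(a$net$W, b$net$W)
  expect_equal(a$stage, "initialized")
  p <- predict_topic(a, c(po$proxy_promotion$pos, po$proxy_promotion$neg))
  y <- c(rep(1, length(po$proxy_promotion$pos)),
         rep(0, length(po$proxy_promotion$neg)))
  expect_gt(mean((p > 0.5) == (y == 1)), 0.5)
  # indistinguishable classes: balanced accuracy is chance by construction
  same <- po$proxy_promotion$pos[1:40]
  c_ <- train_initial(same, same, tiny_topic_params(seed = 31, epochs = 5L))
  ps <- predict_topic(c_, same)
  bal_acc <- (mean(ps > 0.5) + mean(!(ps > 0.5))) / 2
  expect_equal(bal_acc, 0.5)
  expect_error(train_initial(character(0), same), "nonempty")
})

test_that("transfer respects stage order and zero-epoch no-op", {
  po <- gen_posts(tiny_config(seed = 32))
  lab <- po$labeled$promotion
  st <- train_initial(po$proxy_promotion$pos, po$proxy_promotion$neg,
                      tiny_topic_params(seed = 32, epochs = 5L))
  frozen <- transfer(st, lab$body[lab$label == 1], lab$body[lab$label == 0],
                     epochs = 0)
  expect_identical(frozen$net$W, st$net$W)
  expect_equal(frozen$stage, "transferred")
  expect_error(transfer(frozen, "a", "b"), "initialized")
  expect_error(transfer(st, character(0), "b"), "empty labeled set")
  moved <- transfer(st, lab$body[lab$label == 1], lab$body[lab$label == 0],
                    epochs = 5)
  expect_false(identical(moved$net$W, st$net$W))
})

test_that("a larger positive penalty does not hurt positive recall", {
  # imbalanced labeled set (positives rare), trained to convergence: the
  # training-set recall on positives is non-decreasing in C_plus
  po <- gen_posts(tiny_config(seed = 33, post_noise = 0.3,
                              post_confusion = 0.1))
  lab <- po$labeled$promotion
  pos <- lab$body[lab$label == 1][1:20]
  neg <- lab$body[lab$label == 0]
  recalls <- vapply(c(1, 2, 4, 8), function(cp) {
    st <- train_initial(po$proxy_promotion$pos[1:40],
                        po$proxy_promotion$neg[1:40],
                        tiny_topic_params(seed = 33, epochs = 3L))
    st <- transfer(st, pos, neg,
                   spec = weighted_loss_spec(C_plus = cp, lambda = 1e-4),
                   epochs = 80)
    mean(predict_topic(st, pos) > 0.5)
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-9))
})

test_that("refinement audits predicted positives and tags the stage", {
  po <- gen_posts(tiny_config(seed = 34))
  lab <- po$labeled$promotion
  truth <- po$truth$topic_labels
  pool_lab <- truth$topic_label[match(po$pool$post_id, truth$post_id)]
  st <- train_initial(po$proxy_promotion$pos, po$proxy_promotion$neg,
                      tiny_topic_params(seed = 34, epochs = 5L))
  st <- transfer(st, lab$body[lab$label == 1], lab$body[lab$label == 0],
                 epochs = 5)
  oracle <- function(idx) pool_lab[idx] == "promotion"
  # zero iterations: only the stage tag changes
  st0 <- refine(st, po$pool$body, oracle, iterations = 0)
  expect_identical(st0$net$W, st$net$W)
  expect_equal(st0$stage, "refined")
  # full audit inspects every predicted positive
  st1 <- refine(st, po$pool$body, oracle, iterations = 1,
                audit_fraction = 1, epochs = 2)
  expect_equal(st1$refine_log$n_audited,
               st1$refine_log$n_predicted_positive)
  # missing oracle is an error
  expect_error(refine(st, po$pool$body, iterations = 1), "oracle")
  expect_error(refine(st0, po$pool$body, oracle), "transferred")
})

test_that("cross-validation report behaves on separable and null data", {
  # perfectly separable documents
  docs <- c(sprintf("alpha beta gamma %d", 1:40),
            sprintf("delta epsilon zeta %d", 1:40))
  labels <- rep(c(1, 0), each = 40)
  trainer <- function(d, l) {
    st <- train_initial(d[l == 1], d[l == 0],
                        tiny_topic_params(seed = 1, epochs = 20L,
                                          vocab_size = 200L))
    function(newdocs) predict_topic(st, newdocs)
  }
  cv <- evaluate_cv(trainer, docs, labels, folds = 5, seed = 2)
  expect_equal(cv$summary$mean[cv$summary$metric == "precision"], 1)
  expect_equal(cv$summary$mean[cv$summary$metric == "recall"], 1)
  expect_equal(nrow(cv$per_fold), 5)

  # permuted labels: precision collapses to the positive prevalence
  set.seed(9)
  perm <- sample(labels)
  cvp <- evaluate_cv(trainer, docs, perm, folds = 5, seed = 2)
  prec <- cvp$per_fold$precision
  prec <- prec[!is.na(prec)]
  if (length(prec) > 1) {
    tol <- 3 * max(sd(prec), 0.1)
    expect_lt(abs(mean(prec) - 0.5), tol)
  }
})

test_that("post classification honors the lexicon filter", {
  lex <- load_opioid_lexicon()
  # gentler noise: this test checks the filter contract and plumbing, not
  # classifier strength at full noise
  cfg <- tiny_config(seed = 35, post_noise = 0.25, post_confusion = 0.05)
  po <- gen_posts(cfg)
  params <- tiny_topic_params(seed = 35, epochs = 8L)
  truth <- po$truth$topic_labels
  pool_lab <- truth$topic_label[match(po$pool$post_id, truth$post_id)]
  states <- list()
  for (topic in c("promotion", "review")) {
    lab <- po$labeled[[topic]]
    st <- train_initial(po[[paste0("proxy_", topic)]]$pos,
                        po[[paste0("proxy_", topic)]]$neg, params)
    st <- transfer(st, lab$body[lab$label == 1], lab$body[lab$label == 0],
                   epochs = 8)
    st <- refine(st, po$pool$body,
                 function(idx) pool_lab[idx] == topic,
                 iterations = 1, epochs = 2)
    states[[topic]] <- st
  }
  out <- classify_posts(states, po$pool, lex)
  # no keyword -> other, deterministically
  hits <- match_keywords(po$pool$body, lex)
  no_kw <- setdiff(seq_len(nrow(po$pool)), hits$doc)
  expect_true(all(out$topic[no_kw] == "other"))
  # promotion posts are mostly recovered end to end
  promo <- which(pool_lab == "promotion")
  expect_gt(mean(out$topic[promo] == "promotion"), 0.5)
  # empty input passes through
  empty <- classify_posts(states, po$pool[0, ], lex)
  expect_equal(nrow(empty), 0)
})
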