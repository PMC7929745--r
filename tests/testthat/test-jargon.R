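make_embedding <- function(seed = 1, overlap = 0.8, d = 30, epochs = 3) {
  co <- gen_dual_corpora(tiny_config(seed = seed, overlap = overlap))
  list(emb = train_dual_skipgram(co$benign, co$underground, d = d,
                                 epochs = epochs, min_count = 2,
                                 seed = seed),
       truth = co$truth)
}

test_that("training is deterministic and rejects degenerate input", {
  co <- gen_dual_corpora(tiny_config(seed = 2))
  a <- train_dual_skipgram(co$benign, co$underground, d = 10, epochs = 1,
                           min_count = 2, seed = 5)
  b <- train_dual_skipgram(co$benign, co$underground, d = 10, epochs = 1,
                           min_count = 2, seed = 5)
  expect_identical(a$V_benign, b$V_benign)
  expect_identical(a$V_underground, b$V_underground)
  c_ <- train_dual_skipgram(co$benign, co$underground, d = 10, epochs = 1,
                            min_count = 2, seed = 6)
  expect_false(identical(a$V_benign, c_$V_benign))
  expect_error(train_dual_skipgram(character(0), co$underground), "nonempty")
  expect_error(train_dual_skipgram(co$benign, co$underground, d = 0), "d ")
})

test_that("training loss decreases across epochs", {
  fit <- make_embedding(seed = 3, epochs = 3)
  expect_lt(fit$emb$epoch_loss[[2]], fit$emb$epoch_loss[[1]])
  expect_lt(fit$emb$epoch_loss[[3]], fit$emb$epoch_loss[[1]])
})

test_that("words with shared contexts have closer cross-corpus vectors than decoys", {
  # planted terms mimic their seed's contexts; decoys carry unrelated topics.
  # Compare cosine(V_underground[planted], V_benign[seed]) against decoys,
  # averaged over 5 seeds.
  wins <- 0L
  for (s in 1:5) {
    fit <- make_embedding(seed = s, overlap = 1)
    emb <- fit$emb
    cos_to_seed <- function(w, seed_kw) {
      u <- emb$V_underground[w, ]
      b <- emb$V_benign[seed_kw, ]
      sum(u * b) / sqrt(sum(u^2) * sum(b^2))
    }
    planted <- fit$truth$planted
    p_scores <- mapply(cos_to_seed, planted$term, planted$seed)
    d_scores <- vapply(fit$truth$decoys$term, function(w) {
      max(vapply(fit$truth$seeds$term, function(kw) cos_to_seed(w, kw),
                 numeric(1)))
    }, numeric(1))
    if (mean(p_scores) > mean(d_scores)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("planted synonyms are recovered ahead of decoys", {
  wins <- 0L
  for (s in 1:5) {
    fit <- make_embedding(seed = s + 10, overlap = 1)
    cand <- query_jargon(fit$emb, fit$truth$seeds$term,
                         k = length(fit$truth$proper_nouns),
                         pos_filter = TRUE,
                         proper_nouns = fit$truth$proper_nouns)
    top3 <- cand$term[1:3]
    if (all(top3 %in% fit$truth$planted$term)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("query ranking matches a brute-force cosine oracle", {
  fit <- make_embedding(seed = 4)
  emb <- fit$emb
  seeds <- fit$truth$seeds$term
  got <- query_jargon(emb, seeds, k = 25)
  # exhaustive pairwise cosine, no linear algebra shortcuts
  eligible <- setdiff(emb$vocab[emb$count_underground > 0], seeds)
  brute <- vapply(eligible, function(w) {
    u <- emb$V_underground[w, ]
    max(vapply(seeds, function(kw) {
      b <- emb$V_benign[kw, ]
      sum(u * b) / sqrt(sum(u^2) * sum(b^2))
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-brute, eligible)
  expect_equal(got$term, eligible[ord][1:25])
  expect_equal(got$score, unname(brute[ord][1:25]), tolerance = 1e-12)
  expect_true(all(got$score >= -1 & got$score <= 1))
})

test_that("query edge cases behave as specified", {
  fit <- make_embedding(seed = 6)
  emb <- fit$emb
  seeds <- fit$truth$seeds$term
  # k exceeding the eligible set returns all with a warning
  n_elig <- length(setdiff(emb$vocab[emb$count_underground > 0], seeds))
  expect_warning(all_c <- query_jargon(emb, seeds, k = n_elig + 50),
                 "returning all")
  expect_equal(nrow(all_c), n_elig)
  # k = 1 with a single eligible candidate returns its exact cosine
  expect_warning(
    one <- query_jargon(emb, seeds, k = 1, pos_filter = TRUE,
                        proper_nouns = fit$truth$planted$term[[1]]),
    NA)
  w <- fit$truth$planted$term[[1]]
  u <- emb$V_underground[w, ]
  best <- max(vapply(seeds, function(kw) {
    b <- emb$V_benign[kw, ]
    sum(u * b) / sqrt(sum(u^2) * sum(b^2))
  }, numeric(1)))
  expect_equal(one$score, best, tolerance = 1e-12)
  # unknown seeds are skipped; all-unknown errors
  expect_warning(query_jargon(emb, c(seeds, "zzznotaword"), k = 5),
                 "skipping")
  expect_error(suppressWarnings(query_jargon(emb, "zzznotaword")), "no seed")
  expect_error(query_jargon(emb, seeds, k = 5, pos_filter = TRUE),
               "proper_nouns")
})

test_that("corpus-role symmetry does not bias recovery", {
  # swap the corpora and the query direction on symmetric generator output:
  # recovery rates should be statistically indistinguishable across seeds
  rates <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    co <- gen_dual_corpora(tiny_config(seed = s + 20, overlap = 1))
    seeds <- co$truth$seeds$term
    planted <- co$truth$planted$term
    k <- length(co$truth$proper_nouns)
    fwd <- train_dual_skipgram(co$benign, co$underground, d = 30,
                               epochs = 2, min_count = 2, seed = s)
    swp <- train_dual_skipgram(co$underground, co$benign, d = 30,
                               epochs = 2, min_count = 2, seed = s)
    cand_f <- query_jargon(fwd, seeds, k = k, pos_filter = TRUE,
                           proper_nouns = co$truth$proper_nouns)
    # swapped model: underground words now live on the "benign" side, so the
    # same query runs through the mirrored object
    swp2 <- swp
    swp2$V_benign <- swp$V_underground
    swp2$V_underground <- swp$V_benign
    cb <- swp$count_benign
    swp2$count_benign <- swp$count_underground
    swp2$count_underground <- cb
    cand_s <- query_jargon(swp2, seeds, k = k, pos_filter = TRUE,
                           proper_nouns = co$truth$proper_nouns)
    top <- min(10, k)
    rates[s, 1] <- mean(planted %in% cand_f$term[1:top])
    rates[s, 2] <- mean(planted %in% cand_s$term[1:top])
  }
  p <- tryCatch(stats::t.test(rates[, 1], rates[, 2], paired = TRUE)$p.value,
                error = function(e) 1)  # zero-variance differences
  expect_gt(ifelse(is.nan(p), 1, p), 0.05)
})
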