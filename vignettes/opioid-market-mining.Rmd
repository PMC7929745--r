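---
title: "Methods: mining opioid trading activity on anonymous markets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining opioid trading activity on anonymous markets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where several readings
were defensible. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Anonymous (Tor-hidden) marketplaces and their companion forums are a
substantial channel of the opioid supply chain. Profiling that channel
requires four capabilities that this package implements as separable,
individually tested modules: (1) recognizing opioid-related records, which
demands a lexicon that includes community jargon, not just product names;
(2) separating promotion and review posts from general forum chatter; (3)
extracting structured trade facts (price per gram, geography, escrow) from
semi-structured listings; and (4) aggregating those facts into supply-chain
statistics about commodities, suppliers and transactions.

## Dual-corpus skip-gram for jargon discovery

A jargon term behaves like an ordinary word in everyday text but like a
drug name in underground text. The detector makes that comparison
geometric. A single skip-gram-with-negative-sampling model is trained over
the concatenation of a benign and an underground corpus, with the input
layer doubled: a center token updates the input row belonging to its
corpus, so every vocabulary word ends with a benign-context vector and an
underground-context vector, while the shared output layer forces both into
one comparable space. Candidates are ranked by the maximum cosine
similarity between their underground vector and the benign vectors of the
seed opioid keywords, restricted to proper nouns, and the top 100 go to
manual validation (`query_jargon(k = 100)`).

Hyperparameters follow standard skip-gram practice and are all exposed:
dimension `d = 100`, window 5 (reduced per position, as usual), 5 negative
samples from the unigram distribution to the 0.75 power, 5 epochs, minimum
count 5, initial learning rate 0.025 with linear decay. Frequent-word
subsampling is off by default. Training is single-threaded with an
internal xorshift RNG, so a seed fixes the vectors bit-for-bit — we traded
the usual asynchronous-update speedup for exact reproducibility, which
matters more at desk scale.

Two numerical details deserve note. Words absent from one corpus keep a
near-zero untrained vector on that side and are excluded from queries on
that side, avoiding meaningless cosines. And raw-vocabulary rankings
suffer *hubness*: input vectors of rare words receive few updates, and
those few updates are dominated by the globally shared context direction,
so barely trained words can show spuriously high cosine to everything.
The proper-noun restriction of the query — also the protocol that
motivated the method — removes exactly this failure mode; the package's
recovery experiments therefore always rank within the generator's
proper-noun token class, with enough decoy proper nouns (200 by default)
that the top-100 cut remains selective.

## Topic classification with an imbalance-weighted loss

Promotion/review detection is two independent binary models (not one
3-class softmax), each a feed-forward network with three hidden layers —
(256, 64, 16) by default, ReLU activations, sigmoid output — on shared
TF-IDF unigram+bigram features with a capped vocabulary (20,000). The
feature space is built at the initialization stage and reused by all later
stages; transfer would be meaningless across changing feature spaces.

The objective is a class-weighted, L1-regularized log loss: misclassified
positives cost `C_plus`, negatives `C_minus`, with
`LL(z) = log(1 + exp(-z))` computed overflow-safely. The penalty ratio is
inverse class frequency, `C_plus / C_minus = C / P` with `C_minus = 1`,
clamped at 1 from below. Training is three stages:

1. **Initialization** on large proxy corpora (listing-description-like
   positives against review/Q&A negatives) with equal penalties.
2. **Transfer** on a small labeled set (800 + 800 per topic by default)
   under the weighted objective.
3. **Refinement**, two iterations: score the unlabeled pool, audit 10% of
   predicted positives through an oracle (ground truth in tests, a human
   in production), move confirmed false positives into the negative set
   and continue training. Because this grows the negative set, the
   inverse-frequency penalties are recomputed each iteration — the
   imbalance the weighting exists for is created by the procedure itself,
   and refreshing the weights is what keeps refinement from trading recall
   for precision.

The optimizer is plain mini-batch gradient descent (batch 64, learning
rate 0.5 on the mean-scaled objective, L1 via subgradient), stopping at a
relative objective change below 1e-4 or 200 epochs. Momentum and proximal
steps were left out deliberately: the networks are small, determinism under
a fixed seed is a hard requirement, and the comparison of interest
(transfer vs no transfer) must not be confounded by optimizer tuning.

Evaluation is stratified 10-fold cross-validated precision and recall with
normal-approximation 95% intervals. The package's model-comparison
experiment (`evaluate_transfer_benefit()`) holds the architecture and the
total labeled-stage epoch budget fixed and varies only the presence of the
initialization stage, so any gap is attributable to transfer.

## Information extraction

* **Quantity grammar.** `parse_amount()` recognizes "X mg x N pills",
  "N x X mg", "N pills X mg", "X g"/"X grams", and a bare "X mg"; the
  multiplication sign is normalized to "x". Anything else is a no-amount
  marker that excludes the listing from per-gram statistics — silently
  guessing a mass would poison the price distributions.
* **Price filter.** Within each product-category-by-year group, prices
  above 5x or below 0.25x the group median are dismissed in a single pass
  against the full-group median. The iterative re-filtering reading was
  rejected: it changes results, and nothing in the rule's statement calls
  for it. Groups of size one are never filtered. The filter is scale
  equivariant, and kept + removed always partitions the input.
* **Geography.** Structured origin/destination fields win after
  canonicalization against a packaged country dictionary (aliases like
  "uk", "usa", plus the region tokens "Europe" and "worldwide"). In free
  text, a country mention counts only within ±6 tokens of a shipping cue
  (ship/origin/destination), with the nearest preceding "from"/"to"
  deciding the side — so "Vietnamese Heroin" in a product name never sets
  geography.
* **Escrow.** The structured field wins; otherwise the keyword "escrow"
  with a 3-token negation window ("no escrow" → no); else unknown.
* **Sentiment.** Per-term 2x2 chi-square (term presence x class, no
  continuity correction) ranks the vocabulary; a logistic model on the top
  k = 200 binary features classifies reviews. The statistic is
  cross-checked in tests against `chisq.test(correct = FALSE)`.

## Supply-chain analytics

"Disappearance" of a listing is defined as the month after its last
sighting — the only definition computable from first/last dates without
knowing the scrape cadence — which yields the conservation identity (new
minus disappeared equals listings alive in the final month) asserted on
every synthetic run. Supplier identity is exact ID-string equality within
and across markets; the caveat that IDs are not people is propagated in
output metadata and never silently resolved. Migration is a deterministic
predicate, not an estimator: vendor active in a closed market, first
activity in the destination strictly after the closure, no earlier
destination activity. Percentages use two-decimal round-half-up, the
convention under which the package's printed ratios (23.78, 36.37)
reproduce from their own numerators and denominators.

## What the synthetic generator does and does not emulate

Every input is generated from one seeded configuration
(`generator_config()`), with ground truth for each planted property:

* **Corpora** are topic-mixture token streams: each seed keyword owns a
  disjoint block of 40 context words (geometric weights); planted jargon
  shadows a seed's topic at a configurable overlap (default 0.8); 200
  decoy proper nouns carry unrelated topics; both registers share a
  Zipf-distributed background. Defaults give a 5000-word vocabulary and
  about half a million tokens — sized so the full 5-seed recovery
  experiment runs in a few minutes on one CPU.
* **Posts** mix register vocabularies (promotion, review, Q&A) with
  background noise (50% in labeled/pool posts), cross-register confusion
  (25%), and probabilistic price/ship-from phrases, so the desk-scale task
  is genuinely imperfectly separable and a small labeled set cannot cover
  the full register vocabulary — the property that makes proxy
  pretraining help, and the reason the transfer-vs-baseline ordering is a
  meaningful check rather than a ceiling tie. Labeled sets default to
  800 + 800 per topic; proxy sets are roughly 1% of full-scale sizes.
* **Listings** draw clean per-gram prices log-normally (sd 0.25 on the log
  scale) around per-category medians, truncated to the ratio band
  [0.55, 1.9]; injected outliers sit at ≥10.5x or ≤0.12x the category
  median. Those bands are chosen so that, for any group outlier share
  below one half, the overall group median stays inside the clean band
  and the 5x/0.25x rule provably removes exactly the injected set — the
  filter test is exact, not statistical. Outliers are allocated per
  category-year group at `floor(rate * size)` so no group tips past half.
* **Vendors** get activity intervals inside the packaged market
  measurement windows; concurrent cross-market vendors share an anchor
  date in both markets, and planted migrations place the first
  destination listing strictly after the source market's closure, so
  migration detection against ground truth is exact by construction.

What it does **not** emulate: natural-language fluency, HTML structure of
real markets, scrape-cadence artifacts, vendor-name reuse by different
people, non-USD currencies in structured prices, or any distributional
fact about the real corpora beyond their published counts. Passing tests
on generator output therefore demonstrate correctness of the machinery
under controlled conditions, not performance on real darknet text.

## Packaged reference tables

The market summary table ships with lifetimes and measurement windows at
month resolution (open = first day, close = last day of the printed
month; an open-ended lifetime has no close date). The jargon table
expands slash-separated pill codes into individual terms, with
numeric-only parts inheriting the alphabetic prefix of the first code
("M15/30" → M15, M30), and keeps parenthesized alternates as spelling
variants of one canonical term — the only convention under which the
table totals 58 terms. The 253-term product-name list is a constructed
stand-in (the file is named `*_synthetic.tsv`) assembled from public
opioid nomenclature, since the original product-name sources are not
reproduced; merged with the jargon it yields the 311-keyword, 13-category
lexicon the pipeline uses.

## Limitations

The pipeline inherits the identification caveats of its domain: supplier
and buyer counts are upper bounds over ID strings; cross-market identity
is string equality; scam-report counting is keyword-based with no claim of
equivalence to any manual procedure. The desk-scale classifier numbers are
properties of the synthetic register model, not estimates of performance
on human-annotated forum data. The weighted-loss penalty rule and several
training details (hidden widths, optimizer, stopping) are conventions
chosen here and documented above, since no single canonical choice exists;
all are exposed as parameters.
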