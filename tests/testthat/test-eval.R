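test_that("the shipped label map is valid and covers all ten categories", {
  lm <- load_label_map()
  expect_setequal(unique(lm$entry_category), cc_categories())
  expect_equal(anyDuplicated(lm$subcategory_label), 0L)
  # elephant aggregates exactly its two subcategories
  expect_setequal(lm$subcategory_label[lm$entry_category == "elephant"],
                  c("indian_elephant", "african_elephant"))
})

test_that("entry-level aggregation sums subcategory probabilities", {
  lm <- load_label_map()
  vocab <- lm$subcategory_label

  # one-hot on african_elephant decides elephant
  p <- stats::setNames(rep(0, length(vocab)), vocab)
  p["african_elephant"] <- 1
  res <- aggregate_entry_level(p, lm)
  expect_equal(res$decision, "elephant")
  expect_equal(unname(res$scores["elephant"]), 1)

  # uniform over a 1000-label vocabulary: elephant score = 2/1000
  big <- stats::setNames(rep(1 / 1000, 1000),
                         c(vocab, sprintf("unmapped_%03d", seq_len(1000 - length(vocab)))))
  res <- aggregate_entry_level(big, lm)
  expect_equal(unname(res$scores["elephant"]), 0.002, tolerance = 1e-12)
  # brute-force summation oracle over every category
  for (cc in cc_categories()) {
    expect_equal(unname(res$scores[cc]),
                 sum(big[names(big) %in% lm$subcategory_label[lm$entry_category == cc]]),
                 tolerance = 1e-12)
  }
  # aggregated mass cannot exceed 1
  expect_lte(sum(res$scores), 1 + 1e-6)

  # all mass on unmapped labels: decision "none"
  q <- stats::setNames(rep(0, length(vocab) + 1), c(vocab, "zebra"))
  q["zebra"] <- 1
  expect_equal(aggregate_entry_level(q, lm)$decision, "none")

  expect_error(aggregate_entry_level(unname(p), lm), "named")
  expect_error(aggregate_entry_level(p * 2, lm), "sum to 1")
})

test_that("cue-conflict outcomes classify decisions against both cues", {
  man <- fix_manifest()
  inc <- man[!man$congruent, ][1:3, ]
  dec <- c(inc$shape_category[1], inc$texture_category[2], "none")
  # force a decision distinct from both cues on trial 3
  dec[3] <- setdiff(cc_categories(),
                    c(inc$shape_category[3], inc$texture_category[3]))[1]
  out <- score_cue_conflict(dec, inc)
  expect_equal(out$outcome, c("shape_correct", "texture_correct", "other"))
  expect_error(score_cue_conflict(dec[1:2], inc), "one decision per")
  # congruent records are dropped by default
  all_dec <- rep("fish", nrow(man))
  expect_equal(nrow(score_cue_conflict(all_dec, man)), sum(!man$congruent))
  expect_equal(nrow(score_cue_conflict(all_dec, man, exclude_congruent = FALSE)),
               nrow(man))
})

test_that("the bias statistic reproduces the published worked examples", {
  # equal trial counts, shape accuracy 35%, texture accuracy 27% -> 44% bias
  n <- 10000
  out <- data.frame(outcome = c(rep("shape_correct", 3500),
                                rep("texture_correct", 2700),
                                rep("other", n - 6200)))
  b <- compute_bias(out)
  expect_equal(b$texture_bias, 2700 / 6200, tolerance = 1e-12)
  expect_equal(format_percent(b$texture_bias), "44")
  expect_equal(format_percent(b$shape_bias), "56")
  # 3D accuracies 45% / 19% -> shape bias 70%
  out3 <- data.frame(outcome = c(rep("shape_correct", 4500),
                                 rep("texture_correct", 1900),
                                 rep("other", n - 6400)))
  expect_equal(format_percent(compute_bias(out3)$shape_bias), "70")
})

test_that("bias is invariant to 'other' outcomes and handles edge cases", {
  base <- data.frame(outcome = c(rep("shape_correct", 30), rep("texture_correct", 20)))
  more <- rbind(base, data.frame(outcome = rep("other", 500)))
  expect_equal(compute_bias(base)$texture_bias, compute_bias(more)$texture_bias)
  pure <- data.frame(outcome = rep("shape_correct", 10))
  expect_equal(compute_bias(pure)$texture_bias, 0)
  none <- data.frame(outcome = rep("other", 10))
  expect_true(is.na(compute_bias(none)$texture_bias))
  expect_error(compute_bias(base[0, , drop = FALSE]), "nonempty")
})

test_that("oracle classifiers are calibrated", {
  lm <- load_label_map()
  man <- fix_manifest()
  inc <- man[!man$congruent & man$condition == "3D", ]
  shape <- run_evaluation(oracle_classifier("shape_oracle", lm), inc, lm)
  expect_equal(shape$bias$texture_bias, 0)
  expect_equal(shape$bias$shape_accuracy, 1)
  tex <- run_evaluation(oracle_classifier("texture_oracle", lm), inc, lm)
  expect_equal(tex$bias$texture_bias, 1)
  # determinism under seed
  c1 <- oracle_classifier("mixture", lm, p = 0.4, seed = 5)
  c2 <- oracle_classifier("mixture", lm, p = 0.4, seed = 5)
  expect_identical(c1(inc), c2(inc))
  expect_error(oracle_classifier("mixture", lm, p = 1.5), "p must be")
})

test_that("mixture oracles recover 1 - p within binomial error", {
  lm <- load_label_map()
  man <- fix_manifest(3, 3)
  inc <- man[!man$congruent, ]
  n <- 5000
  sub <- inc[local_seed_sample(nrow(inc), n, seed = 99), ]
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    ev <- run_evaluation(oracle_classifier("mixture", lm, p = p, seed = 42), sub, lm)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(ev$bias$texture_bias - (1 - p)), 3 * se + 1e-9,
              label = sprintf("texture bias at p=%.1f", p))
  }
})

test_that("uniform random decisions drive texture bias toward one half", {
  lm <- load_label_map()
  man <- fix_manifest(3, 3)
  inc <- man[!man$congruent, ]
  sub <- inc[local_seed_sample(nrow(inc), 8000, seed = 7), ]
  ev <- run_evaluation(oracle_classifier("uniform_random", lm, seed = 11), sub, lm)
  # both cue-correct rates are ~1/10, so the ratio concentrates near 0.5
  expect_lt(abs(ev$bias$texture_bias - 0.5), 0.06)
  expect_lt(abs(ev$bias$shape_accuracy - 0.1), 0.02)
})

test_that("condition metrics stratify correctly and match pooled bias", {
  lm <- load_label_map()
  man <- fix_manifest()
  inc <- man[!man$congruent, ]
  ev <- run_evaluation(oracle_classifier("shape_oracle", lm), inc, lm)
  cells <- ev$metrics$cells
  strata <- cells[cells$canonicality != "all", ]
  expect_true(all(strata$shape_accuracy == 1))
  expect_true(all(ev$metrics$gain == 0))
  # marginal rows equal compute_bias on the pooled condition outcomes
  for (cd in c("3D", "2D")) {
    row <- cells[cells$condition == cd & cells$canonicality == "all", ]
    pooled <- compute_bias(ev$outcomes[ev$outcomes$condition == cd, ])
    expect_equal(row$shape_accuracy, pooled$shape_accuracy)
    expect_equal(row$texture_bias, pooled$texture_bias)
  }
})

test_that("a canonicality-dependent classifier shows zero 3D gain", {
  lm <- load_label_map()
  man <- fix_manifest()
  inc <- man[!man$congruent, ]
  # accuracy depends only on canonicality: answer shape on canonical views,
  # texture otherwise -- identically in both conditions
  clf <- function(manifest) {
    vocab <- lm$subcategory_label
    rep_label <- vapply(cc_categories(), function(cc)
      vocab[lm$entry_category == cc][1], "")
    ans <- ifelse(manifest$canonicality == "canonical",
                  manifest$shape_category, manifest$texture_category)
    probs <- matrix(0, nrow(manifest), length(vocab),
                    dimnames = list(NULL, vocab))
    probs[cbind(seq_len(nrow(manifest)), match(rep_label[ans], vocab))] <- 1
    probs
  }
  ev <- run_evaluation(clf, inc, lm)
  expect_equal(unname(ev$metrics$gain["canonical"]), 0)
  expect_equal(unname(ev$metrics$gain["noncanonical"]), 0)
})
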