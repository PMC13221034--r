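test_that("the shape block crosses 8 stimuli per category and condition", {
  man <- fix_manifest(3, 3)
  trials <- build_exp1_trials(man, seed = 4)
  shape <- trials[trials$block == "shape_task" & !trials$practice, ]
  expect_equal(nrow(shape), 160)
  tab <- table(shape$shape_category, shape$condition)
  expect_true(all(tab == 8))
  # shape and texture category never coincide, in either block
  main <- trials[!trials$practice, ]
  expect_equal(sum(main$shape_category == main$texture_category), 0)
  texture <- main[main$block == "texture_task", ]
  expect_equal(nrow(texture), 160)
  expect_true(all(table(texture$texture_category, texture$condition) == 8))
  # correct response follows the block's task
  expect_equal(shape$correct_response, shape$shape_category)
  expect_equal(texture$correct_response, texture$texture_category)
  # practice trials flagged, 10 per block
  expect_equal(sum(trials$practice), 20)
})

test_that("exp1 schedules are reproducible permutations across seeds", {
  man <- fix_manifest(3, 3)
  t1 <- build_exp1_trials(man, seed = 4)
  t2 <- build_exp1_trials(man, seed = 4)
  expect_identical(t1, t2)
  t3 <- build_exp1_trials(man, seed = 5)
  expect_false(identical(t1$stimulus_id, t3$stimulus_id))
  # different order, identical cell structure
  expect_equal(table(t3$cell[!t3$practice]), table(t1$cell[!t1$practice]))
  expect_error(build_exp1_trials(fix_manifest()[1:40, ], seed = 1),
               "insufficient")
})

test_that("exp2 schedules fill each condition-by-canonicality cell", {
  man <- fix_manifest(3, 3)
  trials <- build_exp2_trials(man, seed = 4)
  main <- trials[!trials$practice, ]
  expect_equal(nrow(main), 80)
  tab <- table(main$condition, main$canonicality)
  expect_true(all(tab == 20))
  expect_true(all(main$correct_response == main$shape_category))
  expect_equal(sum(trials$practice), 16)
  t2 <- build_exp2_trials(man, seed = 9)
  expect_false(identical(main$stimulus_id,
                         t2$stimulus_id[!t2$practice]))
  expect_equal(table(t2$condition[!t2$practice], t2$canonicality[!t2$practice]),
               tab)
  expect_error(build_exp2_trials(man[man$canonicality == "canonical", ]),
               "empty")
})

test_that("simulated observers hit their per-cell accuracy targets", {
  man <- fix_manifest(3, 3)
  trials <- build_exp2_trials(man, seed = 4)
  perfect <- observer_params(accuracy = c("3D:canonical" = 1, "2D:canonical" = 1,
                                          "3D:noncanonical" = 1, "2D:noncanonical" = 1))
  expect_true(all(simulate_observer(perfect, trials)$correct))
  never <- observer_params(accuracy = c("3D:canonical" = 0, "2D:canonical" = 0,
                                        "3D:noncanonical" = 0, "2D:noncanonical" = 0))
  expect_false(any(simulate_observer(never, trials)$correct))
  # 2D shape accuracy 0.87 recovered within 3 binomial SE on many trials
  big <- do.call(rbind, replicate(125, trials[!trials$practice, ],
                                  simplify = FALSE))
  p87 <- observer_params(accuracy = c("3D:canonical" = 0.87, "2D:canonical" = 0.87,
                                      "3D:noncanonical" = 0.87, "2D:noncanonical" = 0.87),
                         seed = 6)
  resp <- simulate_observer(p87, big)
  se <- sqrt(0.87 * 0.13 / nrow(big))
  expect_lt(abs(mean(resp$correct) - 0.87), 3 * se)
  expect_true(all(resp$rt > 0))
  expect_error(simulate_observer(observer_params(accuracy = c(x = 0.5)), trials),
               "no accuracy parameter")
})

test_that("rm_anova_2x2 matches the independent sums-of-squares oracle", {
  for (rep in 1:5) {
    pop <- simulate_population(4 + rep, n_trials_per_cell = 15, seed = rep)
    got <- rm_anova_2x2(pop)
    want <- oracle_rm_anova(pop)
    expect_equal(got$effects$F[got$effects$effect == "A"], want$F_A, tolerance = 1e-8)
    expect_equal(got$effects$F[got$effects$effect == "B"], want$F_B, tolerance = 1e-8)
    expect_equal(got$effects$F[got$effects$effect == "A:B"], want$F_AB, tolerance = 1e-8)
    expect_equal(got$effects$ss, unname(want$SS[c("A", "B", "AB")]), tolerance = 1e-10)
    expect_equal(got$effects$ss_error, unname(want$SS[c("AS", "BS", "ABS")]),
                 tolerance = 1e-10)
  }
})

test_that("rm_anova_2x2 agrees with aov's within-subject strata", {
  pop <- simulate_population(10, n_trials_per_cell = 25, seed = 17)
  got <- rm_anova_2x2(pop)
  pop$subject <- factor(pop$subject)
  fit <- summary(stats::aov(value ~ A * B + Error(subject / (A * B)), data = pop))
  f_aov <- c(fit[["Error: subject:A"]][[1]]["A", "F value"],
             fit[["Error: subject:B"]][[1]]["B", "F value"],
             fit[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  expect_equal(got$effects$F, unname(f_aov), tolerance = 1e-8)
})

test_that("constant tables give F = 0 and contrasts report paired stats", {
  flat <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  flat$value <- 0.8
  res <- rm_anova_2x2(flat)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$contrasts$delta == 0))
  # hand-built table: contrast delta equals the marginal mean difference
  pop <- simulate_population(8, n_trials_per_cell = 20, seed = 2)
  res2 <- rm_anova_2x2(pop)
  m <- tapply(pop$value, pop$A, mean)
  a_row <- res2$contrasts[startsWith(res2$contrasts$contrast, "A: "), ]
  expect_equal(a_row$delta, unname(m[1] - m[2]), tolerance = 1e-12)
  expect_error(rm_anova_2x2(pop[-1, ]), "balanced")
  expect_error(rm_anova_2x2(pop[pop$subject <= 2, ]), "3 subjects")
})

test_that("a pure interaction inflates only the interaction F", {
  # cells where A and B effects cancel but A:B is strong
  acc <- c("a1:b1" = 0.9, "a1:b2" = 0.6, "a2:b1" = 0.6, "a2:b2" = 0.9)
  f_small <- sapply(1:10, function(s)
    rm_anova_2x2(simulate_population(6, acc, 30, seed = s))$effects$F)
  f_large <- sapply(1:10, function(s)
    rm_anova_2x2(simulate_population(40, acc, 30, seed = s + 100))$effects$F)
  # interaction F grows with sample size; main effects hover near their null
  expect_gt(median(f_large[3, ]), median(f_small[3, ]))
  expect_gt(median(f_large[3, ]), 50)
  expect_lt(median(f_large[1, ]), 5)
  expect_lt(median(f_large[2, ]), 5)
})
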