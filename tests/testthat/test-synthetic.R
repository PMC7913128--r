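test_that("spec validation rejects inconsistent settings", {
  expect_error(synthetic_spec(M = 10, n_actives = 10), "smaller than M")
  expect_error(synthetic_spec(p_signal = 0.4, p_noise = 0.5), "p_noise")
  expect_error(synthetic_spec(n_informative_targets = 20), "n_informative")
  expect_error(synthetic_spec(M = 30, n_actives = 5, n_decoys_per_column = 3),
               "decoys")
})

test_that("generated matrices are deterministic under the seed", {
  sp <- synthetic_spec(M = 50, n_targets = 4, n_off_targets = 2,
                       n_informative_targets = 3, n_informative_off_targets = 1,
                       n_actives = 4, n_decoys_per_column = 1, seed = 99)
  g1 <- gen_probability_matrix(sp)
  g2 <- gen_probability_matrix(sp)
  expect_identical(g1$matrix$P, g2$matrix$P)
  expect_identical(g1$truth$active_ids, g2$truth$active_ids)
  # shape and role partition
  expect_equal(dim(g1$matrix$P), c(50L, 6L))
  expect_equal(sum(g1$matrix$roles == "target"), 4)
  expect_equal(sum(g1$truth$planted_mask), 4)
  expect_true(all(g1$matrix$P >= 0 & g1$matrix$P <= 1))
})

test_that("the degenerate noiseless generator separates actives exactly", {
  sp <- synthetic_spec(M = 40, n_targets = 4, n_off_targets = 2,
                       n_informative_targets = 3, n_informative_off_targets = 1,
                       n_actives = 4, p_signal = 1, p_noise = 0,
                       conc_signal = Inf, conc_background = Inf,
                       conc_noise = Inf, n_decoys_per_column = 0, seed = 1)
  g <- gen_probability_matrix(sp)
  d <- desirability_scores(g$matrix, g$truth$planted_mask)
  expect_equal(sort(d$D[d$compound_id %in% g$truth$active_ids]), rep(1, 4))
  expect_equal(sort(unique(d$D[!d$compound_id %in% g$truth$active_ids])), 0)
})

test_that("the planted mask maximizes BEDROC over all masks in the noiseless case", {
  sp <- synthetic_spec(M = 60, n_targets = 5, n_off_targets = 3,
                       n_informative_targets = 3, n_informative_off_targets = 2,
                       n_actives = 5, p_signal = 1, p_noise = 0,
                       conc_signal = Inf, conc_background = Inf,
                       conc_noise = Inf, n_decoys_per_column = 0, seed = 2)
  g <- gen_probability_matrix(sp)
  ctx <- moscreen:::ga_context(g$matrix, 160.9)
  all_masks <- as.matrix(expand.grid(rep(list(0:1), 8)))
  fits <- moscreen:::eval_population(all_masks, ctx)
  planted_fit <- ga_fitness(g$truth$planted_mask, g$matrix)
  expect_equal(planted_fit, max(fits))
})

test_that("planted-mask ranking achieves high BEDROC across seeds", {
  good <- 0
  for (seed in 1:10) {
    g <- gen_probability_matrix(synthetic_spec(seed = seed))
    b <- bedroc(rank_by_desirability(g$matrix, g$truth$planted_mask), 160.9)
    if (b > 0.5) good <- good + 1
  }
  expect_gte(good, 9)
})

test_that("decoys rank below actives only while their column is selected", {
  sp <- synthetic_spec(M = 300, n_targets = 5, n_off_targets = 3,
                       n_informative_targets = 4, n_informative_off_targets = 2,
                       n_actives = 10, n_decoys_per_column = 3, seed = 8)
  g <- gen_probability_matrix(sp)
  full <- desirability_scores(g$matrix, g$truth$planted_mask)
  col1 <- g$truth$decoys$column[1]
  dec1 <- g$truth$decoys$compound_id[g$truth$decoys$column == col1]
  dropped <- g$truth$planted_mask
  dropped[col1] <- FALSE
  part <- desirability_scores(g$matrix, dropped)
  act_mean_full <- mean(full$D[full$compound_id %in% g$truth$active_ids])
  dec_full <- mean(full$D[full$compound_id %in% dec1])
  dec_part <- mean(part$D[part$compound_id %in% dec1])
  act_mean_part <- mean(part$D[part$compound_id %in% g$truth$active_ids])
  # with the column in, its decoys trail the actives clearly ...
  expect_lt(dec_full, act_mean_full)
  # ... without it, the gap collapses
  expect_lt(act_mean_part - dec_part, act_mean_full - dec_full)
})

test_that("activity-record fixtures recover truth when replicates agree", {
  sp <- synthetic_spec(M = 20, n_targets = 3, n_off_targets = 2,
                       n_informative_targets = 2, n_informative_off_targets = 1,
                       n_actives = 2, replicate_count = 3,
                       disagreement_rate = 0, seed = 5)
  gen <- gen_activity_records(sp)
  lab <- label_activity(gen$records)
  expect_equal(nrow(attr(lab, "rejected")), 0)
  res <- resolve_replicates(lab)
  expect_equal(nrow(res$discarded), 0)
  merged <- merge(res$consensus, gen$truth, by = c("compound_id", "target_id"))
  expect_equal(nrow(merged), nrow(gen$truth))
  expect_equal(as.character(merged$label.x), as.character(merged$label.y))
})

test_that("single-report pairs always pass through", {
  sp <- synthetic_spec(M = 10, n_targets = 2, n_off_targets = 1,
                       n_informative_targets = 1, n_informative_off_targets = 1,
                       n_actives = 2, replicate_count = 1,
                       disagreement_rate = 0.5, seed = 6)
  gen <- gen_activity_records(sp)
  res <- resolve_replicates(label_activity(gen$records))
  expect_equal(nrow(res$discarded), 0)
  expect_equal(nrow(res$consensus), nrow(gen$truth))
})

test_that("heavy disagreement discards pairs at the expected binomial rate", {
  sp <- synthetic_spec(M = 50, n_targets = 5, n_off_targets = 3,
                       n_informative_targets = 4, n_informative_off_targets = 2,
                       n_actives = 5, replicate_count = 4,
                       disagreement_rate = 0.5, seed = 7)
  gen <- gen_activity_records(sp)
  res <- resolve_replicates(label_activity(gen$records))
  n_pairs <- nrow(gen$truth)
  frac <- nrow(res$discarded) / n_pairs
  # each replicate is a coin flip: P(2-2 split) = C(4,2)/16 = 0.375
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.5)
})

test_that("synthetic artifacts re-parse losslessly through the loaders", {
  sp <- synthetic_spec(M = 30, n_targets = 4, n_off_targets = 2,
                       n_informative_targets = 3, n_informative_off_targets = 1,
                       n_actives = 3, n_decoys_per_column = 1, seed = 9)
  g <- gen_probability_matrix(sp)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(g, dir)
  expect_true(all(file.exists(paths)))
  back <- read_probability_matrix(file.path(dir, "probabilities.tsv"),
                                  file.path(dir, "roles.tsv"),
                                  file.path(dir, "actives.txt"))
  expect_equal(back$P, g$matrix$P, tolerance = 1e-12)
  expect_equal(back$roles, g$matrix$roles)
  expect_equal(back$actives, g$matrix$actives)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$active_ids), g$truth$active_ids)
})
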