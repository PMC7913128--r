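# small model population: masks over 4 targets + 2 off-targets
make_models <- function() {
  masks <- rbind(
    c(1, 1, 0, 0, 1, 0),
    c(1, 1, 0, 0, 1, 0),
    c(1, 0, 1, 0, 1, 1),
    c(0, 1, 1, 1, 0, 1))
  colnames(masks) <- c("T1", "T2", "T3", "T4", "O1", "O2")
  list(masks = masks, fitness = c(0.30, 0.25, 0.20, 0.16))
}

test_that("model selection keeps the inclusive threshold boundary", {
  pop <- list(masks = matrix(1, 3, 2), fitness = c(0.10, 0.15, 0.20))
  sel <- select_models(pop, 0.15)
  expect_equal(nrow(sel$masks), 2)
  expect_equal(sel$fitness, c(0.15, 0.20))
  expect_equal(nrow(select_models(pop, -1)$masks), 3)
  expect_error(select_models(pop, 0.99), "lowering the threshold")
})

test_that("duplicate masks are retained through selection", {
  m <- make_models()
  sel <- select_models(m, 0.15)
  expect_equal(nrow(sel$masks), 4)
  expect_equal(sum(duplicated(sel$masks)), 1)
})

test_that("clustering separates identical-mask groups perfectly", {
  masks <- rbind(matrix(rep(c(1, 0, 1, 0, 1, 0), 3), 3, byrow = TRUE),
                 matrix(rep(c(0, 1, 0, 1, 0, 1), 4), 4, byrow = TRUE))
  sel <- select_models(list(masks = masks, fitness = rep(0.5, 7)), 0.15)
  cl <- cluster_models(sel, 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1)
  expect_equal(length(unique(cl$cluster[4:7])), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])
  # k = 1 puts everything together; k > m errors
  expect_equal(unique(cluster_models(sel, 1)$cluster), 1L)
  expect_error(cluster_models(sel, 10), "exceeds")
})

test_that("target relevance is the per-cluster selection frequency", {
  m <- make_models()
  sel <- select_models(m, 0.15)
  S <- target_relevance(sel)
  expect_equal(unname(S[, 1]), unname(colMeans(m$masks)))
  expect_equal(S["T1", 1], 0.75)       # selected in 3 of 4 models
  expect_true(all(S >= 0 & S <= 1))
  # random fixture vs brute-force column mean
  set.seed(20)
  masks <- matrix(sample(0:1, 20 * 6, replace = TRUE), 20,
                  dimnames = list(NULL, colnames(m$masks)))
  sel2 <- select_models(list(masks = masks, fitness = rep(1, 20)), 0.15)
  expect_equal(unname(target_relevance(sel2)[, 1]), unname(colMeans(masks)))
})

test_that("relevance aggregates consistently across clusters", {
  set.seed(21)
  masks <- matrix(sample(0:1, 30 * 6, replace = TRUE), 30,
                  dimnames = list(NULL, c("T1", "T2", "T3", "T4", "O1", "O2")))
  sel <- select_models(list(masks = masks, fitness = rep(1, 30)), 0)
  cl <- cluster_models(sel, 3)
  S <- target_relevance(sel, cl)
  m <- attr(S, "m")
  pooled <- as.numeric(S %*% m) / sum(m)
  expect_equal(pooled, unname(colMeans(masks)))
})

test_that("global desirability averages per-model desirability in a cluster", {
  pm <- rand_pm(M = 15, n_t = 4, n_o = 2)
  m <- make_models()
  sel <- select_models(m, 0.15)
  # single cluster containing one model: GD equals that model's D
  one <- select_models(list(masks = m$masks[1, , drop = FALSE], fitness = 0.3), 0.15)
  gd1 <- global_desirability(pm, one)
  expect_equal(unname(gd1[, 1]),
               desirability_scores(pm, m$masks[1, ] == 1)$D)
  # brute-force double loop over a 4-model cluster
  gd <- global_desirability(pm, sel)
  oracle <- rowMeans(vapply(seq_len(4), function(j) {
    oracle_desirability(pm$P, m$masks[j, ] == 1, as.character(pm$roles))
  }, numeric(15)))
  expect_equal(unname(gd[, 1]), oracle, tolerance = 1e-12)
  # GD lies between the per-model min and max D for every compound
  permodel <- vapply(seq_len(4), function(j)
    desirability_scores(pm, m$masks[j, ] == 1)$D, numeric(15))
  expect_true(all(gd[, 1] >= apply(permodel, 1, min) - 1e-12))
  expect_true(all(gd[, 1] <= apply(permodel, 1, max) + 1e-12))
})

test_that("invalid masks inside a cluster are skipped with a warning", {
  pm <- rand_pm(M = 10, n_t = 4, n_o = 2)
  masks <- rbind(c(1, 1, 0, 0, 1, 0),
                 c(1, 1, 0, 0, 0, 0))   # second mask has no off-target
  sel <- select_models(list(masks = masks, fitness = c(0.3, 0.3)), 0.15)
  expect_warning(gd <- global_desirability(pm, sel), "skipped")
  expect_equal(unname(gd[, 1]), desirability_scores(pm, masks[1, ] == 1)$D)
})

test_that("mean of two model desirabilities is their midpoint", {
  P <- matrix(c(0.4, 0.8, 0.6, 0.4, 0.5, 0.5), 1,
              dimnames = list("drug", c("T1", "T2", "T3", "T4", "O1", "O2")))
  pm <- probability_matrix(P, c(rep("target", 4), rep("off_target", 2)))
  masks <- rbind(c(1, 0, 0, 0, 1, 0),    # D = 0.4 * 0.5 = 0.2
                 c(0, 0, 0, 0, 0, 0))
  masks[2, ] <- c(0, 1, 1, 0, 0, 1)      # D = 0.7 * ... pick to land at 0.6
  P2 <- P; P2[1, 2] <- 1; P2[1, 3] <- 1; P2[1, 6] <- 0.4
  pm2 <- probability_matrix(P2, c(rep("target", 4), rep("off_target", 2)))
  sel <- select_models(list(masks = masks, fitness = c(1, 1)), 0.15)
  gd <- global_desirability(pm2, sel)
  d1 <- desirability_scores(pm2, masks[1, ] == 1)$D
  d2 <- desirability_scores(pm2, masks[2, ] == 1)$D
  expect_equal(unname(gd[1, 1]), mean(c(d1, d2)))
  expect_equal(d2, 0.6)
})

test_that("top-list overlap reports union, intersection and Venn patterns", {
  gd <- matrix(runif(40), 20, 2,
               dimnames = list(sprintf("d%02d", 1:20), c("C1", "C2")))
  gd[, 2] <- gd[, 1]                       # identical rankings
  ov <- top_overlap(gd, 5)
  expect_equal(ov$union_size, 5)
  expect_equal(ov$intersection_size, 5)
  # fully disjoint rankings across 4 clusters
  gd4 <- matrix(0, 40, 4, dimnames = list(sprintf("d%02d", 1:40),
                                          paste0("C", 1:4)))
  for (j in 1:4) gd4[((j - 1) * 10 + 1):(j * 10), j] <- runif(10) + 1
  ov4 <- top_overlap(gd4, 10)
  expect_equal(ov4$union_size, 40)
  expect_equal(ov4$intersection_size, 0)
  expect_equal(sum(ov4$venn), 40)
  # intersection is contained in every per-cluster top list
  common <- Reduce(intersect, ov4$top)
  expect_true(all(common %in% ov4$top[[1]]))
})

test_that("cluster correlations summarize off-diagonal agreement", {
  gd <- matrix(runif(30), 15, 2, dimnames = list(NULL, c("C1", "C2")))
  gd[, 2] <- gd[, 1]
  cc <- cluster_correlation(gd)
  expect_equal(cc$mean, 1)
  expect_equal(unname(cc$matrix), matrix(c(1, 1, 1, 1), 2))
  gd[, 2] <- -gd[, 1]
  expect_equal(cluster_correlation(gd)$min, -1)
  # symmetric PSD on a random fixture
  set.seed(30)
  g3 <- matrix(runif(60), 20, 3)
  m3 <- cluster_correlation(g3)$matrix
  expect_equal(m3, t(m3))
  expect_true(all(eigen(m3, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  expect_error(cluster_correlation(cbind(rep(1, 5), runif(5))), "zero-variance")
  expect_error(cluster_correlation(matrix(runif(5), 5, 1)), "two clusters")
})

test_that("category counting tallies codes with unannotated fallback", {
  cat_tab <- data.frame(
    drug_id = c("a", "a", "b", "c", "c", "d", "e", "f", "g", "h"),
    code = c("N02", "C07", "N02", "N02", "A11", "C07", "A11", "G03", "G03", "J01"))
  expect_equal(length(category_counts(character(), cat_tab)), 0)
  # three drugs sharing one code
  expect_equal(category_counts(c("a", "b", "c"), cat_tab)[["N02"]], 3)
  # 10-drug fixture vs hand tally
  drugs <- c("a", "b", "c", "d", "e", "f", "g", "h", "x", "y")
  counts <- category_counts(drugs, cat_tab)
  expect_equal(counts[["N02"]], 3)
  expect_equal(counts[["C07"]], 2)
  expect_equal(counts[["A11"]], 2)
  expect_equal(counts[["G03"]], 2)
  expect_equal(counts[["J01"]], 1)
  expect_equal(counts[["unannotated"]], 2)
})
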