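test_that("MCC reproduces the worked confusion matrices", {
  expect_equal(mcc(confusion_counts(tp = 50, tn = 50, fp = 0, fn = 0)), 1.0)
  expect_equal(mcc(confusion_counts(tp = 25, tn = 25, fp = 25, fn = 25)), 0.0)
  c3 <- confusion_counts(tp = 45, fn = 5, tn = 40, fp = 10)
  expect_equal(mcc(c3), 1750 / sqrt(55 * 50 * 50 * 45), tolerance = 1e-12)
  expect_equal(mcc(c3), 0.7035, tolerance = 1e-4)
  # zero marginal -> 0 by convention
  expect_equal(mcc(confusion_counts(tp = 0, fn = 0, tn = 10, fp = 5)), 0)
})

test_that("MCC is symmetric under swapping the class convention", {
  set.seed(51)
  for (rep in 1:20) {
    cc <- sample(0:30, 4, replace = TRUE)
    a <- confusion_counts(tp = cc[1], fp = cc[2], tn = cc[3], fn = cc[4])
    b <- confusion_counts(tp = cc[3], fp = cc[4], tn = cc[1], fn = cc[2])
    expect_equal(mcc(a), mcc(b))
  }
})

test_that("AUC: perfect, constant, worked example, pair-counting identity", {
  y <- c(1L, 1L, -1L, -1L)
  expect_equal(auc_score(c(5, 4, 3, 2), y), 1.0)
  expect_equal(auc_score(rep(1, 4), y), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1L, -1L, 1L, -1L)), 0.75)
  expect_error(auc_score(1:3, c(1L, 1L, 1L)), "both classes")
  set.seed(52)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    lab <- c(1L, -1L, sample(c(1L, -1L), n - 2, TRUE))
    sc <- sample(1:6, n, TRUE)  # integer scores force ties
    expect_equal(auc_score(sc, lab), oracle_auc_pairs(sc, lab))
  }
})

test_that("stratified folds keep class proportions within one sample", {
  set.seed(53)
  labels <- c(rep(1L, 33), rep(-1L, 77))
  fold <- stratified_folds(labels, 10L)
  for (f in 1:10) {
    expect_lte(abs(sum(labels[fold == f] == 1L) - 3.3), 1)
    expect_lte(abs(sum(labels[fold == f] == -1L) - 7.7), 1)
  }
})

test_that("perfectly separable data scores MCC = AUC = 1 for any adapter", {
  set.seed(54)
  n <- 60
  y <- rep(c(1L, -1L), each = n / 2)
  x <- matrix(rnorm(n * 8, sd = 0.2), n, 8)
  x[y == 1L, 1:5] <- x[y == 1L, 1:5] + 10
  ds <- expression_dataset(x, y, feature_names = paste0("f", 1:8),
                           sample_ids = paste0("s", seq_len(n)))
  for (clf in c("lda", "gnb", "centroid", "knn")) {
    cv <- cross_validate(ds, "ttest", 5L, clf, n_folds = 5L, n_repeats = 2L,
                         seed = 7L)
    expect_equal(mean(cv$mcc), 1.0, info = clf)
    expect_equal(mean(cv$auc), 1.0, info = clf)
  }
})

test_that("label permutation yields null MCC within 3 SE of zero", {
  # One fixed permutation leaves dataset-level chance associations that
  # honest CV detects (held-out folds of the same fixed dataset share
  # them), so the permutation null must redraw the permutation: each
  # replicate permutes labels afresh, and the SE is taken across
  # replicate means, which does capture that dataset-level noise.
  gen <- generate_dataset(synthetic_config(100, 100, n_features = 30L,
                                           n_informative = 4L,
                                           effect_size = 1.5, seed = 17L))
  data <- gen$data
  set.seed(55)
  reps <- sapply(1:8, function(i) {
    perm <- sample(nrow(data$matrix))
    data_null <- expression_dataset(data$matrix, data$labels[perm],
                                    feature_names = data$feature_names,
                                    sample_ids = data$sample_ids)
    cv <- cross_validate(data_null, "ttest", 5L, "lda", n_folds = 10L,
                         n_repeats = 2L, seed = 100L + i)
    mean(cv$mcc)
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lte(abs(mean(reps)), 3 * se + 1e-9)
})

test_that("cross_validate is deterministic and respects its contracts", {
  gen <- generate_dataset(synthetic_config(30, 30, n_features = 10L,
                                           n_informative = 2L,
                                           effect_size = 1, seed = 18L))
  a <- cross_validate(gen$data, "mim", 3L, "gnb", n_folds = 5L,
                      n_repeats = 3L, seed = 23L)
  b <- cross_validate(gen$data, "mim", 3L, "gnb", n_folds = 5L,
                      n_repeats = 3L, seed = 23L)
  expect_identical(a, b)
  expect_error(cross_validate(gen$data, "mim", 99L, "gnb"), "subset_size")
  expect_error(cross_validate(gen$data, "nope", 3L, "gnb",
                              n_folds = 5L, n_repeats = 1L),
               "unknown selector")
  expect_error(cross_validate(gen$data, "mim", 3L, "nope",
                              n_folds = 5L, n_repeats = 1L),
               "unknown classifier")
})

test_that("a precomputed ranking short-circuits selection (global scope)", {
  gen <- generate_dataset(synthetic_config(25, 25, n_features = 10L,
                                           n_informative = 2L,
                                           effect_size = 1.5, seed = 20L))
  r <- rank_ttest(gen$data)
  a <- cross_validate(gen$data, r, 4L, "centroid", n_folds = 5L,
                      n_repeats = 2L, seed = 3L)
  b <- cross_validate(gen$data, "ttest", 4L, "centroid", n_folds = 5L,
                      n_repeats = 2L, rank_scope = "global", seed = 3L)
  expect_equal(a$mcc, b$mcc)
  expect_equal(a$auc, b$auc)
})

test_that("winning frequency: domination, ties, grouping, coverage", {
  grid <- expand.grid(dataset_id = c("d1", "d2"),
                      classifier_name = c("c1", "c2"),
                      selector_name = c("s1", "s2", "s3"),
                      subset_size = c(5L, 10L),
                      stringsAsFactors = FALSE)
  grid$mean_mcc <- ifelse(grid$selector_name == "s1", 0.9, 0.1)
  grid$mean_auc <- grid$mean_mcc
  wf <- winning_frequency(grid, "mcc", "overall")
  expect_equal(wf$percent[wf$selector_name == "s1"], 100)
  expect_equal(sum(wf$percent), 100)

  # exact tie in one state splits the win
  g2 <- grid
  tie_rows <- g2$dataset_id == "d1" & g2$classifier_name == "c1" &
    g2$subset_size == 5L & g2$selector_name %in% c("s1", "s2")
  g2$mean_mcc[tie_rows] <- 0.5
  wf2 <- winning_frequency(g2, "mcc", "overall")
  expect_equal(wf2$wins[wf2$selector_name == "s2"], 0.5)

  # per-group percentages each sum to 100
  wf3 <- winning_frequency(g2, "mcc", "subset_size")
  expect_equal(as.numeric(tapply(wf3$percent, wf3$group, sum)),
               c(100, 100))

  expect_error(winning_frequency(grid[-1, ], "mcc", "overall"),
               "incomplete grid")
})

test_that("best-method summary reports frmt vs best-other with ±SE format", {
  grid <- expand.grid(dataset_id = "d1", classifier_name = c("c1", "c2"),
                      selector_name = c("frmt", "mim", "wrs"),
                      subset_size = 10L, stringsAsFactors = FALSE)
  grid$mean_mcc <- c(0.40, 0.35, 0.20, 0.30, 0.10, 0.15)
  grid$se_mcc <- 0.01
  grid$mean_auc <- c(0.70, 0.68, 0.60, 0.66, 0.55, 0.58)
  grid$se_auc <- 0.02
  bs <- best_method_summary(grid)
  expect_equal(nrow(bs), 2L)
  expect_equal(bs$method_group, c("frmt", "other"))
  expect_equal(bs$mean_mcc[bs$method_group == "frmt"], 0.40)
  expect_equal(bs$selector_name[bs$method_group == "other"], "mim")
  expect_match(bs$mcc_fmt[1], "^0\\.4±0\\.01$")
  expect_true(all(grepl("±", bs$auc_fmt)))
})

test_that("evaluate_grid produces one row per combination with finite stats", {
  gen1 <- generate_dataset(synthetic_config(20, 20, n_features = 12L,
                                            n_informative = 3L,
                                            effect_size = 1.5, seed = 25L))
  gen2 <- generate_dataset(synthetic_config(15, 25, n_features = 12L,
                                            n_informative = 3L,
                                            effect_size = 1, seed = 26L))
  grid <- evaluate_grid(list(A = gen1$data, B = gen2$data),
                        selectors = c("ttest", "frmt"),
                        classifiers = c("lda", "centroid"),
                        subset_sizes = c(3L, 5L),
                        n_folds = 4L, n_repeats = 2L, rank_scope = "global",
                        seed = 5L)
  expect_equal(nrow(grid), 2 * 2 * 2 * 2)
  expect_true(all(is.finite(grid$mean_mcc)))
  expect_true(all(is.finite(grid$se_mcc)))
  expect_true(all(grid$mean_auc >= 0 & grid$mean_auc <= 1))
})
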