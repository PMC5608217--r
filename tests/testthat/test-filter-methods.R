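make_ds <- function(x, y) {
  expression_dataset(x, y, feature_names = paste0("f", seq_len(ncol(x))),
                     sample_ids = paste0("s", seq_len(nrow(x))))
}

test_that("t-test ranking: planted feature first, flat feature last, ties", {
  set.seed(31)
  n <- 100
  y <- c(rep(1L, n), rep(-1L, n))
  x <- matrix(rnorm(2 * n * 12), 2 * n, 12)
  x[y == 1L, 1] <- x[y == 1L, 1] + 2.0      # planted, 2 SD shift
  x[, 12] <- 7.5                             # identical in both classes
  r <- rank_ttest(make_ds(x, y))
  expect_equal(r$ordered_features[1], 1L)
  expect_equal(r$ordered_features[12], 12L)
  expect_equal(r$scores[12], 0)
  expect_true(all(diff(r$scores) <= 0))

  # exact duplicate columns give equal |t|; lower index wins
  x2 <- cbind(x[, 2], x[, 2], x[, 1])
  r2 <- rank_ttest(make_ds(x2, y))
  expect_equal(r2$ordered_features, c(3L, 1L, 2L))

  # zero variance with unequal means -> +Inf, ranked first
  x3 <- cbind(ifelse(y == 1L, 1, 0), rnorm(2 * n))
  r3 <- rank_ttest(make_ds(x3, y))
  expect_equal(r3$ordered_features[1], 1L)
  expect_equal(r3$scores[1], Inf)
})

test_that("Wilcoxon ranking: extreme separation, constant, alternating", {
  n1 <- 10; n2 <- 10; n <- n1 + n2
  y <- c(rep(1L, n1), rep(-1L, n2))
  sep <- c(11:20, 1:10)              # class A strictly above class B
  # ABBA-interleaved ranks: class A at sorted positions 1,4,5,8,...,20, so
  # its rank sum 105 equals the null mean and z = 0
  a_pos <- c(1, 4, 5, 8, 9, 12, 13, 16, 17, 20)
  alt <- numeric(20)
  alt[1:10] <- a_pos
  alt[11:20] <- setdiff(1:20, a_pos)
  x <- cbind(sep, rep(2, n), alt)
  r <- rank_wilcoxon(make_ds(x, y))
  # maximal |z| for these n: W = n1*n2 + n1(n1+1)/2, var = n1 n2 (n+1)/12
  z_max <- (n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  sc <- r$scores[match(1:3, r$ordered_features)]
  expect_equal(sc[1], z_max, tolerance = 1e-12)
  expect_equal(sc[2], 0)
  expect_equal(sc[3], 0)
  expect_equal(r$ordered_features[1], 1L)
})

test_that("every greedy criterion's first pick maximizes relevance", {
  set.seed(33)
  d <- random_discrete_dataset(6, 25)
  ds <- dataset_from_codes(d$feats, d$y)
  rel <- vapply(d$feats, function(f) mutual_info(f, d$y), numeric(1))
  best <- which(rel >= max(rel) - 1e-10)[1]
  for (crit in c("mim", "mifs", "mrmr", "jmi", "disr", "cmim", "icap",
                 "cife")) {
    r <- rank_greedy(crit, ds, n_bins = 10)
    expect_equal(r$ordered_features[1], best, info = crit)
    expect_equal(r$scores[1], rel[best], tolerance = 1e-10, info = crit)
  }
})

test_that("duplicate feature: mim keeps the copy adjacent, mrmr demotes it", {
  # f1 strongly relevant, f3 an exact copy of f1, f2 weakly relevant
  y <- c(rep(1L, 6), rep(-1L, 6))
  f1 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 1)   # 5/6 match with class
  f2 <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 1, 1, 0)   # 4/6 match
  x <- cbind(f1, f2, f1)
  ds <- make_ds(x, y)
  rel <- vapply(1:3, function(j)
    mutual_info(discrete_vector(x[, j]),
                discrete_vector(ifelse(y == 1L, 1L, 0L))), numeric(1))
  expect_true(rel[1] > rel[2] && rel[2] > 0)
  expect_equal(rank_greedy("mim", ds)$ordered_features, c(1L, 3L, 2L))
  expect_equal(rank_greedy("mrmr", ds)$ordered_features, c(1L, 2L, 3L))
})

test_that("XOR pair: cmim and jmi promote the partner after one is picked", {
  # (x1, x2) with y = xor(x1, x2): both marginally irrelevant but jointly
  # decisive; f3 weakly relevant, f4 weaker still
  base <- expand.grid(x1 = 0:1, x2 = 0:1)
  base$y <- bitwXor(base$x1, base$x2)
  tt <- base[rep(1:4, times = c(4, 3, 3, 4)), ]
  f3 <- ifelse(tt$y == 1, 1L, 0L); f3[c(1, 8)] <- 1L - f3[c(1, 8)]
  f4 <- ifelse(tt$y == 1, 1L, 0L)
  f4[c(1, 5, 8, 11)] <- 1L - f4[c(1, 5, 8, 11)]
  x <- cbind(tt$x1, tt$x2, f3, f4)
  ds <- make_ds(x, ifelse(tt$y == 1, 1L, -1L))
  ord <- list(
    cmim = rank_greedy("cmim", ds)$ordered_features,
    jmi = rank_greedy("jmi", ds)$ordered_features,
    mim = rank_greedy("mim", ds)$ordered_features
  )
  pos <- function(o, f) match(f, o)
  for (crit in c("cmim", "jmi")) {
    o <- ord[[crit]]
    first_of_pair <- min(pos(o, 1), pos(o, 2))
    second_of_pair <- max(pos(o, 1), pos(o, 2))
    # the partner follows immediately once one of the pair is in
    expect_lt(second_of_pair - first_of_pair, 2)
    # and beats the marginally-stronger noise feature f4
    expect_lt(second_of_pair, pos(o, 4))
  }
  # mim ranks purely by marginal relevance: the pair comes last
  expect_equal(ord$mim, c(3L, 4L, 1L, 2L))
})

test_that("greedy orderings match the brute-force oracle (property)", {
  set.seed(34)
  for (rep in 1:25) {
    d <- random_discrete_dataset(6, 25)
    ds <- dataset_from_codes(d$feats, d$y)
    # feed the oracle the same discretization the ranker applies internally
    feats <- lapply(seq_len(d$m), function(j)
      discretize(ds$matrix[, j], n_bins = 10))
    for (crit in c("mim", "mifs", "mrmr", "jmi", "disr", "cmim", "icap",
                   "cife")) {
      expect_equal(rank_greedy(crit, ds, n_bins = 10)$ordered_features,
                   oracle_greedy(crit, feats, d$y),
                   info = paste(crit, "rep", rep))
    }
  }
})

test_that("rank_all_methods returns ten full permutations in fixed order", {
  gen <- generate_dataset(synthetic_config(20, 20, n_features = 15L,
                                           n_informative = 2L,
                                           effect_size = 1.5, seed = 9L))
  all_r <- rank_all_methods(gen$data)
  expect_named(all_r, filter_method_names())
  for (r in all_r) {
    expect_equal(sort(r$ordered_features), 1:15)
  }
})

test_that("column permutation permutes every ranking consistently", {
  gen <- generate_dataset(synthetic_config(25, 25, n_features = 10L,
                                           n_informative = 2L,
                                           effect_size = 2, seed = 12L))
  data <- gen$data
  set.seed(99)
  perm <- sample(10)
  data_p <- expression_dataset(data$matrix[, perm],
                               data$labels,
                               feature_names = data$feature_names[perm],
                               sample_ids = data$sample_ids)
  r1 <- rank_all_methods(data)
  r2 <- rank_all_methods(data_p)
  # the statistical tests have continuous, almost surely tie-free scores:
  # the name order must match exactly
  for (nm in c("ttest", "wrs")) {
    expect_equal(r1[[nm]]$feature_names[r1[[nm]]$ordered_features],
                 r2[[nm]]$feature_names[r2[[nm]]$ordered_features],
                 info = nm)
  }
  # discretized MI scores can tie exactly, and index tie-breaks are not
  # permutation-equivariant; the step-score sequences still must agree
  for (nm in greedy_criteria_names <- setdiff(filter_method_names(),
                                              c("ttest", "wrs"))) {
    expect_equal(r1[[nm]]$scores, r2[[nm]]$scores, tolerance = 1e-9,
                 info = nm)
  }
})

test_that("wrs and MI criteria are invariant to monotone feature transforms", {
  gen <- generate_dataset(synthetic_config(30, 30, n_features = 8L,
                                           n_informative = 2L,
                                           effect_size = 1.5, seed = 13L))
  data <- gen$data
  x2 <- data$matrix
  x2[, 3] <- exp(x2[, 3])
  x2[, 5] <- x2[, 5]^3
  data2 <- expression_dataset(x2, data$labels,
                              feature_names = data$feature_names,
                              sample_ids = data$sample_ids)
  expect_equal(rank_wilcoxon(data)$ordered_features,
               rank_wilcoxon(data2)$ordered_features)
  for (crit in c("mim", "mrmr", "cmim")) {
    expect_equal(rank_greedy(crit, data)$ordered_features,
                 rank_greedy(crit, data2)$ordered_features, info = crit)
  }
})

test_that("rankings are deterministic for identical input and params", {
  gen <- generate_dataset(synthetic_config(20, 25, n_features = 12L,
                                           n_informative = 3L,
                                           effect_size = 1, seed = 14L))
  a <- rank_all_methods(gen$data)
  b <- rank_all_methods(gen$data)
  expect_identical(a, b)
  expect_error(rank_greedy("bogus", gen$data), "unknown criterion")
})
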