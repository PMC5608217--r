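#' Names of all eleven selectors (ten filter criteria plus FRMT)
#' @return character vector of length 11.
#' @export
selector_names <- function() c(filter_method_names(), "frmt")

# dispatch a selector name to its ranker
run_selector <- function(name, data, n_bins = 10L, beta = 1.0) {
  if (name == "frmt") return(frmt_rank(data, n_bins = n_bins, beta = beta))
  if (name == "ttest") return(rank_ttest(data))
  if (name == "wrs") return(rank_wilcoxon(data))
  if (name %in% greedy_criteria()) {
    return(rank_greedy(name, data, n_bins = n_bins, beta = beta))
  }
  stop("unknown selector '", name, "'", call. = FALSE)
}

#' Stratified fold assignment
#'
#' Samples of each class are shuffled and dealt round-robin over folds, so
#' each fold's class proportions deviate from the global proportions by at
#' most one sample per class.
#'
#' @param labels `+1`/`-1` labels.
#' @param n_folds number of folds (>= 2).
#' @return integer fold id (1..n_folds) per sample. Uses the current RNG
#'   state; seed outside.
#' @export
stratified_folds <- function(labels, n_folds) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  fold <- integer(length(labels))
  for (cls in c(1L, -1L)) {
    idx <- which(labels == cls)
    if (length(idx) < n_folds && length(idx) < 2L) {
      stop("class ", cls, " has too few samples to stratify", call. = FALSE)
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of one selector + classifier
#'
#' For each repeat a fresh stratified fold assignment is drawn from a seed
#' derived from `seed`. In `per_fold` scope the selector is fit on the
#' training folds only and its top `subset_size` features feed the
#' classifier; in `global` scope the ranking is computed once on the full
#' dataset (optimistically biased; provided because published pipelines
#' sometimes rank once per dataset). MCC is computed from the pooled held-out
#' label predictions of a repeat and AUC from the pooled continuous scores.
#'
#' @param data an `ExpressionDataset`.
#' @param selector selector name (see [selector_names()]) or a precomputed
#'   `RankingResult` (implies `global` scope).
#' @param subset_size number of top-ranked features handed to the classifier.
#' @param classifier adapter name or adapter list (see
#'   [classifier_adapter()]).
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 30).
#' @param rank_scope `"per_fold"` (default) or `"global"`.
#' @param seed integer seed controlling all fold randomness.
#' @param n_bins,beta forwarded to the MI selectors.
#' @return data.frame with one row per repeat: `repeat_id`, `mcc`, `auc`.
#' @export
cross_validate <- function(data, selector, subset_size, classifier,
                           n_folds = 10L, n_repeats = 30L,
                           rank_scope = c("per_fold", "global"),
                           seed = 1L, n_bins = 10L, beta = 1.0) {
  stopifnot(inherits(data, "ExpressionDataset"))
  rank_scope <- match.arg(rank_scope)
  if (subset_size > length(data$feature_names)) {
    stop("subset_size exceeds number of features", call. = FALSE)
  }
  if (is.character(classifier)) classifier <- classifier_adapter(classifier)

  global_ranking <- NULL
  if (inherits(selector, "RankingResult")) {
    global_ranking <- selector
    rank_scope <- "global"
  } else if (rank_scope == "global") {
    global_ranking <- run_selector(selector, data, n_bins, beta)
  }

  set.seed(seed %% .Machine$integer.max)
  repeat_seeds <- sample.int(2147483646L, n_repeats)

  out <- data.frame(repeat_id = seq_len(n_repeats), mcc = NA_real_,
                    auc = NA_real_)
  n <- nrow(data$matrix)
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    fold <- stratified_folds(data$labels, n_folds)
    pred <- integer(n)
    sc <- numeric(n)
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      y_train <- data$labels[train_idx]
      if (length(unique(y_train)) < 2L) {
        stop("fold ", f, " training split lost a class (n=", n,
             ", folds=", n_folds, "); reduce n_folds", call. = FALSE)
      }
      ranking <- if (!is.null(global_ranking)) {
        global_ranking
      } else {
        run_selector(selector, subset_samples(data, train_idx), n_bins, beta)
      }
      feats <- ranking$ordered_features[seq_len(subset_size)]
      x_train <- data$matrix[train_idx, feats, drop = FALSE]
      x_test <- data$matrix[test_idx, feats, drop = FALSE]
      model <- classifier$fit(x_train, y_train)
      pred[test_idx] <- classifier$predict_label(model, x_test)
      s <- classifier$score(model, x_test)
      if (is.null(s) || anyNA(s)) s <- as.numeric(pred[test_idx] == 1L)
      sc[test_idx] <- s
    }
    out$mcc[r] <- mcc(confusion_counts(data$labels, pred))
    out$auc[r] <- auc_score(sc, data$labels)
  }
  attr(out, "params") <- list(
    selector = if (is.character(selector)) selector else "precomputed",
    classifier = classifier$name, subset_size = subset_size,
    n_folds = n_folds, n_repeats = n_repeats, rank_scope = rank_scope,
    seed = seed, n_bins = n_bins, beta = beta)
  out
}

#' Build the (dataset x classifier x selector x subset size) evaluation grid
#'
#' Runs [cross_validate()] over every combination and summarizes each cell by
#' the mean and standard error of MCC and AUC over repeats
#' (SE = sd of repeat-level means / sqrt(n_repeats)).
#'
#' In `global` scope all eleven selector rankings of a dataset are computed
#' once and shared across classifiers and subset sizes, which keeps large
#' grids tractable.
#'
#' @param datasets named list of `ExpressionDataset`s.
#' @param selectors selector names (default all eleven).
#' @param classifiers adapter names (default the seven-member roster).
#' @param subset_sizes feature-subset sizes (default `c(5, 10, 15, 20)`).
#' @param n_folds,n_repeats,rank_scope,seed,n_bins,beta forwarded to
#'   [cross_validate()].
#' @return An `EvaluationGrid`: data.frame with columns `dataset_id`,
#'   `classifier_name`, `selector_name`, `subset_size`, `mean_mcc`, `se_mcc`,
#'   `mean_auc`, `se_auc`, plus attributes recording the run parameters.
#' @export
evaluate_grid <- function(datasets,
                          selectors = selector_names(),
                          classifiers = default_classifiers(),
                          subset_sizes = c(5L, 10L, 15L, 20L),
                          n_folds = 10L, n_repeats = 30L,
                          rank_scope = c("per_fold", "global"),
                          seed = 1L, n_bins = 10L, beta = 1.0) {
  rank_scope <- match.arg(rank_scope)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("D", seq_along(datasets))
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    data <- datasets[[ds_name]]
    precomputed <- NULL
    if (rank_scope == "global") {
      base <- rank_all_methods(data, n_bins, beta)
      precomputed <- base
      if ("frmt" %in% selectors) {
        precomputed$frmt <- frmt_rank(data, n_bins = n_bins, beta = beta,
                                      rankings = base)
      }
    }
    for (sel in selectors) {
      sel_arg <- if (is.null(precomputed)) sel else precomputed[[sel]]
      for (clf in classifiers) {
        for (k in subset_sizes) {
          cell_seed <- derive_seed(seed, ds_name, sel, clf, k)
          cv <- cross_validate(data, sel_arg, k, clf, n_folds = n_folds,
                               n_repeats = n_repeats,
                               rank_scope = rank_scope, seed = cell_seed,
                               n_bins = n_bins, beta = beta)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset_id = ds_name, classifier_name = clf,
            selector_name = sel, subset_size = k,
            mean_mcc = mean(cv$mcc),
            se_mcc = stats::sd(cv$mcc) / sqrt(nrow(cv)),
            mean_auc = mean(cv$auc),
            se_auc = stats::sd(cv$auc) / sqrt(nrow(cv)))
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  attr(grid, "params") <- list(n_folds = n_folds, n_repeats = n_repeats,
                               rank_scope = rank_scope, seed = seed,
                               n_bins = n_bins, beta = beta)
  class(grid) <- c("EvaluationGrid", "data.frame")
  grid
}

# deterministic 31-bit seed from a base seed and a cell key
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h) + 1L
}

#' Winning frequency of selectors across evaluation states
#'
#' A state is one (dataset, classifier, subset size) cell; within a state the
#' selector with the best metric wins, exact ties splitting the win
#' fractionally among the tied selectors. States are then grouped and win
#' counts are converted to percentages that sum to 100 within each group.
#'
#' @param grid an `EvaluationGrid`.
#' @param metric `"mcc"` (default) or `"auc"`.
#' @param group_by `"subset_size"`, `"dataset"`, or `"overall"`.
#' @return data.frame with columns `group`, `selector_name`, `wins`,
#'   `percent`.
#' @export
winning_frequency <- function(grid, metric = c("mcc", "auc"),
                              group_by = c("subset_size", "dataset",
                                           "overall")) {
  metric <- match.arg(metric)
  group_by <- match.arg(group_by)
  col <- paste0("mean_", metric)
  selectors <- sort(unique(grid$selector_name))
  key <- interaction(grid$dataset_id, grid$classifier_name,
                     grid$subset_size, drop = TRUE)
  # coverage check: every selector in every state
  tab <- table(key, grid$selector_name)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop("incomplete grid: state ", rownames(tab)[bad[1, 1]],
         " missing selector ", colnames(tab)[bad[1, 2]], call. = FALSE)
  }
  states <- split(seq_len(nrow(grid)), key)
  rows <- lapply(states, function(idx) {
    vals <- grid[[col]][idx]
    winners <- idx[vals >= max(vals) - 1e-12]
    data.frame(dataset_id = grid$dataset_id[idx[1]],
               subset_size = grid$subset_size[idx[1]],
               selector_name = grid$selector_name[winners],
               win = 1 / length(winners))
  })
  wins <- do.call(rbind, rows)
  group <- switch(group_by,
                  subset_size = as.character(wins$subset_size),
                  dataset = as.character(wins$dataset_id),
                  overall = rep("overall", nrow(wins)))
  agg <- stats::aggregate(win ~ g + s,
                          data = data.frame(g = group,
                                            s = wins$selector_name,
                                            win = wins$win),
                          FUN = sum)
  # include zero-win selectors so percentages are reported for all
  full <- expand.grid(g = unique(group), s = selectors,
                      stringsAsFactors = FALSE)
  agg <- merge(full, agg, by = c("g", "s"), all.x = TRUE)
  agg$win[is.na(agg$win)] <- 0
  totals <- tapply(agg$win, agg$g, sum)
  agg$percent <- 100 * agg$win / as.numeric(totals[agg$g])
  out <- data.frame(group = agg$g, selector_name = agg$s, wins = agg$win,
                    percent = agg$percent)
  out[order(out$group, -out$percent, out$selector_name), ]
}

#' Best-method summary per dataset
#'
#' For each dataset reports the ensemble's (FRMT's) best cell — the
#' (classifier, subset size) maximizing mean MCC with mean AUC as tie-break —
#' against the best non-FRMT cell, with `mean±SE` formatting.
#'
#' @param grid an `EvaluationGrid` containing the `frmt` selector.
#' @return data.frame with one row per (dataset, method-group) pair and
#'   columns `dataset_id`, `method_group` (`frmt` / `other`),
#'   `selector_name`, `classifier_name`, `subset_size`, `mean_mcc`, `se_mcc`,
#'   `mean_auc`, `se_auc`, `mcc_fmt`, `auc_fmt`.
#' @export
best_method_summary <- function(grid) {
  pick_best <- function(g) {
    g <- g[order(-g$mean_mcc, -g$mean_auc), ]
    g[1, ]
  }
  fmt <- function(m, s) sprintf("%.4g±%.2g", m, s)
  rows <- list()
  for (ds in unique(grid$dataset_id)) {
    sub <- grid[grid$dataset_id == ds, ]
    frmt_best <- pick_best(sub[sub$selector_name == "frmt", ])
    other_best <- pick_best(sub[sub$selector_name != "frmt", ])
    for (grp in c("frmt", "other")) {
      b <- if (grp == "frmt") frmt_best else other_best
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = ds, method_group = grp,
        selector_name = b$selector_name, classifier_name = b$classifier_name,
        subset_size = b$subset_size,
        mean_mcc = b$mean_mcc, se_mcc = b$se_mcc,
        mean_auc = b$mean_auc, se_auc = b$se_auc,
        mcc_fmt = fmt(b$mean_mcc, b$se_mcc),
        auc_fmt = fmt(b$mean_auc, b$se_auc))
    }
  }
  do.call(rbind, rows)
}
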