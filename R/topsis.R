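#' Build a TOPSIS decision matrix from a set of feature rankings
#'
#' Alternatives are features and criteria are ranking methods. By default the
#' cell score is rank-derived: `x_ij = m - r_ij + 1`, where `r_ij` is feature
#' `i`'s rank (1 = best) under method `j` and `m` the number of features, so
#' that larger is better under every criterion (all-benefit). A raw-score
#' mode (`score_mode = "raw"`) fills cells with each method's own scores
#' instead, for sensitivity analysis.
#'
#' @param rankings list of `RankingResult`s covering the same feature set.
#' @param weights optional non-negative criterion weights; default equal.
#'   Weights are normalized to sum to 1.
#' @param score_mode `"rank"` (default) or `"raw"`.
#' @return A `DecisionMatrix`: list with the score matrix `x` (features x
#'   methods), `weights`, `benefit_mask` (all `TRUE` here),
#'   `alternative_names`, `criterion_names`.
#' @export
build_decision_matrix <- function(rankings, weights = NULL,
                                  score_mode = c("rank", "raw")) {
  score_mode <- match.arg(score_mode)
  if (length(rankings) < 1L) stop("need at least one ranking", call. = FALSE)
  stopifnot(all(vapply(rankings, inherits, logical(1), "RankingResult")))
  fn <- rankings[[1]]$feature_names
  m <- length(fn)
  for (r in rankings) {
    if (!identical(sort(r$feature_names), sort(fn))) {
      stop("rankings cover different feature sets", call. = FALSE)
    }
  }
  n <- length(rankings)
  x <- matrix(NA_real_, m, n)
  for (j in seq_len(n)) {
    r <- rankings[[j]]
    # map this ranking's order onto the reference feature-name order
    pos <- match(fn, r$feature_names)
    rank_of <- integer(m)
    rank_of[r$ordered_features] <- seq_len(m)
    if (score_mode == "rank") {
      x[, j] <- m - rank_of[pos] + 1
    } else {
      sc <- numeric(m)
      sc[r$ordered_features] <- r$scores
      x[, j] <- sc[pos]
    }
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length != n criteria", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("weights must not be all zero", call. = FALSE)
  decision_matrix(
    x, weights = weights,
    alternative_names = fn,
    criterion_names = vapply(rankings, function(r) r$method_name, character(1))
  )
}

#' Construct a decision matrix directly from scores
#'
#' @param x m x n score matrix: m alternatives (rows), n criteria (columns).
#' @param weights non-negative weights, normalized internally to sum to 1.
#' @param benefit_mask logical per criterion: `TRUE` = benefit (larger is
#'   better), `FALSE` = cost. Default all-benefit.
#' @param alternative_names,criterion_names optional name vectors.
#' @return A `DecisionMatrix`.
#' @export
decision_matrix <- function(x, weights = NULL, benefit_mask = NULL,
                            alternative_names = rownames(x),
                            criterion_names = colnames(x)) {
  x <- as.matrix(x)
  m <- nrow(x); n <- ncol(x)
  if (m < 1L || n < 1L) stop("decision matrix must be non-empty",
                             call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  weights <- weights / sum(weights)
  if (is.null(benefit_mask)) benefit_mask <- rep(TRUE, n)
  if (length(benefit_mask) != n) stop("benefit_mask length mismatch",
                                      call. = FALSE)
  if (is.null(alternative_names)) alternative_names <- paste0("A", seq_len(m))
  if (is.null(criterion_names)) criterion_names <- paste0("C", seq_len(n))
  structure(
    list(x = x, weights = weights, benefit_mask = benefit_mask,
         alternative_names = as.character(alternative_names),
         criterion_names = as.character(criterion_names)),
    class = "DecisionMatrix"
  )
}

#' TOPSIS relative closeness to the ideal solution
#'
#' The seven-step procedure: (1) the m x n evaluation matrix; (2) vector
#' normalization \eqn{u_{ij} = x_{ij} / \sqrt{\sum_k x_{kj}^2}} (an all-zero
#' column stays all-zero); (3) weighting \eqn{V_{ij} = w_j u_{ij}}; (4-5) the
#' positive ideal \eqn{A^+_j} = per-criterion best of `V` (max for benefit
#' criteria, min for cost) and negative ideal \eqn{A^-_j} = per-criterion
#' worst; (6) Euclidean distances \eqn{P^+_i}, \eqn{P^-_i} of each
#' alternative to the ideals; (7) relative closeness
#' \eqn{H_i = P^-_i / (P^+_i + P^-_i) \in [0,1]}, with the degenerate case
#' \eqn{P^+_i + P^-_i = 0} defined as 0.5. `H = 1` marks the highest rank
#' and `H = 0` the lowest.
#'
#' @param dm a `DecisionMatrix`.
#' @return A `ClosenessResult`: list with `u`, `v`, `a_plus`, `a_minus`,
#'   `p_plus`, `p_minus`, `h` and `order` (alternatives by descending `h`,
#'   ties broken by ascending index).
#' @export
topsis_closeness <- function(dm) {
  stopifnot(inherits(dm, "DecisionMatrix"))
  x <- dm$x
  norms <- sqrt(colSums(x^2))
  u <- sweep(x, 2, ifelse(norms > 0, norms, 1), "/")
  v <- sweep(u, 2, dm$weights, "*")
  col_max <- apply(v, 2, max)
  col_min <- apply(v, 2, min)
  a_plus <- ifelse(dm$benefit_mask, col_max, col_min)
  a_minus <- ifelse(dm$benefit_mask, col_min, col_max)
  p_plus <- sqrt(rowSums(sweep(v, 2, a_plus)^2))
  p_minus <- sqrt(rowSums(sweep(v, 2, a_minus)^2))
  tot <- p_plus + p_minus
  h <- ifelse(tot > 0, p_minus / tot, 0.5)
  ord <- order(-h, seq_along(h))
  structure(
    list(u = u, v = v, a_plus = a_plus, a_minus = a_minus,
         p_plus = p_plus, p_minus = p_minus, h = h, order = ord,
         alternative_names = dm$alternative_names),
    class = "ClosenessResult"
  )
}

#' @export
print.ClosenessResult <- function(x, n = 10L, ...) {
  k <- min(n, length(x$h))
  cat("ClosenessResult:", length(x$h), "alternatives\n")
  idx <- x$order[seq_len(k)]
  print(data.frame(rank = seq_len(k), alternative = x$alternative_names[idx],
                   H = signif(x$h[idx], 5)), row.names = FALSE)
  invisible(x)
}

#' FRMT: ensemble feature ranking by TOPSIS fusion of ten filter criteria
#'
#' Runs all ten filter feature-selection methods ([rank_all_methods()]),
#' assembles the features x methods decision matrix
#' ([build_decision_matrix()]) and ranks features by TOPSIS relative
#' closeness H ([topsis_closeness()]). Equal criterion weights by default.
#'
#' @param data an `ExpressionDataset`.
#' @param n_bins discretization bins for the MI criteria.
#' @param weights optional criterion weights (length 10).
#' @param top_k recorded in params for report truncation; the full order is
#'   always returned.
#' @param beta MIFS redundancy weight.
#' @param score_mode decision-matrix fill mode, see
#'   [build_decision_matrix()].
#' @param rankings optional precomputed output of [rank_all_methods()] (used
#'   by the evaluation machinery to avoid recomputation).
#' @return a `RankingResult` with `method_name = "frmt"` and scores = H
#'   (non-increasing along the order).
#' @export
frmt_rank <- function(data, n_bins = 10L, weights = NULL, top_k = 10L,
                      beta = 1.0, score_mode = "rank", rankings = NULL) {
  stopifnot(inherits(data, "ExpressionDataset"))
  if (top_k < 1L || top_k > length(data$feature_names)) {
    stop("top_k must be in [1, n_features]", call. = FALSE)
  }
  if (is.null(rankings)) rankings <- rank_all_methods(data, n_bins, beta)
  dm <- build_decision_matrix(rankings, weights = weights,
                              score_mode = score_mode)
  cl <- topsis_closeness(dm)
  ranking_result(
    "frmt", cl$order, cl$h[cl$order], data$feature_names,
    params = list(n_bins = n_bins, beta = beta, top_k = top_k,
                  score_mode = score_mode,
                  weights = as.numeric(dm$weights),
                  methods = dm$criterion_names)
  )
}
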