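#' Names of the ten filter feature-selection criteria
#'
#' Fixed declared order: the two statistical tests first, then the eight
#' greedy information-theoretic criteria.
#' @return character vector of length 10.
#' @export
filter_method_names <- function() {
  c("ttest", "wrs", "mim", "mifs", "mrmr", "jmi", "disr", "cmim", "icap",
    "cife")
}

greedy_criteria <- function() {
  c("mim", "mifs", "mrmr", "jmi", "disr", "cmim", "icap", "cife")
}

# tolerance inside which greedy step scores are considered tied; ties are
# broken by ascending feature index (see methods vignette)
TIE_TOL <- 1e-10

# argmax with tolerance-based tie-break to the lowest index
argmax_tied <- function(j) {
  m <- max(j)
  which(j >= m - TIE_TOL)[1]
}

#' Rank features by the two-sample Welch t statistic
#'
#' Score = |t| with the unequal-variance (Welch) denominator, computed on the
#' continuous values. A feature with zero variance in both classes scores 0
#' when the class means are equal and `+Inf` (ranked first) when they differ.
#' Ties are broken by ascending feature index.
#'
#' @param data an `ExpressionDataset` with >= 2 samples per class.
#' @return a `RankingResult` with non-increasing scores.
#' @export
rank_ttest <- function(data) {
  stopifnot(inherits(data, "ExpressionDataset"))
  pos <- data$matrix[data$labels == 1L, , drop = FALSE]
  neg <- data$matrix[data$labels == -1L, , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("t-test needs >= 2 samples per class", call. = FALSE)
  }
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  v1 <- apply(pos, 2, stats::var); v2 <- apply(neg, 2, stats::var)
  se2 <- v1 / nrow(pos) + v2 / nrow(neg)
  tt <- abs(m1 - m2) / sqrt(se2)
  tt[se2 == 0 & m1 == m2] <- 0
  tt[se2 == 0 & m1 != m2] <- Inf
  ord <- order(-tt, seq_along(tt))
  ranking_result("ttest", ord, tt[ord], data$feature_names,
                 params = list(variant = "welch"))
}

#' Rank features by the Wilcoxon rank-sum z statistic
#'
#' Score = |z| from the normal approximation of the rank-sum statistic with
#' midrank tie handling and no continuity correction; the variance carries the
#' standard tie correction. A constant feature scores 0.
#'
#' @param data an `ExpressionDataset` with both classes non-empty.
#' @return a `RankingResult` with non-increasing scores.
#' @export
rank_wilcoxon <- function(data) {
  stopifnot(inherits(data, "ExpressionDataset"))
  is_pos <- data$labels == 1L
  n1 <- sum(is_pos); n2 <- sum(!is_pos); n <- n1 + n2
  z <- apply(data$matrix, 2, function(v) {
    r <- rank(v)
    w <- sum(r[is_pos])
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    v_w <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v_w <= 0) return(0)
    (w - n1 * (n + 1) / 2) / sqrt(v_w)
  })
  z <- abs(z)
  ord <- order(-z, seq_along(z))
  ranking_result("wrs", ord, z[ord], data$feature_names,
                 params = list(ties = "midrank", continuity = FALSE))
}

# Pairwise plug-in statistics shared by all greedy criteria.
# codes: n x m integer matrix of 0-based feature codes; ncat: per-feature
# category counts; y: 0-based class codes. Returns relevance I(Xi;Y) and the
# symmetric matrices I(Xi;Xj), I(Xi;Xj|Y), I(Xi,Xj;Y), H(Xi,Xj,Y).
pairwise_mi_stats <- function(codes, ncat, y, ncat_y) {
  m <- ncol(codes)
  n <- nrow(codes)
  hy <- entropy_from_counts(tabulate(y + 1L, nbins = ncat_y))
  h_i <- numeric(m)
  h_iy <- numeric(m)
  for (i in seq_len(m)) {
    h_i[i] <- entropy_from_counts(tabulate(codes[, i] + 1L, nbins = ncat[i]))
    h_iy[i] <- entropy_from_counts(
      tabulate(codes[, i] * ncat_y + y + 1L, nbins = ncat[i] * ncat_y))
  }
  rel <- pmax(h_i + hy - h_iy, 0)

  mi_xx <- matrix(0, m, m)      # I(Xi;Xj)
  mi_xx_y <- matrix(0, m, m)    # I(Xi;Xj|Y)
  jmi_y <- matrix(0, m, m)      # I(Xi,Xj;Y)
  h_ijy <- matrix(0, m, m)      # H(Xi,Xj,Y)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      ci <- codes[, i]
      for (j in seq.int(i + 1L, m)) {
        cij <- ci * ncat[j] + codes[, j]
        hij <- entropy_from_counts(
          tabulate(cij + 1L, nbins = ncat[i] * ncat[j]))
        hijy <- entropy_from_counts(
          tabulate(cij * ncat_y + y + 1L, nbins = ncat[i] * ncat[j] * ncat_y))
        mi_xx[i, j] <- max(h_i[i] + h_i[j] - hij, 0)
        mi_xx_y[i, j] <- max(h_iy[i] + h_iy[j] - hy - hijy, 0)
        jmi_y[i, j] <- max(hij + hy - hijy, 0)
        h_ijy[i, j] <- hijy
      }
    }
    mi_xx <- mi_xx + t(mi_xx)
    mi_xx_y <- mi_xx_y + t(mi_xx_y)
    jmi_y <- jmi_y + t(jmi_y)
    h_ijy <- h_ijy + t(h_ijy)
  }
  diag(h_ijy) <- h_iy  # H(Xi,Xi,Y) = H(Xi,Y); diagonals unused by the loop
  list(rel = rel, hy = hy, h_i = h_i, h_iy = h_iy,
       mi_xx = mi_xx, mi_xx_y = mi_xx_y, jmi_y = jmi_y, h_ijy = h_ijy)
}

# discretize all feature columns with equal-frequency binning
discretize_matrix <- function(x, n_bins) {
  m <- ncol(x)
  codes <- matrix(0L, nrow(x), m)
  ncat <- integer(m)
  for (i in seq_len(m)) {
    d <- discretize(x[, i], n_bins = n_bins)
    codes[, i] <- d$codes
    ncat[i] <- d$n_categories
  }
  list(codes = codes, ncat = ncat)
}

# Greedy forward selection to full depth given precomputed pairwise stats.
# Returns list(order, scores): scores are the step score J at selection time.
greedy_order <- function(criterion, st, beta = 1.0) {
  m <- length(st$rel)
  rel <- st$rel
  order_out <- integer(m)
  scores <- numeric(m)
  selected <- logical(m)

  # first pick: every criterion reduces to relevance when S is empty
  first <- argmax_tied(rel)
  order_out[1] <- first
  scores[1] <- rel[first]
  selected[first] <- TRUE

  # running accumulators updated when a feature enters S
  acc <- numeric(m)            # additive penalty / reward sums
  cur_min <- rep(Inf, m)       # cmim running minimum of I(Xk;Y|Xj)
  update <- function(j) {
    switch(criterion,
      mim = NULL,
      mifs = acc <<- acc + st$mi_xx[, j],
      mrmr = acc <<- acc + st$mi_xx[, j],
      jmi = acc <<- acc + st$jmi_y[, j],
      disr = {
        term <- ifelse(st$h_ijy[, j] > 0, st$jmi_y[, j] / st$h_ijy[, j], 0)
        acc <<- acc + term
      },
      cmim = {
        cmi <- pmax(st$jmi_y[, j] - rel[j], 0)  # I(Xk;Y|Xj)
        cur_min <<- pmin(cur_min, cmi)
      },
      icap = acc <<- acc + pmax(0, st$mi_xx[, j] - st$mi_xx_y[, j]),
      cife = acc <<- acc + (st$mi_xx[, j] - st$mi_xx_y[, j])
    )
  }
  update(first)

  if (m >= 2L) {
    for (step in seq.int(2L, m)) {
      k <- step - 1L  # |S|
      j_scores <- switch(criterion,
        mim = rel,
        mifs = rel - beta * acc,
        mrmr = rel - acc / k,
        jmi = acc,
        disr = acc,
        cmim = cur_min,
        icap = rel - acc,
        cife = rel - acc
      )
      j_scores[selected] <- -Inf
      pick <- argmax_tied(j_scores)
      order_out[step] <- pick
      scores[step] <- j_scores[pick]
      selected[pick] <- TRUE
      update(pick)
    }
  }
  list(order = order_out, scores = scores)
}

#' Rank features with one greedy information-theoretic criterion
#'
#' Runs greedy forward selection to full depth (all features ranked) with one
#' of the eight criteria. With `S` the selected set, `Y` the class and `X_k` a
#' candidate, the step score is
#' \describe{
#'   \item{mim}{\eqn{I(X_k;Y)}}
#'   \item{mifs}{\eqn{I(X_k;Y) - \beta \sum_{j \in S} I(X_k;X_j)}}
#'   \item{mrmr}{\eqn{I(X_k;Y) - \frac{1}{|S|}\sum_{j \in S} I(X_k;X_j)}}
#'   \item{jmi}{\eqn{\sum_{j \in S} I(X_k,X_j;Y)}}
#'   \item{disr}{\eqn{\sum_{j \in S} I(X_k,X_j;Y)/H(X_k,X_j,Y)}}
#'   \item{cmim}{\eqn{\min_{j \in S} I(X_k;Y|X_j)}}
#'   \item{icap}{\eqn{I(X_k;Y) - \sum_{j \in S}\max(0, I(X_k;X_j)-I(X_k;X_j|Y))}}
#'   \item{cife}{\eqn{I(X_k;Y) - \sum_{j \in S}(I(X_k;X_j)-I(X_k;X_j|Y))}}
#' }
#' The first selection is always the argmax of \eqn{I(X_k;Y)}. Ties (within
#' 1e-10) break to the lowest feature index. Continuous features are
#' discretized with equal-frequency binning; the class labels are used as-is.
#'
#' @param criterion one of `"mim"`, `"mifs"`, `"mrmr"`, `"jmi"`, `"disr"`,
#'   `"cmim"`, `"icap"`, `"cife"`.
#' @param data an `ExpressionDataset`.
#' @param n_bins bins for equal-frequency discretization (default 10).
#' @param beta redundancy weight for MIFS (default 1).
#' @return a `RankingResult`; scores are the step score at selection time
#'   (not necessarily monotone).
#' @export
rank_greedy <- function(criterion, data, n_bins = 10L, beta = 1.0) {
  stopifnot(inherits(data, "ExpressionDataset"))
  if (!criterion %in% greedy_criteria()) {
    stop("unknown criterion '", criterion, "'; must be one of: ",
         paste(greedy_criteria(), collapse = ", "), call. = FALSE)
  }
  dm <- discretize_matrix(data$matrix, n_bins)
  y <- ifelse(data$labels == 1L, 1L, 0L)
  st <- pairwise_mi_stats(dm$codes, dm$ncat, y, 2L)
  g <- greedy_order(criterion, st, beta = beta)
  params <- list(n_bins = n_bins, strategy = "equal_frequency")
  if (criterion == "mifs") params$beta <- beta
  ranking_result(criterion, g$order, g$scores, data$feature_names, params)
}

#' Run all ten filter criteria on a dataset
#'
#' Returns the rankings in the fixed order of [filter_method_names()]. The
#' pairwise information-theoretic statistics are computed once and shared by
#' the eight greedy criteria.
#'
#' @param data an `ExpressionDataset`.
#' @param n_bins discretization bins for the MI criteria.
#' @param beta MIFS redundancy weight.
#' @return named list of 10 `RankingResult`s.
#' @export
rank_all_methods <- function(data, n_bins = 10L, beta = 1.0) {
  stopifnot(inherits(data, "ExpressionDataset"))
  out <- list(ttest = rank_ttest(data), wrs = rank_wilcoxon(data))
  dm <- discretize_matrix(data$matrix, n_bins)
  y <- ifelse(data$labels == 1L, 1L, 0L)
  st <- pairwise_mi_stats(dm$codes, dm$ncat, y, 2L)
  for (crit in greedy_criteria()) {
    g <- greedy_order(crit, st, beta = beta)
    params <- list(n_bins = n_bins, strategy = "equal_frequency")
    if (crit == "mifs") params$beta <- beta
    out[[crit]] <- ranking_result(crit, g$order, g$scores,
                                  data$feature_names, params)
  }
  out[filter_method_names()]
}
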