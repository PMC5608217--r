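# Independent oracle implementations used to cross-check the package.
# These deliberately share no code path with the implementation: scalar
# loops, no caching, public estimator calls only.

# step-by-step TOPSIS on an m x n score matrix (all-benefit by default)
oracle_topsis <- function(x, weights = NULL, benefit = NULL) {
  m <- nrow(x); n <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / sum(weights)
  if (is.null(benefit)) benefit <- rep(TRUE, n)
  u <- matrix(0, m, n)
  for (j in seq_len(n)) {
    nrm <- sqrt(sum(x[, j]^2))
    for (i in seq_len(m)) u[i, j] <- if (nrm > 0) x[i, j] / nrm else 0
  }
  v <- matrix(0, m, n)
  for (j in seq_len(n)) for (i in seq_len(m)) v[i, j] <- weights[j] * u[i, j]
  a_plus <- numeric(n); a_minus <- numeric(n)
  for (j in seq_len(n)) {
    if (benefit[j]) {
      a_plus[j] <- max(v[, j]); a_minus[j] <- min(v[, j])
    } else {
      a_plus[j] <- min(v[, j]); a_minus[j] <- max(v[, j])
    }
  }
  p_plus <- numeric(m); p_minus <- numeric(m)
  for (i in seq_len(m)) {
    p_plus[i] <- sqrt(sum((v[i, ] - a_plus)^2))
    p_minus[i] <- sqrt(sum((v[i, ] - a_minus)^2))
  }
  h <- numeric(m)
  for (i in seq_len(m)) {
    tot <- p_plus[i] + p_minus[i]
    h[i] <- if (tot > 0) p_minus[i] / tot else 0.5
  }
  list(h = h, order = order(-h, seq_len(m)))
}

# brute-force greedy criterion ordering: re-evaluates the step score from
# scratch at every step via the public plug-in estimators.
# feats: list of DiscreteVectors; y: DiscreteVector.
oracle_greedy <- function(criterion, feats, y, beta = 1.0) {
  m <- length(feats)
  selected <- integer(0)
  remaining <- seq_len(m)
  rel <- vapply(feats, function(f) frmt::mutual_info(f, y), numeric(1))
  step_score <- function(k) {
    s <- selected
    if (length(s) == 0L) return(rel[k])
    switch(criterion,
      mim = rel[k],
      mifs = rel[k] - beta * sum(vapply(s, function(j)
        frmt::mutual_info(feats[[k]], feats[[j]]), numeric(1))),
      mrmr = rel[k] - mean(vapply(s, function(j)
        frmt::mutual_info(feats[[k]], feats[[j]]), numeric(1))),
      jmi = sum(vapply(s, function(j)
        frmt::joint_mutual_info(feats[[k]], feats[[j]], y), numeric(1))),
      disr = sum(vapply(s, function(j) {
        hh <- frmt::joint_entropy_bits(feats[[k]], feats[[j]], y)
        if (hh > 0)
          frmt::joint_mutual_info(feats[[k]], feats[[j]], y) / hh
        else 0
      }, numeric(1))),
      cmim = min(vapply(s, function(j)
        frmt::cond_mutual_info(feats[[k]], y, feats[[j]]), numeric(1))),
      icap = rel[k] - sum(vapply(s, function(j)
        max(0, frmt::mutual_info(feats[[k]], feats[[j]]) -
              frmt::cond_mutual_info(feats[[k]], feats[[j]], y)),
        numeric(1))),
      cife = rel[k] - sum(vapply(s, function(j)
        frmt::mutual_info(feats[[k]], feats[[j]]) -
          frmt::cond_mutual_info(feats[[k]], feats[[j]], y), numeric(1)))
    )
  }
  ord <- integer(m)
  for (step in seq_len(m)) {
    js <- vapply(remaining, step_score, numeric(1))
    best <- max(js)
    pick <- remaining[js >= best - 1e-10][1]
    ord[step] <- pick
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  ord
}

# AUC by exhaustive positive-negative pair counting (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == -1L]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random discrete dataset for oracle-equivalence checks
random_discrete_dataset <- function(m_max = 8L, n_max = 30L) {
  m <- sample(2:m_max, 1)
  n <- sample(10:n_max, 1)
  feats <- lapply(seq_len(m), function(i) {
    k <- sample(2:4, 1)
    frmt::discrete_vector(sample(0:(k - 1), n, replace = TRUE), k)
  })
  y <- frmt::discrete_vector(sample(0:1, n, replace = TRUE), 2L)
  list(feats = feats, y = y, m = m, n = n)
}

# ExpressionDataset wrapper around integer codes (codes used verbatim by the
# MI criteria because each integer column discretizes to itself)
dataset_from_codes <- function(feats, y) {
  x <- do.call(cbind, lapply(feats, function(f) as.numeric(f$codes)))
  lab <- ifelse(y$codes == 1L, 1L, -1L)
  frmt::expression_dataset(x, lab,
                           feature_names = paste0("f", seq_len(ncol(x))),
                           sample_ids = paste0("s", seq_len(nrow(x))))
}

# small labeled CSV fixture written to a temp file
write_toy_csv <- function(path, labels = c("early", "early", "advanced",
                                           "advanced"),
                          f1 = c(1, 2, 3, 4), f2 = c(4, 3, 2, 1),
                          blank_at = NULL) {
  f1 <- as.character(f1)
  if (!is.null(blank_at)) f1[blank_at] <- ""
  lines <- c("sample_id,stage,f1,f2",
             paste(paste0("s", seq_along(labels)), labels, f1, f2, sep = ","))
  writeLines(lines, path)
  path
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
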