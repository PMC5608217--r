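#' Classifier adapter contract
#'
#' Every classifier enters the evaluation machinery through a thin adapter:
#' `fit(x, y)` takes a numeric training matrix and `+1`/`-1` labels and
#' returns a fitted object; `predict_label(model, x)` returns `+1`/`-1`
#' labels; `score(model, x)` returns a continuous positive-class score
#' (larger = more positive). Classifier internals are out of scope — the
#' default roster is assembled from lightweight, dependency-free components:
#' `lda` (MASS), `logreg` (stats::glm), `ridge` (glmnet, fixed lambda),
#' `gnb` (Gaussian naive Bayes), `knn` (k = 5 Euclidean), `centroid`
#' (nearest centroid), `stump` (depth-1 Gini tree).
#'
#' @param name adapter name, see [default_classifiers()].
#' @return a list with elements `name`, `fit`, `predict_label`, `score`.
#' @export
classifier_adapter <- function(name) {
  reg <- classifier_registry()
  if (!name %in% names(reg)) {
    stop("unknown classifier '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Names of the default classifier roster
#'
#' Seven adapters, mirroring a seven-classifier evaluation design.
#' @return character vector of length 7.
#' @export
default_classifiers <- function() {
  c("lda", "logreg", "ridge", "gnb", "knn", "centroid", "stump")
}

# jitter-free guard: degenerate training sets (constant columns etc.) must
# not abort a CV run, so fitters fall back to a majority-vote model
majority_model <- function(y) {
  lab <- if (sum(y == 1L) >= sum(y == -1L)) 1L else -1L
  list(kind = "majority", label = lab,
       score = mean(y == 1L))
}

adapter <- function(name, fit, predict_label, score) {
  list(name = name, fit = fit, predict_label = predict_label, score = score)
}

classifier_registry <- function() {
  list(
    lda = adapter(
      "lda",
      fit = function(x, y) {
        fit <- tryCatch(
          suppressWarnings(MASS::lda(x, grouping = factor(y, c(-1, 1)))),
          error = function(e) NULL)
        if (is.null(fit)) majority_model(y) else list(kind = "lda", fit = fit)
      },
      predict_label = function(model, x) {
        if (model$kind == "majority") return(rep(model$label, nrow(x)))
        p <- stats::predict(model$fit, x)
        ifelse(p$class == "1", 1L, -1L)
      },
      score = function(model, x) {
        if (model$kind == "majority") return(rep(model$score, nrow(x)))
        stats::predict(model$fit, x)$posterior[, "1"]
      }
    ),
    logreg = adapter(
      "logreg",
      fit = function(x, y) {
        df <- data.frame(.y = factor(y, c(-1, 1)), x)
        fit <- tryCatch(
          suppressWarnings(stats::glm(.y ~ ., data = df, family = "binomial")),
          error = function(e) NULL)
        if (is.null(fit)) majority_model(y)
        else list(kind = "glm", fit = fit, cols = colnames(df)[-1])
      },
      predict_label = function(model, x) {
        if (model$kind == "majority") return(rep(model$label, nrow(x)))
        df <- data.frame(x); names(df) <- model$cols
        p <- suppressWarnings(stats::predict(model$fit, df, type = "response"))
        ifelse(p >= 0.5, 1L, -1L)
      },
      score = function(model, x) {
        if (model$kind == "majority") return(rep(model$score, nrow(x)))
        df <- data.frame(x); names(df) <- model$cols
        as.numeric(suppressWarnings(
          stats::predict(model$fit, df, type = "response")))
      }
    ),
    ridge = adapter(
      "ridge",
      fit = function(x, y) {
        fit <- tryCatch(
          glmnet::glmnet(x, factor(y, c(-1, 1)), family = "binomial",
                         alpha = 0, lambda = c(1, 0.1, 0.01), standardize = TRUE),
          error = function(e) NULL)
        if (is.null(fit)) majority_model(y) else list(kind = "glmnet", fit = fit)
      },
      predict_label = function(model, x) {
        if (model$kind == "majority") return(rep(model$label, nrow(x)))
        p <- stats::predict(model$fit, x, s = 0.01, type = "response")
        ifelse(as.numeric(p) >= 0.5, 1L, -1L)
      },
      score = function(model, x) {
        if (model$kind == "majority") return(rep(model$score, nrow(x)))
        as.numeric(stats::predict(model$fit, x, s = 0.01, type = "response"))
      }
    ),
    gnb = adapter(
      "gnb",
      fit = function(x, y) {
        fit_class <- function(m) {
          mu <- colMeans(m)
          s2 <- apply(m, 2, stats::var)
          s2[!is.finite(s2) | s2 < 1e-9] <- 1e-9
          list(mu = mu, s2 = s2)
        }
        list(kind = "gnb",
             pos = fit_class(x[y == 1L, , drop = FALSE]),
             neg = fit_class(x[y == -1L, , drop = FALSE]),
             prior_pos = mean(y == 1L))
      },
      predict_label = function(model, x) {
        ifelse(gnb_logodds(model, x) >= 0, 1L, -1L)
      },
      score = function(model, x) gnb_logodds(model, x)
    ),
    knn = adapter(
      "knn",
      fit = function(x, y) list(kind = "knn", x = x, y = y,
                                k = min(5L, nrow(x))),
      predict_label = function(model, x) {
        ifelse(knn_posfrac(model, x) >= 0.5, 1L, -1L)
      },
      score = function(model, x) knn_posfrac(model, x)
    ),
    centroid = adapter(
      "centroid",
      fit = function(x, y) {
        list(kind = "centroid",
             mu_pos = colMeans(x[y == 1L, , drop = FALSE]),
             mu_neg = colMeans(x[y == -1L, , drop = FALSE]))
      },
      predict_label = function(model, x) {
        ifelse(centroid_margin(model, x) >= 0, 1L, -1L)
      },
      score = function(model, x) centroid_margin(model, x)
    ),
    stump = adapter(
      "stump",
      fit = function(x, y) fit_stump(x, y),
      predict_label = function(model, x) {
        ifelse(stump_posfrac(model, x) >= 0.5, 1L, -1L)
      },
      score = function(model, x) stump_posfrac(model, x)
    )
  )
}

# Gaussian naive Bayes posterior log-odds for the positive class
gnb_logodds <- function(model, x) {
  ll <- function(par) {
    rowSums(sweep(sweep(x, 2, par$mu)^2, 2, -2 * par$s2, "/") -
              rep(0.5 * log(2 * pi * par$s2), each = nrow(x)))
  }
  prior <- max(min(model$prior_pos, 1 - 1e-12), 1e-12)
  ll(model$pos) - ll(model$neg) + log(prior / (1 - prior))
}

# fraction of positive neighbors among the k nearest (Euclidean)
knn_posfrac <- function(model, x) {
  tr <- model$x
  d2 <- outer(rowSums(x^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(x)), rowSums(tr^2)) - 2 * x %*% t(tr)
  apply(d2, 1, function(d) {
    nb <- order(d)[seq_len(model$k)]
    mean(model$y[nb] == 1L)
  })
}

# difference of squared distances to class centroids (positive-class margin)
centroid_margin <- function(model, x) {
  d_neg <- rowSums(sweep(x, 2, model$mu_neg)^2)
  d_pos <- rowSums(sweep(x, 2, model$mu_pos)^2)
  d_neg - d_pos
}

# depth-1 CART: best single-feature threshold by Gini impurity
fit_stump <- function(x, y) {
  n <- nrow(x)
  best <- list(gini = Inf, feature = 1L, threshold = -Inf)
  pos <- y == 1L
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ps <- pos[ord]
    cum_pos <- cumsum(ps)
    n_left <- seq_len(n - 1L)
    # candidate splits between distinct consecutive values only
    ok <- which(vs[-n] < vs[-1])
    if (length(ok) == 0L) next
    pl <- cum_pos[ok] / n_left[ok]
    nr <- n - n_left[ok]
    pr <- (sum(ps) - cum_pos[ok]) / nr
    gini <- n_left[ok] / n * 2 * pl * (1 - pl) + nr / n * 2 * pr * (1 - pr)
    b <- which.min(gini)
    if (gini[b] < best$gini - 1e-12) {
      best <- list(gini = gini[b], feature = j,
                   threshold = (vs[ok[b]] + vs[ok[b] + 1L]) / 2)
    }
  }
  if (!is.finite(best$gini)) {
    m <- majority_model(y)
    return(list(kind = "stump", degenerate = TRUE,
                p_left = m$score, p_right = m$score,
                feature = 1L, threshold = -Inf))
  }
  left <- x[, best$feature] <= best$threshold
  list(kind = "stump", degenerate = FALSE,
       feature = best$feature, threshold = best$threshold,
       p_left = mean(pos[left]), p_right = mean(pos[!left]))
}

stump_posfrac <- function(model, x) {
  left <- x[, model$feature] <= model$threshold
  ifelse(left, model$p_left, model$p_right)
}
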