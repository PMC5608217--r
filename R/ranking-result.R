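#' Construct a feature-ranking result
#'
#' @param method_name one of the filter criteria names (`ttest`, `wrs`,
#'   `mim`, `mifs`, `mrmr`, `jmi`, `disr`, `cmim`, `icap`, `cife`) or `frmt`.
#' @param ordered_features integer permutation of all feature indices, best
#'   first.
#' @param scores per-feature score aligned to `ordered_features`. For
#'   score-based methods the scores are non-increasing along the order; for
#'   greedy methods they are the criterion value at the step each feature was
#'   selected.
#' @param feature_names full feature-name vector of the source dataset
#'   (indexed by `ordered_features`).
#' @param params named list of every parameter the ranker used.
#' @return An object of class `RankingResult`.
#' @export
ranking_result <- function(method_name, ordered_features, scores,
                           feature_names, params = list()) {
  ordered_features <- as.integer(ordered_features)
  m <- length(ordered_features)
  if (!identical(sort(ordered_features), seq_len(m))) {
    stop("ordered_features must be a permutation of 1..", m, call. = FALSE)
  }
  if (length(scores) != m) stop("scores length mismatch", call. = FALSE)
  if (length(feature_names) != m) {
    stop("feature_names length mismatch", call. = FALSE)
  }
  structure(
    list(method_name = method_name,
         ordered_features = ordered_features,
         scores = as.numeric(scores),
         feature_names = as.character(feature_names),
         params = params),
    class = "RankingResult"
  )
}

#' @export
print.RankingResult <- function(x, n = 10L, ...) {
  m <- length(x$ordered_features)
  cat("RankingResult <", x$method_name, ">: ", m, " features\n", sep = "")
  k <- min(n, m)
  df <- data.frame(rank = seq_len(k),
                   feature = x$feature_names[x$ordered_features[seq_len(k)]],
                   score = signif(x$scores[seq_len(k)], 5))
  print(df, row.names = FALSE)
  if (m > k) cat("... and", m - k, "more\n")
  invisible(x)
}

#' Top-k feature names of a ranking
#' @param result a `RankingResult`.
#' @param k number of features.
#' @return character vector of the k best feature names.
#' @export
top_features <- function(result, k = 10L) {
  stopifnot(inherits(result, "RankingResult"))
  k <- min(k, length(result$ordered_features))
  result$feature_names[result$ordered_features[seq_len(k)]]
}

#' Serialize a ranking to TSV plus a JSON provenance sidecar
#'
#' Writes a tab-separated table with columns `rank`, `feature_name`, `score`
#' and a `<path>.json` sidecar holding the method name, parameters, the full
#' index order and the feature-name universe, so that [read_ranking()]
#' round-trips losslessly.
#'
#' @param result a non-empty `RankingResult`.
#' @param path output TSV path.
#' @export
write_ranking <- function(result, path) {
  stopifnot(inherits(result, "RankingResult"))
  if (length(result$ordered_features) == 0L) {
    stop("cannot write an empty ranking", call. = FALSE)
  }
  df <- data.frame(
    rank = seq_along(result$ordered_features),
    feature_name = result$feature_names[result$ordered_features],
    score = result$scores
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    method_name = result$method_name,
    params = result$params,
    ordered_features = result$ordered_features,
    feature_names = result$feature_names
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ranking written by [write_ranking()]
#' @param path the TSV path given to [write_ranking()].
#' @return the reconstructed `RankingResult`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- sidecar$params
  if (is.null(params)) params <- list()
  if (!is.list(params)) params <- as.list(params)
  ranking_result(
    method_name = sidecar$method_name,
    ordered_features = sidecar$ordered_features,
    scores = df$score,
    feature_names = sidecar$feature_names,
    params = params
  )
}
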