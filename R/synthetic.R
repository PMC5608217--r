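#' Configuration for the synthetic RPPA-like generator
#'
#' Describes a two-class continuous expression matrix with planted structure:
#' null features are i.i.d. Gaussian within class, informative features are
#' mean-shifted between classes by `effect_size` within-class standard
#' deviations, and redundant features are noisy copies of informative parents
#' with correlation `redundancy_rho`.
#'
#' @param n_early,n_advanced class sample counts (>= 2 each).
#' @param n_features total features (default 115, a typical validated-protein
#'   panel size).
#' @param n_informative number of planted discriminative features.
#' @param effect_size class-mean shift in within-class SD units.
#' @param n_redundant number of correlated copies of informative features.
#' @param redundancy_rho correlation of each redundant copy to its parent,
#'   in (0, 1).
#' @param noise_sd within-class standard deviation.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_early, n_advanced, n_features = 115L,
                             n_informative = 8L, effect_size = 1.0,
                             n_redundant = 0L, redundancy_rho = 0.8,
                             noise_sd = 1.0, seed = 1L) {
  stopifnot(n_early >= 2L, n_advanced >= 2L, n_features >= 1L,
            n_informative >= 0L, n_redundant >= 0L, noise_sd > 0)
  if (n_informative + n_redundant > n_features) {
    stop("n_informative + n_redundant must be <= n_features", call. = FALSE)
  }
  if (n_redundant > 0L && n_informative == 0L) {
    stop("redundant features need informative parents", call. = FALSE)
  }
  if (n_redundant > 0L &&
      (redundancy_rho <= 0 || redundancy_rho >= 1)) {
    stop("redundancy_rho must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_early = as.integer(n_early), n_advanced = as.integer(n_advanced),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, n_redundant = as.integer(n_redundant),
         redundancy_rho = redundancy_rho, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

#' Generate a synthetic two-class expression dataset
#'
#' Draws the matrix described by a [synthetic_config()]: all features are
#' Gaussian with within-class SD `noise_sd`; informative features get a
#' `+effect_size * noise_sd` mean shift in the early (positive) class;
#' redundant features are `rho * parent + sqrt(1 - rho^2) * noise`. Feature
#' columns are then randomly permuted (so planted features do not sit at
#' low, tie-break-favored indices) and the ground-truth record tracks the
#' permuted positions.
#'
#' @param config a `SyntheticConfig`.
#' @return list with `data` (an `ExpressionDataset`) and `truth` (list with
#'   `informative`, `redundant` index vectors, `parents` mapping, and the
#'   generating `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_early + config$n_advanced
  p <- config$n_features
  labels <- c(rep(1L, config$n_early), rep(-1L, config$n_advanced))

  x <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  ninf <- config$n_informative
  if (ninf > 0L) {
    shift <- config$effect_size * config$noise_sd
    x[labels == 1L, seq_len(ninf)] <- x[labels == 1L, seq_len(ninf)] + shift
  }
  nred <- config$n_redundant
  parents <- integer(0)
  if (nred > 0L) {
    rho <- config$redundancy_rho
    parents <- rep_len(seq_len(ninf), nred)
    for (r in seq_len(nred)) {
      noise <- stats::rnorm(n, sd = config$noise_sd)
      x[, ninf + r] <- rho * x[, parents[r]] + sqrt(1 - rho^2) * noise
    }
  }
  perm <- sample.int(p)
  x <- x[, perm, drop = FALSE]
  # position of original column j after permutation
  pos <- match(seq_len(p), perm)
  informative <- if (ninf > 0L) sort(pos[seq_len(ninf)]) else integer(0)
  redundant <- if (nred > 0L) sort(pos[ninf + seq_len(nred)]) else integer(0)

  feature_names <- sprintf("prot_%03d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  data <- expression_dataset(x, labels, feature_names = feature_names,
                             sample_ids = sample_ids)
  list(data = data,
       truth = list(informative = informative, redundant = redundant,
                    parents = if (nred > 0L) pos[parents] else integer(0),
                    config = config))
}

#' Class-count presets mirroring a seven-cancer RPPA staging collection
#'
#' Early/advanced sample counts for seven cancer-type datasets (rectum,
#' head & neck, lung squamous, colon, ovarian, endometrial, kidney), totaling
#' 2101 samples, with imbalance ranging from near-balanced to 33/370.
#'
#' @return data.frame with columns `dataset`, `n_early`, `n_advanced`.
#' @export
dataset_presets <- function() {
  data.frame(
    dataset = c("READ", "HSNE", "LUSC", "COAD", "OV", "UCEC", "KIRC"),
    n_early = c(60L, 48L, 158L, 187L, 33L, 321L, 263L),
    n_advanced = c(62L, 152L, 35L, 139L, 370L, 83L, 190L),
    stringsAsFactors = FALSE
  )
}

#' Seven-dataset synthetic benchmark suite
#'
#' One dataset per preset of [dataset_presets()], each with 115 features, 8
#' informative features at effect sizes spread over 0.5-1.5 SD across the
#' suite, and a block of 8 correlated redundant copies (rho = 0.8) so that
#' redundancy-penalizing criteria are exercised.
#'
#' @param seed master seed; per-dataset seeds are derived from it.
#' @param n_informative,n_redundant,redundancy_rho override the planted
#'   structure.
#' @param effect_sizes length-7 vector of per-dataset effect sizes.
#' @return named list of 7 elements, each the output of
#'   [generate_dataset()].
#' @export
benchmark_suite <- function(seed = 1L, n_informative = 8L, n_redundant = 8L,
                            redundancy_rho = 0.8,
                            effect_sizes = seq(0.5, 1.5, length.out = 7)) {
  presets <- dataset_presets()
  stopifnot(length(effect_sizes) == nrow(presets))
  out <- list()
  for (i in seq_len(nrow(presets))) {
    cfg <- synthetic_config(
      n_early = presets$n_early[i], n_advanced = presets$n_advanced[i],
      n_features = 115L, n_informative = n_informative,
      effect_size = effect_sizes[i], n_redundant = n_redundant,
      redundancy_rho = redundancy_rho,
      seed = derive_seed(seed, "benchmark", presets$dataset[i]))
    out[[presets$dataset[i]]] <- generate_dataset(cfg)
  }
  out
}
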