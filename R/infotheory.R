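#' Discretize a continuous vector into category codes
#'
#' Equal-frequency binning places bin boundaries at empirical quantiles
#' (duplicate boundaries merged), equal-width binning at evenly spaced cut
#' points between the minimum and maximum. A constant vector yields exactly
#' one category. Codes are 0-based consecutive integers over the categories
#' actually observed.
#'
#' @param values finite numeric vector.
#' @param n_bins requested number of bins (>= 2).
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return A `DiscreteVector`: list with integer `codes` in
#'   `[0, n_categories)` and `n_categories`.
#' @export
discretize <- function(values, n_bins = 10L,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("values must be finite for discretization", call. = FALSE)
  }
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(discrete_vector(rep(0L, length(values)), 1L))
  }
  if (strategy == "equal_frequency") {
    brk <- stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7)
    brk <- unique(brk)
  } else {
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  codes <- as.integer(cut(values, breaks = brk, include.lowest = TRUE,
                          labels = FALSE)) - 1L
  recode(codes)
}

#' Build a DiscreteVector from integer codes
#'
#' @param codes integer codes in `[0, n_categories)`.
#' @param n_categories number of categories; defaults to `max(codes) + 1`.
#' @return A `DiscreteVector`.
#' @export
discrete_vector <- function(codes, n_categories = NULL) {
  codes <- as.integer(codes)
  if (anyNA(codes)) stop("codes must not contain NA", call. = FALSE)
  if (is.null(n_categories)) n_categories <- max(codes) + 1L
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L || any(codes < 0L) || any(codes >= n_categories)) {
    stop("codes must lie in [0, n_categories)", call. = FALSE)
  }
  structure(list(codes = codes, n_categories = n_categories),
            class = "DiscreteVector")
}

# compress arbitrary non-negative integer codes to consecutive 0..K-1
recode <- function(codes) {
  u <- sort(unique(codes))
  discrete_vector(match(codes, u) - 1L, length(u))
}

as_discrete <- function(x) {
  if (inherits(x, "DiscreteVector")) return(x)
  recode(as.integer(x))
}

# entropy in bits from a count vector
entropy_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  -sum(p * log2(p))
}

# product-code two discrete vectors into one
joint_code <- function(x, y) {
  discrete_vector(x$codes * y$n_categories + y$codes,
                  x$n_categories * y$n_categories)
}

counts_of <- function(x) tabulate(x$codes + 1L, nbins = x$n_categories)

check_lengths <- function(...) {
  ls <- vapply(list(...), function(v) length(v$codes), integer(1))
  if (length(unique(ls)) != 1L) {
    stop("discrete vectors must have equal length", call. = FALSE)
  }
}

#' Plug-in Shannon entropy in bits
#'
#' Maximum-likelihood estimate \eqn{H(X) = -\sum \hat p \log_2 \hat p} on the
#' empirical distribution; no bias correction.
#'
#' @param x a `DiscreteVector` (or integer codes).
#' @return entropy in bits, in `[0, log2(n_categories)]`.
#' @export
entropy_bits <- function(x) {
  x <- as_discrete(x)
  if (length(x$codes) == 0L) stop("empty vector", call. = FALSE)
  entropy_from_counts(counts_of(x))
}

#' Plug-in mutual information in bits
#'
#' \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)} on the empirical joint distribution.
#' Tiny negative values from floating-point cancellation are clamped to 0.
#'
#' @param x,y `DiscreteVector`s of equal length.
#' @return mutual information in bits (non-negative).
#' @export
mutual_info <- function(x, y) {
  x <- as_discrete(x); y <- as_discrete(y)
  check_lengths(x, y)
  h <- entropy_from_counts(counts_of(x)) +
    entropy_from_counts(counts_of(y)) -
    entropy_from_counts(counts_of(joint_code(x, y)))
  max(h, 0)
}

#' Plug-in conditional mutual information in bits
#'
#' \eqn{I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)}, clamped at 0.
#' Conditioning on a constant reduces to [mutual_info()].
#'
#' @param x,y,z `DiscreteVector`s of equal length.
#' @return conditional mutual information in bits (non-negative).
#' @export
cond_mutual_info <- function(x, y, z) {
  x <- as_discrete(x); y <- as_discrete(y); z <- as_discrete(z)
  check_lengths(x, y, z)
  h <- entropy_from_counts(counts_of(joint_code(x, z))) +
    entropy_from_counts(counts_of(joint_code(y, z))) -
    entropy_from_counts(counts_of(z)) -
    entropy_from_counts(counts_of(joint_code(joint_code(x, y), z)))
  max(h, 0)
}

#' Plug-in joint mutual information in bits
#'
#' \eqn{I(X,Z;Y)} computed by merging `x` and `z` into a product-coded
#' variable. Satisfies the chain rule
#' \eqn{I(X,Z;Y) = I(Z;Y) + I(X;Y|Z)}.
#'
#' @param x,z the two variables forming the joint input.
#' @param y the target variable.
#' @return joint mutual information in bits (non-negative).
#' @export
joint_mutual_info <- function(x, z, y) {
  x <- as_discrete(x); z <- as_discrete(z); y <- as_discrete(y)
  check_lengths(x, z, y)
  mutual_info(joint_code(x, z), y)
}

#' Joint entropy of up to three discrete variables, in bits
#' @param x,y,z `DiscreteVector`s; `z` optional.
#' @return plug-in joint entropy in bits.
#' @export
joint_entropy_bits <- function(x, y, z = NULL) {
  x <- as_discrete(x); y <- as_discrete(y)
  j <- joint_code(x, y)
  if (!is.null(z)) {
    z <- as_discrete(z)
    check_lengths(x, y, z)
    j <- joint_code(j, z)
  } else {
    check_lengths(x, y)
  }
  entropy_from_counts(counts_of(j))
}
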