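#' Discretize a numeric column into integer category codes
#'
#' Bins a continuous feature column so that entropies and mutual information
#' can be computed on empirical category frequencies. Class labels are never
#' passed through this function; only feature columns are binned.
#'
#' @param x Numeric vector; all values must be finite.
#' @param method One of `"equal_width"` (split `[min, max]` into `n_bins`
#'   half-open intervals, the last closed), `"equal_frequency"` (quantile
#'   breaks), or `"none"` (input must already be integer-coded and is
#'   recoded to consecutive non-negative codes).
#' @param n_bins Number of bins (at least 2 unless `method = "none"`).
#'
#' @return Integer vector of 0-based category codes, the same length as `x`,
#'   with attribute `cardinality` giving the number of distinct codes.
#'   A constant column maps to the single code 0. Deterministic.
#' @examples
#' discretize(c(0, 0.1, 0.9, 1), n_bins = 2)
#' @export
discretize <- function(x, method = c("equal_width", "equal_frequency", "none"),
                       n_bins = 10L) {
  method <- match.arg(method)
  if (length(x) == 0L) stop("empty column")
  if (!is.numeric(x)) stop("column must be numeric")
  if (any(!is.finite(x))) stop("non-finite value in column")
  if (method != "none") {
    if (n_bins < 2L) stop("n_bins must be >= 2")
    n_bins <- as.integer(n_bins)
  }
  codes <- switch(method,
    none = {
      if (any(x != round(x))) {
        stop("method 'none' requires integer-coded input")
      }
      match(x, sort(unique(x))) - 1L
    },
    equal_width = {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        rep.int(0L, length(x))
      } else {
        # half-open [a, b) bins; top value falls in the last (closed) bin
        raw <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins)
        as.integer(pmin(raw, n_bins - 1L))
      }
    },
    equal_frequency = {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE, type = 7))
      if (length(br) < 2L) {
        rep.int(0L, length(x))
      } else {
        as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)) - 1L
      }
    }
  )
  codes <- match(codes, sort(unique(codes))) - 1L
  structure(codes, cardinality = length(unique(codes)))
}

# Canonically sorted non-zero counts -> entropy in bits. Sorting fixes the
# floating-point accumulation order, so any two vectors with the same count
# multiset give bit-identical entropy (this is what makes info_gain exactly
# symmetric in its arguments).
.entropy_from_counts <- function(counts) {
  counts <- sort(counts[counts > 0])
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
}

#' Shannon entropy of a discrete vector, in bits
#'
#' Plug-in (maximum-likelihood) estimate \eqn{H(X) = -\sum_x p(x) \log_2 p(x)}
#' over empirical frequencies, with \eqn{0 \log 0 = 0}.
#'
#' @param x Vector of category codes (integer, factor or character).
#' @return Entropy in bits, in `[0, log2(cardinality)]`.
#' @examples
#' entropy(c(0, 0, 1, 1)) # 1 bit
#' @export
entropy <- function(x) {
  if (length(x) == 0L) stop("empty vector")
  .entropy_from_counts(as.vector(table(x)))
}

#' Conditional entropy H(X | Y), in bits
#'
#' \eqn{H(X|Y) = -\sum_j p(y_j) \sum_i p(x_i|y_j) \log_2 p(x_i|y_j)},
#' computed by the direct double sum over the joint contingency table.
#'
#' @param x,y Equal-length vectors of category codes.
#' @return Conditional entropy in bits, in `[0, H(X)]`.
#' @export
conditional_entropy <- function(x, y) {
  .check_pair(x, y)
  tab <- table(x, y)
  p_y <- unname(colSums(tab)) / sum(tab)
  h <- 0
  for (j in seq_along(p_y)) {
    if (p_y[j] > 0) {
      h <- h + p_y[j] * .entropy_from_counts(tab[, j])
    }
  }
  h
}

#' Joint entropy H(X, Y), in bits
#'
#' \eqn{H(X,Y) = -\sum_{x,y} p(x,y) \log_2 p(x,y)} over the empirical joint
#' distribution.
#'
#' @param x,y Equal-length vectors of category codes.
#' @return Joint entropy in bits, in `[max(H(X), H(Y)), H(X) + H(Y)]`.
#' @export
joint_entropy <- function(x, y) {
  .check_pair(x, y)
  .entropy_from_counts(as.vector(table(x, y)))
}

#' Information gain (mutual information) between two discrete vectors
#'
#' Computed as \eqn{IG(X;Y) = H(X) + H(Y) - H(X,Y)}; equal (to numerical
#' precision) to \eqn{H(X) - H(X|Y)}. Symmetric in its arguments and
#' non-negative. All quantities are in bits.
#'
#' @param x,y Equal-length vectors of category codes.
#' @return Mutual information in bits, in `[0, min(H(X), H(Y))]`.
#' @examples
#' info_gain(c(0, 0, 1, 1), c(0, 1, 0, 1)) # independent: 0
#' @export
info_gain <- function(x, y) {
  .check_pair(x, y)
  ig <- entropy(x) + entropy(y) - joint_entropy(x, y)
  max(ig, 0)
}

#' Symmetric uncertainty (normalized relevance) between two discrete vectors
#'
#' The normalized information gain
#' \eqn{R = 2\,IG(X;Y) / (H(X) + H(Y))}, bounded in `[0, 1]`: 0 for
#' independent variables, 1 when the two variables determine each other.
#' This single statistic serves both as feature-class relevance
#' (\eqn{R_{i,c}}) and feature-feature redundancy (\eqn{R_{i,j}}).
#' When both variables are constant the denominator vanishes and the
#' statistic is defined as 0 (a constant carries no usable relevance).
#'
#' @param x,y Equal-length vectors of category codes.
#' @return A value in `[0, 1]`.
#' @examples
#' symmetric_uncertainty(c(0, 1, 0, 1), c(1, 0, 1, 0)) # 1: mutual determination
#' @export
symmetric_uncertainty <- function(x, y) {
  .check_pair(x, y)
  hx <- entropy(x)
  hy <- entropy(y)
  denom <- hx + hy
  if (denom == 0) return(0)
  r <- 2 * (hx + hy - joint_entropy(x, y)) / denom
  min(max(r, 0), 1)
}
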