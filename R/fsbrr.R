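#' @importFrom rlang .data
NULL

# Split a feature table into a list(codes = integer matrix of discretized
# feature columns, class = class codes, features = feature names).
# The class column is factor-coded, never binned.
.prepare_table <- function(data, class_col, binning, n_bins) {
  data <- as.data.frame(data)
  if (!class_col %in% names(data)) {
    stop("class column '", class_col, "' not found")
  }
  cls <- data[[class_col]]
  if (anyNA(data)) stop("missing values in feature table")
  if (length(unique(cls)) < 2L) stop("class attribute must have >= 2 categories")
  feats <- data[setdiff(names(data), class_col)]
  if (ncol(feats) < 1L) stop("no feature columns")
  if (nrow(feats) < 2L) stop("need >= 2 instances")
  if (!all(vapply(feats, is.numeric, logical(1L)))) {
    stop("all feature columns must be numeric")
  }
  codes <- vapply(
    feats,
    function(col) as.integer(discretize(col, method = binning, n_bins = n_bins)),
    integer(nrow(feats))
  )
  codes <- matrix(as.integer(codes), nrow = nrow(feats),
                  dimnames = list(NULL, names(feats)))
  list(codes = codes, class = as.integer(factor(cls)) - 1L,
       features = names(feats))
}

.check_config <- function(tau, delta, alpha) {
  if (tau < 0) stop("tau must be >= 0")
  if (delta < 0.05 || delta > 0.13) {
    warning("delta = ", delta, " outside recommended range [0.05, 0.13]")
  }
  if (alpha < 0.60 || alpha > 0.66) {
    warning("alpha = ", alpha, " outside recommended range [0.60, 0.66]")
  }
  if (delta >= alpha) warning("delta >= alpha: redundancy rule 2 can never fire")
}

#' Feature-class relevance profile
#'
#' Scores every feature against the class attribute by symmetric uncertainty
#' (\eqn{R_{i,c}}), drops features scoring below the irrelevance threshold
#' `tau`, and reports the summary statistics \eqn{R_{max}} and \eqn{\bar R}
#' (maximum and mean relevance over the retained features) used by the
#' redundancy-removal rules.
#'
#' @param data Data frame of numeric feature columns plus one class column.
#' @param class_col Name of the class column (default `"class"`).
#' @param tau Irrelevance threshold: features with \eqn{R_{i,c} < \tau} are
#'   dropped. The default 0 retains every feature (weak relevance is kept in
#'   the absence of prior knowledge).
#' @param binning,n_bins Discretization applied to feature columns before
#'   computing entropies; see [discretize()]. The class column is never binned.
#'
#' @return A tibble with columns `feature` and `relevance`, ordered by
#'   descending relevance (ties broken by original column order), restricted
#'   to retained features; attributes `r_max`, `r_bar` (over retained
#'   features) and `dropped` (tibble of features removed as irrelevant).
#' @examples
#' d <- synth_table(n_instances = 100, n_informative = 2, n_irrelevant = 3,
#'                  seed = 1)
#' relevance_profile(d)
#' @export
relevance_profile <- function(data, class_col = "class", tau = 0,
                              binning = "equal_width", n_bins = 10L) {
  prep <- .prepare_table(data, class_col, binning, n_bins)
  r <- vapply(seq_len(ncol(prep$codes)),
              function(i) symmetric_uncertainty(prep$codes[, i], prep$class),
              numeric(1L))
  keep <- r >= tau
  if (!any(keep)) stop("empty after irrelevance filter (tau = ", tau, ")")
  const <- vapply(seq_len(ncol(prep$codes)),
                  function(i) length(unique(prep$codes[, i])) == 1L, logical(1L))
  if (any(const & keep)) {
    warning("constant feature(s) retained with R = 0: ",
            paste(prep$features[const & keep], collapse = ", "),
            "; consider tau > 0")
  }
  ord <- order(-r[keep], seq_along(r)[keep])
  out <- tibble::tibble(feature = prep$features[keep][ord],
                        relevance = r[keep][ord])
  attr(out, "r_max") <- max(out$relevance)
  attr(out, "r_bar") <- mean(out$relevance)
  attr(out, "dropped") <- tibble::tibble(feature = prep$features[!keep],
                                         relevance = r[!keep])
  out
}

#' FSBRR: filter feature selection by approximate redundancy removal
#'
#' Selects a feature subset in three stages. (1) Every feature is scored
#' against the class by symmetric uncertainty \eqn{R_{i,c}}; features below
#' the irrelevance threshold `tau` are discarded. (2) Survivors are ordered
#' by descending \eqn{R_{i,c}} (ties: original column order). (3) Each
#' surviving feature in turn acts as pivot \eqn{F_i}; every lower-ranked
#' survivor \eqn{F_j} is tested against two removal rules on the pairwise
#' relevance \eqn{R_{i,j}}:
#' \itemize{
#'   \item rule 1: \eqn{R_{i,c} - R_{j,c} \le \delta} and
#'     \eqn{R_{i,j} \ge R_{i,c}} — the pivot nearly matches \eqn{F_j}'s
#'     class relevance and correlates with it at least as strongly as with
#'     the class, so \eqn{F_j} is an approximate duplicate;
#'   \item rule 2: \eqn{\delta < R_{i,c} - R_{j,c} < \alpha} and
#'     \eqn{R_{i,j} > (\bar R + R_{j,c})/2} — \eqn{F_j} is clearly weaker
#'     and the pivot substitutes for it at a lower evidence bar.
#' }
#' Removed features are never revisited as pivots. A feature whose pairwise
#' relevance with every pivot stays below both bars is never removed, no
#' matter how small its class relevance (beyond `tau`). The procedure is
#' fully deterministic.
#'
#' @inheritParams relevance_profile
#' @param delta Gap threshold separating the two rules (recommended
#'   `[0.05, 0.13]`; default 0.08).
#' @param alpha Upper gap bound for rule 2 (recommended `[0.60, 0.66]`;
#'   default 0.64). Values outside the recommended ranges warn but proceed.
#'
#' @return An object of class `"fsbrr"`: a list with
#' \describe{
#'   \item{selected}{tibble of surviving features (`feature`, `relevance`),
#'     in descending relevance order.}
#'   \item{removal_log}{tibble of removals: `pivot`, `removed`, `rule`
#'     (`"irrelevant"`, `"redundancy_rule_1"` or `"redundancy_rule_2"`),
#'     `r_pivot_c`, `r_removed_c`, `r_pivot_removed`. Irrelevance removals
#'     have `NA` pivot and pairwise scores.}
#'   \item{pair_evaluations}{number of pairwise \eqn{R_{i,j}} computations
#'     actually performed: `n - 1` when everything after the first pivot is
#'     redundant, `n (n - 1) / 2` when nothing is removed.}
#'   \item{r_max, r_bar}{summary relevance statistics over the
#'     tau-retained set.}
#'   \item{config}{the parameters the selection was run with.}
#' }
#' @examples
#' d <- synth_table(n_instances = 200, n_informative = 3,
#'                  n_exact_duplicates = 2, n_irrelevant = 3, seed = 7)
#' fit <- fsbrr(d)
#' fit$selected
#' glance(fit)
#' @export
fsbrr <- function(data, class_col = "class", tau = 0, delta = 0.08,
                  alpha = 0.64, binning = "equal_width", n_bins = 10L) {
  .check_config(tau, delta, alpha)
  prep <- .prepare_table(data, class_col, binning, n_bins)
  prof <- relevance_profile(data, class_col = class_col, tau = tau,
                            binning = binning, n_bins = n_bins)
  dropped <- attr(prof, "dropped")
  r_bar <- attr(prof, "r_bar")
  r_max <- attr(prof, "r_max")

  feats <- prof$feature
  r_c <- prof$relevance
  n <- length(feats)
  alive <- rep.int(TRUE, n)
  pair_evals <- 0L
  log_pivot <- character(0)
  log_removed <- character(0)
  log_rule <- character(0)
  log_ric <- numeric(0)
  log_rjc <- numeric(0)
  log_rij <- numeric(0)

  for (i in seq_len(max(n - 1L, 0L))) {
    if (!alive[i]) next
    xi <- prep$codes[, feats[i]]
    for (j in seq.int(i + 1L, n)) {
      if (!alive[j]) next
      r_ij <- symmetric_uncertainty(xi, prep$codes[, feats[j]])
      pair_evals <- pair_evals + 1L
      gap <- r_c[i] - r_c[j]
      rule <- if (gap <= delta && r_ij >= r_c[i]) {
        "redundancy_rule_1"
      } else if (gap > delta && gap < alpha && r_ij > (r_bar + r_c[j]) / 2) {
        "redundancy_rule_2"
      } else {
        NA_character_
      }
      if (!is.na(rule)) {
        alive[j] <- FALSE
        log_pivot <- c(log_pivot, feats[i])
        log_removed <- c(log_removed, feats[j])
        log_rule <- c(log_rule, rule)
        log_ric <- c(log_ric, r_c[i])
        log_rjc <- c(log_rjc, r_c[j])
        log_rij <- c(log_rij, r_ij)
      }
    }
  }

  removal_log <- dplyr::bind_rows(
    tibble::tibble(pivot = NA_character_, removed = dropped$feature,
                   rule = rep("irrelevant", nrow(dropped)),
                   r_pivot_c = NA_real_, r_removed_c = dropped$relevance,
                   r_pivot_removed = NA_real_),
    tibble::tibble(pivot = log_pivot, removed = log_removed, rule = log_rule,
                   r_pivot_c = log_ric, r_removed_c = log_rjc,
                   r_pivot_removed = log_rij)
  )

  structure(
    list(
      selected = tibble::tibble(feature = feats[alive],
                                relevance = r_c[alive]),
      removal_log = removal_log,
      pair_evaluations = pair_evals,
      r_max = r_max,
      r_bar = r_bar,
      n_input = n + nrow(dropped),
      config = list(tau = tau, delta = delta, alpha = alpha,
                    binning = binning, n_bins = as.integer(n_bins),
                    class_col = class_col)
    ),
    class = "fsbrr"
  )
}

#' @export
print.fsbrr <- function(x, ...) {
  cat("FSBRR feature selection\n")
  cat(sprintf("  features: %d in -> %d selected (tau=%g, delta=%g, alpha=%g)\n",
              x$n_input, nrow(x$selected), x$config$tau, x$config$delta,
              x$config$alpha))
  cat(sprintf("  removals: %d irrelevant, %d rule 1, %d rule 2\n",
              sum(x$removal_log$rule == "irrelevant"),
              sum(x$removal_log$rule == "redundancy_rule_1"),
              sum(x$removal_log$rule == "redundancy_rule_2")))
  cat(sprintf("  pairwise evaluations: %d\n", x$pair_evaluations))
  invisible(x)
}

#' Tidy an FSBRR selection
#'
#' One row per input feature with its relevance, fate
#' (`selected` / `irrelevant` / `redundancy_rule_1` / `redundancy_rule_2`)
#' and selection rank (NA for removed features).
#'
#' @param x An object returned by [fsbrr()].
#' @param ... Unused.
#' @return A tibble with columns `feature`, `relevance`, `fate`, `rank`.
#' @export
tidy.fsbrr <- function(x, ...) {
  sel <- dplyr::mutate(x$selected, fate = "selected",
                       rank = dplyr::row_number())
  rem <- tibble::tibble(feature = x$removal_log$removed,
                        relevance = x$removal_log$r_removed_c,
                        fate = x$removal_log$rule,
                        rank = NA_integer_)
  dplyr::bind_rows(sel, rem)
}

#' Glance at an FSBRR selection
#'
#' @param x An object returned by [fsbrr()].
#' @param ... Unused.
#' @return A one-row tibble summarising the selection.
#' @export
glance.fsbrr <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_input,
    n_selected = nrow(x$selected),
    n_irrelevant = sum(x$removal_log$rule == "irrelevant"),
    n_redundant = sum(x$removal_log$rule != "irrelevant"),
    pair_evaluations = x$pair_evaluations,
    r_max = x$r_max,
    r_bar = x$r_bar,
    tau = x$config$tau,
    delta = x$config$delta,
    alpha = x$config$alpha
  )
}

#' Plot an FSBRR selection
#'
#' Relevance of every input feature, coloured by its fate (selected,
#' irrelevant, or removed under one of the two redundancy rules).
#'
#' @param object An object returned by [fsbrr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fsbrr <- function(object, ...) {
  d <- tidy.fsbrr(object)
  d$feature <- factor(d$feature, levels = d$feature[order(-d$relevance)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$relevance,
                                  fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relevance to class (symmetric uncertainty)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Sweep FSBRR over a grid of delta or alpha values
#'
#' Runs one selection per grid point, holding the other parameter fixed,
#' and optionally evaluates each selected subset with a classifier via an
#' evaluator callback. Mirrors the two single-parameter sensitivity
#' experiments the method is usually profiled with (delta swept with alpha
#' fixed, and vice versa).
#'
#' @inheritParams fsbrr
#' @param delta,alpha Numeric vectors; exactly one may have length > 1.
#' @param evaluator Optional function `(data, selected_features) -> number`
#'   returning a performance value recorded alongside each grid point.
#' @return A tibble with columns `delta`, `alpha`, `n_selected`,
#'   `pair_evaluations` and (when an evaluator is given) `performance`,
#'   of class `"fsbrr_sweep"`.
#' @examples
#' d <- synth_table(n_instances = 100, n_informative = 2,
#'                  n_exact_duplicates = 2, n_irrelevant = 2, seed = 3)
#' fsbrr_sweep(d, delta = c(0, 0.1, 0.2))
#' @export
fsbrr_sweep <- function(data, delta = 0.08, alpha = 0.64, class_col = "class",
                        tau = 0, binning = "equal_width", n_bins = 10L,
                        evaluator = NULL) {
  if (length(delta) == 0L || length(alpha) == 0L) stop("empty parameter grid")
  if (length(delta) > 1L && length(alpha) > 1L) {
    stop("sweep one parameter at a time: delta or alpha must be scalar")
  }
  grid <- tidyr::expand_grid(delta = delta, alpha = alpha)
  res <- purrr::pmap_dfr(grid, function(delta, alpha) {
    fit <- suppressWarnings(
      fsbrr(data, class_col = class_col, tau = tau, delta = delta,
            alpha = alpha, binning = binning, n_bins = n_bins)
    )
    row <- tibble::tibble(delta = delta, alpha = alpha,
                          n_selected = nrow(fit$selected),
                          pair_evaluations = fit$pair_evaluations)
    if (!is.null(evaluator)) {
      row$performance <- evaluator(data, fit$selected$feature)
    }
    row
  })
  class(res) <- c("fsbrr_sweep", class(res))
  res
}

#' Plot a parameter sweep
#'
#' @param object A tibble returned by [fsbrr_sweep()].
#' @param ... Unused.
#' @return A ggplot object: selected-subset size (and performance, if
#'   recorded) against the swept parameter.
#' @export
autoplot.fsbrr_sweep <- function(object, ...) {
  swept <- if (length(unique(object$delta)) > 1L) "delta" else "alpha"
  d <- tidyr::pivot_longer(
    object,
    cols = dplyr::any_of(c("n_selected", "performance")),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[swept]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = swept) +
    ggplot2::theme_minimal()
}
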