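# Independent oracles: direct textbook summations over joint count tables,
# and a naive line-by-line transcription of the selection procedure. These
# deliberately share no code with the package internals.

# entropy of a count vector by direct summation (no sorting, natural order)
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# all statistics of a joint count matrix (rows = x categories, cols = y)
oracle_joint_stats <- function(tab) {
  n <- sum(tab)
  hx <- oracle_entropy(rowSums(tab))
  hy <- oracle_entropy(colSums(tab))
  hxy <- oracle_entropy(as.vector(tab))
  # H(X|Y) by the explicit double sum
  hx_given_y <- 0
  for (j in seq_len(ncol(tab))) {
    py <- sum(tab[, j]) / n
    if (py > 0) hx_given_y <- hx_given_y + py * oracle_entropy(tab[, j])
  }
  ig6 <- hx - hx_given_y
  ig7 <- hx + hy - hxy
  list(hx = hx, hy = hy, hxy = hxy, hx_given_y = hx_given_y,
       ig6 = ig6, ig7 = ig7,
       r = if (hx + hy > 0) 2 * ig7 / (hx + hy) else 0)
}

# expand a joint count matrix into a pair of aligned code vectors
oracle_expand <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      x <- c(x, rep.int(i - 1L, tab[i, j]))
      y <- c(y, rep.int(j - 1L, tab[i, j]))
    }
  }
  list(x = x, y = y)
}

# random joint count table with given maximum cardinalities
oracle_random_table <- function(max_levels = 4L, max_count = 20L) {
  kx <- sample(2:max_levels, 1L)
  ky <- sample(2:max_levels, 1L)
  tab <- matrix(sample(0:max_count, kx * ky, replace = TRUE), nrow = kx)
  if (sum(tab) == 0) tab[1, 1] <- 1L
  tab
}

# --- naive transcription of the selection procedure ---------------------

# symmetric uncertainty with its own entropy path (conditional-entropy form)
naive_su <- function(x, y) {
  hx <- oracle_entropy(as.vector(table(x)))
  hy <- oracle_entropy(as.vector(table(y)))
  if (hx + hy == 0) return(0)
  tab <- table(x, y)
  hx_given_y <- 0
  for (j in seq_len(ncol(tab))) {
    py <- sum(tab[, j]) / sum(tab)
    if (py > 0) hx_given_y <- hx_given_y + py * oracle_entropy(tab[, j])
  }
  2 * (hx - hx_given_y) / (hx + hy)
}

# literal transcription: tau filter, mean relevance, descending sort
# (ties by original index), pivot loop with the two removal rules;
# pairwise relevance recomputed directly for every surviving pair
naive_fsbrr <- function(data, class_col = "class", tau = 0, delta = 0.08,
                        alpha = 0.64, n_bins = 10L) {
  df <- as.data.frame(data)
  cls <- df[[class_col]]
  feats <- setdiff(names(df), class_col)
  codes <- lapply(df[feats], function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) rep.int(0L, length(col))
    else pmin(floor((col - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  })
  r_c <- vapply(codes, function(f) naive_su(cls, f), numeric(1))
  keep <- which(r_c >= tau)
  r_bar <- mean(r_c[keep])
  ord <- keep[order(-r_c[keep], keep)]
  fnames <- feats[ord]
  rc <- r_c[ord]
  alive <- rep(TRUE, length(ord))
  log <- list()
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    for (j in seq_along(ord)) {
      if (j <= i || !alive[j]) next
      rjc <- naive_su(cls, codes[[fnames[j]]])
      rij <- naive_su(codes[[fnames[i]]], codes[[fnames[j]]])
      if (rc[i] - rjc <= delta && rij >= rc[i]) {
        alive[j] <- FALSE
        log[[length(log) + 1L]] <- data.frame(
          pivot = fnames[i], removed = fnames[j], rule = "redundancy_rule_1")
      } else if (rc[i] - rjc > delta && rc[i] - rjc < alpha &&
                 rij > (r_bar + rjc) / 2) {
        alive[j] <- FALSE
        log[[length(log) + 1L]] <- data.frame(
          pivot = fnames[i], removed = fnames[j], rule = "redundancy_rule_2")
      }
    }
  }
  list(selected = fnames[alive],
       removal_log = if (length(log)) do.call(rbind, log)
                     else data.frame(pivot = character(0),
                                     removed = character(0),
                                     rule = character(0)))
}

# small random synthetic table for equivalence checks
random_synth_table <- function(seed) {
  synth_table(
    n_instances = sample(40:200, 1L),
    n_informative = sample(2:6, 1L),
    n_exact_duplicates = sample(0:4, 1L),
    n_noisy_duplicates = sample(0:4, 1L),
    n_irrelevant = sample(0:16, 1L),
    shift = stats::runif(1, 0.5, 3),
    seed = seed
  )
}
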