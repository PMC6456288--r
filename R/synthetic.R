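#' Generate a synthetic feature table with planted structure
#'
#' Emulates the regime of high-dimensional biomedical classification data:
#' far more features than would be needed, of which only a few carry class
#' information, some are exact or noisy copies of those, and the rest are
#' class-independent noise. A binary class is drawn first; informative
#' features are class-conditional Gaussians (unit variance, means separated
#' by `shift`); exact duplicates copy informative features verbatim; noisy
#' duplicates add Gaussian noise with sd `noise_sd`; irrelevant features are
#' standard-normal draws independent of the class. Ground-truth roles are
#' recorded per feature.
#'
#' @param n_instances Number of rows.
#' @param n_informative Number of class-informative features (>= 1).
#' @param n_exact_duplicates,n_noisy_duplicates Numbers of verbatim / noisy
#'   copies of informative features (parents assigned round-robin).
#' @param n_irrelevant Number of class-independent features.
#' @param class_balance Probability of the positive class (default 0.5).
#' @param shift Class-conditional mean separation of informative features,
#'   in sd units (default 2, a clearly detectable but not trivial effect).
#' @param noise_sd Standard deviation of the noise added to noisy
#'   duplicates (default 0.2).
#' @param seed Integer seed; the table is fully reproducible from it.
#'
#' @return A tibble of numeric feature columns `inf*`, `dup*`, `noisydup*`,
#'   `irr*` plus a factor column `class` (levels `"neg"`, `"pos"`), with
#'   attribute `truth`: a tibble (`feature`, `role`, `parent`) recording the
#'   planted role of every feature. Retrieve it with [feature_truth()].
#' @examples
#' d <- synth_table(n_instances = 50, n_informative = 2,
#'                  n_exact_duplicates = 1, n_irrelevant = 3, seed = 1)
#' feature_truth(d)
#' @export
synth_table <- function(n_instances, n_informative, n_exact_duplicates = 0L,
                        n_noisy_duplicates = 0L, n_irrelevant = 0L,
                        class_balance = 0.5, shift = 2, noise_sd = 0.2,
                        seed = 1L) {
  if (n_informative < 1L) stop("n_informative must be >= 1")
  if (min(n_exact_duplicates, n_noisy_duplicates, n_irrelevant) < 0L) {
    stop("feature counts must be >= 0")
  }
  if (n_instances < 2L) stop("n_instances must be >= 2")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  cls <- stats::rbinom(n_instances, 1L, class_balance)
  # guard: both classes must be present for a classification table
  if (length(unique(cls)) < 2L) {
    cls[1:2] <- c(0L, 1L)
  }

  inf <- vapply(seq_len(n_informative), function(i) {
    stats::rnorm(n_instances, mean = cls * shift, sd = 1)
  }, numeric(n_instances))
  colnames(inf) <- paste0("inf", seq_len(n_informative))

  parent_of <- function(k) as.integer((k - 1L) %% n_informative) + 1L

  dup <- NULL
  if (n_exact_duplicates > 0L) {
    dup <- vapply(seq_len(n_exact_duplicates),
                  function(k) inf[, parent_of(k)], numeric(n_instances))
    colnames(dup) <- paste0("dup", seq_len(n_exact_duplicates))
  }
  ndup <- NULL
  if (n_noisy_duplicates > 0L) {
    ndup <- vapply(seq_len(n_noisy_duplicates), function(k) {
      inf[, parent_of(k)] + stats::rnorm(n_instances, sd = noise_sd)
    }, numeric(n_instances))
    colnames(ndup) <- paste0("noisydup", seq_len(n_noisy_duplicates))
  }
  irr <- NULL
  if (n_irrelevant > 0L) {
    irr <- matrix(stats::rnorm(n_instances * n_irrelevant),
                  nrow = n_instances,
                  dimnames = list(NULL, paste0("irr", seq_len(n_irrelevant))))
  }

  values <- cbind(inf, dup, ndup, irr)
  out <- tibble::as_tibble(as.data.frame(values))
  out$class <- factor(ifelse(cls == 1L, "pos", "neg"),
                      levels = c("neg", "pos"))

  truth <- tibble::tibble(
    feature = colnames(values),
    role = c(rep("informative", n_informative),
             rep("exact_duplicate", n_exact_duplicates),
             rep("noisy_duplicate", n_noisy_duplicates),
             rep("irrelevant", n_irrelevant)),
    parent = c(rep(NA_character_, n_informative),
               if (n_exact_duplicates > 0L)
                 paste0("inf", vapply(seq_len(n_exact_duplicates), parent_of, 1L)),
               if (n_noisy_duplicates > 0L)
                 paste0("inf", vapply(seq_len(n_noisy_duplicates), parent_of, 1L)),
               rep(NA_character_, n_irrelevant))
  )
  attr(out, "truth") <- truth
  out
}

#' Ground-truth feature roles of a synthetic table
#'
#' @param data A tibble returned by [synth_table()].
#' @return A tibble with columns `feature`, `role`, `parent`.
#' @export
feature_truth <- function(data) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("no ground-truth attribute: not a synth_table()")
  truth
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
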