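# Resampling validation: training bootstrap with a fixed test set,
# label-permutation tests for pair MAE, and a randomization test for
# gene-set overlap.

#' Resampling configuration
#'
#' @param n_boot bootstrap resample count (study design default 1000).
#' @param n_perm permutation / randomization draw count (default 1e4; the
#'   add-one estimator floors p at 1/(n_perm+1)).
#' @param seed integer seed.
#' @param ci_level central percentile mass of the confidence interval.
#' @export
resample_config <- function(n_boot = 1000L, n_perm = 10000L, seed = 1L,
                            ci_level = 0.95) {
  if (n_boot < 1L || n_perm < 1L) stop("counts must be >= 1")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), ci_level = ci_level),
            class = "resample_config")
}

#' Training bootstrap with a fixed test set
#'
#' Draws `n_boot` resamples of the training samples (with replacement, same
#' size), reruns the full pipeline (pair re-selection included, if the
#' pipeline performs it) on each resample, scores the FIXED test set, and
#' summarizes every metric by its median and central percentile interval.
#' Resamples that lose a class entirely are redrawn (up to 100 attempts,
#' counted); pipeline failures are recorded and the resample skipped.
#'
#' @param train,test disjoint [ordinal_dataset()]s; the test set is fixed.
#' @param pipeline `function(train_ds, test_ds)` returning integer predicted
#'   labels for the test samples.
#' @param config a [resample_config()].
#' @return object of class `bootstrap_eval`: `summary` (data frame metric /
#'   median / ci_low / ci_high / n_failed), `samples` (resamples x metrics
#'   matrix of raw values), `n_failed`, `n_redraws`.
#' @export
bootstrap_evaluate <- function(train, test, pipeline, config) {
  n <- ncol(train$values)
  metric_names <- c("mae", "accuracy", "balanced_accuracy", "macro_f1",
                    "cohen_kappa", "mcc")
  samples <- matrix(NA_real_, nrow = config$n_boot, ncol = length(metric_names),
                    dimnames = list(NULL, metric_names))
  n_failed <- 0L
  n_redraws <- 0L
  set.seed(config$seed)
  for (b in seq_len(config$n_boot)) {
    idx <- NULL
    for (try in seq_len(100L)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(train$labels[cand])) == train$p) {
        idx <- cand
        break
      }
      n_redraws <- n_redraws + 1L
    }
    if (is.null(idx)) {
      n_failed <- n_failed + 1L
      next
    }
    boot <- dataset_subset(train, idx)
    pred <- tryCatch(pipeline(boot, test), error = function(e) e)
    if (inherits(pred, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    m <- ordinal_metrics(test$labels, pred, p = train$p)
    samples[b, ] <- m$value[match(metric_names, m$metric)]
  }
  ok <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(ok) == 0L) stop("all bootstrap resamples failed")
  alpha <- (1 - config$ci_level) / 2
  summ <- data.frame(
    metric = metric_names,
    median = apply(ok, 2L, median),
    ci_low = apply(ok, 2L, quantile, probs = alpha),
    ci_high = apply(ok, 2L, quantile, probs = 1 - alpha),
    n_failed = n_failed, row.names = NULL)
  structure(list(summary = summ, samples = samples, n_failed = n_failed,
                 n_redraws = n_redraws),
            class = "bootstrap_eval")
}

#' @export
print.bootstrap_eval <- function(x, ...) {
  cat(sprintf("Training bootstrap over %d resamples (%d failed, %d redraws)\n",
              nrow(x$samples), x$n_failed, x$n_redraws))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Label-permutation test for a gene pair's cross-validated MAE
#'
#' The null distribution is the pair's CV MAE recomputed under `n_perm`
#' seeded permutations of the sample labels (expression untouched, so the
#' pair's joint expression structure is preserved); the one-sided p-value
#' uses the add-one estimator \eqn{(1 + \#\{null \le obs\}) / (n_{perm}+1)}.
#'
#' @param ds an [ordinal_dataset()].
#' @param gene_a,gene_b gene identifiers.
#' @param config a [resample_config()]; its `seed` drives the permutations.
#' @param screen a [screen_config()] for the CV folds (defaults to 5 folds
#'   with the same seed).
#' @return list with `p_value`, `observed`, `null` (the permuted MAEs).
#' @export
permutation_mae_test <- function(ds, gene_a, gene_b, config,
                                 screen = NULL) {
  screen <- screen %||% screen_config(seed = config$seed)
  observed <- pair_mae_cv(ds, gene_a, gene_b, screen)
  n <- length(ds$labels)
  set.seed(config$seed)
  perms <- replicate(config$n_perm, sample.int(n), simplify = FALSE)
  null <- vapply(perms, function(pm) {
    ds2 <- ds
    ds2$labels <- setNames(ds$labels[pm], names(ds$labels))
    pair_mae_cv(ds2, gene_a, gene_b, screen)
  }, numeric(1))
  list(p_value = (1 + sum(null <= observed)) / (config$n_perm + 1),
       observed = observed, null = null)
}

#' Randomization test for gene-set overlap
#'
#' Tests whether two gene sets drawn from a shared universe overlap more
#' than expected by chance: the null redraws random sets of the observed
#' sizes from the universe and the one-sided (enrichment) p-value is
#' \eqn{(1 + \#\{null \ge obs\}) / (n_{perm}+1)}.
#'
#' @param set_a,set_b character vectors of genes, subsets of `universe`.
#' @param universe the shared gene universe.
#' @param config a [resample_config()].
#' @param randomize which set(s) to redraw: both (default), or only one.
#' @return list with `p_value`, `observed`, `null`.
#' @export
overlap_randomization_test <- function(set_a, set_b, universe, config,
                                       randomize = c("both", "a", "b")) {
  randomize <- match.arg(randomize)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must lie within the shared universe")
  observed <- length(intersect(set_a, set_b))
  set.seed(config$seed)
  null <- vapply(seq_len(config$n_perm), function(i) {
    a <- if (randomize %in% c("both", "a"))
      sample(universe, length(set_a)) else set_a
    b <- if (randomize %in% c("both", "b"))
      sample(universe, length(set_b)) else set_b
    length(intersect(a, b))
  }, numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (config$n_perm + 1),
       observed = observed, null = null)
}
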