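# Synthetic expression data with planted monotone gene pairs.
#
# Each planted pair carries a latent score z drawn, conditionally on the
# sample's class, from the class's band of the standard normal (bands cut at
# the cumulative class-weight quantiles). The two expression values split z
# along the anti-diagonal, x1 = s1*(z/2 + e), x2 = s2*(z/2 - e), so the
# oriented score s1*x1 + s2*x2 equals z exactly: the pre-flip label is an
# exactly monotone function of the pair's joint expression and the
# noiseless planted pair achieves full-data MAE 0 by construction. Label
# noise enters only through flip_rate. Non-planted genes are standard
# normal noise, label-independent. Every random component draws from its
# own seeded sub-stream, so e.g. changing n_genes leaves the planted
# columns identical.

#' Synthetic dataset configuration
#'
#' Defaults encode the calibration scenario used throughout the test suite:
#' 150 samples, 3 balanced classes, 50 genes, one planted pair, 10% label
#' flips.
#'
#' @param n_samples,n_genes dimensions (n_genes counts planted + noise).
#' @param p class count.
#' @param n_planted_pairs number of planted monotone pairs.
#' @param flip_rate probability a label is replaced by a uniform random
#'   class.
#' @param orientations list of length-2 sign vectors, one per planted pair
#'   (default cycles through the four orientations).
#' @param class_weights sampling proportions, worst to best (must sum to 1).
#' @param jitter standard deviation of the score-preserving expression
#'   jitter.
#' @param seed master seed; sub-streams are derived deterministically.
#' @export
synth_config <- function(n_samples = 150L, n_genes = 50L, p = 3L,
                         n_planted_pairs = 1L, flip_rate = 0.1,
                         orientations = NULL,
                         class_weights = rep(1 / p, p),
                         jitter = 0.5, seed = 1L) {
  if (n_genes < 2L * n_planted_pairs)
    stop("n_genes must be at least 2 * n_planted_pairs")
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must lie in [0, 1]")
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")
  if (length(class_weights) != p) stop("one weight per class is required")
  base <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  orientations <- orientations %||%
    base[((seq_len(max(n_planted_pairs, 1L)) - 1L) %% 4L) + 1L]
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), p = as.integer(p),
                 n_planted_pairs = as.integer(n_planted_pairs),
                 flip_rate = flip_rate, orientations = orientations,
                 class_weights = class_weights, jitter = jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Deterministic sub-stream seed derivation, kept below 2^31.
.sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic ordinal expression dataset
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (an [ordinal_dataset()]) and `ground_truth`
#'   (data frame gene_a, gene_b, s1, s2 of the planted pairs).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  p <- config$p
  cw <- cumsum(config$class_weights)

  labels0 <- .with_seed(.sub_seed(config$seed, 1L),
                        sample.int(p, n, replace = TRUE,
                                   prob = config$class_weights) - 1L)

  n_noise <- config$n_genes - 2L * config$n_planted_pairs
  gt <- data.frame(gene_a = character(0), gene_b = character(0),
                   s1 = numeric(0), s2 = numeric(0),
                   stringsAsFactors = FALSE)
  cols <- list()
  lo <- c(0, cw[-p])
  for (j in seq_len(config$n_planted_pairs)) {
    s <- config$orientations[[j]]
    vals <- .with_seed(.sub_seed(config$seed, 100L + j), {
      u <- runif(n, min = lo[labels0 + 1L], max = cw[labels0 + 1L])
      z <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
      e <- rnorm(n, sd = config$jitter)
      list(x1 = s[1L] * (z / 2 + e), x2 = s[2L] * (z / 2 - e))
    })
    ga <- sprintf("PG%02dA", j)
    gb <- sprintf("PG%02dB", j)
    cols[[ga]] <- vals$x1
    cols[[gb]] <- vals$x2
    key <- sort(c(ga, gb))
    gt <- rbind(gt, data.frame(gene_a = key[1L], gene_b = key[2L],
                               s1 = s[1L], s2 = s[2L],
                               stringsAsFactors = FALSE))
  }
  if (n_noise > 0L) {
    noise <- .with_seed(.sub_seed(config$seed, 3L),
                        matrix(rnorm(n_noise * n), nrow = n_noise))
    for (g in seq_len(n_noise)) cols[[sprintf("NG%04d", g)]] <- noise[g, ]
  }

  labels <- .with_seed(.sub_seed(config$seed, 2L), {
    flip <- runif(n) < config$flip_rate
    new <- sample.int(p, n, replace = TRUE) - 1L
    ifelse(flip, new, labels0)
  })
  # flips may empty a class in tiny datasets; fall back to pre-flip labels
  if (length(unique(labels)) < p) labels <- labels0

  values <- do.call(rbind, cols)
  rownames(values) <- names(cols)
  colnames(values) <- sprintf("S%04d", seq_len(n))
  ds <- ordinal_dataset(values, labels,
                        class_names = paste0("class_", seq_len(p) - 1L))
  list(dataset = ds, ground_truth = gt)
}

#' Write a synthetic dataset and its ground truth to a directory
#'
#' Produces `expression.tsv`, `labels.tsv` and `ground_truth.tsv`.
#'
#' @param sim result of [synth_generate()].
#' @param dir output directory (created if needed).
#' @export
synth_write <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(sim$dataset, file.path(dir, "expression.tsv"),
                file.path(dir, "labels.tsv"))
  gt <- sim$ground_truth
  con <- file(file.path(dir, "ground_truth.tsv"), open = "wb")
  writeLines("gene_a\tgene_b\ts1\ts2", con)
  if (nrow(gt))
    writeLines(paste(gt$gene_a, gt$gene_b, gt$s1, gt$s2, sep = "\t"), con)
  close(con)
  invisible(dir)
}
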