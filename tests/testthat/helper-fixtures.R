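# Shared fixtures and independent reimplementations used as test oracles.

# Random small instance for oracle-equivalence checks.
random_instance <- function(n_max = 10L, p_max = 3L) {
  n <- sample(2:n_max, 1L)
  p <- sample(2:p_max, 1L)
  list(x1 = sample(1:5, n, replace = TRUE),
       x2 = sample(1:5, n, replace = TRUE),
       y = sample(0:(p - 1L), n, replace = TRUE),
       w = sample(1:2, n, replace = TRUE),
       p = p)
}

# Small handmade ordinal dataset: g genes x n samples, labels cycling.
tiny_dataset <- function(g = 4L, n = 12L, p = 3L, seed = 1L) {
  set.seed(seed)
  v <- matrix(rnorm(g * n), nrow = g,
              dimnames = list(paste0("G", seq_len(g)),
                              paste0("S", seq_len(n))))
  ordinal_dataset(v, rep_len(0:(p - 1L), n))
}

table8_cm <- function() {
  matrix(c(41L, 51L, 13L,
           20L, 66L, 19L,
           7L, 54L, 44L),
         nrow = 3L, byrow = TRUE,
         dimnames = list(true = 0:2, pred = 0:2))
}

# Independent majority-vote-with-worst-bias: explicit arg-min over the
# tied-for-max labels.
brute_vote <- function(votes, p) {
  counts <- vapply(0:(p - 1L), function(l) sum(votes == l), integer(1))
  tied <- which(counts == max(counts)) - 1L
  min(tied)
}

# Independent hand-rolled cross-validated MAE over explicit folds.
brute_mae_cv <- function(ds, gene_a, gene_b, fold) {
  tot <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- staircase_fit(ds$values[gene_a, tr], ds$values[gene_b, tr],
                       ds$labels[tr], p = ds$p)
    pred <- predict(m, ds$values[gene_a, !tr], ds$values[gene_b, !tr])
    tot <- tot + sum(abs(pred - ds$labels[!tr]))
  }
  tot / length(ds$labels)
}

# Exhaustive all-pairs CV screen: the unpruned reference for
# preselect_top_pairs. Returns the same columns / selection rule.
brute_screen <- function(ds, config) {
  genes <- rownames(ds$values)
  pk <- combn(sort(genes), 2L)
  res <- data.frame(gene_a = pk[1L, ], gene_b = pk[2L, ],
                    stringsAsFactors = FALSE)
  res$mae_full <- NA_real_
  res$mae_cv <- NA_real_
  for (i in seq_len(nrow(res))) {
    res$mae_full[i] <- pair_mae_full(ds, res$gene_a[i], res$gene_b[i])$mae
    res$mae_cv[i] <- pair_mae_cv(ds, res$gene_a[i], res$gene_b[i], config)
  }
  o <- order(res$mae_cv, res$gene_a, res$gene_b)
  used <- character(0)
  theta <- Inf
  taken <- 0L
  for (i in o) {
    g <- c(res$gene_a[i], res$gene_b[i])
    if (!any(g %in% used)) {
      used <- c(used, g)
      taken <- taken + 1L
      if (taken == config$min_disjoint) {
        theta <- res$mae_cv[i]
        break
      }
    }
  }
  res$selected <- res$mae_cv <= theta
  attr(res, "theta") <- theta
  res
}

pair_key <- function(df) sort(paste(df$gene_a, df$gene_b, sep = "|"))
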