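# Disjoint-pair voting ensembles: m gene-disjoint staircase classifiers
# combined by majority vote, ties biased toward the worst outcome (label 0).

#' Majority vote with ordinal worst-outcome tie bias
#'
#' Returns the label with the highest vote count; among tied counts the
#' SMALLEST label wins (0 = worst clinical outcome).
#'
#' @param votes integer vector of cast labels.
#' @param p class count.
#' @export
vote_majority_worst <- function(votes, p) {
  counts <- tabulate(votes + 1L, p)
  which.max(counts) - 1L # which.max returns the first (smallest) maximum
}

#' Build a disjoint-pair voting ensemble
#'
#' Selects the `m` best gene-disjoint pairs from a screen result (greedy by
#' ascending CV MAE) and refits each on the full supplied data with the best
#' orientation.
#'
#' @param ds an [ordinal_dataset()] (typically the training data).
#' @param top_pairs pair-score table from [screen_pairs()] (or any table
#'   with `gene_a`, `gene_b`, `mae_cv`).
#' @param m ensemble size.
#' @return object of class `pair_ensemble`: `p`, `members` (each a list
#'   with `gene_a`, `gene_b`, `model`).
#' @export
build_ensemble <- function(ds, top_pairs, m) {
  sel <- select_disjoint(top_pairs, m)
  if (nrow(sel) < m)
    stop(sprintf("only %d disjoint pairs available, %d requested",
                 nrow(sel), m))
  members <- lapply(seq_len(nrow(sel)), function(i) {
    xy <- .pair_xy(ds, sel$gene_a[i], sel$gene_b[i])
    list(gene_a = sel$gene_a[i], gene_b = sel$gene_b[i],
         model = staircase_fit(xy$x1, xy$x2, ds$labels, p = ds$p))
  })
  genes <- unlist(lapply(members, function(mb) c(mb$gene_a, mb$gene_b)))
  stopifnot(!anyDuplicated(genes))
  structure(list(p = ds$p, members = members), class = "pair_ensemble")
}

#' @export
print.pair_ensemble <- function(x, ...) {
  cat(sprintf("Gene-pair voting ensemble: %d members, %d classes\n",
              length(x$members), x$p))
  for (mb in x$members)
    cat(sprintf("  %s / %s (orientation %+d,%+d)\n", mb$gene_a, mb$gene_b,
                mb$model$orientation[1L], mb$model$orientation[2L]))
  invisible(x)
}

#' Predict with a pair ensemble
#'
#' Each member votes the class of its own gene pair; the ensemble returns
#' the majority label, ties biased toward the worst outcome (smallest
#' label).
#'
#' @param object a `pair_ensemble`.
#' @param newdata genes x samples numeric matrix with row names covering all
#'   member genes, a named numeric vector (single sample), or an
#'   [ordinal_dataset()].
#' @param ... unused.
#' @return integer labels, one per sample.
#' @export
predict.pair_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "ordinal_dataset")) newdata <- newdata$values
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "sample"))
  need <- unique(unlist(lapply(object$members,
                               function(mb) c(mb$gene_a, mb$gene_b))))
  miss <- setdiff(need, rownames(newdata))
  if (length(miss))
    stop("missing expression value(s) for gene(s): ",
         paste(miss, collapse = ", "))
  votes <- vapply(object$members, function(mb) {
    predict(mb$model, newdata[mb$gene_a, ], newdata[mb$gene_b, ])
  }, integer(ncol(newdata)))
  votes <- matrix(votes, nrow = ncol(newdata))
  apply(votes, 1L, vote_majority_worst, p = object$p)
}

#' Choose the ensemble size by cross-validated MAE
#'
#' For each candidate size the member pairs (fixed identities from the
#' greedy disjoint ranking of `top_pairs`) are refit within each stratified
#' CV training fold and vote on the held-out samples; the size with minimal
#' CV MAE is returned, ties resolved toward the smallest size. Candidate
#' sizes exceeding the number of achievable disjoint pairs are dropped.
#'
#' @inheritParams build_ensemble
#' @param sizes candidate ensemble sizes (odd by default to reduce vote
#'   ties; even sizes are permitted).
#' @param config a [screen_config()] supplying folds and seed.
#' @return the chosen size (integer); the per-size CV MAE table is attached
#'   as attribute `cv_mae`.
#' @export
choose_ensemble_size <- function(ds, top_pairs, sizes = c(1L, 3L, 5L, 7L, 9L),
                                 config = screen_config()) {
  avail <- nrow(select_disjoint(top_pairs, .Machine$integer.max))
  sizes <- sort(unique(as.integer(sizes)))
  sizes <- sizes[sizes >= 1L & sizes <= avail]
  if (!length(sizes)) stop("no candidate ensemble size is achievable")
  fold <- .make_folds(ds$labels, colnames(ds$values), config$n_folds,
                      config$seed)
  sel <- select_disjoint(top_pairs, max(sizes))
  err <- setNames(numeric(length(sizes)), sizes)
  for (f in seq_len(config$n_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    train <- dataset_subset(ds, tr)
    fits <- lapply(seq_len(nrow(sel)), function(i) {
      xy <- .pair_xy(train, sel$gene_a[i], sel$gene_b[i])
      staircase_fit(xy$x1, xy$x2, train$labels, p = ds$p)
    })
    votes <- vapply(seq_len(nrow(sel)), function(i) {
      predict(fits[[i]], ds$values[sel$gene_a[i], te],
              ds$values[sel$gene_b[i], te])
    }, integer(length(te)))
    votes <- matrix(votes, nrow = length(te))
    for (si in seq_along(sizes)) {
      pred <- apply(votes[, seq_len(sizes[si]), drop = FALSE], 1L,
                    vote_majority_worst, p = ds$p)
      err[si] <- err[si] + sum(abs(pred - ds$labels[te]))
    }
  }
  cv_mae <- err / length(ds$labels)
  structure(sizes[which.min(cv_mae)], cv_mae = cv_mae)
}

#' Serialize / deserialize a pair ensemble as JSON
#'
#' @param ensemble a `pair_ensemble`.
#' @param txt JSON text produced by `ensemble_to_json`.
#' @export
ensemble_to_json <- function(ensemble) {
  jsonlite::toJSON(list(
    p = ensemble$p,
    members = lapply(ensemble$members, function(mb) list(
      gene_a = mb$gene_a, gene_b = mb$gene_b,
      model = jsonlite::fromJSON(staircase_to_json(mb$model),
                                 simplifyVector = FALSE)))
  ), auto_unbox = TRUE, digits = I(17))
}

#' @rdname ensemble_to_json
#' @export
ensemble_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  members <- lapply(obj$members, function(mb) list(
    gene_a = mb$gene_a, gene_b = mb$gene_b,
    model = staircase_from_json(jsonlite::toJSON(mb$model, auto_unbox = TRUE,
                                                 digits = I(17)))))
  structure(list(p = as.integer(obj$p), members = members),
            class = "pair_ensemble")
}
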