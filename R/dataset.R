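# Ordinal expression datasets: container, TSV/CSV IO, MAD filtering,
# stratified splitting. Expression is assumed already normalized; genes are
# rows, samples are columns (transcriptomics convention).

#' Construct an ordinal expression dataset
#'
#' Bundles a genes x samples expression matrix with per-sample ordinal
#' labels. Labels are integers `0..p-1` where 0 is the WORST clinical
#' outcome; `class_names` lists the class names in worst-to-best order.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names and no missing values.
#' @param labels integer vector of per-sample classes (`0..p-1`), in column
#'   order of `values` (or named by sample).
#' @param class_names character vector of class names, worst to best.
#' @return object of class `ordinal_dataset` with elements `values`,
#'   `labels` (named), `class_names`, `p`.
#' @export
ordinal_dataset <- function(values, labels, class_names = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (any(!is.finite(values))) stop("values must be finite (no missing data)")
  labels <- as.integer(labels)
  if (length(labels) != ncol(values))
    stop("one label per sample is required")
  class_names <- class_names %||% paste0("class_", seq_len(max(labels) + 1L) - 1L)
  p <- length(class_names)
  if (any(is.na(labels)) || any(labels < 0L | labels >= p))
    stop("labels must lie in 0..p-1")
  missing_cls <- setdiff(seq_len(p) - 1L, unique(labels))
  if (length(missing_cls))
    stop("every class must be nonempty; empty: ",
         paste(class_names[missing_cls + 1L], collapse = ", "))
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels,
                 class_names = class_names, p = p),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("Ordinal expression dataset: %d genes x %d samples, %d classes (%s; worst first)\n",
              nrow(x$values), ncol(x$values), x$p,
              paste(x$class_names, collapse = " < ")))
  cat("Class sizes:", paste(tabulate(x$labels + 1L, x$p), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ordinal dataset by samples
#'
#' Duplicate indices are permitted (bootstrap resampling); duplicated sample
#' identifiers are made unique.
#'
#' @param ds an `ordinal_dataset`.
#' @param idx sample indices or names.
#' @export
dataset_subset <- function(ds, idx) {
  v <- ds$values[, idx, drop = FALSE]
  lab <- ds$labels[idx]
  colnames(v) <- make.unique(colnames(v))
  ordinal_dataset(v, lab, ds$class_names)
}

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix and ordinal label file
#'
#' The expression file is TSV (or CSV by extension): first column gene id,
#' header row of sample ids. The label file is TSV with a directive line
#' `#order: worst,...,best` declaring class names worst-to-best, then a
#' header `sample_id<TAB>class_name` and one row per sample. Samples are
#' aligned by id (intersection); samples present on only one side are
#' dropped with a message.
#'
#' @param expr_path path to the expression matrix.
#' @param labels_path path to the label file.
#' @param transpose set `TRUE` if the expression file has samples as rows.
#' @return an [ordinal_dataset()].
#' @export
read_dataset <- function(expr_path, labels_path, transpose = FALSE) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)
  tab <- read.delim(expr_path, sep = .sep_for(expr_path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  raw <- tab[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(ids, colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(col) & !is.na(raw[[j]]))
    if (length(bad) || anyNA(raw[[j]]))
      stop(sprintf("non-numeric or missing cell in '%s' at row %d, column '%s'",
                   expr_path, c(bad, which(is.na(raw[[j]])))[1L],
                   colnames(raw)[j]))
    mat[, j] <- col
  }
  if (transpose) mat <- t(mat)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene identifiers in ", expr_path)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers in ", expr_path)

  lines <- readLines(labels_path)
  dir_i <- grep("^#order:", lines)
  if (length(dir_i) != 1L)
    stop("label file must contain exactly one '#order:' directive line")
  order_names <- trimws(strsplit(sub("^#order:", "", lines[dir_i]), ",")[[1L]])
  body <- lines[-dir_i]
  lab_tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class_name") %in% colnames(lab_tab)))
    stop("label file must have columns sample_id and class_name")
  if (anyDuplicated(lab_tab$sample_id))
    stop("duplicate sample identifiers in ", labels_path)
  unknown <- setdiff(unique(lab_tab$class_name), order_names)
  if (length(unknown))
    stop("unknown class name(s) in label file: ", paste(unknown, collapse = ", "))

  common <- intersect(colnames(mat), lab_tab$sample_id)
  n_drop_expr <- ncol(mat) - length(common)
  n_drop_lab <- nrow(lab_tab) - length(common)
  if (n_drop_expr || n_drop_lab)
    message(sprintf("read_dataset: dropped %d unlabeled expression sample(s) and %d label row(s) without expression",
                    n_drop_expr, n_drop_lab))
  if (!length(common)) stop("no samples shared between expression and labels")
  mat <- mat[, common, drop = FALSE]
  lab <- match(lab_tab$class_name[match(common, lab_tab$sample_id)],
               order_names) - 1L
  ordinal_dataset(mat, lab, order_names)
}

#' Write an ordinal dataset to TSV files
#'
#' Inverse of [read_dataset()]. Values are written at 6 significant digits
#' (the documented round-trip precision); reading the result and writing it
#' again reproduces the files byte-identically.
#'
#' @inheritParams read_dataset
#' @param ds an `ordinal_dataset`.
#' @export
write_dataset <- function(ds, expr_path, labels_path) {
  v <- signif(ds$values, 6L)
  out <- cbind(gene = rownames(v),
               as.data.frame(matrix(vapply(v, function(x) as.character(x),
                                           character(1)),
                                    nrow = nrow(v),
                                    dimnames = dimnames(v)),
                             check.names = FALSE))
  con <- file(expr_path, open = "wb")
  writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  close(con)
  con <- file(labels_path, open = "wb")
  writeLines(paste0("#order: ", paste(ds$class_names, collapse = ",")), con)
  writeLines("sample_id\tclass_name", con)
  writeLines(paste(colnames(ds$values), ds$class_names[ds$labels + 1L],
                   sep = "\t"), con)
  close(con)
  invisible(c(expr_path, labels_path))
}

#' Filter genes by median absolute deviation
#'
#' For each gene g, MAD(g) = median over samples of |x - median(x)| (no
#' consistency constant). Keeps either the `keep_top` genes with largest MAD
#' (ties broken by gene id) or the genes with MAD >= `min_mad`. Exactly one
#' criterion must be given; the sample axis is untouched and gene order is
#' preserved.
#'
#' @param ds an `ordinal_dataset`.
#' @param keep_top number of genes to keep.
#' @param min_mad MAD threshold.
#' @export
mad_filter <- function(ds, keep_top = NULL, min_mad = NULL) {
  if (is.null(keep_top) == is.null(min_mad))
    stop("give exactly one of keep_top or min_mad")
  mads <- apply(ds$values, 1L, function(x) median(abs(x - median(x))))
  if (!is.null(keep_top)) {
    if (keep_top > nrow(ds$values)) {
      warning("keep_top exceeds gene count; keeping all genes")
      keep_top <- nrow(ds$values)
    }
    o <- order(-mads, rownames(ds$values))
    keep <- sort(o[seq_len(keep_top)])
  } else {
    keep <- which(mads >= min_mad)
    if (!length(keep)) stop("no gene passes the MAD threshold")
  }
  ordinal_dataset(ds$values[keep, , drop = FALSE], ds$labels, ds$class_names)
}

#' Stratified train/test split
#'
#' Splits samples into disjoint train and test sets preserving class
#' proportions: per class the train count is the nearest integer to
#' `train_frac * n_class` (halves away from zero), membership chosen by a
#' seeded shuffle within class.
#'
#' @param ds an `ordinal_dataset`.
#' @param train_frac training fraction, strictly between 0 and 1.
#' @param seed integer seed for the within-class shuffles.
#' @return list with `train` and `test` datasets.
#' @export
stratified_split <- function(ds, train_frac = 0.8, seed = 1L) {
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be strictly between 0 and 1")
  sizes <- tabulate(ds$labels + 1L, ds$p)
  if (any(sizes < 2L))
    stop("every class needs at least 2 samples to split")
  set.seed(seed)
  tr <- integer(0)
  ids <- colnames(ds$values)
  for (c in seq_len(ds$p) - 1L) {
    idx <- which(ds$labels == c)
    idx <- idx[order(ids[idx])]
    n_tr <- floor(train_frac * length(idx) + 0.5)
    perm <- sample(idx)
    tr <- c(tr, perm[seq_len(n_tr)])
  }
  te <- setdiff(seq_along(ids), tr)
  list(train = dataset_subset(ds, sort(tr)),
       test = dataset_subset(ds, sort(te)))
}
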