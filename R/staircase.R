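# Exact L1-optimal monotone staircase classifiers on two real features.
#
# Geometry conventions (all in ORIENTED coordinates, i.e. after multiplying
# each feature by its sign):
#   * an upper-set boundary is a corner matrix (k x 2); a point belongs to
#     the upper set iff it dominates (>= in both coordinates) some corner;
#   * corners form an antichain (the minimal elements of the upper region);
#   * the whole plane is the single corner (-Inf, -Inf); the empty set is a
#     0-row matrix.

.whole_plane <- function() matrix(c(-Inf, -Inf), nrow = 1L)
.empty_set <- function() matrix(numeric(0), ncol = 2L)

# Minimal elements (Pareto minima) of a 2-column point matrix.
.pareto_min <- function(pts) {
  if (nrow(pts) == 0L) return(.empty_set())
  o <- order(pts[, 1L], pts[, 2L])
  keep <- logical(nrow(pts))
  best <- Inf
  for (i in o) {
    if (pts[i, 2L] < best) {
      keep[i] <- TRUE
      best <- pts[i, 2L]
    }
  }
  m <- pts[keep, , drop = FALSE]
  m[order(m[, 1L]), , drop = FALSE]
}

# Membership of query points in the upper set described by `corners`.
.in_upper <- function(corners, z1, z2) {
  res <- rep(FALSE, length(z1))
  if (nrow(corners) == 0L) return(res)
  for (i in seq_len(nrow(corners)))
    res <- res | (z1 >= corners[i, 1L] & z2 >= corners[i, 2L])
  res
}

# Union of two upper sets: Pareto minima of the pooled corners.
.union_boundaries <- function(a, b) .pareto_min(rbind(a, b))

.check_xy <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop("x1 and x2 must have equal length")
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop("x1 and x2 must be finite")
}

#' Fit the L1-optimal binary monotone upper set
#'
#' Finds, among all upper sets closed under coordinate-wise increase (the
#' predicted-1 region of a classifier nondecreasing in both features), the
#' one minimizing the weighted misclassification
#' \eqn{\sum_i w_i |1[i \in U] - y_i|}. When several upper sets achieve the
#' minimum, the smallest one (fewest points assigned 1) is returned; its
#' corners sit at the coordinates of the points assigned to the upper class.
#' If every point is assigned to the upper class the boundary degenerates to
#' the whole plane (or to a copy of `region` when one is supplied).
#'
#' @param x1,x2 numeric feature vectors (oriented so that the label is
#'   nondecreasing in both).
#' @param y binary integer labels (0/1).
#' @param weights optional non-negative weights (default 1).
#' @param region optional corner matrix; the fitted upper set must lie inside
#'   it and all points are required to be inside it.
#' @return an object of class `upper_set_fit`: list with `corners` (antichain
#'   corner matrix), `error` (achieved weighted L1 error) and `high` (logical
#'   per-point assignment to the upper class).
#' @examples
#' f <- fit_binary_upper_set(c(1, 2), c(1, 2), c(0L, 1L))
#' f$error # 0
#' @export
fit_binary_upper_set <- function(x1, x2, y, weights = NULL, region = NULL) {
  .check_xy(x1, x2)
  n <- length(x1)
  if (n == 0L) stop("at least one point is required")
  w <- weights %||% rep(1, n)
  if (length(w) != n) stop("weights length mismatch")
  if (any(w < 0)) stop("weights must be non-negative")
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 0L | y > 1L)) stop("y must be binary (0/1)")
  if (!is.null(region) && !all(.in_upper(region, x1, x2)))
    stop("all points must lie inside the given region")
  sol <- .dp_binary_upper_set(as.numeric(x1), as.numeric(x2), y, as.numeric(w))
  high <- sol$high
  corners <- if (!any(high)) {
    .empty_set()
  } else if (all(high)) {
    if (is.null(region)) .whole_plane() else region
  } else {
    .pareto_min(cbind(x1[high], x2[high]))
  }
  structure(list(corners = corners, error = sol$error, high = high),
            class = "upper_set_fit")
}

#' Fit a multi-class monotone staircase classifier
#'
#' Fits, for `p` ordered classes (labels `0..p-1`, 0 = worst outcome), the
#' set of p-1 nested upper-set boundaries minimizing the total L1 error
#' \eqn{\sum_i w_i |f(x_i) - y_i|} over ALL decision rules monotone
#' nondecreasing in the oriented features. The recursion splits the class
#' range at its midpoint (integer part of p/2 at the top level), solves the
#' binary threshold problem, and recurses on each side under the parent
#' boundary, guaranteeing nested boundaries.
#'
#' When `orientation` is `NULL` all four sign combinations are fitted and
#' the one with minimal training error is kept, ties broken in the order
#' (+,+), (+,-), (-,+), (-,-).
#'
#' @param x1,x2 numeric feature vectors (raw, un-oriented).
#' @param y integer class labels in `0..p-1`.
#' @param p number of ordered classes (default `max(y) + 1`).
#' @param orientation length-2 vector of signs in \{-1, +1\}, or `NULL` to
#'   select the best orientation.
#' @param weights optional non-negative weights.
#' @return object of class `staircase`: `p`, `orientation`, `boundaries`
#'   (list of p-1 corner matrices in oriented coordinates, nested by
#'   inclusion) and `training_error`.
#' @examples
#' m <- staircase_fit(1:3, 1:3, 0:2, p = 3, orientation = c(1, 1))
#' m$training_error # 0
#' predict(m, 2.5, 2.5) # 1
#' @export
staircase_fit <- function(x1, x2, y, p = NULL, orientation = NULL,
                          weights = NULL) {
  .check_xy(x1, x2)
  n <- length(x1)
  if (n == 0L) stop("at least one point is required")
  y <- as.integer(y)
  p <- as.integer(p %||% (max(y) + 1L))
  if (p < 2L) stop("p must be at least 2")
  if (any(is.na(y)) || any(y < 0L | y >= p))
    stop("labels must lie in 0..p-1")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stop("weights must be non-negative")

  if (!is.null(orientation)) {
    if (length(orientation) != 2L || !all(orientation %in% c(-1, 1)))
      stop("orientation must be two signs in {-1, +1}")
    cand <- matrix(as.integer(orientation), nrow = 1L)
  } else {
    # fixed tie-break order (+,+), (+,-), (-,+), (-,-)
    cand <- rbind(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  }
  sol <- .dp_staircase_multi(as.numeric(x1), as.numeric(x2), y,
                             as.numeric(w), p, cand[, 1L], cand[, 2L])
  structure(list(p = p, orientation = as.numeric(c(sol$s1, sol$s2)),
                 boundaries = sol$boundaries,
                 training_error = sol$training_error),
            class = "staircase")
}

#' @rdname staircase_fit
#' @export
fit_best_orientation <- function(x1, x2, y, p = NULL, weights = NULL) {
  staircase_fit(x1, x2, y, p = p, orientation = NULL, weights = weights)
}

.predict_boundaries <- function(boundaries, z1, z2) {
  lab <- rep(0L, length(z1))
  for (bd in boundaries) lab <- lab + as.integer(.in_upper(bd, z1, z2))
  lab
}

#' Predict ordinal classes from a fitted staircase model
#'
#' Returns, for each query point, the largest threshold t whose upper set
#' contains the (oriented) point, or 0 if none does. Points exactly on a
#' boundary corner belong to the upper (higher-class) region.
#'
#' @param object a `staircase` model.
#' @param x1,x2 numeric query coordinates (raw, un-oriented).
#' @param ... unused.
#' @return integer class labels in `0..p-1`.
#' @export
predict.staircase <- function(object, x1, x2, ...) {
  .check_xy(x1, x2)
  .predict_boundaries(object$boundaries,
                      object$orientation[1L] * x1,
                      object$orientation[2L] * x2)
}

#' @export
print.staircase <- function(x, ...) {
  cat(sprintf(
    "Monotone staircase classifier: %d classes, orientation (%+d,%+d), training L1 error %.4g\n",
    x$p, x$orientation[1L], x$orientation[2L], x$training_error))
  invisible(x)
}

#' Exhaustive L1 oracle for monotone classification
#'
#' Exact minimum of \eqn{\sum_i w_i |f(x_i) - y_i|} over ALL labelings of
#' the points into `0..p-1` respecting non-strict monotonicity (a point
#' dominated componentwise must not receive a larger label), found by
#' exhaustive depth-first search with cost pruning. Intended as an
#' independent test oracle for small instances (n <= 12 recommended).
#'
#' @inheritParams staircase_fit
#' @return the minimal total weighted L1 error (a number).
#' @export
enumerate_monotone_oracle <- function(x1, x2, y, p = NULL, weights = NULL) {
  .check_xy(x1, x2)
  n <- length(x1)
  if (n == 0L) stop("at least one point is required")
  y <- as.integer(y)
  p <- as.integer(p %||% (max(y) + 1L))
  if (any(y < 0L | y >= p)) stop("labels must lie in 0..p-1")
  w <- weights %||% rep(1, n)
  o <- order(x1, x2)
  xs1 <- x1[o]; xs2 <- x2[o]; ys <- y[o]; ws <- w[o]
  best <- Inf
  f <- integer(n)
  rec <- function(i, cost) {
    if (cost >= best) return(invisible())
    if (i > n) {
      best <<- cost
      return(invisible())
    }
    lo <- 0L; hi <- p - 1L
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (xs1[j] <= xs1[i] && xs2[j] <= xs2[i] && f[j] > lo) lo <- f[j]
      if (xs1[i] <= xs1[j] && xs2[i] <= xs2[j] && f[j] < hi) hi <- f[j]
    }
    if (lo > hi) return(invisible())
    for (lab in lo:hi) {
      f[i] <<- lab
      rec(i + 1L, cost + ws[i] * abs(lab - ys[i]))
    }
    invisible()
  }
  rec(1L, 0)
  best
}

# --- JSON serialization ----------------------------------------------------

.corners_to_list <- function(m) {
  lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    lapply(unname(v), function(x) if (is.infinite(x)) "-Inf" else x)
  })
}

.corners_from_list <- function(l) {
  if (length(l) == 0L) return(.empty_set())
  do.call(rbind, lapply(l, function(cc) {
    vapply(cc, function(x) if (identical(x, "-Inf")) -Inf else as.numeric(x),
           numeric(1))
  }))
}

#' Serialize / deserialize a staircase model as JSON
#'
#' The JSON document has fields `p`, `orientation` (two signs), `boundaries`
#' (a list of corner lists, oriented coordinates; `-Inf` encoded as the
#' string `"-Inf"`) and `training_error`.
#'
#' @param model a `staircase` model.
#' @param txt JSON text produced by [staircase_to_json()].
#' @return `staircase_to_json`: a JSON string; `staircase_from_json`: a
#'   `staircase` model.
#' @export
staircase_to_json <- function(model) {
  stopifnot(inherits(model, "staircase"))
  jsonlite::toJSON(list(
    p = model$p,
    orientation = as.numeric(model$orientation),
    boundaries = lapply(model$boundaries, .corners_to_list),
    training_error = model$training_error
  ), auto_unbox = TRUE, digits = I(17))
}

#' @rdname staircase_to_json
#' @export
staircase_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  structure(list(
    p = as.integer(obj$p),
    orientation = as.numeric(unlist(obj$orientation)),
    boundaries = lapply(obj$boundaries, .corners_from_list),
    training_error = as.numeric(obj$training_error)
  ), class = "staircase")
}
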