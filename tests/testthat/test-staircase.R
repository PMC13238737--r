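# Core monotone staircase fitting: binary upper sets, multiclass recursion,
# orientation search, prediction geometry, serialization.

test_that("binary upper-set fit handles the canonical small cases", {
  # perfectly separable: upper set is the single point (2,2)
  f <- fit_binary_upper_set(c(1, 2), c(1, 2), c(0L, 1L))
  expect_equal(f$error, 0)
  expect_equal(f$corners, matrix(c(2, 2), nrow = 1))

  # single-class input: whole plane, represented by the corner (-Inf,-Inf)
  f1 <- fit_binary_upper_set(c(1, 2), c(1, 2), c(1L, 1L))
  expect_equal(f1$error, 0)
  expect_equal(f1$corners, matrix(c(-Inf, -Inf), nrow = 1))

  # two incomparable 1-points around an interior 0: the union of their
  # quadrants is a valid monotone upper set excluding the 0, so the optimum
  # is 0 (value frozen from the exhaustive oracle)
  expect_equal(enumerate_monotone_oracle(c(1, 2, 1.5), c(2, 1, 1.5),
                                         c(1L, 1L, 0L), p = 2), 0)
  f2 <- fit_binary_upper_set(c(1, 2, 1.5), c(2, 1, 1.5), c(1L, 1L, 0L))
  expect_equal(f2$error, 0)
  expect_false(ordpair:::.in_upper(f2$corners, 1.5, 1.5))

  # a 0-point genuinely dominating a 1-point forces one error
  f3 <- fit_binary_upper_set(c(1, 2), c(1, 2), c(1L, 0L))
  expect_equal(f3$error, 1)
  expect_equal(enumerate_monotone_oracle(c(1, 2), c(1, 2), c(1L, 0L), p = 2), 1)
})

test_that("binary fit validates its inputs", {
  expect_error(fit_binary_upper_set(numeric(0), numeric(0), integer(0)),
               "at least one point")
  expect_error(fit_binary_upper_set(1, 1, 1L, weights = -1), "non-negative")
  expect_error(fit_binary_upper_set(Inf, 1, 1L), "finite")
  expect_error(fit_binary_upper_set(c(1, 2), c(1, 2), c(0L, 1L),
                                    region = matrix(c(10, 10), nrow = 1)),
               "inside")
})

test_that("weights steer the binary optimum", {
  # one heavy misordered 0 vs two light 1s below it
  f <- fit_binary_upper_set(c(1, 2, 3), c(1, 2, 3), c(1L, 1L, 0L),
                            weights = c(1, 1, 5))
  expect_equal(f$error, 2) # cheaper to misclassify both 1s
  expect_false(any(f$high))
})

test_that("multiclass staircase fits chains exactly and reduces to binary at p=2", {
  m <- staircase_fit(1:3, 1:3, 0:2, p = 3, orientation = c(1, 1))
  expect_equal(m$training_error, 0)
  expect_length(m$boundaries, 2)
  expect_identical(predict(m, 1:3, 1:3), 0:2)

  set.seed(7)
  for (r in 1:20) {
    inst <- random_instance(p_max = 2L)
    m2 <- staircase_fit(inst$x1, inst$x2, inst$y, p = 2,
                        orientation = c(1, 1), weights = inst$w)
    f2 <- fit_binary_upper_set(inst$x1, inst$x2, inst$y, weights = inst$w)
    expect_equal(m2$training_error, f2$error)
    expect_equal(m2$boundaries[[1]], f2$corners)
  }
})

test_that("multiclass training error matches the exhaustive oracle", {
  set.seed(11)
  for (r in 1:60) {
    inst <- random_instance()
    m <- staircase_fit(inst$x1, inst$x2, inst$y, p = inst$p,
                       orientation = c(1, 1), weights = inst$w)
    expect_equal(m$training_error,
                 enumerate_monotone_oracle(inst$x1, inst$x2, inst$y,
                                           p = inst$p, weights = inst$w))
  }
})

test_that("training error decomposes into per-threshold binary errors", {
  set.seed(13)
  for (r in 1:25) {
    n <- sample(5:20, 1)
    p <- sample(2:4, 1)
    x1 <- runif(n); x2 <- runif(n)
    y <- sample(0:(p - 1), n, replace = TRUE)
    m <- staircase_fit(x1, x2, y, p = p, orientation = c(1, 1))
    bin_sum <- sum(vapply(seq_len(p - 1), function(t) {
      fit_binary_upper_set(x1, x2, as.integer(y >= t))$error
    }, numeric(1)))
    expect_equal(m$training_error, bin_sum)
  }
})

test_that("prediction respects domination and training consistency", {
  set.seed(3)
  x1 <- runif(15); x2 <- runif(15)
  y <- findInterval(x1 + x2, c(0.7, 1.3))
  m <- staircase_fit(x1, x2, y, p = 3, orientation = c(1, 1))
  # dominating every training point -> top class; dominated by all -> 0
  expect_equal(predict(m, 10, 10), 2L)
  expect_equal(predict(m, -10, -10), 0L)
  if (m$training_error == 0)
    expect_identical(predict(m, x1, x2), as.integer(y))
  expect_error(predict(m, NA, 1), "finite")
})

test_that("orientation search finds the generating signs and is symmetric", {
  set.seed(5)
  x1 <- runif(30); x2 <- runif(30)
  y <- findInterval(x1 - x2, c(-0.3, 0.3)) # nondecreasing in x1, nonincreasing in x2
  m <- fit_best_orientation(x1, x2, y, p = 3)
  expect_equal(m$orientation, c(1, -1))
  expect_equal(m$training_error, 0)

  # label-reversal symmetry: y <- (p-1)-y with both signs flipped gives the
  # same training error
  for (r in 1:10) {
    inst <- random_instance()
    a <- fit_best_orientation(inst$x1, inst$x2, inst$y, p = inst$p,
                              weights = inst$w)
    b <- fit_best_orientation(inst$x1, inst$x2, (inst$p - 1L) - inst$y,
                              p = inst$p, weights = inst$w)
    expect_equal(a$training_error, b$training_error)
  }
})

test_that("best orientation equals the minimum of four oracle runs", {
  set.seed(17)
  for (r in 1:15) {
    inst <- random_instance(n_max = 8L)
    m <- fit_best_orientation(inst$x1, inst$x2, inst$y, p = inst$p,
                              weights = inst$w)
    oracle4 <- min(vapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                          function(s) {
                            enumerate_monotone_oracle(s[1] * inst$x1,
                                                      s[2] * inst$x2,
                                                      inst$y, p = inst$p,
                                                      weights = inst$w)
                          }, numeric(1)))
    expect_equal(m$training_error, oracle4)
  }
})

test_that("staircase fit validates labels and class count", {
  expect_error(staircase_fit(1:3, 1:3, c(0L, 1L, 3L), p = 3), "0..p-1")
  expect_error(staircase_fit(1:3, 1:3, rep(0L, 3), p = 1), "at least 2")
  expect_error(staircase_fit(1:2, 1:2, 0:1, orientation = c(2, 1)), "signs")
})

test_that("oracle base cases", {
  expect_equal(enumerate_monotone_oracle(1, 1, 2L, p = 3), 0) # n = 1
  expect_equal(enumerate_monotone_oracle(1:4, 1:4, 0:3, p = 4), 0) # chain
})

test_that("staircase JSON serialization round-trips, including -Inf corners", {
  set.seed(23)
  m <- staircase_fit(runif(20), runif(20), sample(0:2, 20, TRUE), p = 3)
  m2 <- staircase_from_json(staircase_to_json(m))
  expect_equal(m2$p, m$p)
  expect_equal(m2$orientation, m$orientation)
  expect_equal(m2$training_error, m$training_error)
  q1 <- runif(50, -2, 3); q2 <- runif(50, -2, 3)
  expect_identical(predict(m2, q1, q2), predict(m, q1, q2))

  m3 <- staircase_fit(c(1, 2), c(1, 2), c(1L, 1L), p = 2,
                      orientation = c(1, 1))
  m4 <- staircase_from_json(staircase_to_json(m3))
  expect_equal(m4$boundaries[[1]], matrix(c(-Inf, -Inf), nrow = 1))
})
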