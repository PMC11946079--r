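test_that("proportional normalization gives unit column sums", {
  expect_equal(unname(normalize_proportional(cbind(c(2, 2)))), cbind(c(0.5, 0.5)))
  expect_equal(unname(normalize_proportional(cbind(c(1, 3)))), cbind(c(0.25, 0.75)))
  X <- random_matrix(6, 4)
  expect_equal(unname(colSums(normalize_proportional(X))), rep(1, 4))
  Xz <- X; Xz[, 2] <- 0; colnames(Xz)[2] <- "SSC"
  expect_error(normalize_proportional(Xz), "SSC")
})

test_that("non-negative shift removes zeros and rejects non-positive deltas", {
  Y <- cbind(c(0, 0.4, 0.6))
  Z <- nonneg_shift(Y)
  expect_equal(Z[1, 1], 0.01)
  expect_true(all(Z > 0))
  expect_equal(unname(Z - Y), matrix(0.01, 3, 1))  # uniform offset only
  expect_error(nonneg_shift(Y, 0), "positive")
  expect_error(nonneg_shift(Y, -0.01), "positive")
})

test_that("entropy attains its closed-form values", {
  n <- 5
  expect_equal(unname(entropy(cbind(rep(1 / n, n)))), 1)
  expect_equal(unname(entropy(cbind(c(1, 0, 0, 0)))), 0)  # 0*ln0 = 0 convention
  # direct evaluation of -(1/ln 3) * sum(y ln y) for (0.5, 0.25, 0.25)
  y <- c(0.5, 0.25, 0.25)
  expect_equal(unname(entropy(cbind(y))), -sum(y * log(y)) / log(3))
  expect_equal(unname(entropy(cbind(y))), 0.9464, tolerance = 1e-4)
  expect_error(entropy(cbind(1)), "at least 2")
})

test_that("classical weights follow (1 - E) / sum(1 - E)", {
  expect_equal(unname(classical_weights(c(0.8, 0.9))), c(2, 1) / 3)
  expect_equal(unname(classical_weights(c(0.5, 1.0))), c(1, 0))
  E <- c(0.9464, 0.8, 0.99)
  expect_equal(unname(classical_weights(E)), (1 - E) / sum(1 - E))
  expect_error(classical_weights(c(1, 1)), "undefined")
})

test_that("exponential-form weights match hand-derived cases", {
  # equal entropies -> uniform weights, any k
  for (k in c(0.3, 1, 5))
    expect_equal(unname(improved_weights(rep(0.7, 4), k)), rep(0.25, 4))
  # E = (0, 1), k = 1: second numerator exp(1) - exp(1) = 0
  expect_equal(unname(improved_weights(c(0, 1), 1)), c(1, 0))
  # E = (0.8, 0.9), k = 1: exp(1.9) - exp(0.8) vs exp(1.8) - exp(0.9)
  num <- c(exp(1.9) - exp(0.8), exp(1.8) - exp(0.9))
  expect_equal(unname(improved_weights(c(0.8, 0.9), 1)), num / sum(num))
  expect_equal(unname(improved_weights(c(0.8, 0.9), 1)), c(0.554, 0.446),
               tolerance = 1e-3)
  expect_error(improved_weights(c(0.5, 0.6), k_coef = 0), "positive")
  expect_error(improved_weights(0.5), "at least 2")
})

test_that("both weightings are simplex-valued and entropy-monotone", {
  set.seed(21)
  for (i in 1:200) {
    E <- random_entropies(sample(3:10, 1))
    k <- runif(1, 0.2, 4)
    Hc <- classical_weights(E)
    Hx <- improved_weights(E, k)
    expect_equal(sum(Hc), 1, tolerance = 1e-12)
    expect_equal(sum(Hx), 1, tolerance = 1e-12)
    expect_true(all(Hc >= 0) && all(Hx >= 0))
    # lower entropy never gets a smaller weight
    ord <- order(E)
    expect_true(all(diff(Hx[ord]) <= 1e-12))
    expect_true(all(diff(Hc[ord]) <= 1e-12))
  }
})

test_that("exponential form compresses weight dispersion at small entropy spread", {
  spread <- function(w) max(w) - min(w)
  expect_lt(spread(improved_weights(c(0.8, 0.9), 1)),
            spread(classical_weights(c(0.8, 0.9))))
  set.seed(22)
  for (i in 1:100) {
    m <- sample(3:8, 1)
    E <- 0.85 + runif(m, -0.05, 0.05)  # small-spread, high-entropy regime
    expect_lte(spread(improved_weights(E, 1)), spread(classical_weights(E)))
  }
})

test_that("composite scores equal the weighted row sums", {
  expect_equal(unname(composite_scores(rbind(c(0.2, 0.3)), c(0.5, 0.5))), 0.25)
  Z <- rbind(a = c(0.1, 0.2, 0.7), b = c(0.1, 0.2, 0.7))
  expect_equal(unname(diff(composite_scores(Z, c(0.2, 0.3, 0.5)))), 0)
  set.seed(23)
  for (i in 1:20) {
    Z <- random_matrix(sample(3:9, 1), sample(2:6, 1), 0, 1)
    H <- improved_weights(random_entropies(ncol(Z)))
    expect_equal(unname(composite_scores(Z, H)), oracle_composite(Z, H))
    # invariant under joint permutation of indicators and weights
    p <- sample(ncol(Z))
    expect_equal(composite_scores(Z[, p, drop = FALSE], H[p]),
                 composite_scores(Z, H))
  }
  expect_error(composite_scores(Z, c(0.5, 0.5)), "weight length")
})

test_that("entropy_weights runs the full chain coherently", {
  set.seed(24)
  X <- random_matrix(9, 5)
  dir_ <- c("benefit", "cost", "benefit", "benefit", "cost")
  ew <- entropy_weights(X, dir_)
  expect_equal(unname(colSums(ew$normalized)), rep(1, 5))
  expect_true(all(ew$shifted > 0))
  expect_true(all(ew$entropy >= 0 & ew$entropy <= 1))
  expect_equal(sum(ew$weights_classical), 1, tolerance = 1e-12)
  expect_equal(sum(ew$weights_improved), 1, tolerance = 1e-12)
  expect_equal(ew$scores, composite_scores(ew$shifted, ew$weights_improved))
  # cost adjustment flips the ordering of a cost indicator's contribution
  ew_cl <- entropy_weights(X, dir_, method = "classical")
  expect_equal(ew_cl$weights, ew_cl$weights_classical)
  # entropy-on-shifted variant stays a valid weighting
  ew_sh <- entropy_weights(X, dir_, entropy_on_shifted = TRUE)
  expect_equal(sum(ew_sh$weights), 1, tolerance = 1e-12)
})
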