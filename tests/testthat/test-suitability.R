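test_that("temperature response hits its cardinal points and frozen values", {
  expect_equal(sst_score(15.8), 1)
  expect_equal(sst_score(30), 0)
  expect_equal(sst_score(35), 0)
  # frozen from an independent one-line evaluation of the printed formula
  expect_equal(sst_score(20), 0.73618359787697452, tolerance = 1e-12)
  expect_equal(sst_score(10), 0.69204895483075701, tolerance = 1e-12)
  expect_equal(sst_score(25), 0.10976068286817754, tolerance = 1e-12)
})

test_that("temperature response is unimodal on a 0.01 degC grid", {
  up <- sst_score(seq(0, 15.8, by = 0.01))
  down <- sst_score(seq(15.8, 29.99, by = 0.01))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  everything <- sst_score(seq(-10, 40, by = 0.01))
  expect_true(all(everything >= 0 & everything <= 1))
})

test_that("chlorophyll response saturates through the half point", {
  expect_equal(chl_score(0), 0)
  expect_equal(chl_score(1.06), 0.5)
  expect_equal(chl_score(10 * 1.06), 10 / 11, tolerance = 1e-12)
  dense <- chl_score(seq(0, 50, by = 0.01))
  expect_true(all(dense >= 0 & dense < 1))
  expect_true(all(diff(dense) > 0))
  expect_error(chl_score(-0.1), ">= 0")
})

test_that("salinity quartic evaluates raw and standardizes over [0, 40]", {
  expect_equal(sss_score(0, raw = TRUE), -0.875038)
  # independent oracle: dense-grid min-max standardization of the clamped
  # quartic
  p <- function(s) -9e-6 * s^4 + 6.91e-4 * s^3 - 2.087e-2 * s^2 +
    0.296816 * s - 0.875038
  grid <- seq(0, 40, by = 1e-4)
  v <- pmax(p(grid), 0)
  oracle <- (pmax(p(20), 0) - min(v)) / (max(v) - min(v))
  expect_equal(sss_score(20), oracle, tolerance = 1e-9)
  # the domain argmax standardizes to exactly 1
  argmax <- grid[which.max(v)]
  expect_equal(sss_score(argmax), 1, tolerance = 1e-6)
  dense <- sss_score(grid[seq(1, length(grid), by = 100)])
  expect_true(all(dense >= 0 & dense <= 1))
  expect_warning(sss_score(45), "clipped")
})

test_that("sediment quadratic is monotone and zero beyond its root", {
  expect_equal(spm_score(0, raw = TRUE), 0.8273)
  expect_gt(spm_score(10), spm_score(40))
  dense <- spm_score(seq(0, 100, by = 0.05))
  expect_true(all(diff(dense) <= 0))
  expect_true(all(dense >= 0 & dense <= 1))
  expect_equal(spm_score(0), 1) # the quadratic's domain max is at 0
  # positive root of the quadratic via the quadratic formula
  root <- (4.2e-3 - sqrt((4.2e-3)^2 + 4 * 2e-4 * 0.8273)) / (2 * -2e-4)
  expect_equal(spm_score(root), 0, tolerance = 1e-9)
  expect_equal(spm_score(root + 20), 0)
  expect_equal(spm_score(150), 0)
  expect_error(spm_score(-1), ">= 0")
})

test_that("mean factor score is score-then-average with missing excluded", {
  st <- make_test_stack(function(n) rep(12, n), ndays = 10)
  expect_equal(mean_factor_score(st, sst_score)$values,
               matrix(sst_score(12), 4, 4))
  two <- make_test_stack(function(n) n, ndays = 2)
  two$values[1, , ] <- 15.8
  two$values[2, , ] <- 30
  expect_equal(mean_factor_score(two, sst_score)$values,
               matrix(0.5, 4, 4))
  set.seed(51)
  st2 <- make_test_stack(function(n) stats::runif(n, 5, 29), ndays = 20)
  st2$values[3, 1, 1] <- NA
  st2$values[, 2, 2] <- NA
  got <- mean_factor_score(st2, sst_score)$values
  oracle <- matrix(NA_real_, 4, 4)
  for (r in 1:4) for (c in 1:4) {
    x <- st2$values[, r, c]
    if (!all(is.na(x))) oracle[r, c] <- mean(sst_score(x[!is.na(x)]))
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(is.na(got[2, 2]))
})

test_that("AHP recovers weights from the consistent ratio matrix", {
  w_pub <- c(sst = 0.45, chl = 0.30, sss = 0.16, spm = 0.09)
  res <- ahp_weights(consistent_matrix(weight_vector(w_pub)))
  expect_equal(as.numeric(res$weights), unname(w_pub), tolerance = 1e-9)
  expect_equal(res$cr, 0, tolerance = 1e-12)
  expect_true(res$consistent)
  ones <- matrix(1, 4, 4)
  res1 <- ahp_weights(ones)
  expect_equal(as.numeric(res1$weights), rep(0.25, 4))
  expect_equal(res1$cr, 0, tolerance = 1e-12)
})

test_that("AHP matches a dense eigen-solver oracle on random matrices", {
  set.seed(52)
  saaty <- c(1 / (9:2), 1:9)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    A <- diag(n)
    for (r in 1:(n - 1)) for (c in (r + 1):n) {
      A[r, c] <- sample(saaty, 1)
      A[c, r] <- 1 / A[r, c]
    }
    got <- ahp_weights(A)
    e <- eigen(A)
    k <- which.max(Re(e$values))
    lam <- Re(e$values[k])
    wv <- Re(e$vectors[, k])
    wv <- wv / sum(wv)
    expect_equal(got$lambda_max, lam, tolerance = 1e-8)
    expect_equal(as.numeric(got$weights), wv, tolerance = 1e-8)
    expect_equal(got$cr, ((lam - n) / (n - 1)) / saaty_ri(n),
                 tolerance = 1e-8)
  }
})

test_that("invalid judgment matrices are refused", {
  A <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(ahp_weights(A), "reciprocal")
  expect_error(ahp_weights(matrix(c(1, -2, -0.5, 1), 2, 2)), "positive")
  expect_error(ahp_weights(matrix(1, 1, 1)), "square")
})

test_that("weight vectors validate names, sign and unit sum", {
  expect_silent(weight_vector(c(sst = 0.45, chl = 0.30, sss = 0.16,
                                spm = 0.09)))
  expect_error(weight_vector(c(a = 0.6, b = 0.5)), "sum to 1")
  expect_error(weight_vector(c(a = 1.2, b = -0.2)), "non-negative")
  expect_error(weight_vector(c(0.5, 0.5)), "named")
})

test_that("the weighted overlay is the cellwise dot product", {
  g <- make_grid(c(0, 1, 50, 51), 0.25)
  w <- weight_vector()
  mk <- function(v) raster_layer(g, matrix(v, 4, 4))
  all1 <- list(sst = mk(1), chl = mk(1), sss = mk(1), spm = mk(1))
  expect_equal(weighted_overlay(all1, w)$values, matrix(1, 4, 4))
  sst_only <- list(sst = mk(1), chl = mk(0), sss = mk(0), spm = mk(0))
  expect_equal(weighted_overlay(sst_only, w)$values,
               matrix(0.45, 4, 4))
  set.seed(53)
  for (i in 1:10) {
    f <- list(sst = mk(stats::runif(16)), chl = mk(stats::runif(16)),
              sss = mk(stats::runif(16)), spm = mk(stats::runif(16)))
    got <- weighted_overlay(f, w)$values
    oracle <- matrix(0, 4, 4)
    for (r in 1:4) for (c in 1:4)
      oracle[r, c] <- sum(vapply(names(w), function(nm)
        w[[nm]] * f[[nm]]$values[r, c], numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  f <- list(a = mk(1), b = mk(1), c = mk(1), d = mk(1))
  expect_error(weighted_overlay(f, w), "names")
})

test_that("SI rises when any factor score rises (weights positive)", {
  g <- make_grid(c(0, 1, 50, 51), 0.25)
  w <- weight_vector()
  set.seed(54)
  base <- lapply(stats::setNames(names(w), names(w)), function(nm)
    raster_layer(g, matrix(stats::runif(16, 0, 0.8), 4, 4)))
  si0 <- weighted_overlay(base, w)$values
  for (nm in names(w)) {
    bumped <- base
    bumped[[nm]]$values <- bumped[[nm]]$values + 0.1
    si1 <- weighted_overlay(bumped, w)$values
    expect_true(all(si1 >= si0))
  }
})

test_that("classification is exhaustive, exclusive and boundary-correct", {
  g <- make_grid(c(0, 1, 50, 51), 0.5)
  lv <- si_class_levels()
  cls_of <- function(x) {
    v <- matrix(c(x, 0, 0, 0), 2, 2)
    lv[classify_si(raster_layer(g, v))$values[1, 1]]
  }
  expect_identical(cls_of(0.85), "Very high")
  expect_identical(cls_of(0.2), "Low")     # left-closed bins
  expect_identical(cls_of(1.0), "Very high") # closed last bin
  expect_identical(cls_of(0), "Very low")
  expect_identical(cls_of(0.6), "High")
  # every SI in [0,1] lands in exactly one class
  dense <- seq(0, 1, by = 1e-4)
  gd <- make_grid(c(0, 1e-3, 50, 50 + 1e-3 * length(dense)), 1e-3)
  cls <- classify_si(raster_layer(gd, matrix(dense, ncol = 1)))$values
  expect_true(all(cls %in% 1:5))
  expect_true(all(diff(as.numeric(cls)) >= 0)) # monotone in SI
  bad <- raster_layer(g, matrix(c(1.2, 0, 0, 0), 2, 2))
  expect_error(classify_si(bad), "\\[0, 1\\]")
})
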