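test_that("a noiseless line is fit exactly and flagged as a perfect fit", {
  X <- matrix(c(0, 1, 2, 3, 4, 5), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- 2 * X[, 1] + 1
  f <- ols_fit(X, y)
  expect_equal(unname(f$b), 2, tolerance = 1e-12)
  expect_equal(f$constant, 1, tolerance = 1e-12)
  expect_lt(f$sse, 1e-20)
  expect_true(f$perfect_fit)
  expect_equal(unname(f$F), Inf)
})

test_that("coefficients and standard errors match the normal-equations oracle", {
  for (seed in 1:10) {
    X <- random_design(seed, n = 20, p = 3)
    set.seed(seed + 1000)
    y <- drop(X %*% c(1.5, -0.5, 0.25)) + rnorm(20)
    f <- ols_fit(X, y)
    o <- ne_oracle(X, y)
    expect_equal(unname(f$b), unname(o$b), tolerance = 1e-8)
    expect_equal(f$constant, unname(o$constant), tolerance = 1e-8)
    expect_equal(unname(f$SD), unname(o$SD), tolerance = 1e-8)
    expect_equal(f$sse, o$sse, tolerance = 1e-8)
  }
})

test_that("every reported F equals the squared coefficient-to-SD ratio", {
  for (seed in 1:10) {
    X <- random_design(seed, n = 20, p = 4)
    set.seed(seed)
    y <- rnorm(20)
    f <- ols_fit(X, y)
    expect_equal(unname(f$F), unname((f$b / f$SD)^2), tolerance = 1e-14)
    expect_true(all(f$F >= 0))
  }
})

test_that("the published hydrophobicity model is F-consistent within SD rounding", {
  # printed row: F 507.614, coefficient -0.563688, SD printed as 0.025;
  # any SD in the half-unit rounding interval must bracket the printed F
  b <- 0.563688
  expect_lt((b / 0.0255)^2, 507.614)
  expect_gt((b / 0.0245)^2, 507.614)
  # the SD implied by the printed F itself rounds to the printed 0.025
  expect_equal(round(b / sqrt(507.614), 3), 0.025)
})

test_that("degenerate and infeasible designs raise informative errors", {
  X <- random_design(1, n = 20, p = 2)
  Xd <- cbind(X, x3 = X[, 1])           # duplicated column
  set.seed(2)
  y <- rnorm(20)
  expect_error(ols_fit(Xd, y), "collinear")
  expect_error(ols_fit(random_design(1, n = 4, p = 3), rnorm(4)),
               "n > p \\+ 1")
  Xz <- cbind(X, x3 = rep(2, 20))
  expect_error(ols_fit(Xz, y), "constant predictor")
})

test_that("stepwise keeps a single informative predictor and drops noise", {
  X <- canonical_design()
  y <- 3 * X[, "anyO"] + 1   # noiseless, single signal column
  f <- stepwise_select(X, y, F_threshold = 2)
  expect_identical(f$selected, "anyO")
  expect_equal(unname(f$b), 3, tolerance = 1e-10)
  expect_equal(f$constant, 1, tolerance = 1e-10)
})

test_that("stepwise agrees with the exhaustive-subset oracle on correlated predictors", {
  # two predictors with moderate sample correlation, signal on the first
  set.seed(7)
  x1 <- sample(0:5, 20, replace = TRUE)
  x2 <- x1 + sample(0:5, 20, replace = TRUE)  # corr ~ 0.5-0.7 with x1
  X <- cbind(x1 = x1, x2 = x2)
  y <- 1.2 * x1 + rnorm(20, sd = 0.3)
  for (thr in c(2, 4, 8)) {
    f <- stepwise_select(X, y, thr)
    expect_setequal(f$selected, exhaustive_oracle(X, y, thr))
  }
})

test_that("stepwise matches the exhaustive oracle on seeded canonical fixtures", {
  X <- canonical_design()
  cases <- list(
    list(support = c("anyO", "aliphC"), beta = c(-0.6, 0.3), sd = 0.15,
         seed = 11, thr = 3),
    list(support = c("aliphN", "S", "aromC"), beta = c(0.8, -0.5, 0.2),
         sd = 0.2, seed = 12, thr = 2.5),
    list(support = c("dblO", "chiralC"), beta = c(0.9, -0.4), sd = 0.1,
         seed = 13, thr = 4)
  )
  for (cs in cases) {
    spec <- synthetic_spec(cs$support, cs$beta, constant = 0.2,
                           noise_sd = cs$sd, seed = cs$seed)
    y <- generate_property(spec, X)
    # restrict to 6 candidate columns so full enumeration stays the oracle
    cols <- union(cs$support,
                  c("anyO", "aliphC", "aliphN", "S", "dblO", "chiralC"))[1:6]
    Xs <- X[, cols]
    f <- stepwise_select(Xs, y, cs$thr)
    expect_setequal(f$selected, exhaustive_oracle(Xs, y, cs$thr))
  }
})

test_that("stepwise output is a fixpoint with every retained F above threshold", {
  X <- canonical_design()
  for (seed in 1:8) {
    spec <- synthetic_spec(c("anyO", "aromC"), c(1, -0.6), 0.1,
                           noise_sd = 0.25, seed = seed)
    y <- generate_property(spec, X)
    thr <- 2 + seed / 4
    f <- stepwise_select(X, y, thr)
    if (length(f$selected) && !f$perfect_fit) {
      expect_true(all(f$F >= thr))
    }
    # re-running on its own selected candidate set changes nothing
    if (length(f$selected)) {
      f2 <- stepwise_select(X[, f$selected, drop = FALSE], y, thr)
      expect_setequal(f2$selected, f$selected)
      expect_equal(f2$b[f$selected], f$b[f$selected], tolerance = 1e-10)
    }
  }
})

test_that("zero-variance columns are excluded from candidacy, not errors", {
  X <- canonical_design()
  Xz <- cbind(X[, c("anyO", "aliphC")], dead = rep(3L, 20))
  y <- 2 * X[, "anyO"] + rnorm(20, sd = 0.1)
  f <- stepwise_select(Xz, y, 3)
  expect_true("dead" %in% f$dropped_constant)
  expect_false("dead" %in% f$selected)
})

test_that("when nothing survives the gate the constant-only model is returned", {
  X <- canonical_design()
  set.seed(99)
  y <- rnorm(20)                      # pure noise
  f <- stepwise_select(X, y, F_threshold = 1e6)
  expect_length(f$selected, 0L)
  expect_equal(f$constant, mean(y))
  expect_equal(f$fitted, rep(mean(y), 20))
})
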