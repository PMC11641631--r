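test_that("pearson matches the textbook formula and guards degenerate input", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  set.seed(21)
  a <- rnorm(50)
  b <- 0.3 * a + rnorm(50)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), direct, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:4, 1:5), "length")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("rmse is the root mean squared difference", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(4, 6), c(1, 2)), sqrt(12.5))
  expect_equal(rmse(1:7 + 0.25, 1:7), 0.25)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("LOO predictions are exact for a noiseless linear property", {
  X <- canonical_design()
  spec <- synthetic_spec(c("anyO", "aliphC"), c(-0.6, 0.3), 0.5,
                         noise_sd = 0, seed = 5)
  y <- generate_property(spec, X)
  pred <- loo_predict(X, y, F_threshold = 3)
  expect_equal(pred, unname(y), tolerance = 1e-8)
})

test_that("the LOO loop agrees with an independent fold-by-fold oracle", {
  X <- canonical_design()[, c("anyO", "aliphN", "aliphC", "S", "dblO")]
  for (seed in 1:5) {
    spec <- synthetic_spec(c("anyO", "S"), c(0.9, -0.5), 0.2,
                           noise_sd = 0.25, seed = seed)
    y <- generate_property(spec, canonical_design())
    pred <- loo_predict(X, y, F_threshold = 3)
    orac <- loo_oracle(X, y, threshold = 3)
    expect_equal(pred, orac, tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("pure-noise properties earn no positive LOO skill", {
  X <- canonical_design()
  set.seed(1234)
  y <- rnorm(20)
  for (thr in c(2, 4)) {
    pred <- loo_predict(X, y, F_threshold = thr)
    r <- tryCatch(pearson(pred, y), error = function(e) 0)
    expect_lt(r, 0.5)
  }
  # when no fold retains a predictor, each fold predicts the training
  # mean of the other 19 values, a decreasing linear function of the
  # held-out value: the LOO correlation collapses to exactly -1
  pred_hi <- loo_predict(X, y, F_threshold = 1e6)
  expect_equal(pearson(pred_hi, y), -1, tolerance = 1e-12)
})

test_that("threshold scan reports r, r_jn and model size per grid point", {
  X <- canonical_design()
  spec <- synthetic_spec(c("anyO", "aromC"), c(-0.7, 0.2), 0.1,
                         noise_sd = 0.15, seed = 8)
  y <- generate_property(spec, X)
  sc <- threshold_scan(X, y, grid = c(1, 3, 6))
  expect_equal(sc$scan$threshold, c(1, 3, 6))
  expect_equal(dim(sc$loo), c(20L, 3L))
  expect_true(all(sc$scan$r_jn >= -1 & sc$scan$r_jn <= 1, na.rm = TRUE))
  expect_error(threshold_scan(X, y, c(3, 1)), "strictly increasing")
  expect_error(threshold_scan(X, y, numeric(0)), "empty")
})

test_that("noiseless training recovers the model at the sparsest tying threshold", {
  X <- canonical_design()
  spec <- synthetic_spec(c("anyO", "aliphC"), c(-0.6, 0.3), 0.5,
                         noise_sd = 0, seed = 5)
  y <- generate_property(spec, X)
  grid <- c(1, 2, 4, 8)
  m <- optimize_threshold(X, y, grid = grid, accession = "SYN_NOISELESS")
  expect_equal(m$r_jn, 1, tolerance = 1e-8)
  # perfect fits carry no meaningful threshold and zero error
  expect_true(is.na(m$F_star))
  expect_equal(m$RMSE, 0)
  expect_setequal(m$selected, spec$support)
  expect_equal(m$b[spec$support], spec$beta, tolerance = 1e-8)
  expect_equal(m$constant, spec$constant, tolerance = 1e-8)
})

test_that("RMSE and r_jn come from the same LOO prediction vector", {
  X <- canonical_design()
  spec <- synthetic_spec(c("aliphN", "dblO"), c(0.8, -0.5), 0,
                         noise_sd = 0.2, seed = 17)
  y <- generate_property(spec, X)
  m <- optimize_threshold(X, y, grid = c(2, 3, 4), accession = "SYN_CONS")
  expect_equal(m$RMSE, rmse(m$loo, unname(y)), tolerance = 1e-12)
  expect_equal(m$r_jn, pearson(m$loo, unname(y)), tolerance = 1e-12)
})

test_that("refining the grid never lowers the achieved maximum r_jn", {
  X <- canonical_design()
  spec <- synthetic_spec(c("anyO", "S"), c(0.9, -0.4), 0.3,
                         noise_sd = 0.25, seed = 23)
  y <- generate_property(spec, X)
  coarse <- c(1, 4, 8)
  fine <- sort(c(coarse, 2, 3, 6))
  sc_c <- threshold_scan(X, y, coarse)$scan
  sc_f <- threshold_scan(X, y, fine)$scan
  expect_gte(max(sc_f$r_jn, na.rm = TRUE), max(sc_c$r_jn, na.rm = TRUE))
})

test_that("train_models handles NA-masked residues by dropping them", {
  canon <- canonical_aa_table()
  X <- build_design_matrix(canon)
  spec <- synthetic_spec(c("anyO", "aliphC"), c(-0.6, 0.3), 0.5,
                         noise_sd = 0.1, seed = 31)
  y <- generate_property(spec, X)
  toks <- sprintf("%.4f", y[match(aaindex_order(), canon$one_letter)])
  toks[which(aaindex_order() == "P")] <- "NA"
  rec <- parse_aaindex1(make_record("SYN0002", toks))
  models <- train_models(rec, canon, grid = c(2, 4))
  expect_length(models, 1L)
  expect_equal(models[[1]]$n_used, 19L)
  expect_true(models[[1]]$P_num == length(models[[1]]$selected))
})
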