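#' Pearson correlation
#'
#' Plain sample Pearson correlation, with explicit errors for the
#' degenerate inputs for which the statistic is undefined.
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Root mean square error
#'
#' @param pred,actual Numeric vectors of equal length.
#' @return sqrt(mean((pred - actual)^2)).
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch", call. = FALSE)
  if (!length(pred)) stop("empty input", call. = FALSE)
  sqrt(mean((pred - actual)^2))
}

#' Leave-one-out predictions at a fixed F threshold
#'
#' For each row i, a stepwise model is selected and fit on the other
#' n - 1 rows at the given threshold and applied to row i. Folds in which
#' no predictor survives the gate predict the training mean. Zero-variance
#' columns are dropped from candidacy independently inside each fold.
#'
#' @param X Design matrix (rows = amino acids, columns = components).
#' @param y Property values, one per row of X.
#' @param F_threshold Positive F-to-stay threshold.
#' @return Numeric vector of held-out predictions, one per row.
#' @export
loo_predict <- function(X, y, F_threshold) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3L) stop("leave-one-out needs n >= 3", call. = FALSE)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  vapply(seq_len(n), function(i) {
    fit <- stepwise_select(X[-i, , drop = FALSE], y[-i], F_threshold)
    predict_fit(fit, X[i, ])
  }, 0)
}

.safe_pearson <- function(a, b) {
  tryCatch(pearson(a, b), error = function(e) NA_real_)
}

#' Scan a grid of F thresholds
#'
#' Computes, for every threshold in the grid, the full-data stepwise
#' model (in-sample r and number of retained predictors) and the
#' leave-one-out correlation r_jn.
#'
#' @inheritParams loo_predict
#' @param grid Strictly increasing numeric vector of thresholds.
#' @return A list with `scan` (data.frame threshold, r, r_jn, P_num) and
#'   `loo` (matrix of LOO predictions, one column per threshold).
#' @export
threshold_scan <- function(X, y, grid) {
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("threshold grid must be strictly increasing", call. = FALSE)
  }
  loo <- vapply(grid, function(thr) loo_predict(X, y, thr),
                numeric(length(y)))
  rows <- lapply(seq_along(grid), function(j) {
    fit <- stepwise_select(X, y, grid[j])
    data.frame(threshold = grid[j],
               r = .safe_pearson(fit$fitted, y),
               r_jn = .safe_pearson(loo[, j], y),
               P_num = length(fit$selected))
  })
  list(scan = do.call(rbind, rows), loo = loo)
}

#' Train one property model with LOO-optimized F threshold
#'
#' Runs [threshold_scan()] over the grid, picks the threshold with the
#' highest leave-one-out correlation r_jn (ties, within 1e-9, go to the
#' largest threshold, i.e. the sparsest model), refits the stepwise model
#' on all rows at that threshold, and reports the LOO prediction quality:
#' r_jn and the RMSE of the LOO predictions at the chosen threshold. For
#' properties the design fits perfectly (zero residual), the threshold is
#' reported as NA and the RMSE as 0, since the gate plays no role.
#'
#' @inheritParams threshold_scan
#' @param accession,description Identifier metadata carried to the model.
#' @param grid Threshold grid; default `default_f_grid()`.
#' @return An object of class `"ncaa_model"`: accession, selected
#'   components, coefficients `b`, `constant`, `F_star`, `r_jn`,
#'   `r_insample`, `P_num`, `RMSE`, `n_used`, `perfect_fit`, plus the
#'   `scan` data.frame and the LOO prediction vector `loo` at `F_star`.
#' @export
optimize_threshold <- function(X, y, grid = default_f_grid(),
                               accession = "SYNTHETIC", description = "") {
  sc <- threshold_scan(X, y, grid)
  r_jn <- sc$scan$r_jn
  if (all(is.na(r_jn))) {
    best <- length(grid)      # degenerate: no fold produced usable spread
  } else {
    top <- max(r_jn, na.rm = TRUE)
    best <- max(which(!is.na(r_jn) & r_jn >= top - 1e-9))
  }
  thr <- grid[best]
  fit <- stepwise_select(X, y, thr)
  loo <- sc$loo[, best]
  model <- structure(list(
    accession = accession,
    description = description,
    selected = fit$selected,
    b = fit$b,
    constant = fit$constant,
    F_star = if (fit$perfect_fit) NA_real_ else thr,
    r_jn = r_jn[best],
    r_insample = .safe_pearson(fit$fitted, y),
    P_num = length(fit$selected),
    RMSE = if (fit$perfect_fit) 0 else rmse(loo, y),
    n_used = length(y),
    perfect_fit = fit$perfect_fit,
    scan = sc$scan,
    loo = loo
  ), class = "ncaa_model")
  model
}

#' Default F-threshold grid
#'
#' @param from,to,by Grid limits and step.
#' @return Numeric vector of thresholds.
#' @export
default_f_grid <- function(from = 0.5, to = 12, by = 0.1) {
  seq(from, to, by = by)
}

#' Train models for a set of AAindex properties
#'
#' For each property record, aligns the 20 values to the canonical
#' design-matrix rows via 1-letter codes, drops amino acids masked as NA
#' for that property (reducing n below 20 for that property only), and
#' trains via [optimize_threshold()].
#'
#' @param records List of property records from [parse_aaindex1()].
#' @param canonical Canonical amino-acid table
#'   (see [canonical_aa_table()]); must cover all 20 one-letter codes.
#' @param grid Threshold grid.
#' @param verbose Print one progress line per property.
#' @return List of `"ncaa_model"` objects, one per trainable record.
#' @export
train_models <- function(records, canonical, grid = default_f_grid(),
                         verbose = FALSE) {
  X <- build_design_matrix(canonical)
  one <- if ("one_letter" %in% names(canonical)) canonical$one_letter
         else aa_three_to_one(canonical$code)
  out <- list()
  for (r in records) {
    y <- r$values[one]
    keep <- !is.na(y)
    if (sum(keep) < 5L) {
      warning(sprintf("property %s: only %d usable values, skipped",
                      r$accession, sum(keep)))
      next
    }
    m <- optimize_threshold(X[keep, , drop = FALSE], unname(y[keep]),
                            grid = grid, accession = r$accession,
                            description = r$description)
    if (verbose) {
      message(sprintf("%s  r_jn=%.3f RMSE=%.3g F*=%s P=%d n=%d",
                      m$accession, m$r_jn, m$RMSE,
                      ifelse(is.na(m$F_star), "NA", format(m$F_star)),
                      m$P_num, m$n_used))
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' @export
print.ncaa_model <- function(x, ...) {
  cat(sprintf("<ncaa_model> %s%s\n", x$accession,
              if (nzchar(x$description)) paste0(" -- ", x$description) else ""))
  cat(sprintf("  F* = %s, P_num = %d, n = %d\n",
              ifelse(is.na(x$F_star), "NA (perfect fit)", format(x$F_star)),
              x$P_num, x$n_used))
  cat(sprintf("  r_jn = %.3f, in-sample r = %.3f, RMSE = %.4g\n",
              x$r_jn, x$r_insample, x$RMSE))
  if (length(x$selected)) {
    cat("  coefficients:\n")
    for (k in x$selected) cat(sprintf("    %-8s %12.6f\n", k, x$b[[k]]))
  }
  cat(sprintf("  constant %12.6f\n", x$constant))
  invisible(x)
}

#' Per-property summary table
#'
#' @param models List of `"ncaa_model"` objects.
#' @return data.frame with columns accession, r_jn, RMSE, F_star, P_num,
#'   n_used.
#' @export
model_summary <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(accession = m$accession, r_jn = m$r_jn, RMSE = m$RMSE,
               F_star = m$F_star, P_num = m$P_num, n_used = m$n_used)
  }))
}
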