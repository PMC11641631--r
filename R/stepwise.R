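# Per-coefficient significance is the squared ratio of a coefficient to
# its standard error ("F-value" in the output): the squared t statistic.
# It gates both entry and stay of predictors in the stepwise search.

#' Ordinary least squares with per-coefficient F statistics
#'
#' Fits y on the given predictor columns plus an intercept and reports,
#' for every predictor, the coefficient, its standard deviation (standard
#' error with residual variance sse / (n - p - 1)) and the F statistic
#' (coefficient / SD)^2. The intercept is always present and carries no
#' F statistic. When the residual sum of squares is below the
#' perfect-fit tolerance (sse/n <= 1e-12 * var(y)), the standard
#' deviations are meaningless, `perfect_fit` is set, and all F values are
#' reported as `Inf` so a perfectly predictive model survives any gate.
#'
#' @param X Numeric matrix of predictors (no intercept column); may have
#'   zero columns for the constant-only model.
#' @param y Numeric response, `length(y) == nrow(X)`.
#' @param perfect_tol Relative tolerance defining a perfect fit.
#' @return An object of class `"ncaa_fit"`: list with `selected`
#'   (predictor names), `b`, `SD`, `F`, `constant`, `n`, `sse`, `sigma2`,
#'   `df`, `fitted`, `perfect_fit`.
#' @export
ols_fit <- function(X, y, perfect_tol = 1e-12) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n < p + 2L) {
    stop(sprintf("need n > p + 1 (n = %d, p = %d)", n, p), call. = FALSE)
  }
  if (p > 0L) {
    cvar <- apply(X, 2L, stats::var)
    if (any(cvar == 0)) {
      stop("constant predictor column(s): ",
           paste(colnames(X)[cvar == 0], collapse = ", "), call. = FALSE)
    }
  }
  Xc <- cbind("(Intercept)" = rep(1, n), X)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):ncol(Xc)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrX, y)
  fitted <- drop(Xc %*% coef)
  sse <- sum((y - fitted)^2)
  df <- n - p - 1L
  sigma2 <- sse / df
  R <- qr.R(qrX)
  xtxinv <- chol2inv(R)
  piv <- qrX$pivot
  unscr <- xtxinv
  unscr[piv, piv] <- xtxinv
  se <- sqrt(pmax(diag(unscr) * sigma2, 0))
  names(se) <- colnames(Xc)

  vy <- stats::var(y)
  perfect <- (sse / n) <= perfect_tol * max(vy, .Machine$double.eps)

  b <- coef[-1L]
  SD <- se[-1L]
  Fval <- if (p == 0L) numeric(0) else if (perfect) {
    stats::setNames(rep(Inf, p), names(b))
  } else {
    (b / SD)^2
  }
  structure(list(
    selected = colnames(X) %||% character(0),
    b = b, SD = SD, F = Fval,
    constant = unname(coef[1L]),
    n = n, sse = sse, sigma2 = sigma2, df = df,
    fitted = fitted, perfect_fit = perfect
  ), class = "ncaa_fit")
}

# constant-only "fit" (used when no predictor survives the gate)
.constant_fit <- function(y, perfect_tol = 1e-12) {
  n <- length(y)
  m <- mean(y)
  sse <- sum((y - m)^2)
  vy <- stats::var(y)
  structure(list(
    selected = character(0),
    b = numeric(0), SD = numeric(0), F = numeric(0),
    constant = m, n = n, sse = sse,
    sigma2 = if (n > 1L) sse / (n - 1L) else NA_real_, df = n - 1L,
    fitted = rep(m, n),
    perfect_fit = (sse / n) <= perfect_tol * max(vy, .Machine$double.eps)
  ), class = "ncaa_fit")
}

#' Predict from a fitted subset model
#'
#' @param fit An `"ncaa_fit"` from [ols_fit()] or [stepwise_select()].
#' @param newX Numeric matrix (or single named row) holding at least the
#'   fitted predictor columns.
#' @return Numeric vector of predictions.
#' @export
predict_fit <- function(fit, newX) {
  if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1L,
                                         dimnames = list(NULL, names(newX)))
  if (!length(fit$selected)) {
    return(rep(fit$constant, nrow(newX)))
  }
  missing <- setdiff(fit$selected, colnames(newX))
  if (length(missing)) {
    stop("prediction input lacks component column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(newX[, fit$selected, drop = FALSE] %*% fit$b) + fit$constant
}

#' F-gated stepwise predictor selection
#'
#' Selects a subset of predictor columns such that, in the final joint
#' refit, every retained predictor's F statistic is at least
#' `F_threshold` (the intercept is never gated). The search is forward
#' inclusion -- at each step the candidate giving the greatest reduction
#' in residual sum of squares is tried first, ties broken by column
#' order -- interleaved with backward elimination, which repeatedly drops
#' the lowest-F predictor while any F is below the threshold. The loop
#' runs to a fixpoint: a candidate step is accepted only if the model it
#' leads to (after elimination) is new and strictly reduces the residual
#' sum of squares. Because predictors can be jointly significant while
#' individually failing the gate, a second pass runs backward elimination
#' from the full feasible candidate set and the lower-sse fixpoint of the
#' two routes is returned. Zero-variance columns are removed from
#' candidacy before the search. If no predictor survives, the
#' constant-only model (mean of y) is returned.
#'
#' @param X Numeric matrix of candidate predictors with column names.
#' @param y Numeric response.
#' @param F_threshold Positive F-to-stay threshold.
#' @param perfect_tol Passed to [ols_fit()].
#' @return An `"ncaa_fit"` (see [ols_fit()]) with additional fields
#'   `F_threshold` and `dropped_constant` (zero-variance columns removed
#'   from candidacy).
#' @export
stepwise_select <- function(X, y, F_threshold, perfect_tol = 1e-12) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(F_threshold > 0)
  n <- length(y)
  keys <- colnames(X)
  cvar <- apply(X, 2L, stats::var)
  dropped <- keys[cvar == 0]
  cand <- keys[cvar > 0]

  fit_of <- function(s) {
    if (!length(s)) .constant_fit(y, perfect_tol)
    else ols_fit(X[, s, drop = FALSE], y, perfect_tol)
  }
  # keep subsets in fixed column order so ties and output are stable
  canon <- function(s) keys[keys %in% s]
  sid <- function(s) paste(canon(s), collapse = "|")

  backward <- function(s) {
    repeat {
      if (!length(s)) return(s)
      f <- tryCatch(fit_of(s), error = function(e) NULL)
      if (is.null(f)) {
        # collinear subset: drop the last column involved and continue
        s <- s[-length(s)]
        next
      }
      if (f$perfect_fit) return(s)
      low <- which(f$F < F_threshold)
      if (!length(low)) return(s)
      worst <- which(f$F == min(f$F))
      s <- setdiff(s, f$selected[worst[length(worst)]])
    }
  }

  S <- character(0)
  fS <- fit_of(S)
  visited <- sid(S)
  repeat {
    if (fS$perfect_fit) break   # zero residual: nothing left to explain
    rem <- setdiff(cand, S)
    # adding one predictor must leave at least one residual df
    if (!length(rem) || (length(S) + 1L) > n - 2L) break
    red <- vapply(rem, function(k) {
      f <- tryCatch(fit_of(c(S, k)), error = function(e) NULL)
      if (is.null(f)) -Inf else fS$sse - f$sse
    }, 0)
    ord <- order(-red, match(rem, keys))
    accepted <- FALSE
    for (k in rem[ord]) {
      if (!is.finite(red[k])) next
      S2 <- canon(backward(c(S, k)))
      id2 <- sid(S2)
      if (id2 %in% visited) next
      f2 <- fit_of(S2)
      if (f2$sse < fS$sse - 1e-12 * max(fS$sse, .Machine$double.eps)) {
        S <- S2
        fS <- f2
        visited <- c(visited, id2)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  # Predictors can be jointly significant while individually failing the
  # gate, which the forward path cannot see; backward elimination from
  # the full feasible candidate set reaches such fixpoints, and the
  # lower-sse of the two is kept.
  # (skipped after a perfect greedy fit: zero residual makes every F
  # infinite, so elimination from the full set could not prune anything)
  if (!fS$perfect_fit && length(cand) && length(cand) <= n - 2L) {
    S_alt <- canon(backward(cand))
    f_alt <- fit_of(S_alt)
    if (f_alt$perfect_fit) {
      # a perfect fit defeats F-based elimination (all F infinite); find
      # a minimal perfectly fitting subset by gate-free forward selection
      # followed by pruning of redundant columns
      Sp <- character(0)
      fp <- fit_of(Sp)
      repeat {
        if (fp$perfect_fit) break
        rem <- setdiff(cand, Sp)
        if (!length(rem) || (length(Sp) + 1L) > n - 2L) break
        red <- vapply(rem, function(k) {
          f <- tryCatch(fit_of(c(Sp, k)), error = function(e) NULL)
          if (is.null(f)) -Inf else fp$sse - f$sse
        }, 0)
        if (max(red) <= 0) break
        Sp <- canon(c(Sp, rem[order(-red, match(rem, keys))][1]))
        fp <- fit_of(Sp)
      }
      if (fp$perfect_fit) {
        for (k in rev(Sp)) {
          if (length(Sp) > 1L) {
            ftry <- tryCatch(fit_of(setdiff(Sp, k)),
                             error = function(e) NULL)
            if (!is.null(ftry) && ftry$perfect_fit) Sp <- setdiff(Sp, k)
          }
        }
        S_alt <- canon(Sp)
        f_alt <- fit_of(S_alt)
      }
    }
    if (f_alt$sse < fS$sse - 1e-12 * max(fS$sse, .Machine$double.eps)) {
      S <- S_alt
      fS <- f_alt
    }
  }
  S <- canon(backward(S))
  fS <- fit_of(S)
  # a perfect fit makes every F infinite, so the gate cannot discard
  # columns that contribute nothing; prune to a minimal zero-residual set
  if (fS$perfect_fit && length(S) > 1L) {
    for (k in rev(S)) {
      if (length(S) > 1L) {
        ftry <- tryCatch(fit_of(setdiff(S, k)), error = function(e) NULL)
        if (!is.null(ftry) && ftry$perfect_fit) S <- setdiff(S, k)
      }
    }
    S <- canon(S)
    fS <- fit_of(S)
  }
  fS$F_threshold <- F_threshold
  fS$dropped_constant <- dropped
  fS
}
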