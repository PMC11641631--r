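# Independent oracles: deliberately written along different routes than
# the implementation they check (normal equations instead of QR,
# exhaustive enumeration instead of greedy search, a character walker
# instead of the tokenizer).

# --- normal-equations OLS oracle ------------------------------------------
ne_oracle <- function(X, y) {
  Xc <- cbind(1, as.matrix(X))
  XtX <- t(Xc) %*% Xc
  XtXinv <- solve(XtX)
  coef <- drop(XtXinv %*% t(Xc) %*% y)
  res <- y - drop(Xc %*% coef)
  sse <- sum(res^2)
  df <- length(y) - ncol(Xc)
  se <- sqrt(diag(XtXinv) * sse / df)
  list(constant = coef[1], b = coef[-1], SD = se[-1], sse = sse)
}

# --- exhaustive-subset fixpoint oracle ------------------------------------
# Best-sse subset among all subsets whose joint refit has every F >=
# threshold (perfect fits count as admissible); ties go to the smaller
# subset, then to column order.
exhaustive_oracle <- function(X, y, threshold) {
  X <- as.matrix(X)
  keys <- colnames(X)[apply(X, 2, stats::var) > 0]
  n <- length(y)
  best <- list(sel = character(0),
               sse = sum((y - mean(y))^2))
  for (size in seq_len(min(length(keys), n - 2L))) {
    for (s in utils::combn(keys, size, simplify = FALSE)) {
      f <- tryCatch(ols_fit(X[, s, drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(f)) next
      if (!f$perfect_fit && any(f$F < threshold)) next
      if (f$sse < best$sse - 1e-9 * max(best$sse, 1e-300)) {
        best <- list(sel = s, sse = f$sse)
      }
    }
  }
  best$sel
}

# --- regex-free element walker --------------------------------------------
walker_elements <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  upper <- LETTERS
  lower <- letters
  out <- character(0)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      body <- character(0)
      while (j <= n && chars[j] != "]") {
        body <- c(body, chars[j])
        j <- j + 1
      }
      k <- 1
      while (k <= length(body) && body[k] %in% as.character(0:9)) k <- k + 1
      if (k <= length(body)) {
        first <- body[k]
        if (first %in% upper) {
          sym <- first
          if (k + 1 <= length(body) && body[k + 1] %in% lower) {
            sym <- paste0(sym, body[k + 1])
          }
          out <- c(out, sym)
        } else if (first %in% c("a", "s") && k + 1 <= length(body) &&
                   paste0(first, body[k + 1]) %in% c("as", "se")) {
          out <- c(out, paste0(toupper(first), body[k + 1]))
        } else if (first %in% c("b", "c", "n", "o", "p", "s")) {
          out <- c(out, toupper(first))
        }
      }
      i <- j + 1
    } else if (i < n && paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1]))
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      out <- c(out, ch)
      i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      out <- c(out, toupper(ch))
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  unique(out)
}

walker_has_excluded <- function(s, excluded = excluded_elements()) {
  length(intersect(walker_elements(s), excluded)) > 0
}

# --- independent LOO loop (exhaustive selection inside each fold) ---------
loo_oracle <- function(X, y, threshold) {
  X <- as.matrix(X)
  n <- length(y)
  sapply(seq_len(n), function(i) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    sel <- exhaustive_oracle(Xt, yt, threshold)
    if (!length(sel)) return(mean(yt))
    f <- ols_fit(Xt[, sel, drop = FALSE], yt)
    sum(f$b * X[i, sel]) + f$constant
  })
}

# --- shared fixtures -------------------------------------------------------
canonical_design <- local({
  X <- NULL
  function() {
    if (is.null(X)) X <<- build_design_matrix(canonical_aa_table())
    X
  }
})

# seeded random design matrices shaped like the canonical one
random_design <- function(seed, n = 20, p = 3) {
  set.seed(seed)
  X <- matrix(sample(0:6, n * p, replace = TRUE), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  while (any(apply(X, 2, stats::var) == 0)) {
    X <- matrix(sample(0:6, n * p, replace = TRUE), n, p)
    colnames(X) <- paste0("x", seq_len(p))
  }
  X
}
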