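# Bundled reference tables and the synthetic-property generator.
# Fixture checksums are pinned so silent edits fail loudly.
.fixture_md5 <- c(
  "canonical_aa.tsv" = "0b1757516c297871357bfbdd90b14407",
  "ncaa_frequent.tsv" = "b44453f08007516d20840525df8b2e73",
  "synthetic_aaindex1.txt" = "adcaf2cdbfaa54e011a3e723fb2e139b"
)

.fixture_path <- function(name, dir = NULL) {
  path <- if (is.null(dir)) system.file("extdata", name, package = "ncaaprop")
          else file.path(dir, name)
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled fixture not found: ", name, call. = FALSE)
  }
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[name]))) {
    stop(sprintf("fixture %s fails its checksum (%s); file was modified",
                 name, sum), call. = FALSE)
  }
  path
}

#' Bundled canonical amino-acid SMILES table
#'
#' The 20 canonical amino acids with isomeric SMILES in the PDB
#' chemical-component-dictionary dialect (side-chain/backbone written as
#' in the dictionary entries, ARG and HIS in their +1 protonation).
#' The file is checksum-pinned; a modified copy is an error.
#'
#' @return data.frame with columns code, one_letter, name, smiles.
#' @export
canonical_aa_table <- function() {
  load_smiles_table(.fixture_path("canonical_aa.tsv"))
}

#' Bundled table of frequent PDB non-canonical amino acids
#'
#' The 25 most frequently occurring ncAAs in the PDB (jointly over 70%
#' of all ncAA occurrences), with chemical-component codes, names,
#' isomeric SMILES, occurrence counts and percentages.
#'
#' @return data.frame with columns code, name, smiles, count, percent.
#' @export
ncaa_frequent_table <- function() {
  load_smiles_table(.fixture_path("ncaa_frequent.tsv"))
}

#' Published EISD840101 model (consensus normalized hydrophobicity)
#'
#' The published learning model for the AAindex property EISD840101:
#' ten F-gated predictors with their regression coefficients, standard
#' deviations and F values, the constant term, and the reported quality
#' statistics (r_jn = 0.924 at F threshold 2.4, RMSE 0.282). Useful as a
#' frozen reference model for the worked 4-hydroxyproline example.
#'
#' @return An `"ncaa_model"` with an extra `published` data.frame
#'   (columns component, F, b, SD).
#' @export
eisd840101_published_model <- function() {
  pub <- data.frame(
    component = c("anyO", "aliphN", "aromN", "dblN", "aliphC",
                  "aromC", "S", "ring1", "ring2", "plus"),
    F = c(507.614, 120.263, 9.014, 11.118, 56.734,
          111.808, 22.228, 68.744, 44.738, 189.686),
    b = c(-0.563688, -0.556289, 0.163592, 0.452579, 0.113070,
          0.148830, -0.248443, -0.290756, -0.688098, -1.168294),
    SD = c(0.025, 0.050, 0.054, 0.135, 0.015,
           0.014, 0.052, 0.035, 0.102, 0.084),
    stringsAsFactors = FALSE
  )
  b <- stats::setNames(pub$b, pub$component)
  structure(list(
    accession = "EISD840101",
    description = "Consensus normalized hydrophobicity scale",
    selected = pub$component,
    b = b,
    constant = 1.629829,
    F_star = 2.4,
    r_jn = 0.924,
    r_insample = 0.953,
    P_num = 10L,
    RMSE = 0.282,
    n_used = 20L,
    perfect_fit = FALSE,
    published = pub
  ), class = "ncaa_model")
}

#' Published component vector for 4-hydroxyproline
#'
#' The 13 component counts of the HYP worked example
#' (SMILES `O[C@H]1CN[C@@H](C1)C(O)=O`), as published.
#'
#' @return Named integer vector over [component_keys()].
#' @export
hyp_published_components <- function() {
  stats::setNames(
    c(1L, 3L, 1L, 0L, 0L, 5L, 0L, 2L, 0L, 1L, 0L, 1L, 0L),
    component_keys()
  )
}

#' Published F-threshold scan for EISD840101
#'
#' The four probed thresholds of the published scan, with the in-sample
#' correlation r, the leave-one-out correlation r_jn and the number of
#' retained predictors at each; r_jn peaks at threshold 2.4.
#'
#' @return data.frame with columns threshold, r, r_jn, P_num.
#' @export
eisd840101_published_scan <- function() {
  data.frame(
    threshold = c(1, 2, 2.4, 3),
    r = c(0.997, 0.997, 0.953, 0.953),
    r_jn = c(0.850, 0.848, 0.924, 0.890),
    P_num = c(11L, 10L, 10L, 3L)
  )
}

#' Path to the bundled synthetic AAindex1 demo file
#'
#' Three small property records in AAindex1 flat-file layout, generated
#' by [generate_property()] from known sparse linear models over the
#' canonical design matrix (the D lines state each generating model).
#' Entirely synthetic: no values from the real AAindex database are
#' redistributed. Useful for demonstrating [parse_aaindex1()] and
#' [train_models()] end to end.
#'
#' @return File path to the checksum-pinned fixture.
#' @export
synthetic_aaindex_path <- function() {
  .fixture_path("synthetic_aaindex1.txt")
}

#' Define a synthetic property specification
#'
#' A synthetic AAindex-like property is a known sparse linear function of
#' the component design matrix plus Gaussian noise. Used to validate the
#' whole training pipeline by parameter recovery.
#'
#' @param support Character vector of component keys carrying signal.
#' @param beta Numeric coefficients, one per support key.
#' @param constant Intercept.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(support, beta, constant = 0, noise_sd = 0,
                           seed = 1L) {
  if (length(support) != length(beta)) {
    stop("`support` and `beta` must have the same length", call. = FALSE)
  }
  unknown <- setdiff(support, component_keys())
  if (length(unknown)) {
    stop("unknown component key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(support = support,
                 beta = stats::setNames(as.numeric(beta), support),
                 constant = constant, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic property vector over a design matrix
#'
#' Computes `y = X[, support] %*% beta + constant + N(0, noise_sd)`,
#' seeded and reproducible; the caller's RNG state is restored on exit.
#'
#' @param spec A [synthetic_spec()].
#' @param X Design matrix whose columns cover `spec$support`.
#' @return Numeric vector of length `nrow(X)`.
#' @export
generate_property <- function(spec, X) {
  stopifnot(inherits(spec, "synthetic_spec"))
  missing <- setdiff(spec$support, colnames(X))
  if (length(missing)) {
    stop("design matrix lacks support column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  mu <- if (length(spec$support)) {
    drop(X[, spec$support, drop = FALSE] %*% spec$beta) + spec$constant
  } else rep(spec$constant, nrow(X))
  mu + stats::rnorm(nrow(X), 0, spec$noise_sd)
}

#' Component supports with a well-conditioned, identifiable canonical design
#'
#' Enumerates supports of the given size whose canonical design
#' submatrix (with intercept) has 2-norm condition number below
#' `kappa_max`. With `identifiable = TRUE` (the default), supports
#' containing any column involved in an exact linear dependency of the
#' full design are also excluded: the canonical design has only 20 rows
#' and exact aliases among its count columns (for instance, every double
#' bond in a canonical amino acid is a double bond to O or to N, so the
#' any-double-bond column equals the sum of the two), and a signal
#' placed on an aliased column has multiple perfect representations.
#' Synthetic-recovery fixtures draw from this set so that a recovery
#' failure indicates a bug, not collinearity or aliasing.
#'
#' @param X Design matrix (default: canonical).
#' @param size Support size.
#' @param kappa_max Condition-number bound.
#' @param identifiable Exclude columns carrying exact design dependencies.
#' @return List of character vectors (supports).
#' @export
well_conditioned_supports <- function(X = NULL, size = 2L, kappa_max = 100,
                                      identifiable = TRUE) {
  if (is.null(X)) X <- build_design_matrix(canonical_aa_table())
  keys <- colnames(X)[apply(X, 2L, stats::var) > 0]
  if (identifiable) {
    M <- cbind(1, X[, keys, drop = FALSE])
    sv <- svd(M)
    null <- sv$v[, sv$d < 1e-8 * sv$d[1], drop = FALSE]
    aliased <- keys[rowSums(abs(null[-1, , drop = FALSE])) > 1e-8]
    keys <- setdiff(keys, aliased)
  }
  combs <- utils::combn(keys, size, simplify = FALSE)
  Filter(function(s) {
    M <- cbind(1, X[, s, drop = FALSE])
    kappa(M, exact = TRUE) < kappa_max
  }, combs)
}

#' Run the package self-test
#'
#' Recomputes the 4-hydroxyproline worked example against the published
#' EISD840101 model and runs a small noiseless parameter-recovery suite
#' over the canonical design matrix, printing pass/fail per check.
#'
#' @return TRUE (invisibly) if all checks pass, FALSE otherwise.
#' @export
selftest <- function() {
  ok <- TRUE
  report <- function(label, pass) {
    ok <<- ok && pass
    cat(sprintf("[%s] %s\n", if (pass) "PASS" else "FAIL", label))
  }
  hyp <- "O[C@H]1CN[C@@H](C1)C(O)=O"
  cv <- count_components(hyp)
  report("HYP component vector matches the published worked example",
         identical(unname(cv[component_keys()]),
                   unname(hyp_published_components())))
  m <- eisd840101_published_model()
  val <- predict_property(m, cv)
  report("EISD840101(HYP) = -0.34293 under the published coefficients",
         isTRUE(all.equal(round(val, 5), -0.34293, tolerance = 1e-8)))
  pe <- predict_with_error(m, cv)
  report("display rounding gives -0.343 +/- 0.282",
         round(pe[["value"]], 3) == -0.343 && pe[["rmse"]] == 0.282)

  X <- build_design_matrix(canonical_aa_table())
  supports <- well_conditioned_supports(X, size = 2L)[c(1, 5, 9)]
  rec_ok <- TRUE
  for (s in supports) {
    spec <- synthetic_spec(s, beta = c(1.5, -2), constant = 0.3,
                           noise_sd = 0, seed = 7L)
    y <- generate_property(spec, X)
    fit <- stepwise_select(X, y, F_threshold = 4)
    rec_ok <- rec_ok && setequal(fit$selected, s) &&
      max(abs(fit$b[s] - spec$beta[s])) < 1e-8 &&
      abs(fit$constant - spec$constant) < 1e-8
  }
  report("noiseless synthetic properties are recovered exactly", rec_ok)
  invisible(ok)
}
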