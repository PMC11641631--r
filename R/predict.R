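#' Predict one property value from a component vector
#'
#' The prediction is the dot product of the model's coefficients with the
#' corresponding component counts, plus the constant term.
#'
#' @param model An `"ncaa_model"` (trained or loaded).
#' @param cv Named component vector from [count_components()].
#' @return Predicted property value (full precision).
#' @export
#' @examples
#' m <- eisd840101_published_model()
#' predict_property(m, count_components("O[C@H]1CN[C@@H](C1)C(O)=O"))
predict_property <- function(model, cv) {
  missing <- setdiff(model$selected, names(cv))
  if (length(missing)) {
    stop("component vector lacks key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(model$selected)) return(model$constant)
  sum(model$b * as.numeric(cv[model$selected])) + model$constant
}

#' Predict a property value with its uncertainty
#'
#' Pairs the prediction with the model's stored RMSE (the LOO prediction
#' error over the canonical amino acids), the quantity reported as the
#' "plus/minus" on every non-canonical amino-acid prediction.
#'
#' @inheritParams predict_property
#' @return Named numeric vector `c(value = ..., rmse = ...)`, full
#'   precision (reports round to 3 decimals for display only).
#' @export
predict_with_error <- function(model, cv) {
  c(value = predict_property(model, cv), rmse = model$RMSE)
}

#' Build a predicted-property database over an ncAA table
#'
#' Applies the element-domain filter first: entries whose SMILES contains
#' an excluded element get no predictions and are listed with their
#' offending elements. Entries whose SMILES fails to tokenize are marked
#' failed and the build continues. Every kept entry receives one
#' prediction per model.
#'
#' @param models List of `"ncaa_model"` objects.
#' @param table ncAA table from [load_smiles_table()].
#' @param min_rjn Optional quality gate: predictions from models with
#'   r_jn below this value are suppressed (default `NULL`, no gate).
#' @param excluded Element exclusion list.
#' @return A list of class `"ncaa_database"`: `records` (per-ncAA list
#'   with code, name, smiles, kept, offending, predictions), `long`
#'   (data.frame code, accession, value, rmse, r_jn), `excluded`
#'   (data.frame of filtered entries), `failed` (character codes).
#' @export
build_database <- function(models, table, min_rjn = NULL,
                           excluded = excluded_elements()) {
  if (!is.null(min_rjn)) {
    models <- Filter(function(m) !is.na(m$r_jn) && m$r_jn >= min_rjn, models)
  }
  records <- list()
  failed <- character(0)
  excl_rows <- list()
  long_rows <- list()
  for (i in seq_len(nrow(table))) {
    code <- table$code[i]
    smi <- table$smiles[i]
    rep_ <- tryCatch(element_report(smi, excluded), error = function(e) e)
    if (inherits(rep_, "error")) {
      failed <- c(failed, code)
      records[[code]] <- list(code = code, name = table$name[i],
                              smiles = smi, kept = FALSE,
                              offending = character(0),
                              error = conditionMessage(rep_),
                              predictions = NULL)
      next
    }
    if (rep_$excluded_hit) {
      excl_rows[[length(excl_rows) + 1L]] <-
        data.frame(code = code,
                   offending = paste(rep_$offending, collapse = ","))
      records[[code]] <- list(code = code, name = table$name[i],
                              smiles = smi, kept = FALSE,
                              offending = rep_$offending,
                              predictions = NULL)
      next
    }
    cv <- count_components(smi)
    preds <- do.call(rbind, lapply(models, function(m) {
      pe <- predict_with_error(m, cv)
      data.frame(code = code, accession = m$accession,
                 value = unname(pe["value"]), rmse = unname(pe["rmse"]),
                 r_jn = m$r_jn)
    }))
    long_rows[[length(long_rows) + 1L]] <- preds
    records[[code]] <- list(code = code, name = table$name[i],
                            smiles = smi, kept = TRUE,
                            offending = character(0),
                            predictions = preds)
  }
  structure(list(
    records = records,
    long = if (length(long_rows)) do.call(rbind, long_rows) else
      data.frame(code = character(0), accession = character(0),
                 value = numeric(0), rmse = numeric(0), r_jn = numeric(0)),
    excluded = if (length(excl_rows)) do.call(rbind, excl_rows) else
      data.frame(code = character(0), offending = character(0)),
    failed = failed
  ), class = "ncaa_database")
}

#' Write a predicted-property database as TSV
#'
#' @param db An `"ncaa_database"` from [build_database()].
#' @param path Output path for the long-format table (one row per
#'   ncAA x property).
#' @param wide Optional path for a wide-format table (ncAA rows,
#'   property columns, full-precision values).
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path, wide = NULL) {
  utils::write.table(db$long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(wide) && nrow(db$long)) {
    w <- stats::reshape(db$long[, c("code", "accession", "value")],
                        idvar = "code", timevar = "accession",
                        direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    utils::write.table(w, wide, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.ncaa_database <- function(x, ...) {
  cat(sprintf("<ncaa_database> %d record(s): %d kept, %d excluded, %d failed\n",
              length(x$records),
              sum(vapply(x$records, function(r) isTRUE(r$kept), TRUE)),
              nrow(x$excluded), length(x$failed)))
  cat(sprintf("  %d prediction row(s) over %d propert%s\n",
              nrow(x$long), length(unique(x$long$accession)),
              if (length(unique(x$long$accession)) == 1L) "y" else "ies"))
  invisible(x)
}
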