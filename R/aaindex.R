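# AAindex1 flat files list 20 values per property on two I-section rows,
# in the fixed residue order below (first row A..I, second row L..V).
.aa_one_letter <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Canonical amino-acid ordering of AAindex property vectors
#'
#' @return The 20 one-letter codes in AAindex I-line order
#'   (A R N D C Q E G H I L K M F P S T W Y V).
#' @export
aaindex_order <- function() .aa_one_letter

#' Map 3-letter amino-acid codes to 1-letter codes
#'
#' @param code3 Character vector of canonical 3-letter codes.
#' @return Character vector of 1-letter codes; unknown codes are an error.
#' @export
aa_three_to_one <- function(code3) {
  out <- .aa_three_to_one[toupper(code3)]
  if (anyNA(out)) {
    stop("unknown canonical 3-letter code(s): ",
         paste(code3[is.na(out)], collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Parse an AAindex1 flat file
#'
#' Reads the standard AAindex1 record layout: records are separated by
#' "//"; the "H" line holds the accession, the "D" line the description,
#' and the line starting "I" is followed by two rows of ten values each
#' in the order A R N D C Q E G H I / L K M F P S T W Y V. The literal
#' token "NA" marks a missing value.
#'
#' @param x Path to an AAindex1 file, or a character vector of lines.
#' @return A list of property records, each a list with fields
#'   `accession`, `description`, `values` (named numeric of length 20 in
#'   [aaindex_order()], NA where masked), `na_mask` (named logical) and
#'   `value_strings` (the verbatim numeric tokens, for lossless re-emission).
#' @export
parse_aaindex1 <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  # split into records on lines equal to "//"
  recs <- list()
  cur <- character(0)
  for (ln in lines) {
    if (trimws(ln) == "//") {
      if (length(cur) && any(nzchar(trimws(cur)))) recs[[length(recs) + 1L]] <- cur
      cur <- character(0)
    } else {
      cur <- c(cur, ln)
    }
  }
  if (length(cur) && any(nzchar(trimws(cur)))) recs[[length(recs) + 1L]] <- cur

  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    rl <- recs[[k]]
    first <- substr(rl, 1L, 1L)
    h <- which(first == "H")
    iline <- which(first == "I")
    if (length(h) < 1L) {
      stop(sprintf("AAindex record %d: missing H (accession) line", k),
           call. = FALSE)
    }
    if (length(iline) < 1L) {
      stop(sprintf("AAindex record %d: missing I (index data) line", k),
           call. = FALSE)
    }
    accession <- trimws(sub("^H", "", rl[h[1]]))
    d <- which(first == "D")
    description <- if (length(d)) {
      # D text may continue on indented lines up to the next tagged line
      dtxt <- trimws(sub("^D", "", rl[d[1]]))
      j <- d[1] + 1L
      while (j <= length(rl) && first[j] == " " && j < iline[1]) {
        dtxt <- paste(dtxt, trimws(rl[j]))
        j <- j + 1L
      }
      dtxt
    } else ""
    if (iline[1] + 2L > length(rl)) {
      stop(sprintf("AAindex record %s: I line not followed by two value rows",
                   accession), call. = FALSE)
    }
    toks <- unlist(strsplit(trimws(rl[iline[1] + (1:2)]), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 20L) {
      stop(sprintf("AAindex record %s: expected 20 values, found %d",
                   accession, length(toks)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(toks))
    bad <- is.na(vals) & toks != "NA"
    if (any(bad)) {
      stop(sprintf("AAindex record %s: non-numeric value token(s): %s",
                   accession, paste(toks[bad], collapse = ", ")),
           call. = FALSE)
    }
    names(vals) <- .aa_one_letter
    na_mask <- is.na(vals)
    names(na_mask) <- .aa_one_letter
    out[[k]] <- list(accession = accession, description = description,
                     values = vals, na_mask = na_mask,
                     value_strings = toks)
  }
  out
}

#' Re-emit property records in AAindex1 layout
#'
#' Writes records back in the minimal H/D/I layout read by
#' [parse_aaindex1()]. Unmodified values are emitted from their verbatim
#' parsed tokens, so a parse/format round trip preserves every value
#' bit-exactly as a decimal string.
#'
#' @param records List of property records as returned by [parse_aaindex1()].
#' @return Character vector of lines.
#' @export
format_aaindex1 <- function(records) {
  lines <- character(0)
  for (r in records) {
    toks <- if (!is.null(r$value_strings)) r$value_strings else {
      ifelse(r$na_mask, "NA", format(r$values, trim = TRUE))
    }
    lines <- c(lines,
               paste("H", r$accession),
               paste("D", r$description),
               "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
               paste0("     ", paste(toks[1:10], collapse = "  ")),
               paste0("     ", paste(toks[11:20], collapse = "  ")),
               "//")
  }
  lines
}

#' Load an amino-acid SMILES table
#'
#' Reads a tab-separated table with columns `code`, `name`, `smiles`
#' (an optional `one_letter` column is kept if present). Codes must be
#' unique and every SMILES must tokenize and pass ring-closure validation.
#'
#' @param path Path to a TSV file, or a connection.
#' @return A data.frame with the table's columns, codes as character.
#' @export
load_smiles_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  need <- c("code", "name", "smiles")
  if (!all(need %in% names(tab))) {
    stop("SMILES table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab$code[duplicated(tab$code)]
  if (length(dup)) {
    stop("duplicate code(s) in SMILES table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch(smiles_validate(tab$smiles[i]), error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("invalid SMILES for code %s: %s",
                   tab$code[i], conditionMessage(res)), call. = FALSE)
    }
  }
  tab
}

#' Build the component design matrix for an amino-acid table
#'
#' Featurizes every SMILES in the table with [count_components()] and
#' stacks the 13-count vectors into an integer matrix: one row per amino
#' acid in table order, one column per component in [component_keys()]
#' order.
#'
#' @param table A data.frame as returned by [load_smiles_table()].
#' @return Integer matrix with rownames `table$code`.
#' @export
build_design_matrix <- function(table) {
  X <- t(vapply(table$smiles, count_components,
                integer(length(component_keys()))))
  rownames(X) <- table$code
  colnames(X) <- component_keys()
  X
}

.model_schema <- "ncaaprop-models"
.model_schema_version <- 1L

#' Save trained property models to a JSON store
#'
#' @param models List of trained models as returned by
#'   [optimize_threshold()] or [train_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_models()]
#' @export
save_models <- function(models, path) {
  doc <- list(
    schema = .model_schema,
    version = .model_schema_version,
    rmse_definition = "loo",
    na_policy = "drop-masked",
    models = lapply(models, function(m) {
      list(accession = m$accession,
           description = m$description %||% "",
           selected = as.list(m$selected),
           b = as.list(m$b),
           constant = m$constant,
           F_star = m$F_star,
           r_jn = m$r_jn,
           r_insample = m$r_insample,
           P_num = m$P_num,
           RMSE = m$RMSE,
           n_used = m$n_used,
           perfect_fit = isTRUE(m$perfect_fit))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load trained property models from a JSON store
#'
#' @param path Path to a file written by [save_models()].
#' @return List of trained-model objects.
#' @export
load_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, .model_schema) ||
      !identical(as.integer(doc$version), .model_schema_version)) {
    stop(sprintf("model store schema mismatch: expected %s v%d",
                 .model_schema, .model_schema_version), call. = FALSE)
  }
  lapply(doc$models, function(m) {
    selected <- as.character(unlist(m$selected))
    unknown <- setdiff(selected, component_keys())
    if (length(unknown)) {
      stop("unknown component key(s) in model store: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    b <- as.numeric(unlist(m$b))
    if (length(b) != length(selected)) {
      stop(sprintf("model %s: coefficient/selected length mismatch",
                   m$accession), call. = FALSE)
    }
    names(b) <- selected
    null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    structure(list(
      accession = m$accession,
      description = if (is.null(m$description)) "" else m$description,
      selected = selected,
      b = b,
      constant = as.numeric(m$constant),
      F_star = null2na(m$F_star),
      r_jn = null2na(m$r_jn),
      r_insample = null2na(m$r_insample),
      P_num = as.integer(m$P_num),
      RMSE = null2na(m$RMSE),
      n_used = as.integer(m$n_used),
      perfect_fit = isTRUE(m$perfect_fit)
    ), class = "ncaa_model")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
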