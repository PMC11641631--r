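# Organic-subset atom symbols writable without brackets; two-letter symbols
# must be matched before their one-letter prefixes (Cl before C, Br before B).
.organic_two <- c("Cl", "Br")
.organic_one <- c("B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s")
.bond_chars <- c("-", "=", "#", "$", ":", "/", "\\", "~")

#' The 13 SMILES component keys
#'
#' Returns the names of the 13 substring-count descriptors, in their fixed
#' reporting order, used as regression predictors throughout the package:
#' double-bonded oxygen, any oxygen, non-aromatic nitrogen, aromatic
#' nitrogen, double-bonded nitrogen, non-aromatic carbon, aromatic carbon,
#' chiral carbon, sulfur, first ring closure, second ring closure, any
#' double bond, and positive charge.
#'
#' @return Character vector of length 13.
#' @export
#' @examples
#' component_keys()
component_keys <- function() {
  c("dblO", "anyO", "aliphN", "aromN", "dblN", "aliphC", "aromC",
    "chiralC", "S", "ring1", "ring2", "dbl", "plus")
}

#' Elements outside the canonical amino-acid domain
#'
#' Chemical elements that never occur in the 20 canonical amino acids.
#' Amino acids containing any of them are outside the training domain of
#' the property models and are filtered out of prediction databases.
#'
#' @return Character vector of element symbols.
#' @export
excluded_elements <- function() {
  c("As", "B", "Br", "Cl", "F", "I", "P", "Se")
}

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom, bond, ring-closure and branch tokens.
#' Bracket atoms carry their parsed element symbol; two-letter symbols
#' (Cl, Br, Se, As, ...) are recognized both inside brackets and, for the
#' organic subset, outside them, so element tests never confuse "Cl" with
#' carbon or "Se" with sulfur. Aromatic lowercase atoms are reported with
#' their capitalized element symbol.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A data.frame with columns `token`, `type` (one of "atom",
#'   "bond", "ring", "branch_open", "branch_close", "dot"), `element`
#'   (NA for non-atom tokens) and `pos` (1-based character offset).
#'   The attribute `"two_letter_mask"` is a logical vector over the input
#'   characters marking characters that belong to a two-letter element
#'   symbol; concatenating `token` reproduces the input.
#' @export
#' @examples
#' smiles_tokenize("CSC[C@H](N)C(O)=O")
smiles_tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single character string", call. = FALSE)
  }
  if (!nzchar(smiles)) {
    stop("empty SMILES string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mask <- logical(n)
  tok <- vector("list", n)
  ntok <- 0L
  add <- function(token, type, element, pos) {
    ntok <<- ntok + 1L
    tok[[ntok]] <<- list(token = token, type = type,
                         element = element, pos = pos)
  }
  depth <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unclosed '[' at position %d in \"%s\"", i, smiles),
             call. = FALSE)
      }
      lex <- substr(smiles, i, j)
      body <- substr(smiles, i + 1L, j - 1L)
      # optional isotope digits, then the element symbol
      off <- regmatches(body, regexpr("^[0-9]*", body))
      rest <- substr(body, nchar(off) + 1L, nchar(body))
      m <- regexpr("^([A-Z][a-z]?|as|se|[bcnops]|\\*)", rest)
      if (m == -1L) {
        stop(sprintf("cannot parse bracket atom \"%s\" at position %d",
                     lex, i), call. = FALSE)
      }
      sym <- regmatches(rest, m)
      elem <- if (sym == "*") NA_character_ else
        paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
      if (!is.na(elem) && nchar(sym) == 2L) {
        start <- i + nchar(off) + 1L
        mask[start:(start + 1L)] <- TRUE
      }
      add(lex, "atom", elem, i)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .organic_two) {
      add(paste0(ch, chars[i + 1L]), "atom", paste0(ch, chars[i + 1L]), i)
      mask[i:(i + 1L)] <- TRUE
      i <- i + 2L
    } else if (ch %in% .organic_one) {
      elem <- if (ch %in% c("b", "c", "n", "o", "p", "s")) toupper(ch) else ch
      add(ch, "atom", elem, i)
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      add(ch, "ring", NA_character_, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
        stop(sprintf("'%%' ring closure at position %d needs two digits", i),
             call. = FALSE)
      }
      add(substr(smiles, i, i + 2L), "ring", NA_character_, i)
      i <- i + 3L
    } else if (ch == "(") {
      depth <- depth + 1L
      add(ch, "branch_open", NA_character_, i)
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("unbalanced ')' at position %d in \"%s\"", i, smiles),
             call. = FALSE)
      }
      add(ch, "branch_close", NA_character_, i)
      i <- i + 1L
    } else if (ch %in% .bond_chars) {
      add(ch, "bond", NA_character_, i)
      i <- i + 1L
    } else if (ch == ".") {
      add(ch, "dot", NA_character_, i)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d in \"%s\"",
                   ch, i, smiles), call. = FALSE)
    }
  }
  if (depth > 0L) {
    stop(sprintf("unbalanced '(' in \"%s\"", smiles), call. = FALSE)
  }
  tok <- tok[seq_len(ntok)]
  last <- tok[[ntok]]
  if (last$type == "bond") {
    stop(sprintf("dangling bond '%s' at position %d in \"%s\"",
                 last$token, last$pos, smiles), call. = FALSE)
  }
  out <- data.frame(
    token = vapply(tok, `[[`, "", "token"),
    type = vapply(tok, `[[`, "", "type"),
    element = vapply(tok, `[[`, "", "element"),
    pos = vapply(tok, function(t) as.integer(t$pos), 0L),
    stringsAsFactors = FALSE
  )
  attr(out, "two_letter_mask") <- mask
  out
}

#' Validate a SMILES string
#'
#' Tokenizes the string and additionally checks that every ring-closure
#' digit occurs an even number of times (every opened ring is closed).
#'
#' @param smiles A single SMILES string.
#' @return The token data.frame from [smiles_tokenize()], invisibly usable.
#' @export
smiles_validate <- function(smiles) {
  tok <- smiles_tokenize(smiles)
  rings <- tok$token[tok$type == "ring"]
  if (length(rings)) {
    cnt <- table(rings)
    odd <- names(cnt)[cnt %% 2L != 0L]
    if (length(odd)) {
      stop(sprintf("ring closure(s) %s appear an odd number of times in \"%s\"",
                   paste(odd, collapse = ", "), smiles), call. = FALSE)
    }
  }
  tok
}

#' Element symbols present in a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return Character vector of unique element symbols (hydrogens written
#'   only inside bracket atoms are not reported as atoms of their own).
#' @export
smiles_elements <- function(smiles) {
  tok <- smiles_tokenize(smiles)
  unique(tok$element[tok$type == "atom" & !is.na(tok$element)])
}

#' Report excluded-element content of a SMILES string
#'
#' @param smiles A single SMILES string.
#' @param excluded Character vector of element symbols defining the
#'   excluded domain; defaults to [excluded_elements()].
#' @return A list with `elements` (all element symbols present),
#'   `offending` (the subset in `excluded`) and `excluded_hit` (TRUE iff
#'   `offending` is non-empty).
#' @export
element_report <- function(smiles, excluded = excluded_elements()) {
  elems <- smiles_elements(smiles)
  offending <- intersect(elems, excluded)
  list(elements = elems, offending = offending,
       excluded_hit = length(offending) > 0L)
}

#' Does a SMILES string contain an excluded element?
#'
#' Matching is by parsed element symbol, never raw substring, so "CCl"
#' flags chlorine without flagging via carbon and "C[Se]C" flags selenium
#' without involving sulfur.
#'
#' @inheritParams element_report
#' @return TRUE iff any atom's element is in `excluded`.
#' @export
#' @examples
#' contains_excluded_element("CSC")    # FALSE
#' contains_excluded_element("C[Se]C") # TRUE
contains_excluded_element <- function(smiles, excluded = excluded_elements()) {
  element_report(smiles, excluded)$excluded_hit
}

# number of (non-overlapping) occurrences of a fixed substring
.count_fixed <- function(s, pat) {
  m <- gregexpr(pat, s, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Count the 13 SMILES components of an amino acid
#'
#' Computes the 13 integer substring-count descriptors by case-sensitive
#' literal pattern counting over the raw SMILES string (the counting is
#' defined on the string as distributed, not on a perceived molecular
#' graph). Counts deliberately overlap: every "=O" also counts toward "O"
#' and toward "="; every "\[C@" also counts toward "C". Atom letters inside
#' brackets count toward their component. The letters of a two-letter
#' element symbol (such as Cl) never count toward one-letter components;
#' such elements do not occur in the modeling domain, but the tokenizer
#' enforces the distinction regardless.
#'
#' Ring components count an atom letter in {c, C, n, N, S} immediately
#' followed by the closure digit '1' (first ring) or '2' (second ring).
#' Closure digits of 3 and above, and '%nn' closures, have no component;
#' their presence is recorded in the `"deep_rings"` attribute.
#'
#' @param smiles A single SMILES string; the empty string is an error.
#' @return Named integer vector over [component_keys()], with attribute
#'   `"deep_rings"` (number of ring-closure tokens beyond the second ring).
#' @export
#' @examples
#' count_components("O[C@H]1CN[C@@H](C1)C(O)=O") # 4-hydroxyproline
count_components <- function(smiles) {
  tok <- smiles_validate(smiles)
  mask <- attr(tok, "two_letter_mask")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  ok <- !mask
  n <- length(chars)
  nxt <- c(chars[-1], "")

  ring_at <- function(digit) {
    sum(chars %in% c("c", "C", "n", "N", "S") & ok & nxt == digit)
  }

  counts <- c(
    dblO    = .count_fixed(smiles, "=O") + .count_fixed(smiles, "O="),
    anyO    = sum(chars == "O" & ok),
    aliphN  = sum(chars == "N" & ok),
    aromN   = sum(chars == "n" & ok),
    dblN    = .count_fixed(smiles, "=N") + .count_fixed(smiles, "N=") +
              .count_fixed(smiles, "=[N"),
    aliphC  = sum(chars == "C" & ok),
    aromC   = sum(chars == "c" & ok),
    chiralC = .count_fixed(smiles, "[C@"),
    S       = sum(chars == "S" & ok),
    ring1   = ring_at("1"),
    ring2   = ring_at("2"),
    dbl     = sum(chars == "="),
    plus    = sum(chars == "+")
  )
  counts <- as.integer(counts)
  names(counts) <- component_keys()

  rings <- tok$token[tok$type == "ring"]
  deep <- sum(!(rings %in% c("1", "2")))
  if (deep > 0L && isTRUE(getOption("ncaaprop.verbose", FALSE))) {
    message(sprintf("note: %d ring closure token(s) beyond the second ring in \"%s\" carry no component",
                    deep, smiles))
  }
  attr(counts, "deep_rings") <- as.integer(deep)
  counts
}
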