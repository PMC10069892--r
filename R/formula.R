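#' Parse an elemental formula in Hill notation
#'
#' Returns a named integer vector of element counts, or `NULL` when the
#' formula is absent or unusable for atom accounting. A trailing charge
#' suffix (`+`, `-`, optionally with digits, e.g. `"C6H11O9P-2"`) is
#' stripped. Formulas containing generic group symbols (`R`, `X`, `*`) have
#' undefined atom counts and are treated as unusable.
#'
#' @param formula a single character string (or `NA`).
#' @return named numeric vector of element counts, or `NULL`.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C10H16N5O13P3")
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(formula)) {
    return(NULL)
  }
  f <- sub("[+-][0-9]*$", "", formula)
  if (grepl("[*().]", f)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
  parts <- regmatches(f, list(m))[[1]]
  if (length(parts) == 0 || sum(attr(m, "match.length")) != nchar(f)) {
    return(NULL)
  }
  elems <- sub("[0-9]*$", "", parts)
  # Generic groups make atom counts undefined.
  if (any(elems %in% c("R", "X")) || any(grepl("^R[a-z]?$", elems) & elems == "R")) {
    return(NULL)
  }
  counts <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", parts)))
  counts[is.na(counts)] <- 1
  out <- tapply(counts, elems, sum)
  structure(as.numeric(out), names = names(out))
}

#' Number of atoms of one element in a formula
#' @param formula formula string.
#' @param element element symbol, default `"C"`.
#' @return atom count, or `NA` if the formula is unusable.
#' @export
element_count <- function(formula, element = "C") {
  p <- parse_formula(formula)
  if (is.null(p)) return(NA_real_)
  v <- p[element]
  if (is.na(v)) 0 else unname(v)
}
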