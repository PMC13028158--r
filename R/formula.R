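#' Parse a molecular formula over C, H, O, S
#'
#' Formulas are accepted permissively: Hill order (`"C2H4O4S"`), the
#' sulfur-before-oxygen order used in much of the bisulfite literature
#' (`"C2H4SO4"`), single atoms without a count (`"CO2"`, `"H2SO3"`), and
#' repeated element tokens (counts are summed). Only the elements C, H, O
#' and S are representable; anything else is an error.
#'
#' @param x Character scalar, e.g. `"C2H4SO4"`.
#' @return Named integer vector with entries `C`, `H`, `O`, `S`.
#' @examples
#' parse_formula("C2H4SO4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  s <- gsub("[[:space:]_]", "", x)
  counts <- c(C = 0L, H = 0L, O = 0L, S = 0L)
  m <- gregexpr("([A-Za-z][a-z]?)([0-9]*)", s)[[1]]
  consumed <- 0L
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    tok <- substr(s, starts[i], starts[i] + lens[i] - 1L)
    consumed <- consumed + lens[i]
    el <- sub("^([A-Za-z][a-z]?).*$", "\\1", tok)
    n <- sub("^[A-Za-z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% ELEMENTS) {
      stop(sprintf("unsupported element '%s' in formula '%s' (only C, H, O, S)", el, x),
           call. = FALSE)
    }
    counts[el] <- counts[el] + n
  }
  if (consumed != nchar(s)) {
    stop(sprintf("could not parse formula '%s'", x), call. = FALSE)
  }
  if (sum(counts) == 0L) {
    stop(sprintf("formula '%s' has no atoms", x), call. = FALSE)
  }
  counts
}

#' Render an element-count vector as a Hill-order formula string
#'
#' @param counts Named integer vector over `C`, `H`, `O`, `S`.
#' @return Character scalar such as `"C2H4O4S"`.
#' @export
format_formula <- function(counts) {
  counts <- counts[ELEMENTS]
  counts[is.na(counts)] <- 0L
  parts <- character(0)
  for (el in c("C", "H", "O", "S")) {
    n <- counts[[el]]
    if (n > 0L) {
      parts <- c(parts, if (n == 1L) el else paste0(el, n))
    }
  }
  paste0(parts, collapse = "")
}

# Element-count matrix (4 x n) from a character vector of formulas.
formula_matrix <- function(formulas) {
  m <- vapply(formulas, parse_formula, integer(4L))
  rownames(m) <- ELEMENTS
  m
}
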