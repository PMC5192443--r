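#' Parse a molecular formula string
#'
#' Parses a Hill-style element-count string (e.g. `"C4H7NO4"`) into a named
#' integer vector of element counts. Element symbols without an explicit count
#' default to 1; repeated symbols are summed. Charges, isotope labels and
#' grouping parentheses are not supported.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts (class `molecular_formula`).
#' @examples
#' parse_formula("C4H7NO4")
#' parse_formula("C5H10BO7")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula '", text, "': unexpected characters", call. = FALSE)
  }
  symbols <- sub("[0-9]*$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(symbols, names(.isotope_data))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s) in '", text, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(counts, factor(symbols, levels = unique(symbols)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[out > 0]
  class(out) <- "molecular_formula"
  out
}

.as_formula <- function(formula) {
  if (inherits(formula, "molecular_formula")) return(formula)
  if (is.character(formula)) return(parse_formula(formula))
  if (is.numeric(formula) && length(formula) == 0) {
    return(structure(integer(0), class = "molecular_formula"))
  }
  if (is.numeric(formula) && !is.null(names(formula))) {
    if (any(formula < 0) || any(formula != round(formula))) {
      stop("element counts must be non-negative integers", call. = FALSE)
    }
    unknown <- setdiff(names(formula), names(.isotope_data))
    if (length(unknown) > 0) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out <- as.integer(formula)
    names(out) <- names(formula)
    out <- out[out > 0]
    class(out) <- "molecular_formula"
    return(out)
  }
  stop("`formula` must be a formula string or named element-count vector",
       call. = FALSE)
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  # Hill order: C, H, then alphabetical
  nm <- names(x)
  ord <- order(match(nm, c("C", "H"), nomatch = 3L), nm)
  paste0(nm[ord], ifelse(unclass(x)[ord] == 1, "", unclass(x)[ord]),
         collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic (exact) mass of a molecular formula
#'
#' Sums, over all elements, the element count times the mass of its lightest
#' isotope. Neutral masses; the electron mass is ignored.
#'
#' @param formula A formula string, a `molecular_formula`, or a character
#'   vector of formula strings (vectorised).
#' @return Exact mass(es) in dalton; an empty formula has mass 0.
#' @examples
#' exact_mass("C4H7NO4")   # 133.037508
#' exact_mass("C29H44O8")  # 520.303618
#' @export
exact_mass <- function(formula) {
  if (is.character(formula) && length(formula) > 1) {
    return(vapply(formula, function(f) exact_mass(f), numeric(1),
                  USE.NAMES = FALSE))
  }
  f <- if (is.character(formula) && length(formula) == 1 && !nzchar(formula)) {
    structure(integer(0), class = "molecular_formula")
  } else {
    .as_formula(formula)
  }
  if (length(f) == 0) return(0)
  mono <- vapply(names(f), function(el) .isotope_data[[el]]$mass[1], numeric(1))
  sum(unclass(f) * mono)
}
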