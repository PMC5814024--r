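# Chemical formulas are named numeric vectors (element symbol -> count) in
# canonical form: strictly positive counts, Hill element order, S3 class
# "chemFormula", with a logical "variable" attribute marking formulas of
# indeterminate composition (repeat variables, dot-separated composites).

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

# lowercase letters accepted as repeat variables ("(C2H4O)n" and friends)
.REPEAT_VARS <- c("n", "m", "x", "y")

.hillOrder <- function(els) {
  if ("C" %in% els) {
    c("C", intersect("H", els), sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els)
  }
}

# canonical constructor; drops zero counts, orders elements, attaches class
.formula <- function(counts = numeric(0), variable = FALSE) {
  counts <- counts[!is.na(counts) & counts != 0]
  if (any(counts < 0)) {
    stop("formula counts must be non-negative")
  }
  if (length(counts)) {
    agg <- tapply(counts, names(counts), sum)
    counts <- as.numeric(agg)
    names(counts) <- names(agg)
    counts <- counts[.hillOrder(names(counts))]
  } else {
    counts <- numeric(0)
    names(counts) <- character(0)
  }
  structure(counts, class = "chemFormula", variable = isTRUE(variable))
}

#' Test whether a formula has indeterminate composition
#'
#' Formulas containing a repeat variable (e.g. \code{"(C2H4O)n"}) or a
#' dot-separated composite notation cannot take part in element arithmetic;
#' they are flagged at parse time and rejected by all arithmetic operations.
#'
#' @param f a \code{chemFormula} as returned by [parseFormula()].
#' @return \code{TRUE} if the formula is variable, \code{FALSE} otherwise.
#' @export
isVariableFormula <- function(f) {
  isTRUE(attr(f, "variable"))
}

.assertArithmetic <- function(f, what = "formula") {
  if (!inherits(f, "chemFormula")) {
    stop(what, " is not a chemFormula object")
  }
  if (isVariableFormula(f)) {
    stop(what, " has indeterminate (variable) composition and cannot be ",
         "used in element arithmetic")
  }
  invisible(f)
}

# find index of matching ')' for '(' at position i
.matchParen <- function(chars, i) {
  depth <- 0L
  for (j in i:length(chars)) {
    if (chars[j] == "(") depth <- depth + 1L
    if (chars[j] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(j)
    }
  }
  stop("unmatched '(' at position ", i)
}

# recursive parse of a formula substring; returns list(counts, variable)
.parseFragment <- function(txt, full) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  counts <- numeric(0)
  variable <- FALSE
  i <- 1L
  readInt <- function(i) {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    list(value = if (j > i) as.numeric(paste(chars[i:(j - 1)], collapse = ""))
                 else NA_real_,
         nxt = j)
  }
  add <- function(cts, el, k) {
    cts[el] <- if (el %in% names(cts)) cts[[el]] + k else k
    cts
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- .matchParen(chars, i)
      innerTxt <- if (j - i > 1) {
        paste(chars[(i + 1):(j - 1)], collapse = "")
      } else {
        ""
      }
      inner <- if (nzchar(innerTxt)) {
        .parseFragment(innerTxt, full)
      } else {
        list(counts = numeric(0), variable = FALSE)
      }
      variable <- variable || inner$variable
      i <- j + 1L
      mult <- 1
      if (i <= n && grepl("[0-9]", chars[i])) {
        r <- readInt(i)
        mult <- r$value
        i <- r$nxt
      } else if (i <= n && chars[i] %in% .REPEAT_VARS) {
        variable <- TRUE
        i <- i + 1L
      }
      if (!variable) {
        for (el in names(inner$counts)) {
          counts <- add(counts, el, inner$counts[[el]] * mult)
        }
      }
    } else if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (i < n && grepl("[a-z]", chars[i + 1]) &&
          paste0(ch, chars[i + 1]) %in% .ELEMENTS) {
        sym <- paste0(ch, chars[i + 1])
        i <- i + 1L
      } else if (!ch %in% .ELEMENTS) {
        stop("unknown element symbol '", ch, "' in formula '", full,
             "' at position ", i)
      }
      i <- i + 1L
      k <- 1
      if (i <= n && grepl("[0-9]", chars[i])) {
        r <- readInt(i)
        k <- r$value
        i <- r$nxt
      } else if (i <= n && chars[i] %in% .REPEAT_VARS &&
                 !(i < n && grepl("[a-z]", chars[i + 1]))) {
        # trailing letter exponent, e.g. "C2H4On"
        variable <- TRUE
        i <- i + 1L
      }
      counts <- add(counts, sym, k)
    } else if (grepl("[a-z]", ch)) {
      if (ch %in% .REPEAT_VARS) {
        variable <- TRUE
        i <- i + 1L
      } else {
        stop("unknown element symbol '", ch, "' in formula '", full,
             "' at position ", i)
      }
    } else if (grepl("[0-9]", ch)) {
      stop("dangling digit '", ch, "' in formula '", full, "' at position ",
           i, " (no preceding element)")
    } else {
      stop("unexpected character '", ch, "' in formula '", full,
           "' at position ", i)
    }
  }
  list(counts = counts, variable = variable)
}

#' Parse a chemical formula string
#'
#' Accepts Hill-style formulas over standard one/two-letter element symbols
#' with optional integer counts (\code{"C6H12O6"}, \code{"H"}), parenthesized
#' groups with integer multipliers (\code{"Fe(CN)6"}), and the two notations
#' that mark a formula as having indeterminate composition: a repeat variable
#' (a trailing lowercase exponent such as \code{"(C2H4O)n"}) and
#' dot-separated composites (\code{"CuSO4.5H2O"}). Indeterminate formulas are
#' returned with the variable flag set (see [isVariableFormula()]) and are
#' excluded from all arithmetic. A trailing charge annotation (\code{"+"},
#' \code{"2-"}, ...) is stripped and ignored. Unknown element symbols and
#' dangling digits raise a parse error identifying the offending span.
#'
#' @param text a single non-empty formula string.
#' @return a \code{chemFormula}: a named numeric vector of element counts in
#'   canonical (Hill-ordered, positive-count) form.
#' @examples
#' parseFormula("C6H12O6")
#' parseFormula("H")
#' isVariableFormula(parseFormula("(C2H4O)n"))
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula text must be a single non-empty string")
  }
  txt <- trimws(text)
  # charge annotations carry no element information
  txt <- sub("([0-9]*[+-]|[+-][0-9]*)$", "", txt)
  if (!nzchar(txt)) {
    stop("formula '", text, "' contains no element information")
  }
  if (grepl(".", txt, fixed = TRUE)) {
    # dot-separated composite: indeterminate composition
    return(.formula(variable = TRUE))
  }
  parsed <- .parseFragment(txt, full = text)
  if (parsed$variable) {
    return(.formula(variable = TRUE))
  }
  if (length(parsed$counts) && any(parsed$counts != round(parsed$counts))) {
    return(.formula(variable = TRUE))
  }
  .formula(parsed$counts)
}

#' Render a formula in canonical Hill notation
#'
#' Elements are ordered carbon, hydrogen, then alphabetically (plain
#' alphabetical when no carbon is present); counts of one are omitted.
#' The empty formula renders as \code{""}.
#'
#' @param f a non-variable \code{chemFormula}.
#' @return a single character string.
#' @examples
#' formulaToText(parseFormula("O6C6H12"))  # "C6H12O6"
#' @export
formulaToText <- function(f) {
  .assertArithmetic(f)
  if (!length(f)) {
    return("")
  }
  v <- as.numeric(f)
  paste0(names(f), ifelse(v == 1, "", as.character(v)), collapse = "")
}

#' @export
print.chemFormula <- function(x, ...) {
  if (isVariableFormula(x)) {
    cat("<chemFormula: variable composition>\n")
  } else if (!length(x)) {
    cat("<chemFormula: empty>\n")
  } else {
    cat("<chemFormula:", formulaToText(x), ">\n")
  }
  invisible(x)
}

#' Element-wise formula difference
#'
#' Subtracts the counts of \code{b} from \code{a}. Every element of \code{b}
#' must be present in \code{a} with at least the same count; this is the
#' residue-update step after an element transfer.
#'
#' @param a,b non-variable \code{chemFormula} objects.
#' @return the canonical difference as a \code{chemFormula}.
#' @examples
#' subtractCounts(parseFormula("C6H12O6"), parseFormula("C6H11O6"))  # H
#' @export
subtractCounts <- function(a, b) {
  .assertArithmetic(a, "first formula")
  .assertArithmetic(b, "second formula")
  els <- union(names(a), names(b))
  av <- as.numeric(a)[match(els, names(a))]
  bv <- as.numeric(b)[match(els, names(b))]
  av[is.na(av)] <- 0
  bv[is.na(bv)] <- 0
  d <- av - bv
  if (any(d < -1e-9)) {
    bad <- els[d < -1e-9][1]
    stop("cannot subtract: element '", bad, "' count ", bv[els == bad],
         " exceeds ", av[els == bad])
  }
  d[abs(d) < 1e-9] <- 0
  names(d) <- els
  .formula(d)
}

#' Shared element counts of two formulas
#'
#' The element-wise minimum of two formulas: the count of every element
#' shared between them. This defines the element transfer between a selected
#' reactant/product instance pair.
#'
#' @param a,b non-variable \code{chemFormula} objects.
#' @return the canonical element-wise minimum as a \code{chemFormula}.
#' @examples
#' sharedCounts(parseFormula("C5H4O5"), parseFormula("CO2"))  # CO2
#' @export
sharedCounts <- function(a, b) {
  .assertArithmetic(a, "first formula")
  .assertArithmetic(b, "second formula")
  els <- intersect(names(a), names(b))
  if (!length(els)) {
    return(.formula())
  }
  m <- pmin(as.numeric(a)[match(els, names(a))],
            as.numeric(b)[match(els, names(b))])
  names(m) <- els
  .formula(m)
}

#' Does a formula contain a given element?
#'
#' @param f a non-variable \code{chemFormula}.
#' @param element an element symbol; carbon by default (the network
#'   visualization filter keeps carbon-containing compounds only).
#' @return \code{TRUE} iff the element occurs with count >= 1.
#' @examples
#' containsCarbon(parseFormula("CO2"))  # TRUE
#' containsCarbon(parseFormula("NH3"))  # FALSE
#' @export
containsCarbon <- function(f, element = "C") {
  .assertArithmetic(f)
  element %in% names(f) && f[[element]] >= 1
}
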