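# reaction balance checking

#' Check elemental balance of a reaction
#'
#' Computes, for every element occurring in the reaction, the
#' stoichiometry-weighted signed difference (products minus reactants).
#' A reaction is considered balanced when every non-hydrogen element
#' difference is zero; the hydrogen difference is reported separately and
#' never affects the flag, since hydrogen bookkeeping (protons, water) is
#' routinely inconsistent in metabolic models.
#'
#' @param reaction a reaction as returned by [getReaction()].
#' @param formulas a named list of parsed formulas covering every compound
#'   of the reaction (see [compoundFormulas()]).
#' @return an object of class \code{balanceReport}: a list with
#'   \code{differences} (named numeric, non-hydrogen elements),
#'   \code{hydrogen} (the hydrogen difference) and \code{balanced}.
#' @examples
#' rs <- toyModel()
#' checkBalance(getReaction(rs, "HEX1"), compoundFormulas(rs))
#' @export
checkBalance <- function(reaction, formulas) {
  totals <- numeric(0)
  accumulate <- function(side, sign) {
    for (k in seq_len(nrow(side))) {
      cid <- side$compound[k]
      f <- formulas[[cid]]
      if (is.null(f) || isVariableFormula(f)) {
        stop("balance undecidable: compound '", cid,
             "' has no usable formula")
      }
      for (el in names(f)) {
        cur <- if (el %in% names(totals)) totals[[el]] else 0
        totals[el] <<- cur + sign * side$coef[k] * f[[el]]
      }
    }
  }
  accumulate(reaction$reactants, -1)
  accumulate(reaction$products, +1)
  totals[abs(totals) < 1e-9] <- 0
  hydrogen <- if ("H" %in% names(totals)) totals[["H"]] else 0
  differences <- totals[setdiff(names(totals), "H")]
  structure(list(differences = differences,
                 hydrogen = hydrogen,
                 balanced = all(differences == 0)),
            class = "balanceReport")
}

#' @export
print.balanceReport <- function(x, ...) {
  cat("balanceReport:", if (x$balanced) "balanced" else "UNBALANCED",
      "(non-hydrogen elements)\n")
  nz <- x$differences[x$differences != 0]
  if (length(nz)) {
    cat("  imbalances:",
        paste(names(nz), sprintf("%+g", nz), collapse = ", "), "\n")
  }
  if (x$hydrogen != 0) {
    cat(sprintf("  hydrogen difference: %+g (ignored for the flag)\n",
                x$hydrogen))
  }
  invisible(x)
}
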