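# model tables: readers, writers, reaction-exclusion filters
#
# Dialects (all tab-separated, header required):
#   compounds.tsv : id, formula, [name], [compartment]
#   reactions.tsv : id, equation, [synthetic]
#   pairs.tsv     : reaction, reactant, product
# Equation dialect: "2 A + B => C + D" (irreversible) or "<=>" (reversible);
# compound tokens may carry a "[c]"-style compartment suffix.

.parseEquation <- function(eq, rid) {
  eq <- trimws(eq)
  reversible <- grepl("<=>", eq, fixed = TRUE) || grepl("<->", eq, fixed = TRUE)
  parts <- strsplit(eq, "<=>|<->|=>|->")[[1]]
  if (length(parts) > 2L ||
      !grepl("<=>|<->|=>|->", eq)) {
    stop("reaction '", rid, "': cannot parse equation '", eq, "'")
  }
  if (length(parts) == 1L) parts <- c(parts, "")
  side <- function(txt) {
    txt <- trimws(txt)
    if (!nzchar(txt)) {
      return(data.frame(compound = character(0), coef = numeric(0),
                        stringsAsFactors = FALSE))
    }
    terms <- trimws(strsplit(txt, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
    terms <- terms[nzchar(terms)]
    coef <- rep(1, length(terms))
    compound <- character(length(terms))
    for (k in seq_along(terms)) {
      m <- regmatches(terms[k],
                      regexec("^([0-9]+\\.?[0-9]*|\\.[0-9]+)\\s+(.+)$",
                              terms[k]))[[1]]
      if (length(m)) {
        coef[k] <- as.numeric(m[2])
        compound[k] <- m[3]
      } else {
        compound[k] <- terms[k]
      }
    }
    data.frame(compound = compound, coef = coef, stringsAsFactors = FALSE)
  }
  list(reactants = side(parts[1]), products = side(parts[2]),
       reversible = reversible)
}

.renderEquation <- function(r) {
  term <- function(df) {
    if (!nrow(df)) return("")
    paste(ifelse(df$coef == 1, df$compound,
                 paste(df$coef, df$compound)), collapse = " + ")
  }
  paste(term(r$reactants), if (r$reversible) "<=>" else "=>",
        term(r$products))
}

.readTable <- function(path, required, what) {
  if (!file.exists(path)) {
    stop("missing ", what, " table: ", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

.asFlag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

#' Read a reaction set from a model directory
#'
#' Loads \code{compounds.tsv} and \code{reactions.tsv} from a directory (see
#' the dialect in the package README and above). Formulas are parsed with
#' [parseFormula()]; unparseable or variable formulas do not abort the load
#' but mark the compound so that [filterReactions()] can exclude the
#' affected reactions. Synthetic (biomass/exchange) reactions are recognized
#' by an optional \code{synthetic} column and, as a fallback, by id patterns
#' (an id containing \code{"biomass"} or starting with \code{"EX_"}); the
#' pattern fallback can be disabled.
#'
#' @param path directory containing the two model tables.
#' @param detectSynthetic apply the id-pattern fallback for synthetic
#'   reactions when no explicit \code{synthetic} column is present.
#' @return a [ReactionSet-class].
#' @examples
#' rs <- readReactionSet(system.file("extdata", "toy_model",
#'                                   package = "primarypairs"))
#' @export
readReactionSet <- function(path, detectSynthetic = TRUE) {
  if (!dir.exists(path)) {
    stop("model directory not found: ", path)
  }
  cpd <- .readTable(file.path(path, "compounds.tsv"),
                    c("id", "formula"), "compound")
  rxn <- .readTable(file.path(path, "reactions.tsv"),
                    c("id", "equation"), "reaction")
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id in ", file.path(path, "reactions.tsv"),
         ": ", rxn$id[duplicated(rxn$id)][1])
  }
  if (!nrow(rxn)) {
    warning("reaction table is empty: ", file.path(path, "reactions.tsv"))
  }
  hasFlag <- "synthetic" %in% names(rxn)
  reactions <- lapply(seq_len(nrow(rxn)), function(i) {
    rid <- as.character(rxn$id[i])
    eq <- .parseEquation(rxn$equation[i], rid)
    synthetic <- if (hasFlag) {
      .asFlag(rxn$synthetic[i])
    } else if (detectSynthetic) {
      grepl("biomass", rid, ignore.case = TRUE) || startsWith(rid, "EX_")
    } else {
      FALSE
    }
    list(id = rid, reactants = eq$reactants, products = eq$products,
         reversible = eq$reversible, synthetic = synthetic)
  })
  ReactionSet(cpd, reactions)
}

#' Write a reaction set as model tables
#'
#' Inverse of [readReactionSet()]: writes \code{compounds.tsv} and
#' \code{reactions.tsv} into a directory, creating it if needed.
#'
#' @param rs a [ReactionSet-class].
#' @param path output directory.
#' @return the directory path, invisibly.
#' @export
writeReactionSet <- function(rs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cpd <- compounds(rs)[, c("id", "formula", "name", "compartment")]
  utils::write.table(cpd, file.path(path, "compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  rxns <- rs@reactions
  df <- data.frame(
    id = names(rxns),
    equation = vapply(rxns, .renderEquation, character(1)),
    synthetic = vapply(rxns, function(r) r$synthetic, logical(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the standard reaction-exclusion filters
#'
#' Retains the reactions usable for primary-pair prediction, excluding (in
#' this order, logging the first triggering reason per reaction):
#' \enumerate{
#'   \item \code{unparseable-formula} / \code{variable-formula}: a
#'     participating compound has a missing/unparseable formula, or one with
#'     indeterminate composition (repeat variable or dot notation);
#'   \item \code{unbalanced}: non-hydrogen elements differ between the two
#'     sides ([checkBalance()]);
#'   \item \code{synthetic}: biomass/exchange-type artificial reactions;
#'   \item \code{non-integer-stoichiometry}: instance expansion requires
#'     countable compound instances.
#' }
#' Filtering is idempotent: a filtered set passes unchanged.
#'
#' @param rs a [ReactionSet-class].
#' @return a list with \code{model} (the retained [ReactionSet-class]) and
#'   \code{exclusions} (a \code{data.frame} with columns \code{reaction} and
#'   \code{reason}).
#' @examples
#' flt <- filterReactions(toyModel())
#' nReactions(flt$model)
#' @export
filterReactions <- function(rs) {
  status <- compounds(rs)$status
  names(status) <- compounds(rs)$id
  formulas <- compoundFormulas(rs)
  keep <- character(0)
  exReaction <- character(0)
  exReason <- character(0)
  for (rid in reactionIds(rs)) {
    r <- getReaction(rs, rid)
    cids <- c(r$reactants$compound, r$products$compound)
    st <- status[cids]
    reason <- NULL
    if (any(st == "unparseable")) {
      reason <- "unparseable-formula"
    } else if (any(st == "variable")) {
      reason <- "variable-formula"
    } else if (!checkBalance(r, formulas)$balanced) {
      reason <- "unbalanced"
    } else if (r$synthetic) {
      reason <- "synthetic"
    } else if (any(abs(c(r$reactants$coef, r$products$coef) -
                       round(c(r$reactants$coef, r$products$coef))) > 1e-9)) {
      reason <- "non-integer-stoichiometry"
    }
    if (is.null(reason)) {
      keep <- c(keep, rid)
    } else {
      exReaction <- c(exReaction, rid)
      exReason <- c(exReason, reason)
    }
  }
  list(model = rs[keep],
       exclusions = data.frame(reaction = exReaction, reason = exReason,
                               stringsAsFactors = FALSE))
}

#' Read reference reactant/product pair annotations
#'
#' Reads a three-column table (\code{reaction}, \code{reactant},
#' \code{product}) of curated element-transferring pairs. Rows referencing
#' reactions absent from \code{rs}, or compounds not found on the proper
#' side of their reaction, are dropped with a warning giving the count.
#' Reactions of \code{rs} that involve at least one carbon-containing
#' compound but have no usable reference pair are logged with reason
#' \code{missing-reference} so they can be excluded from evaluation.
#'
#' @param path path to the pair table.
#' @param rs the [ReactionSet-class] the annotations refer to.
#' @return a list with \code{pairs} (a \code{data.frame} of surviving
#'   triples) and \code{exclusions} (reactions lacking reference coverage).
#' @export
readReferencePairs <- function(path, rs) {
  df <- .readTable(path, c("reaction", "reactant", "product"),
                   "reference pair")
  df <- data.frame(reaction = as.character(df$reaction),
                   reactant = as.character(df$reactant),
                   product = as.character(df$product),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$reaction) | !nzchar(df$reaction) |
    is.na(df$reactant) | !nzchar(df$reactant) |
    is.na(df$product) | !nzchar(df$product)
  if (any(bad)) {
    stop("malformed reference pair row(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), " of ", path)
  }
  known <- df$reaction %in% reactionIds(rs)
  dropped <- sum(!known)
  df <- df[known, , drop = FALSE]
  onSides <- vapply(seq_len(nrow(df)), function(i) {
    r <- getReaction(rs, df$reaction[i])
    df$reactant[i] %in% r$reactants$compound &&
      df$product[i] %in% r$products$compound
  }, logical(1))
  dropped <- dropped + sum(!onSides)
  if (dropped > 0) {
    warning(dropped, " reference pair row(s) referenced unknown reactions ",
            "or compounds and were dropped")
  }
  df <- df[onSides, , drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  formulas <- compoundFormulas(rs)
  uncovered <- character(0)
  for (rid in reactionIds(rs)) {
    r <- getReaction(rs, rid)
    cids <- c(r$reactants$compound, r$products$compound)
    hasCarbon <- any(vapply(cids, function(cid) {
      f <- formulas[[cid]]
      !is.null(f) && !isVariableFormula(f) && containsCarbon(f)
    }, logical(1)))
    if (hasCarbon && !rid %in% df$reaction) {
      uncovered <- c(uncovered, rid)
    }
  }
  list(pairs = df,
       exclusions = data.frame(
         reaction = uncovered,
         reason = rep("missing-reference", length(uncovered)),
         stringsAsFactors = FALSE))
}

#' Write predicted primary pairs to a table
#'
#' One row per predicted pair: reaction id, reactant id, product id,
#' transferred formula in canonical Hill text, and the final corrected
#' score. Rows are ordered by reaction id, then by assignment order within
#' the reaction; the score is formatted with a fixed rule so that repeated
#' runs on the same input produce byte-identical files.
#'
#' @param result a [PredictionResult-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePairPredictions <- function(result, path) {
  stopifnot(is(result, "PredictionResult"))
  df <- primaryPairs(result)
  df <- df[order(df$reaction), , drop = FALSE]  # stable: keeps pair order
  out <- data.frame(reaction = df$reaction, reactant = df$reactant,
                    product = df$product, transfer = df$transfer,
                    score = sprintf("%.10g", df$score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
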