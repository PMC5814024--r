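# construction and accessors for ReactionSet

#' Construct a ReactionSet
#'
#' Builds the validated container from a compound table and a reaction list.
#' Most users will prefer [readReactionSet()] (delimited model tables),
#' [toyModel()] (the bundled worked example) or [generateSynthetic()].
#'
#' @param compounds a \code{data.frame} with at least columns \code{id} and
#'   \code{formula}; optional \code{name} (defaults to the id) and
#'   \code{compartment} (parsed from a trailing \code{"[c]"}-style suffix of
#'   the id when absent). Formulas are parsed with [parseFormula()]; strings
#'   that fail to parse mark the compound unparseable rather than aborting.
#' @param reactions a list of reactions; each element needs \code{id},
#'   \code{reactants} and \code{products} (data frames with columns
#'   \code{compound} and \code{coef}), and optionally \code{reversible} and
#'   \code{synthetic} (default \code{FALSE}). Duplicate compound entries on
#'   one side are merged by summing coefficients.
#' @return a [ReactionSet-class] object.
#' @export
ReactionSet <- function(compounds, reactions = list()) {
  stopifnot(is.data.frame(compounds), all(c("id", "formula") %in%
                                          names(compounds)))
  id <- as.character(compounds$id)
  if (anyDuplicated(id)) {
    stop("duplicate compound id: ", id[duplicated(id)][1])
  }
  name <- if ("name" %in% names(compounds)) {
    as.character(compounds$name)
  } else {
    id
  }
  name[is.na(name) | !nzchar(name)] <- id[is.na(name) | !nzchar(name)]
  compartment <- if ("compartment" %in% names(compounds)) {
    as.character(compounds$compartment)
  } else {
    .compartmentOf(id)
  }
  formula <- as.character(compounds$formula)
  status <- character(length(id))
  formulaList <- list()
  for (i in seq_along(id)) {
    if (is.na(formula[i]) || !nzchar(trimws(formula[i]))) {
      status[i] <- "unparseable"
      next
    }
    f <- tryCatch(parseFormula(formula[i]), error = function(e) NULL)
    if (is.null(f)) {
      status[i] <- "unparseable"
    } else if (isVariableFormula(f)) {
      status[i] <- "variable"
    } else {
      status[i] <- "ok"
      formulaList[[id[i]]] <- f
    }
  }
  cpd <- data.frame(id = id, name = name, compartment = compartment,
                    formula = formula, status = status,
                    stringsAsFactors = FALSE)
  rxns <- list()
  for (r in reactions) {
    stopifnot(!is.null(r$id))
    rid <- as.character(r$id)
    if (rid %in% names(rxns)) {
      stop("duplicate reaction id: ", rid)
    }
    entry <- list(
      id = rid,
      reactants = .mergeSide(r$reactants, rid),
      products = .mergeSide(r$products, rid),
      reversible = isTRUE(r$reversible),
      synthetic = isTRUE(r$synthetic))
    for (side in c("reactants", "products")) {
      missing <- setdiff(entry[[side]]$compound, id)
      if (length(missing)) {
        stop("reaction '", rid, "' references undeclared compound '",
             missing[1], "'")
      }
    }
    rxns[[rid]] <- entry
  }
  new("ReactionSet", compounds = cpd, formulaList = formulaList,
      reactions = rxns)
}

# merge duplicate compound rows on one reaction side, keep positive coefs
.mergeSide <- function(df, rid) {
  if (is.null(df) || !nrow(df)) {
    return(data.frame(compound = character(0), coef = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("compound", "coef") %in% names(df)))
  if (any(df$coef <= 0)) {
    stop("reaction '", rid, "': stoichiometric coefficients must be positive")
  }
  agg <- tapply(as.numeric(df$coef), as.character(df$compound), sum)
  out <- data.frame(compound = names(agg), coef = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(match(out$compound, df$compound)), , drop = FALSE]
}

# trailing "[c]"-style compartment tag, NA when absent
.compartmentOf <- function(ids) {
  m <- regmatches(ids, regexpr("\\[[^][]+\\]$", ids))
  out <- rep(NA_character_, length(ids))
  has <- grepl("\\[[^][]+\\]$", ids)
  out[has] <- substr(m, 2, nchar(m) - 1)
  out
}

.stripCompartment <- function(ids) {
  sub("\\[[^][]+\\]$", "", ids)
}

#' Accessors for ReactionSet objects
#'
#' \code{compounds()} returns the compound table; \code{compoundFormulas()}
#' the named list of parsed formulas (parseable compounds only);
#' \code{reactionIds()} the reaction identifiers in set order;
#' \code{getReaction()} one reaction (a list with \code{reactants} and
#' \code{products} data frames, \code{reversible}, \code{synthetic});
#' \code{nReactions()}/\code{nCompounds()} the set sizes. \code{x[ids]}
#' subsets to the given reactions (keeping the full compound table).
#'
#' @param x a [ReactionSet-class].
#' @param id a single reaction id.
#' @name ReactionSet-accessors
NULL

#' @rdname ReactionSet-accessors
#' @export
setMethod("compounds", "ReactionSet", function(x) x@compounds)

#' @rdname ReactionSet-accessors
#' @export
setMethod("compoundFormulas", "ReactionSet", function(x) x@formulaList)

#' @rdname ReactionSet-accessors
#' @export
setMethod("reactionIds", "ReactionSet", function(x) names(x@reactions))

#' @rdname ReactionSet-accessors
#' @export
setMethod("getReaction", "ReactionSet", function(x, id) {
  if (!id %in% names(x@reactions)) {
    stop("no reaction '", id, "' in this ReactionSet")
  }
  x@reactions[[id]]
})

#' @rdname ReactionSet-accessors
#' @export
setMethod("nReactions", "ReactionSet", function(x) length(x@reactions))

#' @rdname ReactionSet-accessors
#' @export
setMethod("nCompounds", "ReactionSet", function(x) nrow(x@compounds))

#' @rdname ReactionSet-accessors
#' @param i character or integer index of reactions to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ReactionSet", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else names(x@reactions)[i]
  missing <- setdiff(ids, names(x@reactions))
  if (length(missing)) {
    stop("no reaction '", missing[1], "' in this ReactionSet")
  }
  initialize(x, reactions = x@reactions[ids])
})

setMethod("show", "ReactionSet", function(object) {
  cat("ReactionSet with", nReactions(object), "reactions over",
      nCompounds(object), "compounds\n")
  st <- table(object@compounds$status)
  if (any(object@compounds$status != "ok")) {
    cat("  compound formulas:",
        paste(names(st), as.integer(st), sep = "=", collapse = ", "), "\n")
  }
  n <- min(5L, nReactions(object))
  if (n > 0) {
    for (rid in reactionIds(object)[seq_len(n)]) {
      cat(" ", rid, ":", .renderEquation(object@reactions[[rid]]), "\n")
    }
    if (nReactions(object) > n) {
      cat("  ...", nReactions(object) - n, "more\n")
    }
  }
  invisible(NULL)
})

#' Accessors for PredictionResult objects
#'
#' \code{primaryPairs()} returns the predicted pair table (columns
#' \code{reaction}, \code{reactant}, \code{product}, \code{transfer},
#' \code{score}); \code{thetaTable()} the final per-compound-pair
#' probability table; \code{iterations()} and \code{converged()} the
#' convergence diagnostics.
#'
#' @param x a [PredictionResult-class].
#' @name PredictionResult-accessors
NULL

#' @rdname PredictionResult-accessors
#' @export
setMethod("primaryPairs", "PredictionResult", function(x) x@pairs)

#' @rdname PredictionResult-accessors
#' @export
setMethod("thetaTable", "PredictionResult", function(x) x@theta)

#' @rdname PredictionResult-accessors
#' @export
setMethod("iterations", "PredictionResult", function(x) x@iterations)

#' @rdname PredictionResult-accessors
#' @export
setMethod("converged", "PredictionResult", function(x) x@converged)

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", nrow(object@pairs), "primary pairs in",
      length(unique(object@pairs$reaction)), "reactions\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  compound pairs tracked:", nrow(object@theta), "\n")
  if (length(object@ties)) {
    cat("  ambiguous (score-tied) reactions:", length(object@ties), "\n")
  }
  invisible(NULL)
})

#' Accessors for ConfusionMatrix objects
#'
#' \code{cmCounts()} returns the four cells as a named vector
#' (\code{tp}, \code{fp}, \code{fn}, \code{tn}).
#'
#' @param x a [ConfusionMatrix-class].
#' @name ConfusionMatrix-accessors
NULL

#' @rdname ConfusionMatrix-accessors
#' @export
setMethod("cmCounts", "ConfusionMatrix", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix\n")
  cat(sprintf("  TP=%g FP=%g FN=%g TN=%g\n",
              object@tp, object@fp, object@fn, object@tn))
  cat(sprintf("  MCC=%.4f\n", mcc(object)))
  invisible(NULL)
})

setMethod("show", "GridResult", function(object) {
  cat("GridResult over", nrow(object@grid), "grid points\n")
  b <- object@best
  cat(sprintf("  best: W_other=%g alpha=%g beta=%g MCC=%.4f\n",
              b$wOther, b$alpha, b$beta, b$mcc))
  invisible(NULL)
})

#' @rdname GridResult-accessors
#' @name GridResult-accessors
#' @param x a [GridResult-class].
#' @export
gridSurface <- function(x) {
  stopifnot(is(x, "GridResult"))
  x@grid
}

#' @rdname GridResult-accessors
#' @export
gridBest <- function(x) {
  stopifnot(is(x, "GridResult"))
  x@best
}
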