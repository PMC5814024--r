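#' @import methods
NULL

#' ReactionSet: a set of reactions over a compound table
#'
#' The central container of the package: a compound table (identifier,
#' display name, compartment, formula string and its parse status) together
#' with a list of stoichiometric reactions over those compounds. Use
#' [ReactionSet()] or [readReactionSet()] to construct one, and the
#' accessors [compounds()], [reactionIds()], [getReaction()],
#' [compoundFormulas()], [nReactions()] and [nCompounds()] rather than
#' direct slot access.
#'
#' @slot compounds a \code{data.frame} with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (the original string) and
#'   \code{status} (\code{"ok"}, \code{"variable"} or \code{"unparseable"}).
#' @slot formulaList a named list of parsed \code{chemFormula} objects for
#'   every compound whose status is \code{"ok"}.
#' @slot reactions a named list; each element is a list with entries
#'   \code{id}, \code{reactants} and \code{products} (data frames with
#'   columns \code{compound}, \code{coef}), \code{reversible} and
#'   \code{synthetic}.
#' @export
setClass("ReactionSet",
         slots = c(compounds = "data.frame",
                   formulaList = "list",
                   reactions = "list"))

setValidity("ReactionSet", function(object) {
  msgs <- character(0)
  cpd <- object@compounds
  need <- c("id", "name", "compartment", "formula", "status")
  if (!all(need %in% names(cpd))) {
    return(paste("compound table must have columns:",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cpd$id)) {
    msgs <- c(msgs, paste("duplicate compound id:",
                          cpd$id[duplicated(cpd$id)][1]))
  }
  if (!all(cpd$status %in% c("ok", "variable", "unparseable"))) {
    msgs <- c(msgs, "compound status must be ok/variable/unparseable")
  }
  okIds <- cpd$id[cpd$status == "ok"]
  if (!setequal(names(object@formulaList), okIds)) {
    msgs <- c(msgs, "formulaList must hold exactly the parseable compounds")
  }
  rxns <- object@reactions
  if (length(rxns)) {
    ids <- vapply(rxns, function(r) r$id, character(1))
    if (anyDuplicated(ids)) {
      msgs <- c(msgs, paste("duplicate reaction id:", ids[duplicated(ids)][1]))
    }
    if (!identical(names(rxns), unname(ids))) {
      msgs <- c(msgs, "reaction list names must equal reaction ids")
    }
    for (r in rxns) {
      for (side in c("reactants", "products")) {
        df <- r[[side]]
        if (!all(c("compound", "coef") %in% names(df))) {
          msgs <- c(msgs, paste0("reaction '", r$id, "': ", side,
                                 " must have compound and coef columns"))
          next
        }
        if (nrow(df) && any(df$coef <= 0)) {
          msgs <- c(msgs, paste0("reaction '", r$id,
                                 "': coefficients must be positive"))
        }
        if (nrow(df) && anyDuplicated(df$compound)) {
          msgs <- c(msgs, paste0("reaction '", r$id, "': duplicate compound ",
                                 "on one side (merge coefficients)"))
        }
        missing <- setdiff(df$compound, cpd$id)
        if (length(missing)) {
          msgs <- c(msgs, paste0("reaction '", r$id,
                                 "' references undeclared compound '",
                                 missing[1], "'"))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PredictionResult: primary-pair predictions for a reaction set
#'
#' Holds the per-reaction primary-pair assignments from the final iteration
#' of [findPrimaryPairs()], the final per-compound-pair probability table,
#' and convergence/ambiguity diagnostics. Use [primaryPairs()],
#' [thetaTable()], [iterations()], [converged()] and
#' [detectAmbiguousReactions()].
#'
#' @slot pairs a \code{data.frame} with columns \code{reaction},
#'   \code{reactant}, \code{product}, \code{transfer} (canonical formula
#'   text of the transferred elements) and \code{score} (final corrected
#'   score), in deterministic assignment order.
#' @slot theta a \code{data.frame} with columns \code{x}, \code{y} (the
#'   unordered compound pair), \code{yCount} (reactions where the pair was
#'   assigned), \code{nCount} (reactions where the pair co-occurs on
#'   opposite sides) and \code{thetaHat} (the MAP point estimate).
#' @slot iterations number of global iterations executed.
#' @slot converged whether the point estimates stabilized within tolerance.
#' @slot ties reaction ids for which at least one selection step saw a score
#'   tie between distinct compound-pair mappings in the final iteration.
#' @export
setClass("PredictionResult",
         slots = c(pairs = "data.frame",
                   theta = "data.frame",
                   iterations = "integer",
                   converged = "logical",
                   ties = "character"))

setValidity("PredictionResult", function(object) {
  need <- c("reaction", "reactant", "product", "transfer", "score")
  if (!all(need %in% names(object@pairs))) {
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  }
  needT <- c("x", "y", "yCount", "nCount", "thetaHat")
  if (!all(needT %in% names(object@theta))) {
    return(paste("theta must have columns:", paste(needT, collapse = ", ")))
  }
  if (nrow(object@theta)) {
    if (any(object@theta$yCount > object@theta$nCount)) {
      return("theta: yCount may not exceed nCount")
    }
    if (any(object@theta$thetaHat < 0 | object@theta$thetaHat > 1)) {
      return("theta: thetaHat must lie in [0, 1]")
    }
  }
  TRUE
})

#' ConfusionMatrix: prediction vs. reference pair counts
#'
#' True/false positive/negative counts over the per-reaction universe of
#' candidate reactant/product pairs, as built by [buildConfusionMatrix()].
#'
#' @slot tp,fp,fn,tn non-negative counts.
#' @export
setClass("ConfusionMatrix",
         slots = c(tp = "numeric", fp = "numeric",
                   fn = "numeric", tn = "numeric"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || any(is.na(v))) {
    return("tp, fp, fn, tn must each be a single number")
  }
  if (any(v < 0)) {
    return("confusion matrix counts must be non-negative")
  }
  TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,fn,tn non-negative counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return a [ConfusionMatrix-class] object.
#' @examples
#' mcc(ConfusionMatrix(3626, 60, 62, 1577))
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' GridResult: a parameter grid-search surface
#'
#' One row per grid point of (W_other, alpha, beta) with its MCC, plus the
#' argmax point (ties broken toward lexicographically smaller parameters).
#'
#' @slot grid a \code{data.frame} with columns \code{wOther}, \code{alpha},
#'   \code{beta}, \code{mcc}.
#' @slot best the single argmax row of \code{grid}.
#' @export
setClass("GridResult",
         slots = c(grid = "data.frame", best = "data.frame"))
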