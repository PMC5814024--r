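# evaluation against reference pair annotations: confusion matrix, MCC,
# parameter grid search

#' Build a confusion matrix of predicted vs. reference pairs
#'
#' The evaluation universe is, per reaction, every (reactant compound,
#' product compound) candidate pair, with multiplicity collapsed (a pair
#' either is or is not predicted for a reaction). In \code{"carbon"} mode
#' the universe is restricted to candidate pairs in which both compounds
#' contain carbon, and a pair counts as predicted only when at least one
#' carbon atom is transferred — this is the mode used against references
#' that annotate carbon transfers only. TP/FP/FN/TN partition the universe:
#' predicted-and-annotated, predicted-only, annotated-only, neither.
#'
#' @param result a [PredictionResult-class].
#' @param reference a \code{data.frame} of reference triples with columns
#'   \code{reaction}, \code{reactant}, \code{product} (see
#'   [readReferencePairs()]). Triples outside the universe are dropped with
#'   a warning.
#' @param rs the [ReactionSet-class] defining the universe; restrict it
#'   beforehand to the reactions under evaluation.
#' @param mode \code{"all"} (every element) or \code{"carbon"}.
#' @return a [ConfusionMatrix-class].
#' @examples
#' rs <- filterReactions(toyModel())$model
#' res <- findPrimaryPairs(rs)
#' ref <- readReferencePairs(system.file("extdata", "toy_model", "pairs.tsv",
#'                                       package = "primarypairs"), rs)
#' buildConfusionMatrix(res, ref$pairs, rs)
#' @export
buildConfusionMatrix <- function(result, reference, rs,
                                 mode = c("all", "carbon")) {
  mode <- match.arg(mode)
  stopifnot(is(result, "PredictionResult"), is(rs, "ReactionSet"),
            is.data.frame(reference))
  formulas <- compoundFormulas(rs)
  hasC <- function(cid) {
    f <- formulas[[cid]]
    !is.null(f) && !isVariableFormula(f) && containsCarbon(f)
  }
  universe <- character(0)
  for (rid in reactionIds(rs)) {
    r <- getReaction(rs, rid)
    rc <- unique(r$reactants$compound)
    pc <- unique(r$products$compound)
    if (mode == "carbon") {
      rc <- rc[vapply(rc, hasC, logical(1))]
      pc <- pc[vapply(pc, hasC, logical(1))]
    }
    if (length(rc) && length(pc)) {
      universe <- c(universe,
                    paste(rid, rep(rc, times = length(pc)),
                          rep(pc, each = length(rc)), sep = "\r"))
    }
  }
  universe <- unique(universe)

  pp <- primaryPairs(result)
  if (mode == "carbon" && nrow(pp)) {
    carbonTransfer <- vapply(pp$transfer, function(tr) {
      grepl("C(?![a-z])", tr, perl = TRUE)
    }, logical(1), USE.NAMES = FALSE)
    pp <- pp[carbonTransfer, , drop = FALSE]
  }
  predicted <- unique(paste(pp$reaction, pp$reactant, pp$product,
                            sep = "\r"))
  predicted <- intersect(predicted, universe)

  refKeys <- unique(paste(reference$reaction, reference$reactant,
                          reference$product, sep = "\r"))
  outside <- setdiff(refKeys, universe)
  if (length(outside)) {
    warning(length(outside), " reference pair(s) fall outside the ",
            "evaluation universe and were dropped")
    refKeys <- intersect(refKeys, universe)
  }

  tp <- length(intersect(predicted, refKeys))
  fp <- length(setdiff(predicted, refKeys))
  fn <- length(setdiff(refKeys, predicted))
  tn <- length(universe) - tp - fp - fn
  ConfusionMatrix(tp, fp, fn, tn)
}

#' Matthews correlation coefficient
#'
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}, the balanced
#' accuracy measure used for benchmarking pair predictions. Returns 0 when
#' any marginal factor is 0 (the standard convention).
#'
#' @param x a [ConfusionMatrix-class].
#' @return a value in \code{[-1, 1]}.
#' @examples
#' mcc(ConfusionMatrix(3626, 60, 62, 1577))
#' @rdname mcc
#' @export
setMethod("mcc", "ConfusionMatrix", function(x) {
  tp <- x@tp
  fp <- x@fp
  fn <- x@fn
  tn <- x@tn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den <= 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
})

#' Enumerate parameter grid points
#'
#' The default ranges are the full search grid: the non-carbon non-hydrogen
#' weight in 51 steps of 0.02 from 0 to 1, and integer prior parameters from
#' 1 to 50 each (127500 points in total). Points are ordered
#' lexicographically by (\code{wOther}, \code{alpha}, \code{beta}), which is
#' also the tie-break order of [gridSearch()].
#'
#' @param wOther,alpha,beta numeric vectors of parameter values.
#' @return a \code{data.frame} with one row per grid point.
#' @examples
#' nrow(gridPoints())  # 127500
#' @export
gridPoints <- function(wOther = seq(0, 1, by = 0.02),
                       alpha = 1:50, beta = 1:50) {
  g <- expand.grid(beta = beta, alpha = alpha, wOther = wOther,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("wOther", "alpha", "beta")]
  g <- g[order(g$wOther, g$alpha, g$beta), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Grid search over algorithm parameters
#'
#' Runs the full prediction pipeline at every grid point of
#' (\code{wOther}, \code{alpha}, \code{beta}) — with no warm starting, since
#' the probability estimates depend on all three parameters — evaluates each
#' against the reference annotation, and reports the MCC surface together
#' with the argmax point (ties broken toward lexicographically smaller
#' parameters). Override the ranges to run small grids; the defaults
#' enumerate the full 51 x 50 x 50 search grid.
#'
#' @param rs a filtered [ReactionSet-class] restricted to the reactions
#'   under evaluation.
#' @param reference reference triples (see [buildConfusionMatrix()]).
#' @param wOther,alpha,beta parameter ranges (see [gridPoints()]).
#' @param mode evaluation mode passed to [buildConfusionMatrix()].
#' @param epsilon,maxIterations convergence settings per point.
#' @param strictCompartments see [findPrimaryPairs()].
#' @return a [GridResult-class].
#' @examples
#' rs <- filterReactions(toyModel())$model
#' ref <- readReferencePairs(system.file("extdata", "toy_model", "pairs.tsv",
#'                                       package = "primarypairs"), rs)
#' gridSearch(rs, ref$pairs, wOther = c(0.5, 0.82), alpha = 1, beta = c(10, 43))
#' @export
gridSearch <- function(rs, reference, wOther = seq(0, 1, by = 0.02),
                       alpha = 1:50, beta = 1:50,
                       mode = c("all", "carbon"),
                       epsilon = 1e-5, maxIterations = 100L,
                       strictCompartments = FALSE) {
  mode <- match.arg(mode)
  g <- gridPoints(wOther, alpha, beta)
  g$mcc <- vapply(seq_len(nrow(g)), function(i) {
    res <- findPrimaryPairs(
      rs,
      weights = elementWeights(other = g$wOther[i]),
      prior = priorParams(alpha = g$alpha[i], beta = g$beta[i],
                          epsilon = epsilon,
                          maxIterations = maxIterations),
      strictCompartments = strictCompartments)
    cm <- suppressWarnings(
      buildConfusionMatrix(res, reference, rs, mode = mode))
    mcc(cm)
  }, numeric(1))
  best <- g[which.max(g$mcc), , drop = FALSE]  # rows already in tie order
  rownames(best) <- NULL
  new("GridResult", grid = g, best = best)
}
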