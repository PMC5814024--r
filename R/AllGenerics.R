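#' @rdname ReactionSet-accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname ReactionSet-accessors
#' @export
setGeneric("compoundFormulas", function(x) standardGeneric("compoundFormulas"))

#' @rdname ReactionSet-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname ReactionSet-accessors
#' @export
setGeneric("getReaction", function(x, id) standardGeneric("getReaction"))

#' @rdname ReactionSet-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname ReactionSet-accessors
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @rdname PredictionResult-accessors
#' @export
setGeneric("primaryPairs", function(x) standardGeneric("primaryPairs"))

#' @rdname PredictionResult-accessors
#' @export
setGeneric("thetaTable", function(x) standardGeneric("thetaTable"))

#' @rdname PredictionResult-accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @rdname PredictionResult-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname mcc
#' @export
setGeneric("mcc", function(x) standardGeneric("mcc"))

#' @rdname ConfusionMatrix-accessors
#' @export
setGeneric("cmCounts", function(x) standardGeneric("cmCounts"))
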