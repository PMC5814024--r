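# bipartite metabolic graphs: conventional form, primary-pairs form with
# reaction-vertex replication, and serialization

#' @importFrom igraph graph_from_data_frame components as_data_frame
#'   write_graph V vcount ecount
NULL

# ids of compounds containing the filter element; element NULL/"none" keeps
# everything with a usable formula
.elementCompounds <- function(rs, element) {
  cpd <- compounds(rs)
  formulas <- compoundFormulas(rs)
  if (is.null(element) || identical(element, "none")) {
    return(cpd$id)
  }
  keep <- vapply(cpd$id, function(cid) {
    f <- formulas[[cid]]
    !is.null(f) && !isVariableFormula(f) && containsCarbon(f, element)
  }, logical(1))
  cpd$id[keep]
}

.compoundVertices <- function(rs, ids) {
  cpd <- compounds(rs)
  cpd <- cpd[match(ids, cpd$id), , drop = FALSE]
  data.frame(name = cpd$id, kind = rep("compound", nrow(cpd)),
             label = cpd$name,
             compartment = ifelse(is.na(cpd$compartment), "",
                                  cpd$compartment),
             stringsAsFactors = FALSE)
}

.makeBipartite <- function(vdf, edf) {
  if (!nrow(edf)) {
    edf <- data.frame(from = character(0), to = character(0),
                      transfer = character(0), main = logical(0),
                      stringsAsFactors = FALSE)
  }
  graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Conventional bipartite metabolic graph
#'
#' One vertex per compound and one per reaction, with a directed edge from
#' every reactant to its reaction vertex and from the reaction vertex to
#' every product. By default only carbon-containing compounds are kept; any
#' other element symbol may be used as the filter, or \code{"none"} to keep
#' every compound.
#'
#' @param rs a [ReactionSet-class].
#' @param element filter element symbol (default \code{"C"}), or
#'   \code{"none"}/\code{NULL} for no filtering.
#' @param mainCompounds compound ids whose edges receive the \code{main}
#'   width hint (e.g. the compounds of a pathway of interest).
#' @return a directed \code{igraph} graph with vertex attributes
#'   \code{kind} (\code{"compound"}/\code{"reaction"}), \code{label},
#'   \code{compartment}, and edge attributes \code{transfer} (empty here)
#'   and \code{main}.
#' @examples
#' g <- buildConventionalGraph(toyModel()["AKGDH"])
#' igraph::vcount(g)
#' @export
buildConventionalGraph <- function(rs, element = "C",
                                   mainCompounds = character(0)) {
  stopifnot(is(rs, "ReactionSet"))
  keep <- .elementCompounds(rs, element)
  from <- character(0)
  to <- character(0)
  usedCompounds <- character(0)
  for (rid in reactionIds(rs)) {
    r <- getReaction(rs, rid)
    rc <- intersect(unique(r$reactants$compound), keep)
    pc <- intersect(unique(r$products$compound), keep)
    from <- c(from, rc, rep(rid, length(pc)))
    to <- c(to, rep(rid, length(rc)), pc)
    usedCompounds <- c(usedCompounds, rc, pc)
  }
  rids <- reactionIds(rs)
  vdf <- rbind(
    .compoundVertices(rs, intersect(keep, unique(usedCompounds))),
    data.frame(name = rids, kind = rep("reaction", length(rids)),
               label = rids, compartment = rep("", length(rids)),
               stringsAsFactors = FALSE))
  edf <- data.frame(from = from, to = to,
                    transfer = rep("", length(from)),
                    main = from %in% mainCompounds | to %in% mainCompounds,
                    stringsAsFactors = FALSE)
  .makeBipartite(vdf, edf)
}

#' Partition a reaction's primary pairs into independent groups
#'
#' Groups the predicted pairs of one reaction into the connected components
#' of the graph whose vertices are the paired compounds and whose edges are
#' the pairs. Each component carries out an element transfer that is
#' independent of the others, so it is drawn with its own replicated
#' reaction vertex. With an element filter, pairs whose transfer does not
#' contain the element are dropped before partitioning.
#'
#' @param pairs a \code{data.frame} of one reaction's pairs with columns
#'   \code{reactant}, \code{product}, \code{transfer}.
#' @param element filter element symbol (default \code{"C"}), or
#'   \code{"none"}/\code{NULL}.
#' @return a list of data frames (one per group), ordered by each group's
#'   smallest member compound id.
#' @examples
#' rs <- toyModel()
#' p <- assignReactionPairs(rs, "AKGDH")$pairs
#' length(partitionReactionPairs(p))  # 2: NAD-NADH is independent
#' @export
partitionReactionPairs <- function(pairs, element = "C") {
  stopifnot(is.data.frame(pairs))
  if (!is.null(element) && !identical(element, "none") && nrow(pairs)) {
    keep <- vapply(pairs$transfer, function(tr) {
      nzchar(tr) && containsCarbon(parseFormula(tr), element)
    }, logical(1), USE.NAMES = FALSE)
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(list())
  }
  g <- graph_from_data_frame(pairs[, c("reactant", "product")],
                             directed = FALSE)
  comp <- components(g)
  member <- comp$membership
  groupOf <- member[pairs$reactant]
  groups <- split(seq_len(nrow(pairs)), groupOf)
  out <- lapply(groups, function(i) {
    df <- pairs[i, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  smallest <- vapply(out, function(df) {
    min(c(df$reactant, df$product))
  }, character(1))
  out <- out[order(smallest)]
  names(out) <- NULL
  out
}

#' Primary-pairs bipartite graph with reaction-vertex replication
#'
#' Builds the bipartite graph in which each reaction is represented by one
#' vertex per independent group of its predicted primary pairs
#' ([partitionReactionPairs()]); instance vertices are named
#' \code{"<reaction>#<k>"} with \code{k} assigned in deterministic group
#' order. Edges run reactant -> instance -> product and carry the canonical
#' text of the transferred formula (summed when one compound transfers to an
#' instance through several pairs). This separates currency-compound
#' connections (e.g. ATP/ADP, NAD/NADH) from the primary pathway flow.
#'
#' @param rs a [ReactionSet-class].
#' @param result a [PredictionResult-class] covering \code{rs}.
#' @param element filter element symbol (default \code{"C"}), or
#'   \code{"none"}/\code{NULL}.
#' @param mainCompounds compound ids whose edges receive the \code{main}
#'   width hint.
#' @return a directed \code{igraph} graph (attributes as in
#'   [buildConventionalGraph()]).
#' @examples
#' rs <- filterReactions(toyModel())$model["AKGDH"]
#' g <- buildPrimaryPairsGraph(rs, findPrimaryPairs(rs))
#' igraph::V(g)$name
#' @export
buildPrimaryPairsGraph <- function(rs, result, element = "C",
                                   mainCompounds = character(0)) {
  stopifnot(is(rs, "ReactionSet"), is(result, "PredictionResult"))
  pp <- primaryPairs(result)
  from <- character(0)
  to <- character(0)
  transfer <- character(0)
  instances <- character(0)
  usedCompounds <- character(0)
  addEdges <- function(src, dst, trs) {
    # merge parallel edges between one compound and one instance by
    # summing the transferred formulas
    m <- max(length(src), length(dst))
    src <- rep(src, length.out = m)
    dst <- rep(dst, length.out = m)
    key <- paste(src, dst, sep = "\r")
    for (u in unique(key)) {
      i <- which(key == u)
      tot <- .formula()
      for (tr in trs[i]) {
        f <- parseFormula(tr)
        v <- c(as.numeric(tot), as.numeric(f))
        names(v) <- c(names(tot), names(f))
        tot <- .formula(v)
      }
      from <<- c(from, src[i[1]])
      to <<- c(to, dst[i[1]])
      transfer <<- c(transfer, formulaToText(tot))
    }
  }
  for (rid in reactionIds(rs)) {
    p <- pp[pp$reaction == rid, , drop = FALSE]
    groups <- partitionReactionPairs(p, element = element)
    for (k in seq_along(groups)) {
      inst <- paste0(rid, "#", k)
      instances <- c(instances, inst)
      df <- groups[[k]]
      addEdges(df$reactant, inst, df$transfer)
      addEdges(inst, df$product, df$transfer)
      usedCompounds <- c(usedCompounds, df$reactant, df$product)
    }
  }
  usedCompounds <- unique(usedCompounds)
  vdf <- rbind(
    .compoundVertices(rs, usedCompounds[order(usedCompounds)]),
    data.frame(name = instances, kind = rep("reaction", length(instances)),
               label = sub("#[0-9]+$", "", instances),
               compartment = rep("", length(instances)),
               stringsAsFactors = FALSE))
  edf <- data.frame(from = from, to = to, transfer = transfer,
                    main = from %in% mainCompounds | to %in% mainCompounds,
                    stringsAsFactors = FALSE)
  .makeBipartite(vdf, edf)
}

#' Serialize a bipartite metabolic graph
#'
#' Writes a graph built by [buildConventionalGraph()] or
#' [buildPrimaryPairsGraph()] in one of three Cytoscape-importable forms:
#' \describe{
#'   \item{\code{"sif"}}{simple interaction format, one edge per line
#'     (\code{source} \code{interaction} \code{target}, tab-separated);
#'     the interaction is \code{"cr"} for compound -> reaction edges and
#'     \code{"rc"} for reaction -> compound edges.}
#'   \item{\code{"graphml"}}{GraphML with the vertex attributes
#'     \code{kind}, \code{label}, \code{compartment} and edge attributes
#'     \code{transfer}, \code{main} (via \code{igraph::write_graph}).}
#'   \item{\code{"tables"}}{two delimited tables, \code{<path>-nodes.tsv}
#'     and \code{<path>-edges.tsv}.}
#' }
#'
#' @param g an \code{igraph} graph from this package.
#' @param format \code{"sif"}, \code{"graphml"} or \code{"tables"}.
#' @param path output file path (for \code{"tables"}: the path prefix).
#' @return the written file path(s), invisibly.
#' @export
exportGraph <- function(g, format = c("sif", "graphml", "tables"), path) {
  format <- tryCatch(match.arg(format),
                     error = function(e) {
                       stop("unknown graph format '", format[1],
                            "' (use sif, graphml or tables)")
                     })
  if (format == "graphml") {
    write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  edges <- as_data_frame(g, what = "edges")
  nodes <- as_data_frame(g, what = "vertices")
  if (format == "sif") {
    kindOf <- nodes$kind
    names(kindOf) <- nodes$name
    lines <- character(0)
    if (nrow(edges)) {
      interaction <- ifelse(kindOf[edges$from] == "compound", "cr", "rc")
      lines <- paste(edges$from, interaction, edges$to, sep = "\t")
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  nodePath <- paste0(path, "-nodes.tsv")
  edgePath <- paste0(path, "-edges.tsv")
  utils::write.table(
    data.frame(id = nodes$name, kind = nodes$kind, label = nodes$label,
               compartment = nodes$compartment, stringsAsFactors = FALSE),
    nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(source = edges$from, target = edges$to,
               transfer = edges$transfer, main = edges$main,
               stringsAsFactors = FALSE),
    edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodePath, edgePath))
}
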