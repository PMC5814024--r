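# bipartite graph construction and serialization

library(igraph)

expect_bipartite <- function(g) {
  if (ecount(g) == 0) return(invisible(TRUE))
  kinds <- V(g)$kind
  names(kinds) <- V(g)$name
  e <- as_data_frame(g, what = "edges")
  expect_true(all(kinds[e$from] != kinds[e$to]))
}

test_that("the conventional graph has one vertex per reaction", {
  rs <- toyFiltered()
  g <- buildConventionalGraph(rs["AKGDH"])
  expect_equal(sum(V(g)$kind == "reaction"), 1)
  expect_equal(sum(V(g)$kind == "compound"), 6)
  expect_equal(ecount(g), 6)
  expect_bipartite(g)

  # carbon filter drops the proton from HEX1
  gh <- buildConventionalGraph(rs["HEX1"])
  expect_false("h" %in% V(gh)$name)
  ghAll <- buildConventionalGraph(rs["HEX1"], element = "none")
  expect_true("h" %in% V(ghAll)$name)

  # empty set gives a valid empty graph
  e <- ReactionSet(data.frame(id = character(0), formula = character(0)),
                   list())
  expect_equal(vcount(buildConventionalGraph(e)), 0)
})

test_that("partitionReactionPairs groups by shared-compound connectivity", {
  rs <- toyFiltered()
  akg <- assignReactionPairs(rs, "AKGDH")$pairs
  groups <- partitionReactionPairs(akg)
  expect_length(groups, 2)
  # NAD-NADH stands alone; the other three pairs share compounds
  sizes <- vapply(groups, nrow, integer(1))
  expect_setequal(sizes, c(3L, 1L))
  solo <- groups[[which(sizes == 1)]]
  expect_identical(solo$reactant, "nad")
  expect_identical(solo$product, "nadh")

  # HEX1 in carbon mode drops the phosphate and proton pairs
  hex <- assignReactionPairs(rs, "HEX1")$pairs
  gh <- partitionReactionPairs(hex)
  expect_length(gh, 2)
  kept <- do.call(rbind, gh)
  expect_setequal(paste(kept$reactant, kept$product),
                  c("glc-D g6p", "atp adp"))

  expect_length(partitionReactionPairs(hex[1, , drop = FALSE],
                                       element = "none"), 1)
  expect_length(partitionReactionPairs(hex[0, , drop = FALSE]), 0)
})

test_that("the primary-pairs graph replicates reaction vertices", {
  rs <- toyFiltered()["AKGDH"]
  res <- findPrimaryPairs(rs)
  g <- buildPrimaryPairsGraph(rs, res)
  inst <- V(g)$name[V(g)$kind == "reaction"]
  expect_setequal(inst, c("AKGDH#1", "AKGDH#2"))
  expect_bipartite(g)
  # NAD-NADH hangs off its own instance
  e <- as_data_frame(g, what = "edges")
  nadInst <- e$to[e$from == "nad"]
  expect_equal(sort(c(e$from[e$to == nadInst], e$to[e$from == nadInst])),
               c("nad", "nadh"))
  # edge labels carry the transferred formulas
  expect_true("C21H26N7O14P2" %in% e$transfer)
})

test_that("graphs stay bipartite with disjoint per-instance edges", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs)
  g <- buildPrimaryPairsGraph(rs, res)
  expect_bipartite(g)
  expect_bipartite(buildConventionalGraph(rs))
  syn <- generateSynthetic(syntheticSpec(seed = 2, nReactions = 15))
  resS <- findPrimaryPairs(syn$model)
  expect_bipartite(buildPrimaryPairsGraph(syn$model, resS, element = "none"))
  expect_bipartite(buildConventionalGraph(syn$model, element = "none"))

  # per-instance compound sets of one reaction are disjoint
  e <- as_data_frame(g, what = "edges")
  isInst <- grepl("#", c(e$from, e$to))
  inst <- c(e$from, e$to)[isInst]
  cpd <- c(e$to, e$from)[isInst]
  for (rid in reactionIds(rs)) {
    of <- sub("#.*", "", inst) == rid
    sets <- split(cpd[of], inst[of])
    if (length(sets) > 1) {
      expect_length(Reduce(intersect, sets), 0)
    }
  }
})

test_that("collapsing instances yields a conventional-graph subgraph", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs)
  gp <- buildPrimaryPairsGraph(rs, res)
  gc <- buildConventionalGraph(rs)
  ep <- as_data_frame(gp, what = "edges")
  ep$from <- sub("#.*", "", ep$from)
  ep$to <- sub("#.*", "", ep$to)
  ec <- as_data_frame(gc, what = "edges")
  expect_true(all(paste(ep$from, ep$to) %in% paste(ec$from, ec$to)))
})

test_that("exportGraph writes SIF, GraphML, and tables", {
  rs <- toyFiltered()["AKGDH"]
  g <- buildPrimaryPairsGraph(rs, findPrimaryPairs(rs))

  sif <- tempfile(fileext = ".sif")
  exportGraph(g, "sif", sif)
  lines <- readLines(sif)
  expect_equal(length(lines), ecount(g))
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 3))
  expect_setequal(unique(vapply(fields, `[`, character(1), 2)),
                  c("cr", "rc"))

  gml <- tempfile(fileext = ".graphml")
  exportGraph(g, "graphml", gml)
  g2 <- read_graph(gml, format = "graphml")
  expect_equal(vcount(g2), vcount(g))
  expect_setequal(V(g2)$kind, c("compound", "reaction"))

  # edge-table round trip reproduces the edge multiset
  prefix <- tempfile()
  paths <- exportGraph(g, "tables", prefix)
  nodes <- utils::read.delim(paste0(prefix, "-nodes.tsv"))
  edges <- utils::read.delim(paste0(prefix, "-edges.tsv"))
  expect_setequal(nodes$id, V(g)$name)
  e <- as_data_frame(g, what = "edges")
  expect_setequal(paste(edges$source, edges$target, edges$transfer),
                  paste(e$from, e$to, e$transfer))

  expect_error(exportGraph(g, "dot", tempfile()), "unknown graph format")

  # empty graphs serialize to valid empty documents
  eg <- buildConventionalGraph(
    ReactionSet(data.frame(id = character(0), formula = character(0)),
                list()))
  f <- tempfile()
  exportGraph(eg, "sif", f)
  expect_length(readLines(f), 0)
  exportGraph(eg, "graphml", f)
  expect_equal(vcount(read_graph(f, format = "graphml")), 0)
})

test_that("main-pathway compounds receive the width hint", {
  rs <- toyFiltered()
  g <- buildConventionalGraph(rs, mainCompounds = c("akg", "succoa"))
  e <- as_data_frame(g, what = "edges")
  expect_true(all(e$main[e$from == "akg" | e$to == "akg"]))
  expect_false(any(e$main[e$from == "glc-D"]))
})
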