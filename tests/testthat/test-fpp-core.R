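# scoring, greedy assignment, and iterative refinement

test_that("weightedJaccard matches hand-evaluated values", {
  w <- elementWeights()
  glc <- parseFormula("C6H12O6")
  g6p <- parseFormula("C6H11O9P")
  # shared C6 + 0.82*(O6) over C6 + 0.82*(O9+P1)
  expect_equal(weightedJaccard(glc, g6p, w), 10.92 / 14.20,
               tolerance = 1e-12)
  atp <- parseFormula("C10H12N5O13P3")
  adp <- parseFormula("C10H12N5O10P2")
  expect_equal(weightedJaccard(atp, adp, w), 23.94 / 27.22,
               tolerance = 1e-12)
  # hydrogen has weight zero: NAD vs NADH are indistinguishable
  expect_equal(weightedJaccard(parseFormula("C21H26N7O14P2"),
                               parseFormula("C21H27N7O14P2"), w), 1)
  # self-similarity
  expect_equal(weightedJaccard(glc, glc, w), 1)
  # zero denominator convention
  expect_equal(weightedJaccard(parseFormula("H2"), parseFormula("H"), w), 0)
})

test_that("weightedJaccard is symmetric, bounded, and reduces to the", {
  # unweighted Jaccard under equal positive weights
  set.seed(7)
  wEq <- elementWeights(C = 0.5, H = 0.5, other = 0.5)
  for (i in 1:30) {
    a <- randomFormula()
    b <- randomFormula()
    j1 <- weightedJaccard(a, b)
    expect_equal(j1, weightedJaccard(b, a))
    expect_gte(j1, 0)
    expect_lte(j1, 1)
    els <- union(names(a), names(b))
    av <- as.numeric(a)[match(els, names(a))]
    bv <- as.numeric(b)[match(els, names(b))]
    av[is.na(av)] <- 0
    bv[is.na(bv)] <- 0
    expect_equal(weightedJaccard(a, b, wEq),
                 sum(pmin(av, bv)) / sum(pmax(av, bv)))
  }
})

test_that("correctedScore is the product with the identity at theta0 = 1", {
  expect_equal(correctedScore(0.769, 1.0), 0.769)
  expect_equal(correctedScore(0.42, 0), 0)
  expect_equal(correctedScore(0.8795, 0.0233), 0.8795 * 0.0233)
  expect_error(correctedScore(1.2, 0.5), "\\[0, 1\\]")
})

test_that("thetaMapEstimate is the beta posterior mode", {
  p <- priorParams()
  expect_equal(thetaMapEstimate(0, 5, p), 0)
  expect_equal(thetaMapEstimate(1, 1, p), 1 / 43)
  expect_equal(thetaMapEstimate(10, 10, p), 10 / 52)
  expect_error(thetaMapEstimate(3, 2, p), "y must satisfy")
  # degenerate denominator convention (outside the grid range)
  expect_equal(thetaMapEstimate(0, 0, priorParams(alpha = 0.5, beta = 0.5)),
               0.5)
  # cross-check against numeric maximization of the posterior density
  for (n in c(1, 3, 10)) {
    for (y in 0:n) {
      expect_equal(thetaMapEstimate(y, n, p), thetaNumericOracle(y, n),
                   tolerance = 1e-6)
    }
  }
})

test_that("HEX1 resolves to the four expected transfers at theta0 = 1", {
  rs <- toyFiltered()
  out <- assignReactionPairs(rs, "HEX1")
  expect_false(out$tie)
  p <- out$pairs
  expect_equal(nrow(p), 4)
  key <- paste(p$reactant, p$product, p$transfer)
  expect_setequal(key, c("glc-D g6p C6H11O6",
                         "atp adp C10H12N5O10P2",
                         "atp g6p O3P",
                         "glc-D h H"))
})

test_that("AKGDH resolves to the four expected transfers at theta0 = 1", {
  rs <- toyFiltered()
  out <- assignReactionPairs(rs, "AKGDH")
  p <- out$pairs
  expect_equal(nrow(p), 4)
  key <- paste(p$reactant, p$product, p$transfer)
  expect_setequal(key, c("nad nadh C21H26N7O14P2",
                         "coa succoa C21H32N7O16P3S",
                         "akg succoa C4H3O3",
                         "akg co2 CO2"))
})

test_that("a single identical reactant/product gives one full transfer", {
  rs <- makeRS(c(A = "C2H6O", B = "C2H6O"), list(R1 = "A => B"))
  p <- assignReactionPairs(rs, "R1")$pairs
  expect_equal(nrow(p), 1)
  expect_identical(p$transfer, "C2H6O")
})

test_that("one carbon-transferring pair on a 1-to-1 carbon reaction", {
  set.seed(11)
  for (i in 1:10) {
    a <- randomFormula()
    if (!("C" %in% names(a))) a <- primarypairs:::.formula(c(unclass(a), C = 3))
    rs <- makeRS(c(A = formulaToText(a), B = formulaToText(a)),
                 list(R1 = "A => B"))
    p <- assignReactionPairs(rs, "R1")$pairs
    carbon <- vapply(p$transfer,
                     function(tr) containsCarbon(parseFormula(tr)),
                     logical(1))
    expect_equal(sum(carbon), 1)
  }
})

test_that("updateThetaTable counts binary incidence per reaction", {
  rs <- toyFiltered()["HEX1"]
  a <- assignReactionPairs(rs, "HEX1")$pairs
  th <- updateThetaTable(list(HEX1 = a), rs)
  # 2 reactants x 3 products co-occur
  expect_equal(nrow(th), 6)
  expect_true(all(th$nCount == 1))
  row <- function(x, y) th[th$x == min(x, y) & th$y == max(x, y), ]
  expect_equal(row("atp", "adp")$yCount, 1)
  expect_equal(row("atp", "adp")$thetaHat, 1 / 43)
  expect_equal(row("glc-D", "adp")$yCount, 0)
  expect_equal(row("glc-D", "adp")$thetaHat, 0)

  # a pair assigned through two instances still counts once
  rs2 <- makeRS(c(A = "C2H4", B = "C2H4"), list(DUP = "2 A => 2 B"))
  a2 <- assignReactionPairs(rs2, "DUP")$pairs
  expect_equal(nrow(a2), 2)
  th2 <- updateThetaTable(list(DUP = a2), rs2)
  expect_equal(th2$yCount, 1)
  expect_equal(th2$nCount, 1)

  # empty input
  e <- ReactionSet(data.frame(id = character(0), formula = character(0)),
                   list())
  expect_equal(nrow(updateThetaTable(list(), e)), 0)
})

test_that("findPrimaryPairs converges on the toy fixtures", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs["HEX1"])
  expect_true(converged(res))
  expect_equal(nrow(primaryPairs(res)), 4)

  # k duplicated copies: theta for assigned pairs is k/(k+42)
  k <- 5
  rx <- lapply(seq_len(k), function(i) {
    r <- getReaction(rs, "HEX1")
    r$id <- paste0("HEX1_", i)
    r
  })
  rs5 <- ReactionSet(compounds(toyModel()), rx)
  res5 <- findPrimaryPairs(rs5)
  th <- thetaTable(res5)
  expect_true(all(th$thetaHat[th$yCount > 0] == k / (k + 42)))
  for (i in seq_len(k)) {
    p <- primaryPairs(res5)
    expect_equal(sum(p$reaction == paste0("HEX1_", i)), 4)
  }

  # empty set converges in one iteration
  e <- ReactionSet(data.frame(id = character(0), formula = character(0)),
                   list())
  rese <- findPrimaryPairs(e)
  expect_true(converged(rese))
  expect_equal(iterations(rese), 1L)
  expect_equal(nrow(primaryPairs(rese)), 0)
})

test_that("assignments are stable at convergence (idempotence)", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs)
  expect_true(converged(res))
  pp <- primaryPairs(res)
  for (rid in reactionIds(rs)) {
    again <- assignReactionPairs(rs, rid, theta = res)$pairs
    have <- pp[pp$reaction == rid, c("reactant", "product", "transfer")]
    rownames(have) <- NULL
    expect_identical(again[, c("reactant", "product", "transfer")], have)
  }
})

test_that("non-hydrogen elements are conserved on fixtures and synthetics", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs)
  expect_length(verifyElementConservation(res, rs), 0)

  syn <- generateSynthetic(syntheticSpec(seed = 3, nReactions = 40))
  res2 <- findPrimaryPairs(syn$model)
  expect_length(verifyElementConservation(res2, syn$model), 0)
})

test_that("every element is accounted for even at W_other = 0", {
  # with zero weight on non-carbon elements, phosphate-type transfers score
  # zero; the rescue selection must still conserve them
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs, weights = elementWeights(other = 0))
  expect_true(converged(res))
  expect_length(verifyElementConservation(res, rs), 0)
})

test_that("prediction output is byte-identical across repeated runs", {
  syn <- generateSynthetic(syntheticSpec(seed = 5, nReactions = 20))
  f1 <- tempfile()
  f2 <- tempfile()
  writePairPredictions(findPrimaryPairs(syn$model), f1)
  writePairPredictions(findPrimaryPairs(syn$model), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("score ties between distinct compound pairs are flagged", {
  sym <- makeRS(c(A = "C2H4", B = "C2H4", C = "C2H4", D = "C2H4"),
                list(SYM = "A + B => C + D"))
  res <- findPrimaryPairs(sym)
  expect_identical(detectAmbiguousReactions(res), "SYM")
  # tie broken by sorted names: A pairs with C first
  p <- primaryPairs(res)
  expect_identical(p$reactant[1], "A")
  expect_identical(p$product[1], "C")

  # duplicate instances of the same compound pair are not a real tie
  dup <- makeRS(c(A = "C2H4", B = "C2H4"), list(DUP = "2 A => 2 B"))
  expect_length(detectAmbiguousReactions(findPrimaryPairs(dup)), 0)

  # HEX1 has strictly ordered scores at every step
  expect_length(detectAmbiguousReactions(findPrimaryPairs(toyFiltered()["HEX1"])),
                0)
})

test_that("transaldolase pairs by formula similarity, not mechanism", {
  tala <- makeRS(c(s7p = "C7H13O10P", g3p = "C3H5O6P",
                   e4p = "C4H7O7P", f6p = "C6H11O9P"),
                 list(TALA = "s7p + g3p => e4p + f6p"))
  res <- findPrimaryPairs(tala)
  p <- primaryPairs(res)
  expect_true(any(p$reactant == "s7p" & p$product == "f6p"))
  expect_true(any(p$reactant == "g3p" & p$product == "e4p"))
})

test_that("compartment handling: merged theta keys, strict mode separates", {
  rs <- makeRS(c("X[c]" = "C3H6O", "X[p]" = "C3H6O", "Y[c]" = "C3H4O",
                 "Z[c]" = "C3H8O"),
               list(T1 = "X[p] => X[c]", R1 = "X[c] => Y[c]",
                    R2 = "X[c] => Z[c]"))
  res <- findPrimaryPairs(rs)
  th <- thetaTable(res)
  # default keying strips the compartment: the transporter reinforces {X, X}
  expect_true("X" %in% th$x | "X" %in% th$y)
  resStrict <- findPrimaryPairs(rs, strictCompartments = TRUE)
  thS <- thetaTable(resStrict)
  expect_true(any(grepl("\\[", thS$x)))
})

test_that("unconverged runs are reported honestly", {
  syn <- generateSynthetic(syntheticSpec(seed = 9, nReactions = 30))
  expect_warning(
    res <- findPrimaryPairs(syn$model,
                            prior = priorParams(maxIterations = 1L)),
    "did not converge")
  expect_false(converged(res))
  expect_equal(iterations(res), 1L)
})
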