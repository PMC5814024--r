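# model table reading/writing and the reaction-exclusion filters

test_that("the bundled model tables round-trip against toyModel()", {
  dir <- system.file("extdata", "toy_model", package = "primarypairs")
  rs <- readReactionSet(dir)
  toy <- toyModel()
  expect_identical(reactionIds(rs), reactionIds(toy))
  expect_identical(compounds(rs)$id, compounds(toy)$id)
  expect_identical(compounds(rs)$formula, compounds(toy)$formula)
  for (rid in reactionIds(rs)) {
    expect_identical(getReaction(rs, rid)$reactants,
                     getReaction(toy, rid)$reactants)
    expect_identical(getReaction(rs, rid)$products,
                     getReaction(toy, rid)$products)
  }
  expect_true(getReaction(rs, "SUCOAS")$reversible)
  expect_false(getReaction(rs, "HEX1")$reversible)
})

test_that("writeReactionSet is the inverse of readReactionSet", {
  dir <- tempfile()
  writeReactionSet(toyModel(), dir)
  rs <- readReactionSet(dir)
  expect_identical(compounds(rs), compounds(toyModel()))
  expect_equal(rs@reactions, toyModel()@reactions)
})

test_that("reader errors and warnings follow the contract", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("id\tformula\nA\tC2H4", file.path(dir, "compounds.tsv"))
  writeLines("id\tequation\nR1\tA => B", file.path(dir, "reactions.tsv"))
  expect_error(readReactionSet(dir), "R1.*B|B.*R1")

  writeLines("id\tequation\nR1\tA => A\nR1\tA => A",
             file.path(dir, "reactions.tsv"))
  expect_error(readReactionSet(dir), "duplicate reaction id")

  writeLines("id\tequation", file.path(dir, "reactions.tsv"))
  expect_warning(rs <- readReactionSet(dir), "empty")
  expect_equal(nReactions(rs), 0)
})

test_that("equation dialect: coefficients, reversibility, compartments", {
  rs <- makeRS(c("A[c]" = "C2H4", "A[p]" = "C2H4", B = "C4H8"),
               list(T1 = "A[c] => A[p]", R1 = "2 A[c] <=> B"))
  r <- getReaction(rs, "R1")
  expect_equal(r$reactants$coef, 2)
  expect_true(r$reversible)
  cpd <- compounds(rs)
  expect_equal(cpd$compartment[cpd$id == "A[c]"], "c")
  expect_true(is.na(cpd$compartment[cpd$id == "B"]))
})

test_that("duplicate compounds on one side merge by summing coefficients", {
  rs <- ReactionSet(
    data.frame(id = c("A", "B"), formula = c("C2H4", "C4H8")),
    list(list(id = "R1",
              reactants = data.frame(compound = c("A", "A"), coef = c(1, 1)),
              products = data.frame(compound = "B", coef = 1))))
  expect_equal(getReaction(rs, "R1")$reactants$coef, 2)
})

test_that("filterReactions applies the exclusion rules in order", {
  rs <- makeRS(
    c(A = "C2H4", B = "C2H4", V = "(C2H4O)n", U = "xyz", C3 = "C3H6",
      D = "C2H4"),
    list(OK = "A => B",
         VAR = "V => A",         # variable formula
         UNP = "U => A",          # unparseable formula
         BAL = "A => C3",         # non-hydrogen imbalance
         SYN = "A => D",          # synthetic flag
         FRC = "0.5 A => 0.5 B"), # non-integer stoichiometry
    synthetic = "SYN")
  flt <- filterReactions(rs)
  expect_identical(reactionIds(flt$model), "OK")
  ex <- flt$exclusions
  expect_equal(ex$reason[match(c("VAR", "UNP", "BAL", "SYN", "FRC"),
                               ex$reaction)],
               c("variable-formula", "unparseable-formula", "unbalanced",
                 "synthetic", "non-integer-stoichiometry"))
  # partition: every reaction in exactly one of retained/log
  expect_setequal(c(reactionIds(flt$model), ex$reaction), reactionIds(rs))
  expect_equal(nReactions(flt$model) + nrow(ex), nReactions(rs))
  # idempotent
  again <- filterReactions(flt$model)
  expect_equal(nrow(again$exclusions), 0)
  expect_identical(reactionIds(again$model), reactionIds(flt$model))
})

test_that("synthetic reactions are recognized by id pattern fallback", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("id\tformula\nA\tC2H4", file.path(dir, "compounds.tsv"))
  writeLines("id\tequation\nBiomass_core\tA =>\nEX_a\tA =>\nR1\tA => A",
             file.path(dir, "reactions.tsv"))
  rs <- readReactionSet(dir)
  expect_true(getReaction(rs, "Biomass_core")$synthetic)
  expect_true(getReaction(rs, "EX_a")$synthetic)
  expect_false(getReaction(rs, "R1")$synthetic)
  rs2 <- readReactionSet(dir, detectSynthetic = FALSE)
  expect_false(getReaction(rs2, "Biomass_core")$synthetic)
})

test_that("readReferencePairs validates, drops, and logs coverage", {
  rs <- toyFiltered()
  ref <- readReferencePairs(toyReferencePath(), rs)
  expect_equal(nrow(ref$pairs), 15)
  expect_true(all(c("HEX1", "AKGDH") %in% ref$pairs$reaction))
  expect_equal(nrow(ref$exclusions), 0)  # every toy reaction is covered

  # unknown reaction and off-side compound rows are dropped with a warning
  p <- tempfile()
  writeLines(c("reaction\treactant\tproduct",
               "HEX1\tatp\tadp",
               "NOPE\tatp\tadp",
               "HEX1\tg6p\tatp"), p)
  expect_warning(ref2 <- readReferencePairs(p, rs), "2 reference pair")
  expect_equal(nrow(ref2$pairs), 1)
  # carbon-containing reactions without coverage get logged
  expect_true(all(c("AKGDH", "ICL") %in% ref2$exclusions$reaction))
  expect_true(all(ref2$exclusions$reason == "missing-reference"))

  # empty file is a valid empty reference
  p2 <- tempfile()
  writeLines("reaction\treactant\tproduct", p2)
  ref3 <- suppressWarnings(readReferencePairs(p2, rs))
  expect_equal(nrow(ref3$pairs), 0)

  # malformed rows are an error naming the line
  p3 <- tempfile()
  writeLines(c("reaction\treactant\tproduct", "HEX1\tatp\t"), p3)
  expect_error(readReferencePairs(p3, rs), "line")
})

test_that("writePairPredictions emits the documented deterministic table", {
  rs <- toyFiltered()
  res <- findPrimaryPairs(rs["HEX1"])
  p <- tempfile()
  writePairPredictions(res, p)
  df <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_identical(names(df), c("reaction", "reactant", "product",
                                "transfer", "score"))
  expect_equal(nrow(df), 4)
  akg <- findPrimaryPairs(rs["AKGDH"])
  writePairPredictions(akg, p)
  df <- utils::read.delim(p, stringsAsFactors = FALSE)
  expect_true(any(df$reactant == "nad" & df$product == "nadh" &
                  df$transfer == "C21H26N7O14P2"))

  # empty prediction: header-only file
  e <- ReactionSet(data.frame(id = character(0), formula = character(0)),
                   list())
  writePairPredictions(findPrimaryPairs(e), p)
  expect_equal(length(readLines(p)), 1)
})
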