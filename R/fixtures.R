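# bundled worked-example model and synthetic balanced-reaction generator

.TOY_COMPOUNDS <- data.frame(
  id = c("glc-D", "atp", "adp", "g6p", "h", "akg", "coa", "succoa", "co2",
         "nad", "nadh", "pi", "succ", "icit", "glx", "accoa", "h2o",
         "mal-L"),
  formula = c("C6H12O6", "C10H12N5O13P3", "C10H12N5O10P2", "C6H11O9P", "H",
              "C5H4O5", "C21H32N7O16P3S", "C25H35N7O19P3S", "CO2",
              "C21H26N7O14P2", "C21H27N7O14P2", "HO4P", "C4H4O4", "C6H5O7",
              "C2HO3", "C23H34N7O17P3S", "H2O", "C4H4O5"),
  name = c("D-Glucose", "ATP", "ADP", "D-Glucose 6-phosphate", "H+",
           "2-Oxoglutarate", "Coenzyme A", "Succinyl-CoA", "CO2", "NAD",
           "NADH", "Phosphate", "Succinate", "Isocitrate", "Glyoxylate",
           "Acetyl-CoA", "H2O", "L-Malate"),
  stringsAsFactors = FALSE)

.TOY_REACTIONS <- data.frame(
  id = c("HEX1", "AKGDH", "SUCOAS", "ICL", "MALS"),
  equation = c(
    "atp + glc-D => adp + g6p + h",
    "akg + coa + nad => co2 + nadh + succoa",
    "atp + coa + succ <=> adp + pi + succoa",
    "icit => glx + succ",
    "accoa + glx + h2o => coa + h + mal-L"),
  stringsAsFactors = FALSE)

#' Bundled worked-example reaction set
#'
#' A small glycolysis/TCA-cycle neighborhood: the glucose kinase reaction
#' HEX1 (\code{atp + glc-D => adp + g6p + h}), the 2-oxoglutarate
#' dehydrogenase reaction AKGDH
#' (\code{akg + coa + nad => co2 + nadh + succoa}), succinyl-CoA synthetase
#' SUCOAS, isocitrate lyase ICL, and malate synthase MALS, with standard
#' compound formulas. Every reaction is balanced in its non-hydrogen
#' elements and passes [filterReactions()] unchanged. The same model is
#' shipped as delimited tables under
#' \code{system.file("extdata", "toy_model", package = "primarypairs")}
#' together with curated reference pairs for the evaluation examples.
#'
#' @return a [ReactionSet-class] with 5 reactions over 18 compounds.
#' @examples
#' rs <- toyModel()
#' checkBalance(getReaction(rs, "AKGDH"), compoundFormulas(rs))$balanced
#' @export
toyModel <- function() {
  reactions <- lapply(seq_len(nrow(.TOY_REACTIONS)), function(i) {
    rid <- .TOY_REACTIONS$id[i]
    eq <- .parseEquation(.TOY_REACTIONS$equation[i], rid)
    list(id = rid, reactants = eq$reactants, products = eq$products,
         reversible = eq$reversible, synthetic = FALSE)
  })
  ReactionSet(.TOY_COMPOUNDS, reactions)
}

#' Specification for the synthetic balanced-reaction generator
#'
#' @param seed integer random seed; identical specs generate identical
#'   reaction sets.
#' @param nReactions number of reactions to generate.
#' @param poolSize number of distinct moieties (indivisible transferred
#'   sub-formulas) in the compound pool. Moieties are constructed pairwise
#'   dissimilar (weighted Jaccard below \code{maxSimilarity} at default
#'   weights), so the ground-truth pairing is recoverable from formula
#'   similarity.
#' @param elements element alphabet the moieties draw from (carbon and
#'   hydrogen are always included).
#' @param maxCoef maximum stoichiometric coefficient a compound may take.
#' @param currencyFraction fraction of reactions that additionally consume
#'   an ATP-like currency compound and release its ADP-like and
#'   phosphate-like moieties, so the probability-reinforcement mechanism
#'   sees a recurring compound pair.
#' @param maxSimilarity pairwise moiety similarity ceiling.
#' @return a \code{syntheticSpec} object (a named list).
#' @export
syntheticSpec <- function(seed = 1L, nReactions = 50L, poolSize = 10L,
                          elements = c("C", "H", "O", "N", "S"),
                          maxCoef = 2L, currencyFraction = 0.3,
                          maxSimilarity = 0.5) {
  if (poolSize < 3L) {
    stop("degenerate spec: poolSize must be at least 3")
  }
  if (nReactions < 1L) {
    stop("degenerate spec: nReactions must be at least 1")
  }
  if (currencyFraction < 0 || currencyFraction > 1) {
    stop("currencyFraction must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), nReactions = as.integer(nReactions),
                 poolSize = as.integer(poolSize),
                 elements = union(c("C", "H"), elements),
                 maxCoef = as.integer(maxCoef),
                 currencyFraction = currencyFraction,
                 maxSimilarity = maxSimilarity),
            class = "syntheticSpec")
}

.CURRENCY <- list(
  A = c(C = 10, H = 12, N = 5, O = 13, P = 3),
  B = c(C = 10, H = 12, N = 5, O = 10, P = 2),
  P = c(O = 3, P = 1))

# moiety pool: carbon counts spaced geometrically so that any two moieties
# are dissimilar under the default weights; composition is randomized and
# screened against the ceiling
.makeMoieties <- function(spec) {
  w <- elementWeights()
  screen <- lapply(.CURRENCY, function(v) .formula(v))
  out <- list()
  base <- 2
  attempts <- 0L
  while (length(out) < spec$poolSize) {
    attempts <- attempts + 1L
    if (attempts > 1000L * spec$poolSize) {
      stop("degenerate spec: could not build ", spec$poolSize,
           " pairwise dissimilar moieties")
    }
    c0 <- max(2L, round(base * stats::runif(1, 0.85, 1.15)))
    f <- c(C = c0,
           H = sample.int(2L * c0 + 1L, 1L) - 1L,
           O = sample.int(max(1L, c0 %/% 2L) + 1L, 1L) - 1L,
           N = sample.int(max(1L, c0 %/% 3L) + 1L, 1L) - 1L,
           S = sample.int(2L, 1L) - 1L)
    f <- .formula(f[names(f) %in% spec$elements])
    ok <- all(vapply(c(out, screen), function(g) {
      weightedJaccard(f, g, w) < spec$maxSimilarity
    }, logical(1)))
    if (ok) {
      out[[length(out) + 1L]] <- f
      base <- base * 2.6
    }
  }
  names(out) <- sprintf("M%02d", seq_along(out))
  out
}

#' Generate a synthetic balanced reaction set with known pairing
#'
#' Each reaction is built by drawing a small multiset of moieties from a
#' pool of pairwise-dissimilar formulas; the reactant side carries one
#' compound per moiety and the product side re-partitions the same moieties
#' into compounds (single-moiety products, or conjugates summing two
#' moieties). Because both sides are exact sums of the same moiety
#' formulas, every reaction is element-balanced by construction, and the
#' moiety movements define a known ground-truth reactant/product pairing.
#' Optionally a currency triple (an ATP-like compound splitting into an
#' ADP-like and a phosphate-like product) recurs across reactions so that
#' the global probability-reinforcement mechanism is exercised.
#'
#' @param spec a [syntheticSpec()].
#' @return a list with \code{model} (a [ReactionSet-class]) and
#'   \code{reference} (the ground-truth pairs: a \code{data.frame} with
#'   columns \code{reaction}, \code{reactant}, \code{product}).
#' @examples
#' syn <- generateSynthetic(syntheticSpec(seed = 1, nReactions = 5))
#' nReactions(syn$model)
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "syntheticSpec"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(oldSeed)) {
      assign(".Random.seed", oldSeed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  moieties <- .makeMoieties(spec)
  mNames <- names(moieties)
  sumFormulas <- function(fs) {
    fs <- unname(fs)
    v <- unlist(lapply(fs, function(f) {
      x <- as.numeric(f)
      names(x) <- names(f)
      x
    }))
    .formula(v)
  }

  cpdId <- character(0)
  cpdFormula <- character(0)
  declare <- function(id, f) {
    if (!id %in% cpdId) {
      cpdId <<- c(cpdId, id)
      cpdFormula <<- c(cpdFormula, formulaToText(f))
    }
    id
  }
  for (nm in c("A", "B", "P")) {
    declare(paste0("cur_", nm), .formula(.CURRENCY[[nm]]))
  }

  reactions <- list()
  refReaction <- character(0)
  refReactant <- character(0)
  refProduct <- character(0)
  for (i in seq_len(spec$nReactions)) {
    rid <- sprintf("S%04d", i)
    k <- sample(2:3, 1L)
    picked <- sample(mNames, k)
    coef <- ifelse(stats::runif(k) < 0.2,
                   sample(seq_len(spec$maxCoef), k, replace = TRUE), 1L)
    reactants <- data.frame(compound = character(0), coef = numeric(0),
                            stringsAsFactors = FALSE)
    products <- data.frame(compound = character(0), coef = numeric(0),
                           stringsAsFactors = FALSE)
    addRow <- function(df, id, cf) {
      rbind(df, data.frame(compound = id, coef = cf,
                           stringsAsFactors = FALSE))
    }
    # moieties with coefficient 1 may merge pairwise into conjugate products
    mergeable <- picked[coef == 1L]
    merged <- character(0)
    if (length(mergeable) >= 2L && stats::runif(1) < 0.5) {
      merged <- sort(sample(mergeable, 2L))
    }
    for (j in seq_len(k)) {
      m <- picked[j]
      rId <- declare(paste0("r_", m), moieties[[m]])
      reactants <- addRow(reactants, rId, coef[j])
      if (m %in% merged) {
        cId <- declare(paste0("x_", paste(merged, collapse = "_")),
                       sumFormulas(moieties[merged]))
        if (!cId %in% products$compound) {
          products <- addRow(products, cId, 1L)
        }
        pId <- cId
      } else {
        pId <- declare(paste0("p_", m), moieties[[m]])
        products <- addRow(products, pId, coef[j])
      }
      refReaction <- c(refReaction, rid)
      refReactant <- c(refReactant, rId)
      refProduct <- c(refProduct, pId)
    }
    if (stats::runif(1) < spec$currencyFraction) {
      reactants <- addRow(reactants, "cur_A", 1L)
      products <- addRow(products, "cur_B", 1L)
      products <- addRow(products, "cur_P", 1L)
      refReaction <- c(refReaction, rid, rid)
      refReactant <- c(refReactant, "cur_A", "cur_A")
      refProduct <- c(refProduct, "cur_B", "cur_P")
    }
    reactions[[rid]] <- list(id = rid, reactants = reactants,
                             products = products, reversible = FALSE,
                             synthetic = FALSE)
  }

  cpd <- data.frame(id = cpdId, formula = cpdFormula,
                    stringsAsFactors = FALSE)
  list(model = ReactionSet(cpd, reactions),
       reference = unique(data.frame(reaction = refReaction,
                                     reactant = refReactant,
                                     product = refProduct,
                                     stringsAsFactors = FALSE)))
}
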