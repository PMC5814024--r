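# shared test helpers

# quick ReactionSet from formula strings and equation strings
makeRS <- function(formulas, equations, synthetic = NULL) {
  cpd <- data.frame(id = names(formulas), formula = unname(formulas),
                    stringsAsFactors = FALSE)
  rx <- lapply(seq_along(equations), function(i) {
    eq <- primarypairs:::.parseEquation(equations[[i]], names(equations)[i])
    list(id = names(equations)[i], reactants = eq$reactants,
         products = eq$products, reversible = eq$reversible,
         synthetic = !is.null(synthetic) && names(equations)[i] %in% synthetic)
  })
  ReactionSet(cpd, rx)
}

# independent oracle: numeric maximization of the beta posterior density
thetaNumericOracle <- function(y, n, alpha = 1, beta = 43) {
  a <- alpha + y
  b <- beta + n - y
  stats::optimize(function(t) stats::dbeta(t, a, b),
                  interval = c(0, 1), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# independent oracle: MCC as Pearson correlation of binary label vectors
mccPearsonOracle <- function(tp, fp, fn, tn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  stats::cor(pred, truth)
}

# random canonical formula over a small alphabet
randomFormula <- function() {
  els <- sample(c("C", "H", "N", "O", "P", "S"), sample(1:4, 1))
  counts <- sample(1:20, length(els), replace = TRUE)
  names(counts) <- els
  primarypairs:::.formula(counts)
}

toyFiltered <- function() filterReactions(toyModel())$model

toyReferencePath <- function() {
  system.file("extdata", "toy_model", "pairs.tsv", package = "primarypairs")
}
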