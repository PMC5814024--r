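# primary-pair prediction: weighted Jaccard scoring, greedy per-reaction
# assignment, and global iterative beta-binomial MAP refinement

#' Element weights for the similarity score
#'
#' Carbon forms the backbone of organic molecules, so matching carbon counts
#' are the strongest evidence of structural similarity; hydrogen is
#' peripheral and uninformative. The defaults (carbon 1, hydrogen 0, all
#' other elements 0.82) are the grid-search optima used throughout.
#'
#' @param C,H,other weights in \code{[0, 1]} for carbon, hydrogen, and every
#'   other element.
#' @return an \code{elementWeights} object (a named list).
#' @export
elementWeights <- function(C = 1, H = 0, other = 0.82) {
  w <- c(C = as.numeric(C), H = as.numeric(H), other = as.numeric(other))
  if (any(is.na(w)) || any(w < 0) || any(w > 1)) {
    stop("element weights must lie in [0, 1]")
  }
  structure(as.list(w), class = "elementWeights")
}

#' Prior and convergence parameters
#'
#' The per-compound-pair probability of being a primary pair is modeled with
#' a beta distribution; its prior \code{Beta(alpha, beta)} is updated with
#' the binary per-reaction assignment incidences and summarized by the
#' posterior mode (MAP). Defaults \code{alpha = 1}, \code{beta = 43} are the
#' grid-search optima; iteration stops when every point estimate moves less
#' than \code{epsilon} between successive iterations.
#'
#' @param alpha,beta beta prior parameters (each >= 1 in the supported
#'   grid range).
#' @param epsilon convergence tolerance on the point estimates.
#' @param maxIterations iteration cap; exceeding it returns an unconverged
#'   result with a warning.
#' @return a \code{priorParams} object (a named list).
#' @export
priorParams <- function(alpha = 1, beta = 43, epsilon = 1e-5,
                        maxIterations = 100L) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0) {
    stop("alpha and beta must be non-negative numbers")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be positive")
  }
  if (!is.numeric(maxIterations) || maxIterations < 1) {
    stop("maxIterations must be a positive integer")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 epsilon = as.numeric(epsilon),
                 maxIterations = as.integer(maxIterations)),
            class = "priorParams")
}

# raw (unclassed named numeric) formula helpers for the inner loop
.rawAlign <- function(a, b) {
  els <- union(names(a), names(b))
  av <- as.numeric(a)[match(els, names(a))]
  bv <- as.numeric(b)[match(els, names(b))]
  av[is.na(av)] <- 0
  bv[is.na(bv)] <- 0
  list(els = els, a = av, b = bv)
}

.rawJaccard <- function(a, b, wC, wH, wOther) {
  x <- .rawAlign(a, b)
  if (!length(x$els)) {
    return(0)
  }
  we <- ifelse(x$els == "C", wC, ifelse(x$els == "H", wH, wOther))
  den <- sum(pmax(x$a, x$b) * we)
  if (den <= 0) 0 else sum(pmin(x$a, x$b) * we) / den
}

.rawShared <- function(a, b) {
  els <- intersect(names(a), names(b))
  if (!length(els)) {
    return(numeric(0))
  }
  m <- pmin(a[els], b[els])
  m[m > 0]
}

.rawSubtract <- function(a, b) {
  for (el in names(b)) {
    a[el] <- a[el] - b[el]
  }
  a[a > 1e-9]
}

#' Weighted Jaccard similarity of two formulas
#'
#' The ratio of weighted element-wise minima to weighted element-wise maxima
#' over the union of elements of the two formulas. Returns 0 when the
#' denominator is 0 (both formulas contain only zero-weight elements).
#'
#' @param a,b non-variable \code{chemFormula} objects.
#' @param weights an [elementWeights()] object.
#' @return a similarity in \code{[0, 1]}.
#' @examples
#' weightedJaccard(parseFormula("C6H12O6"), parseFormula("C6H11O9P"))
#' @export
weightedJaccard <- function(a, b, weights = elementWeights()) {
  .assertArithmetic(a, "first formula")
  .assertArithmetic(b, "second formula")
  stopifnot(inherits(weights, "elementWeights"))
  .rawJaccard(a, b, weights$C, weights$H, weights$other)
}

#' Corrected pair score
#'
#' The similarity of a candidate instance pair multiplied by the current
#' point estimate of the probability that its compound pair is a primary
#' pair in any reaction.
#'
#' @param jaccard a similarity in \code{[0, 1]}.
#' @param thetaHat a point estimate in \code{[0, 1]}.
#' @return the product.
#' @export
correctedScore <- function(jaccard, thetaHat) {
  if (any(jaccard < 0 | jaccard > 1) || any(thetaHat < 0 | thetaHat > 1)) {
    stop("both arguments must lie in [0, 1]")
  }
  jaccard * thetaHat
}

#' MAP estimate of the pair probability
#'
#' The mode of the beta posterior \code{Beta(alpha + y, beta + n - y)},
#' i.e. \code{(alpha + y - 1) / (alpha + beta + n - 2)}, clamped to
#' \code{[0, 1]}. When the denominator is not positive (only possible for
#' \code{alpha + beta < 2}, outside the supported grid range) the
#' uninformative value 0.5 is returned by convention.
#'
#' @param y number of reactions in which the pair was assigned (0 <= y <= n).
#' @param n number of reactions in which the pair co-occurs on opposite
#'   sides.
#' @param prior a [priorParams()] object.
#' @return the point estimate(s); vectorized over \code{y} and \code{n}.
#' @examples
#' thetaMapEstimate(1, 1)   # 1/43
#' thetaMapEstimate(10, 10) # 10/52
#' @export
thetaMapEstimate <- function(y, n, prior = priorParams()) {
  stopifnot(inherits(prior, "priorParams"))
  if (any(y < 0) || any(y > n)) {
    stop("y must satisfy 0 <= y <= n")
  }
  k <- max(length(y), length(n))
  y <- rep_len(y, k)
  n <- rep_len(n, k)
  den <- prior$alpha + prior$beta + n - 2
  out <- ifelse(den > 0, (prior$alpha + y - 1) / den, 0.5)
  pmin(1, pmax(0, out))
}

# --- theta table keying ----------------------------------------------------

.thetaId <- function(ids, strict) {
  if (strict) ids else .stripCompartment(ids)
}

.pairKey <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# turn various user-supplied theta representations into a lookup function
.thetaLookup <- function(theta, strict) {
  if (is.null(theta)) {
    return(function(keys) rep(1, length(keys)))
  }
  if (is(theta, "PredictionResult")) {
    theta <- thetaTable(theta)
  }
  if (is.data.frame(theta)) {
    v <- theta$thetaHat
    names(v) <- .pairKey(theta$x, theta$y)
    theta <- v
  }
  stopifnot(is.numeric(theta), !is.null(names(theta)))
  function(keys) {
    out <- unname(theta[keys])
    out[is.na(out)] <- 1
    out
  }
}

# --- per-reaction greedy assignment ----------------------------------------

# expand one reaction side into compound instances
.expandSide <- function(side, formulas) {
  type <- character(0)
  idx <- integer(0)
  for (k in seq_len(nrow(side))) {
    cf <- round(side$coef[k])
    if (abs(side$coef[k] - cf) > 1e-9) {
      stop("non-integer stoichiometric coefficient for compound '",
           side$compound[k], "' (filter the reaction set first)")
    }
    type <- c(type, rep(side$compound[k], cf))
    idx <- c(idx, seq_len(cf))
  }
  residual <- lapply(type, function(cid) {
    f <- formulas[[cid]]
    if (is.null(f) || isVariableFormula(f)) {
      stop("compound '", cid, "' has no usable formula ",
           "(filter the reaction set first)")
    }
    v <- as.numeric(f)
    names(v) <- names(f)
    v
  })
  hOnly <- vapply(residual, function(v) {
    length(v) > 0 && all(names(v) == "H")
  }, logical(1))
  list(type = type, idx = idx, residual = residual, hOnly = hOnly,
       alive = rep(TRUE, length(type)), paired = rep(FALSE, length(type)))
}

# greedy pair selection for one reaction; theta held fixed throughout
.assignPairs <- function(reaction, formulas, nameOf, thetaOf, weights,
                         tieTol = 1e-9, strict = FALSE) {
  L <- .expandSide(reaction$reactants, formulas)
  R <- .expandSide(reaction$products, formulas)
  outReactant <- character(0)
  outProduct <- character(0)
  outTransfer <- character(0)
  outScore <- numeric(0)
  tie <- FALSE
  wC <- weights$C
  wH <- weights$H
  wO <- weights$other

  repeat {
    ia <- which(L$alive)
    ib <- which(R$alive)
    if (!length(ia) || !length(ib)) break
    m <- length(ia) * length(ib)
    li <- rep(ia, times = length(ib))
    rj <- rep(ib, each = length(ia))
    jac <- vapply(seq_len(m), function(k) {
      .rawJaccard(L$residual[[li[k]]], R$residual[[rj[k]]], wC, wH, wO)
    }, numeric(1))
    keys <- .pairKey(.thetaId(L$type[li], strict), .thetaId(R$type[rj], strict))
    th <- thetaOf(keys)
    corrected <- jac * th
    pool <- corrected
    if (max(pool) <= 0) pool <- jac
    if (max(pool) <= 0) {
      # rescue: all weighted scores vanish (zero-weight elements only);
      # select by hydrogen-blind unweighted similarity so that every
      # remaining non-hydrogen element is still accounted for
      pool <- vapply(seq_len(m), function(k) {
        .rawJaccard(L$residual[[li[k]]], R$residual[[rj[k]]], 1, 0, 1)
      }, numeric(1))
    }
    top <- max(pool)
    if (top <= 0) break
    sel <- which(pool >= top * (1 - tieTol))
    if (length(unique(keys[sel])) > 1L) tie <- TRUE
    if (length(sel) > 1L) {
      ord <- order(nameOf[L$type[li[sel]]], nameOf[R$type[rj[sel]]],
                   L$idx[li[sel]], R$idx[rj[sel]])
      sel <- sel[ord]
    }
    k <- sel[1]
    a <- li[k]
    b <- rj[k]
    transfer <- .rawShared(L$residual[[a]], R$residual[[b]])
    if (!length(transfer)) break  # cannot happen when pool > 0
    outReactant <- c(outReactant, L$type[a])
    outProduct <- c(outProduct, R$type[b])
    outTransfer <- c(outTransfer, formulaToText(.formula(transfer)))
    outScore <- c(outScore, corrected[k])
    L$residual[[a]] <- .rawSubtract(L$residual[[a]], transfer)
    R$residual[[b]] <- .rawSubtract(R$residual[[b]], transfer)
    L$paired[a] <- TRUE
    R$paired[b] <- TRUE
    if (!length(L$residual[[a]])) L$alive[a] <- FALSE
    if (!length(R$residual[[b]])) R$alive[b] <- FALSE
  }

  # hydrogen-residue rule:
  # (a) a wholly hydrogen-only compound instance (e.g. the proton) that was
  #     never paired receives its hydrogen from (or donates it to) the
  #     opposite-side instance holding the largest hydrogen residual;
  # (b) residual hydrogen on multi-element compounds is dropped silently.
  hPair <- function(xSide, oppSide, xIsProduct) {
    cand <- which(xSide$hOnly & !xSide$paired & xSide$alive)
    if (length(cand) > 1L) {
      cand <- cand[order(nameOf[xSide$type[cand]], xSide$idx[cand])]
    }
    for (a in cand) {
      hRes <- vapply(seq_along(oppSide$type), function(b) {
        if (!oppSide$alive[b]) return(0)
        v <- oppSide$residual[[b]]
        if ("H" %in% names(v)) v[["H"]] else 0
      }, numeric(1))
      if (max(hRes) <= 0) next
      best <- which(hRes >= max(hRes) - 1e-9)
      if (length(best) > 1L) {
        best <- best[order(nameOf[oppSide$type[best]], oppSide$idx[best])]
      }
      b <- best[1]
      amount <- min(xSide$residual[[a]][["H"]], hRes[b])
      transfer <- c(H = amount)
      if (xIsProduct) {
        outReactant <<- c(outReactant, oppSide$type[b])
        outProduct <<- c(outProduct, xSide$type[a])
      } else {
        outReactant <<- c(outReactant, xSide$type[a])
        outProduct <<- c(outProduct, oppSide$type[b])
      }
      outTransfer <<- c(outTransfer, formulaToText(.formula(transfer)))
      outScore <<- c(outScore, 0)
      xSide$residual[[a]] <- .rawSubtract(xSide$residual[[a]], transfer)
      xSide$paired[a] <- TRUE
      if (!length(xSide$residual[[a]])) xSide$alive[a] <- FALSE
      oppSide$residual[[b]] <- .rawSubtract(oppSide$residual[[b]], transfer)
      if (!length(oppSide$residual[[b]])) oppSide$alive[b] <- FALSE
    }
    list(x = xSide, opp = oppSide)
  }
  upd <- hPair(R, L, xIsProduct = TRUE)
  R <- upd$x
  L <- upd$opp
  upd <- hPair(L, R, xIsProduct = FALSE)
  L <- upd$x
  R <- upd$opp

  leftover <- function(S) {
    sum(vapply(which(S$alive), function(a) {
      v <- S$residual[[a]]
      sum(v[names(v) != "H"])
    }, numeric(1)))
  }
  if (leftover(L) > 1e-9 || leftover(R) > 1e-9) {
    stop("internal consistency error in reaction '", reaction$id,
         "': non-hydrogen elements left unaccounted ",
         "(the reaction violates the balance precondition)")
  }

  list(pairs = data.frame(reactant = outReactant, product = outProduct,
                          transfer = outTransfer, score = outScore,
                          stringsAsFactors = FALSE),
       tie = tie)
}

#' Assign primary pairs for a single reaction
#'
#' Runs the greedy per-reaction procedure: expand compounds into instances
#' by stoichiometry, score every reactant/product instance pair by weighted
#' Jaccard similarity of the residual formulas times the pair probability
#' estimate, repeatedly select the top-scoring pair (ties broken by sorted
#' compound names, then instance indices), record the shared element counts
#' as the transfer, subtract it from both residuals, and continue until all
#' element transfers are accounted for. Residual hydrogen is resolved by the
#' hydrogen-residue rule (see [findPrimaryPairs()] details).
#'
#' @param rs a filtered [ReactionSet-class].
#' @param reaction a reaction id in \code{rs}.
#' @param theta pair probability estimates: \code{NULL} (all 1, the
#'   first-iteration setting), a [PredictionResult-class], or a theta table
#'   as returned by [thetaTable()].
#' @param weights an [elementWeights()] object.
#' @param strictCompartments key the probability estimates on the full
#'   compound id including its compartment tag instead of merging
#'   compartments (see [findPrimaryPairs()]).
#' @param tieTol relative tolerance for score-tie detection.
#' @return a list with \code{pairs} (a \code{data.frame} with columns
#'   \code{reactant}, \code{product}, \code{transfer}, \code{score}) and
#'   \code{tie} (whether any selection step tied between distinct compound
#'   pairs).
#' @examples
#' rs <- toyModel()
#' assignReactionPairs(rs, "AKGDH")$pairs
#' @export
assignReactionPairs <- function(rs, reaction, theta = NULL,
                                weights = elementWeights(),
                                strictCompartments = FALSE,
                                tieTol = 1e-9) {
  stopifnot(is(rs, "ReactionSet"))
  r <- getReaction(rs, reaction)
  nameOf <- compounds(rs)$name
  names(nameOf) <- compounds(rs)$id
  .assignPairs(r, compoundFormulas(rs), nameOf,
               .thetaLookup(theta, strictCompartments), weights,
               tieTol = tieTol, strict = strictCompartments)
}

# --- global refinement ------------------------------------------------------

# unique co-occurring (theta-keyed) pairs of one reaction
.coKeys <- function(r, strict) {
  rk <- unique(.thetaId(r$reactants$compound, strict))
  pk <- unique(.thetaId(r$products$compound, strict))
  unique(as.vector(outer(rk, pk, .pairKey)))
}

#' Update the pair probability table from assignments
#'
#' For every unordered compound pair occurring on opposite sides of at least
#' one reaction: \code{nCount} is the number of such reactions and
#' \code{yCount} the number of those in which the pair was assigned at least
#' once (the incidence is binary per reaction, regardless of how many
#' instance pairs mapped to the compound pair). The point estimate is the
#' beta posterior mode ([thetaMapEstimate()]).
#'
#' @param assignments a named list (by reaction id) of pair data frames with
#'   columns \code{reactant} and \code{product}, e.g. split from
#'   [primaryPairs()].
#' @param rs the [ReactionSet-class] the assignments cover.
#' @param prior a [priorParams()] object.
#' @param strictCompartments key compound pairs on the full id including the
#'   compartment tag.
#' @return a \code{data.frame} with columns \code{x}, \code{y},
#'   \code{yCount}, \code{nCount}, \code{thetaHat}.
#' @export
updateThetaTable <- function(assignments, rs, prior = priorParams(),
                             strictCompartments = FALSE) {
  stopifnot(is(rs, "ReactionSet"))
  strict <- strictCompartments
  coAll <- character(0)
  asAll <- character(0)
  for (rid in reactionIds(rs)) {
    co <- .coKeys(getReaction(rs, rid), strict)
    coAll <- c(coAll, co)
    a <- assignments[[rid]]
    if (!is.null(a) && nrow(a)) {
      ak <- unique(.pairKey(.thetaId(a$reactant, strict),
                            .thetaId(a$product, strict)))
      asAll <- c(asAll, intersect(ak, co))
    }
  }
  if (!length(coAll)) {
    return(data.frame(x = character(0), y = character(0),
                      yCount = integer(0), nCount = integer(0),
                      thetaHat = numeric(0), stringsAsFactors = FALSE))
  }
  nTab <- table(coAll)
  keys <- sort(names(nTab))
  n <- as.integer(nTab[keys])
  yTab <- table(asAll)
  y <- as.integer(yTab[keys])
  y[is.na(y)] <- 0L
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(x = vapply(parts, `[`, character(1), 1),
             y = vapply(parts, `[`, character(1), 2),
             yCount = y, nCount = n,
             thetaHat = thetaMapEstimate(y, n, prior),
             stringsAsFactors = FALSE)
}

#' Predict primary pairs for a reaction set
#'
#' The full iterative procedure. Starting from point estimates fixed at 1
#' for every compound pair, each global iteration (i) assigns primary pairs
#' in every reaction by the greedy scored procedure
#' ([assignReactionPairs()]) with the current estimates held fixed, and
#' (ii) re-estimates every pair probability from the binary assignment
#' incidences by beta-binomial MAP ([updateThetaTable()]). Iteration stops
#' when no point estimate moves by \code{prior$epsilon} or more, or at
#' \code{prior$maxIterations} (unconverged, with a warning). The reported
#' pair lists are those of the final iteration; the procedure is fully
#' deterministic given its inputs.
#'
#' @details The hydrogen-residue rule applied after each reaction's scored
#' loop: a wholly hydrogen-only compound instance (e.g. a proton) that was
#' never selected is paired with the opposite-side instance holding the
#' largest hydrogen residual, yielding a hydrogen-only transfer; residual
#' hydrogen left on multi-element compounds creates no pair. By default the
#' probability estimates merge compounds across compartments (so a
#' transporter moving X between compartments reinforces the X/X pair);
#' \code{strictCompartments = TRUE} keys them on the full compound id.
#'
#' @param rs a [ReactionSet-class] that already passed [filterReactions()]
#'   (balanced non-hydrogen elements, integer coefficients, usable
#'   formulas).
#' @param weights an [elementWeights()] object.
#' @param prior a [priorParams()] object.
#' @param strictCompartments see details.
#' @param tieTol relative tolerance for score-tie (ambiguity) detection.
#' @return a [PredictionResult-class].
#' @examples
#' rs <- filterReactions(toyModel())$model
#' res <- findPrimaryPairs(rs)
#' primaryPairs(res)
#' @export
findPrimaryPairs <- function(rs, weights = elementWeights(),
                             prior = priorParams(),
                             strictCompartments = FALSE,
                             tieTol = 1e-9) {
  stopifnot(is(rs, "ReactionSet"), inherits(weights, "elementWeights"),
            inherits(prior, "priorParams"))
  strict <- strictCompartments
  rids <- reactionIds(rs)
  formulas <- compoundFormulas(rs)
  nameOf <- compounds(rs)$name
  names(nameOf) <- compounds(rs)$id

  coPerReaction <- lapply(rids, function(rid) {
    .coKeys(getReaction(rs, rid), strict)
  })
  names(coPerReaction) <- rids
  if (length(rids)) {
    nTab <- table(unlist(coPerReaction, use.names = FALSE))
    keys <- sort(names(nTab))
    n <- as.integer(nTab[keys])
  } else {
    keys <- character(0)
    n <- integer(0)
  }
  thetaCur <- rep(1, length(keys))
  names(thetaCur) <- keys

  assignments <- list()
  ties <- logical(length(rids))
  names(ties) <- rids
  convergedFlag <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    thetaOf <- .thetaLookup(if (iter == 1L) NULL else thetaCur, strict)
    for (rid in rids) {
      a <- .assignPairs(getReaction(rs, rid), formulas, nameOf, thetaOf,
                        weights, tieTol = tieTol, strict = strict)
      assignments[[rid]] <- a$pairs
      ties[rid] <- a$tie
    }
    if (length(keys)) {
      asAll <- unlist(lapply(rids, function(rid) {
        a <- assignments[[rid]]
        if (!nrow(a)) return(character(0))
        intersect(unique(.pairKey(.thetaId(a$reactant, strict),
                                  .thetaId(a$product, strict))),
                  coPerReaction[[rid]])
      }), use.names = FALSE)
      yTab <- table(asAll)
      y <- as.integer(yTab[keys])
      y[is.na(y)] <- 0L
      thetaNew <- thetaMapEstimate(y, n, prior)
      names(thetaNew) <- keys
    } else {
      y <- integer(0)
      thetaNew <- thetaCur
    }
    delta <- if (length(keys)) max(abs(thetaCur - thetaNew)) else 0
    thetaCur <- thetaNew
    if (delta < prior$epsilon) {
      convergedFlag <- TRUE
      break
    }
    if (iter >= prior$maxIterations) {
      warning("findPrimaryPairs did not converge within ",
              prior$maxIterations, " iterations (last max change ",
              signif(delta, 3), ")")
      break
    }
  }

  if (length(rids)) {
    pairRows <- lapply(rids, function(rid) {
      a <- assignments[[rid]]
      if (!nrow(a)) return(NULL)
      cbind(data.frame(reaction = rid, stringsAsFactors = FALSE), a)
    })
    pairs <- do.call(rbind, c(pairRows, list(make.row.names = FALSE)))
    if (is.null(pairs)) {
      pairs <- data.frame(reaction = character(0), reactant = character(0),
                          product = character(0), transfer = character(0),
                          score = numeric(0), stringsAsFactors = FALSE)
    }
  } else {
    pairs <- data.frame(reaction = character(0), reactant = character(0),
                        product = character(0), transfer = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
    y <- integer(0)
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  theta <- data.frame(
    x = vapply(parts, `[`, character(1), 1),
    y = vapply(parts, `[`, character(1), 2),
    yCount = if (length(keys)) y else integer(0),
    nCount = n,
    thetaHat = unname(thetaCur),
    stringsAsFactors = FALSE)
  new("PredictionResult", pairs = pairs, theta = theta,
      iterations = iter, converged = convergedFlag,
      ties = as.character(names(which(ties))))
}

#' Reactions with ambiguous (score-tied) predictions
#'
#' Returns the ids of reactions for which, in the final iteration, at least
#' one selection step saw two or more distinct compound-pair mappings within
#' the score-tie tolerance. Ties between instance pairs that map to the same
#' compound pair are not counted, since they cannot change the prediction.
#' The count is an upper bound on true prediction ambiguity: not every tie
#' leads to a different final pair list.
#'
#' @param result a [PredictionResult-class].
#' @return a sorted character vector of reaction ids.
#' @export
detectAmbiguousReactions <- function(result) {
  stopifnot(is(result, "PredictionResult"))
  sort(result@ties)
}

#' Check element conservation of a prediction
#'
#' For every reaction, the summed transferred counts over its predicted
#' pairs must equal the reaction-side totals for every non-hydrogen element
#' (both sides agree by the balance precondition). Returns the ids of
#' reactions violating this, so an empty result means full conservation.
#'
#' @param result a [PredictionResult-class].
#' @param rs the [ReactionSet-class] the prediction was computed on.
#' @return a character vector of violating reaction ids (empty if none).
#' @export
verifyElementConservation <- function(result, rs) {
  stopifnot(is(result, "PredictionResult"), is(rs, "ReactionSet"))
  formulas <- compoundFormulas(rs)
  pp <- primaryPairs(result)
  bad <- character(0)
  for (rid in reactionIds(rs)) {
    r <- getReaction(rs, rid)
    expected <- numeric(0)
    for (k in seq_len(nrow(r$reactants))) {
      f <- formulas[[r$reactants$compound[k]]]
      for (el in names(f)) {
        cur <- if (el %in% names(expected)) expected[[el]] else 0
        expected[el] <- cur + r$reactants$coef[k] * f[[el]]
      }
    }
    got <- numeric(0)
    for (tr in pp$transfer[pp$reaction == rid]) {
      f <- parseFormula(tr)
      for (el in names(f)) {
        cur <- if (el %in% names(got)) got[[el]] else 0
        got[el] <- cur + f[[el]]
      }
    }
    els <- setdiff(union(names(expected), names(got)), "H")
    e <- expected[match(els, names(expected))]
    g <- got[match(els, names(got))]
    e[is.na(e)] <- 0
    g[is.na(g)] <- 0
    if (any(abs(e - g) > 1e-9)) {
      bad <- c(bad, rid)
    }
  }
  bad
}
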