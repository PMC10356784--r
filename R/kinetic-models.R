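# Mass-action kinetic models: ground-truth generators for the inverse
# workflow. A model is a stoichiometry matrix S (allSpecies x reactions), a
# kinetic-order matrix E (same shape; |substrate coefficient| for mass
# action), and rate constants k, so v_r(M) = k_r * prod_i M_i^E[i, r].

#' Construct a mass-action KineticModel
#'
#' @param species dynamic species ids, in state order
#' @param stoichiometry species-by-reaction matrix (rows named by species,
#'   columns by reaction)
#' @param rateConstants named numeric vector, one per reaction column
#' @param rateExponents optional kinetic-order matrix; defaults to
#'   \code{pmax(-stoichiometry, 0)} (mass action on substrates)
#' @return a \linkS4class{KineticModel}
#' @export
kineticModel <- function(species, stoichiometry, rateConstants,
                         rateExponents = NULL) {
  if (is.null(rateExponents)) rateExponents <- pmax(-stoichiometry, 0)
  if (is.null(names(rateConstants)))
    names(rateConstants) <- colnames(stoichiometry)
  new("KineticModel", species = species, allSpecies = species,
      stoichiometry = stoichiometry, rateConstants = rateConstants,
      rateExponents = rateExponents, dependent = list())
}

# full concentration vector (kept + dependent species) from the kept state
fullConcentrations <- function(model, M) {
  names(M) <- model@species
  if (!length(model@dependent)) return(M[model@allSpecies])
  full <- stats::setNames(numeric(length(model@allSpecies)),
                          model@allSpecies)
  full[model@species] <- M
  for (d in model@dependent)
    full[d$species] <- d$intercept + sum(d$coef * M[names(d$coef)])
  full
}

# reaction rates at kept state M
reactionRates <- function(model, M) {
  full <- fullConcentrations(model, M)
  E <- model@rateExponents
  v <- model@rateConstants
  for (r in seq_along(v)) {
    act <- which(E[, r] > 0)
    if (length(act)) v[r] <- v[r] * prod(full[act]^E[act, r])
  }
  v
}

#' Time derivatives dM/dt = F(M) of a kinetic model
#'
#' @param model a \linkS4class{KineticModel}
#' @param M concentrations of the kept species
#' @return named numeric vector of derivatives
#' @export
modelRatesOfChange <- function(model, M) {
  v <- reactionRates(model, M)
  drop(model@stoichiometry[model@species, , drop = FALSE] %*% v)
}

# analytic Jacobian of the reduced system at kept state M
analyticJacobian <- function(model, M) {
  full <- fullConcentrations(model, M)
  E <- model@rateExponents
  k <- model@rateConstants
  nAll <- length(model@allSpecies)
  G <- matrix(0, nAll, length(k),
              dimnames = list(model@allSpecies, names(k)))
  v <- reactionRates(model, M)
  for (r in seq_along(k)) {
    act <- which(E[, r] > 0)
    for (s in act) {
      G[s, r] <- if (full[s] > 0) v[r] * E[s, r] / full[s] else {
        # derivative at zero concentration: nonzero only for first order
        if (E[s, r] == 1) {
          others <- setdiff(act, s)
          k[r] * if (length(others)) prod(full[others]^E[others, r]) else 1
        } else 0
      }
    }
  }
  # chain rule through dependent species
  nKept <- length(model@species)
  Tm <- matrix(0, nAll, nKept,
               dimnames = list(model@allSpecies, model@species))
  Tm[cbind(model@species, model@species)] <- 1
  for (d in model@dependent) Tm[d$species, names(d$coef)] <- d$coef
  dvdM <- t(G) %*% Tm
  J <- model@stoichiometry[model@species, , drop = FALSE] %*% dvdM
  dimnames(J) <- list(model@species, model@species)
  J
}

#' Steady state and Jacobian of a kinetic model
#'
#' Relaxes the ODE system from \code{M0} (deSolve) and polishes the root with
#' damped Newton iterations until \eqn{\|F(M^*)\|_\infty \le 10^{-10}
#' \max(1, \max_r |v_r|)}. The Jacobian is evaluated analytically from the
#' mass-action rate laws by default, or by central finite differences with
#' per-species step \code{1e-6 * max(1, M_i)}.
#'
#' @param model a \linkS4class{KineticModel}
#' @param M0 starting concentrations (default all 1)
#' @param method "analytic" (default) or "fd" for the Jacobian
#' @return list with \code{steadyState}, \code{jacobian}, \code{residual}
#' @export
steadyStateAndJacobian <- function(model, M0 = NULL,
                                   method = c("analytic", "fd")) {
  method <- match.arg(method)
  n <- length(model@species)
  if (is.null(M0)) M0 <- rep(1, n)
  names(M0) <- model@species
  rhs <- function(t, y, parms) list(modelRatesOfChange(model, pmax(y, 0)))
  sol <- deSolve::ode(y = M0, times = c(0, 2^(0:8)), func = rhs,
                      parms = NULL, method = "lsoda")
  M <- pmax(sol[nrow(sol), -1L], 1e-12)
  tolF <- function(M) 1e-10 * max(1, max(abs(reactionRates(model, M))))
  for (it in seq_len(100L)) {
    Fv <- modelRatesOfChange(model, M)
    if (max(abs(Fv)) <= tolF(M)) break
    J <- analyticJacobian(model, M)
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) step <- -drop(MASS_ginv(J) %*% Fv)
    lam <- 1
    repeat {
      Mn <- M + lam * step
      if (all(Mn > 0) &&
          sum(modelRatesOfChange(model, Mn)^2) < sum(Fv^2) * (1 + 1e-12))
        break
      lam <- lam / 2
      if (lam < 1e-8) { Mn <- pmax(M + lam * step, 1e-12); break }
    }
    M <- Mn
  }
  Fv <- modelRatesOfChange(model, M)
  if (max(abs(Fv)) > tolF(M))
    stop("steady-state search did not converge; final residual ",
         format(max(abs(Fv))))
  J <- if (method == "analytic") analyticJacobian(model, M)
       else finiteDifferenceJacobian(model, M)
  list(steadyState = M, jacobian = J, residual = max(abs(Fv)))
}

# central finite differences, per-species step 1e-6 * max(1, M_i)
finiteDifferenceJacobian <- function(model, M) {
  n <- length(M)
  J <- matrix(0, n, n, dimnames = list(model@species, model@species))
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, M[j])
    Mp <- M; Mp[j] <- Mp[j] + h
    Mm <- M; Mm[j] <- Mm[j] - h
    J[, j] <- (modelRatesOfChange(model, Mp) -
               modelRatesOfChange(model, Mm)) / (2 * h)
  }
  J
}

# minimal pseudo-inverse (avoids a MASS dependency for one fallback)
MASS_ginv <- function(X) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r == 0L) return(matrix(0, ncol(X), nrow(X)))
  sv$v[, seq_len(r), drop = FALSE] %*%
    (t(sv$u[, seq_len(r), drop = FALSE]) / sv$d[seq_len(r)])
}

#' Generate a random stable mass-action model
#'
#' Builds a random sparse uni/bi-molecular mass-action network: a conversion
#' chain X1 -> X2 -> ... -> Xn plus random extra conversions (70% Xi -> Xj,
#' 15% Xi + Xj -> Xk, 15% Xi -> Xj + Xk), a constant inflow into X1, and a
#' first-order outflow from every species (dilution), which anchors a positive
#' steady state. Candidate models are rejected and regenerated (bounded
#' retries) until the steady state is positive and the Jacobian is
#' Hurwitz-stable.
#'
#' @param nSpecies number of species (>= 2)
#' @param nReactions number of internal conversion reactions (chain plus
#'   extras); must be >= nSpecies - 1. Inflow/outflow exchange reactions are
#'   added on top.
#' @param seed integer RNG seed; generation is fully reproducible
#' @param maxTries rejection budget (default 50)
#' @return a \linkS4class{KineticModel}
#' @export
generateMassActionModel <- function(nSpecies, nReactions, seed,
                                    maxTries = 50L) {
  if (nSpecies < 2L) stop("nSpecies must be >= 2")
  if (nReactions < nSpecies - 1L) stop("nReactions must be >= nSpecies - 1")
  subSeeds <- deriveSeeds(seed, maxTries)
  for (try in seq_len(maxTries)) {
    model <- withSeed(subSeeds[try], function()
      randomMassActionCandidate(nSpecies, nReactions))
    ok <- tryCatch({
      ss <- steadyStateAndJacobian(model)
      all(ss$steadyState > 1e-6) &&
        max(Re(eigen(ss$jacobian, only.values = TRUE)$values)) < -1e-8
    }, error = function(e) FALSE)
    if (ok) return(model)
  }
  stop("no stable positive model found in ", maxTries,
       " attempts; try a different seed")
}

randomMassActionCandidate <- function(n, nReactions) {
  species <- sprintf("X%d", seq_len(n))
  cols <- list()
  addReaction <- function(name, stoich) {
    v <- stats::setNames(numeric(n), species)
    v[names(stoich)] <- stoich
    cols[[name]] <<- v
  }
  for (i in seq_len(n - 1L))
    addReaction(sprintf("chain_%d", i),
                stats::setNames(c(-1, 1), species[c(i, i + 1L)]))
  nExtra <- nReactions - (n - 1L)
  for (e in seq_len(max(nExtra, 0L))) {
    type <- sample(c("uni", "bi", "split"), 1L, prob = c(0.7, 0.15, 0.15))
    if (type == "uni" || n < 3L) {
      ij <- sample(n, 2L)
      addReaction(sprintf("extra_%d", e),
                  stats::setNames(c(-1, 1), species[ij]))
    } else if (type == "bi") {
      ijk <- sample(n, 3L)
      addReaction(sprintf("extra_%d", e),
                  stats::setNames(c(-1, -1, 1), species[ijk]))
    } else {
      ijk <- sample(n, 3L)
      addReaction(sprintf("extra_%d", e),
                  stats::setNames(c(-1, 1, 1), species[ijk]))
    }
  }
  addReaction("inflow", stats::setNames(1, species[1L]))
  for (i in seq_len(n))
    addReaction(sprintf("outflow_%d", i), stats::setNames(-1, species[i]))
  S <- do.call(cbind, cols)
  rownames(S) <- species
  E <- pmax(-S, 0)
  E[, "inflow"] <- 0                       # zeroth-order inflow
  k <- stats::setNames(stats::runif(ncol(S), 0.5, 2), colnames(S))
  k["inflow"] <- 1
  k[grep("^outflow_", names(k))] <- 0.3
  k[grep("^extra_", names(k))] <- stats::runif(max(length(k) - 2 * n, 0),
                                               0.2, 0.8)
  kineticModel(species, S, k, E)
}

#' Remove constant species and conserved moieties
#'
#' Constant species (all-zero stoichiometry rows) are folded into the rate
#' constants at a reference concentration. For each independent left-null
#' vector g of the stoichiometric matrix (g' S = 0, a conserved moiety), one
#' participating species is made dependent and re-expressed through the
#' conserved total: M_dep = (T - sum over kept g_i M_i) / g_dep, with T
#' evaluated at the reference state. Required before Jacobian/covariance
#' analysis: a conserved system has a singular Jacobian and no unique
#' stationary covariance.
#'
#' @param model a \linkS4class{KineticModel} without prior reductions
#' @param reference reference concentrations for conserved totals and
#'   constant-species folding (default all 1)
#' @return reduced \linkS4class{KineticModel}
#' @export
removeConservedMoieties <- function(model, reference = NULL) {
  if (length(model@dependent))
    stop("model already carries dependent species")
  S <- model@stoichiometry
  E <- model@rateExponents
  k <- model@rateConstants
  species <- model@species
  if (is.null(reference)) reference <- rep(1, length(species))
  names(reference) <- species

  constant <- rownames(S)[rowSums(S != 0) == 0L]
  for (cs in constant) {
    scale <- reference[cs]^E[cs, ]
    k <- k * scale
  }
  keepRows <- setdiff(rownames(S), constant)
  S <- S[keepRows, , drop = FALSE]
  E <- E[keepRows, , drop = FALSE]
  reference <- reference[keepRows]

  # left null space of S -> conservation relations
  sv <- svd(S, nu = nrow(S))
  tol <- max(dim(S)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  nCons <- nrow(S) - rank
  dependent <- list()
  if (nCons > 0L) {
    N <- sv$u[, rank + seq_len(nCons), drop = FALSE]
    rownames(N) <- rownames(S)
    depSpecies <- character(0)
    for (c0 in seq_len(nCons)) {
      g <- N[, c0]
      cand <- setdiff(rownames(S)[abs(g) > 1e-10], depSpecies)
      d <- cand[length(cand)]               # last participating species
      # eliminate d from the remaining basis vectors
      if (c0 < nCons)
        for (c1 in (c0 + 1L):nCons)
          N[, c1] <- N[, c1] - N[d, c1] / g[d] * g
      g <- g / g[d]                          # coefficient of d becomes 1
      kept <- setdiff(names(g)[abs(g) > 1e-10], d)
      total <- sum(g * reference)
      dependent[[length(dependent) + 1L]] <-
        list(species = d, coef = -g[kept], intercept = total)
      depSpecies <- c(depSpecies, d)
    }
    keepDyn <- setdiff(rownames(S), depSpecies)
  } else keepDyn <- rownames(S)

  # dependents whose coefficients reference other dependents: resolve chains
  dependent <- lapply(dependent, function(d) {
    repeat {
      bad <- intersect(names(d$coef), vapply(dependent, `[[`, "",
                                             "species"))
      if (!length(bad)) break
      for (b in bad) {
        other <- dependent[[which(vapply(dependent, `[[`, "", "species")
                                  == b)]]
        w <- d$coef[b]
        d$coef <- d$coef[names(d$coef) != b]
        d$intercept <- d$intercept + w * other$intercept
        add <- w * other$coef
        for (nm in names(add))
          d$coef[nm] <- if (nm %in% names(d$coef)) d$coef[nm] + add[nm]
                        else add[nm]
      }
    }
    d$coef <- d$coef[abs(d$coef) > 1e-12]
    d
  })

  new("KineticModel", species = keepDyn, allSpecies = rownames(S),
      stoichiometry = S, rateConstants = k, rateExponents = E,
      dependent = dependent)
}

#' Covariance from the Lyapunov equation with a randomized fluctuation matrix
#'
#' Draws a diagonal fluctuation matrix with entries uniform on
#' (1 - epsD, 1 + epsD) and solves the forward Lyapunov equation. epsD = 0
#' gives the nominal identity fluctuation matrix.
#'
#' @param J stable Jacobian matrix
#' @param epsD fluctuation randomness amplitude in [0, 1)
#' @param seed integer RNG seed
#' @return list with covariance \code{C} and the drawn \code{D}
#' @export
covarianceViaLyapunov <- function(J, epsD, seed) {
  if (epsD < 0 || epsD >= 1) stop("epsD must be in [0, 1)")
  n <- nrow(J)
  d <- withSeed(seed, function() stats::runif(n, 1 - epsD, 1 + epsD))
  D <- diag(d, n)
  dimnames(D) <- dimnames(J)
  list(C = solveForwardLyapunov(J, D), D = D)
}

#' Stationary samples and covariance from SDE simulation
#'
#' Euler-Maruyama integration of dM = F(M) dt + sigma dW per species, started
#' at the steady state, with concentrations floored at 0. After a burn-in the
#' trajectory is recorded every \code{thin} steps (one long stationary
#' trajectory with thinning). For a linear(ized) system the sample covariance
#' converges to the Lyapunov covariance with D = (sigma^2 / 2) I.
#'
#' @param model a \linkS4class{KineticModel}
#' @param sigma additive noise amplitude (per species, per sqrt(time))
#' @param nSamples number of recorded states
#' @param dt integration step
#' @param burnIn number of discarded initial steps
#' @param thin record every \code{thin}-th step (default 50)
#' @param seed integer RNG seed
#' @return \code{simulateSde}: nSamples-by-nSpecies matrix;
#'   \code{covarianceViaSde}: the sample covariance matrix
#' @export
simulateSde <- function(model, sigma, nSamples, dt = 0.01,
                        burnIn = 1000L, thin = 50L, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  ss <- steadyStateAndJacobian(model)
  M <- ss$steadyState
  n <- length(M)
  nSamples <- as.integer(nSamples)
  total <- burnIn + nSamples * thin
  noise <- withSeed(seed, function()
    matrix(stats::rnorm(n * total, sd = sigma * sqrt(dt)), nrow = n))
  out <- matrix(0, nSamples, n, dimnames = list(NULL, model@species))
  rec <- 0L
  for (step in seq_len(total)) {
    M <- pmax(M + modelRatesOfChange(model, M) * dt + noise[, step], 0)
    if (any(!is.finite(M)) || max(M) > 1e8)
      stop("SDE trajectory diverged; reduce dt = ", dt)
    if (step > burnIn && (step - burnIn) %% thin == 0L) {
      rec <- rec + 1L
      out[rec, ] <- M
    }
  }
  out
}

#' @rdname simulateSde
#' @export
covarianceViaSde <- function(model, sigma, nSamples, dt = 0.01,
                             burnIn = 1000L, thin = 50L, seed) {
  X <- simulateSde(model, sigma, nSamples, dt, burnIn, thin, seed)
  stats::cov(X)
}

#' Build a two-condition pair by perturbing rate constants
#'
#' Deep-copies the model, multiplies the named rate constants by the given
#' factors, and re-checks that both models admit a positive stable steady
#' state.
#'
#' @param model the reference ("h") \linkS4class{KineticModel}
#' @param perturbations named numeric vector: rate-constant name -> factor
#' @return a \linkS4class{ConditionPair}
#' @export
makeConditionPair <- function(model, perturbations) {
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations))))
    stop("perturbations must be a named numeric vector (parameter -> factor)")
  unknown <- setdiff(names(perturbations), names(model@rateConstants))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  modelD <- model
  modelD@rateConstants[names(perturbations)] <-
    modelD@rateConstants[names(perturbations)] * perturbations
  for (m in list(h = model, d = modelD)) {
    ss <- steadyStateAndJacobian(m)
    if (max(Re(eigen(ss$jacobian, only.values = TRUE)$values)) >= 0)
      stop("perturbation destabilizes the model")
  }
  new("ConditionPair", modelH = model, modelD = modelD,
      perturbed = data.frame(parameter = names(perturbations),
                             factor = unname(perturbations)))
}

#' Ground truth of a condition pair
#'
#' Steady states and analytic Jacobians of both conditions, the union
#' sparsity structure, and the true differential Jacobian.
#'
#' @param pair a \linkS4class{ConditionPair}
#' @return list with \code{Jh}, \code{Jd}, \code{structure}, \code{dj}
#' @export
conditionTruth <- function(pair) {
  stopifnot(is(pair, "ConditionPair"))
  ssh <- steadyStateAndJacobian(pair@modelH)
  ssd <- steadyStateAndJacobian(pair@modelD)
  Jh <- ssh$jacobian; Jd <- ssd$jacobian
  mask <- (abs(Jh) > 1e-12) | (abs(Jd) > 1e-12)
  struct <- jacobianStructure(pair@modelH@species, mask)
  list(Jh = Jh, Jd = Jd, structure = struct,
       dj = differentialJacobian(Jh, Jd))
}

#' Serialize / read a KineticModel (JSON or SBML mass-action dialect)
#'
#' JSON stores the slots directly. The SBML writer emits Level 3 core with
#' explicit mass-action kinetic laws (a product of the rate constant and
#' powered reactant concentrations); the reader parses that dialect back.
#'
#' @param model a \linkS4class{KineticModel}
#' @param path output file
#' @param format "json" or "sbml"
#' @export
writeKineticModel <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(species = model@species, allSpecies = model@allSpecies,
                stoichiometry = as.data.frame(model@stoichiometry),
                rateConstants = as.list(model@rateConstants),
                rateExponents = as.data.frame(model@rateExponents),
                dependent = lapply(model@dependent, function(d)
                  list(species = d$species, coef = as.list(d$coef),
                       intercept = d$intercept)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeKineticSbml(model, path)
  }
  invisible(path)
}

#' @rdname writeKineticModel
#' @export
readKineticModel <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(readKineticSbml(path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.matrix(obj$stoichiometry)
  rownames(S) <- obj$allSpecies
  E <- as.matrix(obj$rateExponents)
  rownames(E) <- obj$allSpecies
  dep <- lapply(obj$dependent, function(d)
    list(species = d$species, coef = unlist(d$coef),
         intercept = d$intercept))
  new("KineticModel", species = obj$species, allSpecies = obj$allSpecies,
      stoichiometry = S, rateConstants = unlist(obj$rateConstants),
      rateExponents = E, dependent = dep)
}
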