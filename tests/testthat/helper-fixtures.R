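# Fixtures built in code, shared across test files.

# small metabolic model: glycolysis-flavoured toy with compartment tags,
# genes, mixed reversibility and a side metabolite (atp/adp)
makeToyModel <- function() {
  met <- data.frame(
    id = c("glc_c", "g6p_c", "f6p_c", "atp_c", "adp_c"),
    name = c("glucose", "glucose-6-phosphate", "fructose-6-phosphate",
             "ATP", "ADP"),
    compartment = "c", stringsAsFactors = FALSE)
  rx <- list(
    list(id = "HEX1",
         stoichiometry = c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
         reversible = FALSE, genes = c("HK1", "HK2"), source = "custom"),
    list(id = "PGI",
         stoichiometry = c(g6p_c = -1, f6p_c = 1),
         reversible = TRUE, genes = "GPI", source = "custom"),
    list(id = "F6P_SINK",
         stoichiometry = c(f6p_c = -1, glc_c = 1),
         reversible = FALSE, genes = character(0), source = "custom"),
    list(id = "ATPM",
         stoichiometry = c(atp_c = -1, adp_c = 1),
         reversible = FALSE, genes = "ATP1", source = "custom"))
  new("MetabolicModel", metabolites = met, reactions = rx, organism = "")
}

# two-species linear chain: inflow -> A -> B -> outflow, all rates 1;
# steady state (1, 1), Jacobian [[-1, 0], [1, -1]]
chainKineticModel <- function() {
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(c("A", "B"), c("inflow", "conv", "outflow")))
  m <- kineticModel(c("A", "B"), S, c(inflow = 1, conv = 1, outflow = 1))
  m@rateExponents[, "inflow"] <- 0
  m
}

# linear five-species chain (uni-molecular only): exact linear SDE regime
linearChainModel <- function(n = 5) {
  species <- sprintf("X%d", seq_len(n))
  cols <- list(inflow = stats::setNames(c(1, rep(0, n - 1)), species))
  for (i in seq_len(n - 1)) {
    v <- stats::setNames(numeric(n), species)
    v[i] <- -1; v[i + 1] <- 1
    cols[[sprintf("chain_%d", i)]] <- v
  }
  for (i in seq_len(n)) {
    v <- stats::setNames(numeric(n), species)
    v[i] <- -1
    cols[[sprintf("outflow_%d", i)]] <- v
  }
  S <- do.call(cbind, cols)
  k <- stats::setNames(rep(1, ncol(S)), colnames(S))
  k[grep("^outflow", names(k))] <- 0.5
  m <- kineticModel(species, S, k)
  m@rateExponents[, "inflow"] <- 0
  m
}

# cached condition-pair fixtures (single perturbed outflow rate constant)
.fixtureCache <- new.env(parent = emptyenv())
getFixturePair <- function(n) {
  key <- as.character(n)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- switch(key,
    "5"  = list(nr = 7,  seed = 11, pert = c(outflow_3 = 5)),
    "12" = list(nr = 16, seed = 4,  pert = c(outflow_5 = 5)),
    "27" = list(nr = 34, seed = 8,  pert = c(outflow_9 = 5)),
    stop("no fixture for n = ", n))
  m <- generateMassActionModel(n, cfg$nr, seed = cfg$seed)
  pair <- makeConditionPair(m, cfg$pert)
  out <- list(pair = pair, truth = conditionTruth(pair))
  .fixtureCache[[key]] <- out
  out
}

# exhaustive simple-path enumeration oracle for shortest-path costs
enumerateShortestCost <- function(edges, from, to) {
  best <- Inf
  recurse <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == to) { best <<- cost; return() }
    nxt <- edges[edges$from == node & !(edges$to %in% visited), ,
                 drop = FALSE]
    for (r in seq_len(nrow(nxt)))
      recurse(nxt$to[r], c(visited, nxt$to[r]), cost + nxt$weight[r])
  }
  recurse(from, from, 0)
  best
}

# random Hurwitz-stable Jacobian with a sparse mask
randomStableJacobian <- function(n, density = 0.4) {
  J <- matrix(stats::rnorm(n * n), n, n)
  mask <- matrix(stats::runif(n * n) < density, n, n)
  diag(mask) <- TRUE
  J[!mask] <- 0
  diag(J) <- diag(J) - 1.5 * n
  dimnames(J) <- list(paste0("X", seq_len(n)), paste0("X", seq_len(n)))
  J
}

# random symmetric PSD matrix
randomPsd <- function(n, labels = NULL) {
  M <- matrix(stats::rnorm(n * n), n, n)
  D <- crossprod(M) / n + diag(0.1, n)
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  D
}
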