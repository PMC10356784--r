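#' @import methods
NULL

#' MetabolicModel: a normalized genome-scale (or toy) metabolic model
#'
#' Container for metabolites and reactions read from SBML, BIGG-style JSON or
#' KEGG flat-file records. Metabolites are stored as a data.frame with columns
#' \code{id}, \code{name}, \code{compartment} (and optional cross-reference
#' columns); reactions as a list of records with fields \code{id},
#' \code{stoichiometry} (named numeric, negative = substrate),
#' \code{reversible}, \code{genes} and \code{source}.
#'
#' @slot metabolites data.frame of metabolite records
#' @slot reactions list of reaction records
#' @slot organism organism code (e.g. \code{"hsa"}), possibly empty
#' @export
setClass("MetabolicModel",
  slots = c(
    metabolites = "data.frame",
    reactions   = "list",
    organism    = "character"
  ),
  prototype = prototype(
    metabolites = data.frame(id = character(), name = character(),
                             compartment = character(),
                             stringsAsFactors = FALSE),
    reactions = list(),
    organism = ""
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  if (!all(c("id", "name", "compartment") %in% names(met)))
    msgs <- c(msgs, "metabolites must have columns id, name, compartment")
  else if (anyDuplicated(met$id))
    msgs <- c(msgs, "metabolite ids must be unique")
  ids <- met$id
  for (rx in object@reactions) {
    st <- rx$stoichiometry
    if (is.null(names(st)) || any(!nzchar(names(st))))
      msgs <- c(msgs, sprintf("reaction %s: unnamed stoichiometry", rx$id))
    else if (!all(names(st) %in% ids))
      msgs <- c(msgs, sprintf("reaction %s references undeclared species: %s",
                              rx$id,
                              paste(setdiff(names(st), ids), collapse = ", ")))
    if (any(st == 0))
      msgs <- c(msgs, sprintf("reaction %s: zero stoichiometric coefficient", rx$id))
    if (!any(st < 0) || !any(st > 0))
      msgs <- c(msgs, sprintf("reaction %s: needs at least one substrate and one product", rx$id))
  }
  if (length(msgs)) msgs else TRUE
})

#' ReactionGraph: weighted directed metabolite graph
#'
#' Directed graph over (compartment-stripped) metabolites with positive edge
#' weights derived from reaction direction, reversibility and thermodynamics.
#' Parallel edges between a node pair are collapsed to the minimum weight with
#' merged provenance; \code{provenance[[k]]} is a data.frame (reaction,
#' direction, relation) for edge row \code{k}.
#'
#' @slot nodes character vector of node ids (sorted)
#' @slot edges data.frame with columns from, to, weight
#' @slot provenance list of per-edge provenance data.frames
#' @export
setClass("ReactionGraph",
  slots = c(nodes = "character", edges = "data.frame", provenance = "list")
)

setValidity("ReactionGraph", function(object) {
  msgs <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    msgs <- c(msgs, "edges must have columns from, to, weight")
  else {
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      msgs <- c(msgs, "all edge weights must be positive and finite")
    if (anyDuplicated(paste(e$from, e$to)))
      msgs <- c(msgs, "parallel edges must be collapsed")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be graph nodes")
    if (length(object@provenance) != nrow(e))
      msgs <- c(msgs, "provenance must have one entry per edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' JacobianStructure: sparsity pattern of the system Jacobian
#'
#' An n-by-n logical mask over an ordered metabolite label set. The diagonal is
#' always TRUE (self-regulation); an off-diagonal entry (i, j) is TRUE when an
#' accepted superpathway route from metabolite j to metabolite i exists, so
#' that Jacobian entry J[i, j] = df_i/dM_j may be nonzero. Accepted routes are
#' kept in \code{annotation}, keyed \code{"i,j"}.
#'
#' @slot labels ordered metabolite ids (row/column order of the Jacobian)
#' @slot mask n-by-n logical matrix
#' @slot annotation named list of path records for off-diagonal TRUE entries
#' @export
setClass("JacobianStructure",
  slots = c(labels = "character", mask = "matrix", annotation = "list")
)

setValidity("JacobianStructure", function(object) {
  msgs <- character()
  n <- length(object@labels)
  m <- object@mask
  if (!is.logical(m) || !all(dim(m) == c(n, n)))
    msgs <- c(msgs, "mask must be an n-by-n logical matrix matching labels")
  else if (!all(diag(m)))
    msgs <- c(msgs, "all diagonal mask entries must be TRUE")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' LyapunovSystem: vectorized Lyapunov equation A q = b
#'
#' For the Lyapunov equation J C + C J' = -2 D with symmetric C, rows index
#' the m = n(n+1)/2 unordered pairs (i, j), i <= j (row-major in i then j),
#' and columns index the L masked Jacobian positions in row-major scan order.
#' The coefficient of column (a, b) in row (i, j) is
#' [i == a] C[b, j] + [j == a] C[i, b].
#'
#' @slot A m-by-L coefficient matrix
#' @slot indexMap L-by-2 integer matrix: column k corresponds to J[indexMap[k,1], indexMap[k,2]]
#' @slot rowMap m-by-2 integer matrix: row r corresponds to pair (i, j), i <= j
#' @slot labels metabolite label order shared with the covariance matrix
#' @export
setClass("LyapunovSystem",
  slots = c(A = "matrix", indexMap = "matrix", rowMap = "matrix",
            labels = "character")
)

setValidity("LyapunovSystem", function(object) {
  msgs <- character()
  n <- length(object@labels)
  if (nrow(object@A) != n * (n + 1L) / 2L)
    msgs <- c(msgs, "A must have n(n+1)/2 rows")
  if (ncol(object@A) != nrow(object@indexMap))
    msgs <- c(msgs, "one indexMap row per column of A")
  if (length(msgs)) msgs else TRUE
})

#' KineticModel: mass-action kinetic model
#'
#' A reaction network with mass-action rate laws v_r = k_r * prod_i M_i^e_ir,
#' where the kinetic orders e_ir are the absolute substrate stoichiometries.
#' After conserved-moiety removal, some species become dependent: their
#' concentration is an affine function of the kept species (via the conserved
#' total), recorded in \code{dependent}.
#'
#' @slot species ids of the dynamic (kept) species, in state-vector order
#' @slot allSpecies ids of every species referenced by the rate laws
#' @slot stoichiometry allSpecies-by-reactions matrix
#' @slot rateConstants named numeric vector of mass-action rate constants
#' @slot rateExponents allSpecies-by-reactions matrix of kinetic orders
#' @slot dependent list of records (species, coef, intercept) expressing
#'   removed species as affine functions of the kept species
#' @export
setClass("KineticModel",
  slots = c(
    species       = "character",
    allSpecies    = "character",
    stoichiometry = "matrix",
    rateConstants = "numeric",
    rateExponents = "matrix",
    dependent     = "list"
  )
)

setValidity("KineticModel", function(object) {
  msgs <- character()
  nAll <- length(object@allSpecies)
  r <- length(object@rateConstants)
  if (!all(dim(object@stoichiometry) == c(nAll, r)))
    msgs <- c(msgs, "stoichiometry must be allSpecies-by-reactions")
  if (!all(dim(object@rateExponents) == c(nAll, r)))
    msgs <- c(msgs, "rateExponents must be allSpecies-by-reactions")
  if (is.null(names(object@rateConstants)) ||
      anyDuplicated(names(object@rateConstants)))
    msgs <- c(msgs, "rateConstants must have unique names")
  if (!all(object@species %in% object@allSpecies))
    msgs <- c(msgs, "species must be a subset of allSpecies")
  dep <- vapply(object@dependent, function(d) d$species, character(1))
  if (!setequal(c(object@species, dep), object@allSpecies))
    msgs <- c(msgs, "kept plus dependent species must cover allSpecies")
  if (any(object@rateExponents < 0))
    msgs <- c(msgs, "kinetic orders must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' ConditionPair: two kinetic models differing in listed parameters
#'
#' @slot modelH reference ("h") condition model
#' @slot modelD perturbed ("d") condition model
#' @slot perturbed data.frame with columns parameter, factor
#' @export
setClass("ConditionPair",
  slots = c(modelH = "KineticModel", modelD = "KineticModel",
            perturbed = "data.frame")
)

setValidity("ConditionPair", function(object) {
  msgs <- character()
  if (!all(c("parameter", "factor") %in% names(object@perturbed)))
    msgs <- c(msgs, "perturbed must have columns parameter, factor")
  if (!identical(object@modelH@species, object@modelD@species))
    msgs <- c(msgs, "both models must share the species set")
  if (length(msgs)) msgs else TRUE
})

#' RelevanceMatrix: per-position regression-loss scores
#'
#' \code{rawLoss[i, j]} is the minimum (over sampled fluctuation vectors)
#' relative regression loss of the combined two-condition system in which only
#' Jacobian position (i, j) may differ between conditions; NA outside the
#' mask. \code{relevance} is the min-max inversion of rawLoss over the mask
#' (low loss = high relevance), 0 outside the mask.
#'
#' @slot labels metabolite label order
#' @slot rawLoss n-by-n numeric matrix (NA outside mask)
#' @slot relevance n-by-n numeric matrix in [0, 1]
#' @slot mask n-by-n logical matrix
#' @slot nSamples number of sampled fluctuation vectors
#' @slot seed RNG seed used for the sample draws
#' @export
setClass("RelevanceMatrix",
  slots = c(labels = "character", rawLoss = "matrix", relevance = "matrix",
            mask = "matrix", nSamples = "integer", seed = "integer")
)

setValidity("RelevanceMatrix", function(object) {
  msgs <- character()
  n <- length(object@labels)
  for (nm in c("rawLoss", "relevance", "mask"))
    if (!all(dim(slot(object, nm)) == c(n, n)))
      msgs <- c(msgs, sprintf("%s must be n-by-n", nm))
  rel <- object@relevance[object@mask]
  if (length(rel) && (any(rel < -1e-12) || any(rel > 1 + 1e-12)))
    msgs <- c(msgs, "relevance must lie in [0, 1]")
  if (any(object@relevance[!object@mask] != 0))
    msgs <- c(msgs, "relevance must be 0 outside the mask")
  if (length(msgs)) msgs else TRUE
})
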