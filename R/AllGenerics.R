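#' @include AllClasses.R
NULL

#' Accessors for covrecon classes
#'
#' Small accessor generics: \code{metabolites} and \code{reactions} return the
#' metabolite table and reaction list of a \linkS4class{MetabolicModel};
#' \code{organismCode} its organism; \code{graphNodes}/\code{graphEdges} the
#' node set and edge table of a \linkS4class{ReactionGraph};
#' \code{structureLabels}, \code{maskMatrix} and \code{pathAnnotations} the
#' parts of a \linkS4class{JacobianStructure}; \code{speciesIds} and
#' \code{rateConstants} those of a \linkS4class{KineticModel};
#' \code{modelH}/\code{modelD} the two members of a
#' \linkS4class{ConditionPair}; \code{relevanceScores} and \code{rawLoss} the
#' score matrices of a \linkS4class{RelevanceMatrix}.
#'
#' @param x object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("organismCode", function(x) standardGeneric("organismCode"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("structureLabels", function(x) standardGeneric("structureLabels"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("pathAnnotations", function(x) standardGeneric("pathAnnotations"))
#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @rdname accessors
#' @export
setGeneric("rateConstants", function(x) standardGeneric("rateConstants"))
#' @rdname accessors
#' @export
setGeneric("modelH", function(x) standardGeneric("modelH"))
#' @rdname accessors
#' @export
setGeneric("modelD", function(x) standardGeneric("modelD"))
#' @rdname accessors
#' @export
setGeneric("relevanceScores", function(x) standardGeneric("relevanceScores"))
#' @rdname accessors
#' @export
setGeneric("rawLoss", function(x) standardGeneric("rawLoss"))

#' @rdname accessors
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)
#' @rdname accessors
setMethod("reactions", "MetabolicModel", function(x) x@reactions)
#' @rdname accessors
setMethod("organismCode", "MetabolicModel", function(x) x@organism)
#' @rdname accessors
setMethod("graphNodes", "ReactionGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "ReactionGraph", function(x) x@edges)
#' @rdname accessors
setMethod("structureLabels", "JacobianStructure", function(x) x@labels)
#' @rdname accessors
setMethod("maskMatrix", "JacobianStructure", function(x) x@mask)
#' @rdname accessors
setMethod("pathAnnotations", "JacobianStructure", function(x) x@annotation)
#' @rdname accessors
setMethod("speciesIds", "KineticModel", function(x) x@species)
#' @rdname accessors
setMethod("rateConstants", "KineticModel", function(x) x@rateConstants)
#' @rdname accessors
setMethod("modelH", "ConditionPair", function(x) x@modelH)
#' @rdname accessors
setMethod("modelD", "ConditionPair", function(x) x@modelD)
#' @rdname accessors
setMethod("relevanceScores", "RelevanceMatrix", function(x) x@relevance)
#' @rdname accessors
setMethod("rawLoss", "RelevanceMatrix", function(x) x@rawLoss)
#' @rdname accessors
setMethod("structureLabels", "RelevanceMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("maskMatrix", "RelevanceMatrix", function(x) x@mask)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@metabolites), "metabolites,",
      length(object@reactions), "reactions")
  if (nzchar(object@organism)) cat(" [", object@organism, "]", sep = "")
  cat("\n")
})

setMethod("show", "ReactionGraph", function(object) {
  cat("ReactionGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "directed edges\n")
})

setMethod("show", "JacobianStructure", function(object) {
  n <- length(object@labels)
  off <- sum(object@mask) - n
  cat("JacobianStructure:", n, "metabolites,", off,
      "off-diagonal interactions\n")
})

setMethod("show", "LyapunovSystem", function(object) {
  cat("LyapunovSystem: A is", nrow(object@A), "x", ncol(object@A),
      "(rows = covariance pairs, cols = masked Jacobian positions)\n")
})

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:", length(object@species), "species,",
      ncol(object@stoichiometry), "mass-action reactions")
  if (length(object@dependent))
    cat(" (", length(object@dependent), " dependent via conservation)", sep = "")
  cat("\n")
})

setMethod("show", "ConditionPair", function(object) {
  cat("ConditionPair:", length(object@modelH@species), "species;",
      nrow(object@perturbed), "perturbed parameter(s):",
      paste(sprintf("%s x%g", object@perturbed$parameter,
                    object@perturbed$factor), collapse = ", "), "\n")
})

setMethod("show", "RelevanceMatrix", function(object) {
  cat("RelevanceMatrix:", length(object@labels), "metabolites,",
      sum(object@mask), "scored positions,", object@nSamples,
      "fluctuation samples (seed", object@seed, ")\n")
})

#' Dimensions of matrix-like covrecon objects
#' @param x a JacobianStructure or RelevanceMatrix
#' @return integer vector of length 2
#' @export
setMethod("dim", "JacobianStructure", function(x) dim(x@mask))
#' @rdname dim-JacobianStructure-method
#' @export
setMethod("dim", "RelevanceMatrix", function(x) dim(x@relevance))
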