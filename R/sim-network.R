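# Sim-Network: reduce a metabolic model to a weighted directed metabolite
# graph, search cost-bounded shortest superpathways between measured
# metabolites, and derive the Jacobian sparsity structure.

stripCompartment <- function(ids, pattern = "_[a-z][a-z0-9]?$") {
  sub(pattern, "", ids)
}

#' Build the weighted directed metabolite graph of a model
#'
#' Converts each reaction (after excluding side metabolites, matched on
#' compartment-stripped base ids) into directed edges between base
#' metabolites: every (substrate, product) pair gets a forward edge of weight
#' 1; for reversible reactions every (product, substrate) pair gets a reverse
#' edge of weight \code{reverseWeight}, increased by log10(deltaG) when
#' thermodynamics are used and the reaction's delta Gibbs free energy exceeds
#' 100 kcal/mol. Because a reaction rate is influenced by all its reactants,
#' every unordered substrate pair is linked in both directions at the forward
#' weight (co-substrate relation), and every unordered product pair of a
#' reversible reaction at the reverse weight (co-product relation). Parallel
#' edges collapse to the minimum weight with merged provenance.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param thermo optional thermodynamics table from
#'   \code{\link{readModelseedThermo}}
#' @param sides side-metabolite base ids (default
#'   \code{\link{defaultSideMetabolites}})
#' @param reverseWeight weight of the reverse direction of reversible
#'   reactions (>= 1, default 2)
#' @param useThermo apply the delta-G penalty to reverse edges (default TRUE)
#' @param compartmentPattern regular expression stripped from metabolite ids
#'   to obtain base ids
#' @return a \linkS4class{ReactionGraph}
#' @export
buildGraph <- function(model, thermo = NULL,
                       sides = defaultSideMetabolites(),
                       reverseWeight = 2, useThermo = TRUE,
                       compartmentPattern = "_[a-z][a-z0-9]?$") {
  stopifnot(is(model, "MetabolicModel"))
  if (reverseWeight < 1) stop("reverseWeight must be >= 1")
  dgOf <- function(id) {
    if (is.null(thermo)) return(NA_real_)
    hit <- match(id, thermo$reaction_id)
    if (is.na(hit)) NA_real_ else thermo$delta_g[hit]
  }
  edges <- new.env(parent = emptyenv())
  addEdge <- function(u, v, w, rx, direction, relation) {
    key <- paste0(u, "\r", v)
    prev <- edges[[key]]
    rec <- data.frame(reaction = rx, direction = direction,
                      relation = relation, stringsAsFactors = FALSE)
    if (is.null(prev)) {
      edges[[key]] <- list(from = u, to = v, weight = w, prov = rec)
    } else {
      prev$weight <- min(prev$weight, w)
      prev$prov <- rbind(prev$prov, rec)
      edges[[key]] <- prev
    }
  }
  for (rx in model@reactions) {
    st <- rx$stoichiometry
    base <- stripCompartment(names(st), compartmentPattern)
    keep <- !(base %in% sides)
    st <- st[keep]; base <- base[keep]
    subs <- unique(base[st < 0])
    prods <- unique(base[st > 0])
    subs <- setdiff(subs, prods)            # same base id on both sides:
    prods <- setdiff(prods, unique(base[st < 0]))  # transport, no edge
    wf <- 1
    dg <- dgOf(rx$id)
    wr <- reverseWeight +
      if (useThermo && !is.na(dg) && dg > 100) log10(dg) else 0
    if (length(subs) && length(prods)) {
      for (s in subs) for (p in prods) {
        addEdge(s, p, wf, rx$id, "forward", "substrate->product")
        if (rx$reversible)
          addEdge(p, s, wr, rx$id, "reverse", "substrate->product")
      }
    }
    if (length(subs) > 1L) {
      pairs <- utils::combn(sort(subs), 2L)
      for (c0 in seq_len(ncol(pairs))) {
        addEdge(pairs[1, c0], pairs[2, c0], wf, rx$id, "forward",
                "co-substrate")
        addEdge(pairs[2, c0], pairs[1, c0], wf, rx$id, "forward",
                "co-substrate")
      }
    }
    if (rx$reversible && length(prods) > 1L) {
      pairs <- utils::combn(sort(prods), 2L)
      for (c0 in seq_len(ncol(pairs))) {
        addEdge(pairs[1, c0], pairs[2, c0], wr, rx$id, "reverse",
                "co-product")
        addEdge(pairs[2, c0], pairs[1, c0], wr, rx$id, "reverse",
                "co-product")
      }
    }
  }
  keys <- sort(ls(edges))
  recs <- lapply(keys, function(k) edges[[k]])
  edf <- data.frame(
    from = vapply(recs, `[[`, "", "from"),
    to = vapply(recs, `[[`, "", "to"),
    weight = vapply(recs, `[[`, 0, "weight"),
    stringsAsFactors = FALSE)
  prov <- lapply(recs, function(r) {
    p <- r$prov
    p[order(p$reaction, p$direction, p$relation), , drop = FALSE]
  })
  nodes <- sort(unique(c(edf$from, edf$to)))
  new("ReactionGraph", nodes = nodes, edges = edf, provenance = prov)
}

# lexicographic comparison of node-index paths; TRUE iff a < b
pathLess <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (k in seq_len(min(la, lb))) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  la < lb
}

#' All-pairs shortest superpathways between measured metabolites
#'
#' Dijkstra's algorithm from each source, with deterministic tie-breaking:
#' among equal-cost routes the one with the lexicographically smaller node
#' sequence (by node id) is returned. Targets absent from the graph are
#' reported and treated as isolated; ordered pairs without a route are
#' omitted.
#'
#' @param graph a \linkS4class{ReactionGraph}
#' @param targets ordered measured-metabolite ids
#' @return list of path records (source, target, cost, route, reactions),
#'   named \code{"source->target"}
#' @export
shortestPaths <- function(graph, targets) {
  stopifnot(is(graph, "ReactionGraph"))
  absent <- setdiff(targets, graph@nodes)
  if (length(absent))
    warning("target(s) not in graph, kept as isolated: ",
            paste(absent, collapse = ", "))
  # node order: sorted ids, so index comparison = lexicographic id comparison
  nodes <- graph@nodes
  nV <- length(nodes)
  eFrom <- match(graph@edges$from, nodes)
  eTo <- match(graph@edges$to, nodes)
  eW <- graph@edges$weight
  adj <- split(seq_along(eW), eFrom)
  out <- list()
  for (src in intersect(targets, nodes)) {
    s <- match(src, nodes)
    dist <- rep(Inf, nV)
    paths <- vector("list", nV)
    dist[s] <- 0; paths[[s]] <- s
    done <- logical(nV)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      ties <- cand[dist[cand] == dist[u]]
      if (length(ties) > 1L)
        for (t0 in ties) if (pathLess(paths[[t0]], paths[[u]])) u <- t0
      done[u] <- TRUE
      for (ei in adj[[as.character(u)]]) {
        v <- eTo[ei]
        nd <- dist[u] + eW[ei]
        if (nd < dist[v] - 1e-12) {
          dist[v] <- nd
          paths[[v]] <- c(paths[[u]], v)
        } else if (abs(nd - dist[v]) <= 1e-12) {
          candPath <- c(paths[[u]], v)
          if (pathLess(candPath, paths[[v]])) paths[[v]] <- candPath
        }
      }
    }
    for (tgt in intersect(setdiff(targets, src), nodes)) {
      t1 <- match(tgt, nodes)
      if (!is.finite(dist[t1])) next
      route <- nodes[paths[[t1]]]
      hops <- cbind(route[-length(route)], route[-1])
      rxs <- lapply(seq_len(nrow(hops)), function(h) {
        ei <- which(graph@edges$from == hops[h, 1] &
                    graph@edges$to == hops[h, 2])
        graph@provenance[[ei]]$reaction
      })
      out[[paste0(src, "->", tgt)]] <-
        list(source = src, target = tgt, cost = dist[t1], route = route,
             reactions = rxs)
    }
  }
  out
}

#' Prune routes and derive the Jacobian sparsity structure
#'
#' A route from source j to target i is kept iff its cost does not exceed
#' \code{costThreshold} (routes costing exactly the threshold are kept) and
#' no interior route metabolite is itself a target: an indirect interaction
#' through a measured metabolite is captured by the two shorter connections.
#' Kept routes set mask entry (i, j) (J[i, j] = df_i/dM_j: j influences i);
#' the diagonal is always TRUE.
#'
#' @param paths result of \code{\link{shortestPaths}}
#' @param targets ordered measured-metabolite ids (defines label order)
#' @param costThreshold maximum accepted route cost (default 3)
#' @return a \linkS4class{JacobianStructure}
#' @export
pruneAndStructure <- function(paths, targets, costThreshold = 3) {
  n <- length(targets)
  mask <- diag(TRUE, n)
  annotation <- list()
  for (p in paths) {
    if (!(p$source %in% targets) || !(p$target %in% targets))
      stop("path endpoints must be targets: ", p$source, "->", p$target)
    if (p$cost > costThreshold) next
    interior <- p$route[-c(1L, length(p$route))]
    if (any(interior %in% targets)) next
    i <- match(p$target, targets)
    j <- match(p$source, targets)
    mask[i, j] <- TRUE
    annotation[[sprintf("%d,%d", i, j)]] <- p
  }
  jacobianStructure(targets, mask, annotation)
}

#' Compare two Jacobian structures
#'
#' Partitions off-diagonal entries into found-only ("added"),
#' reference-only ("missing") and shared.
#'
#' @param found,reference \linkS4class{JacobianStructure} objects with
#'   identical label order
#' @return list of class \code{structureComparison} with counts and entry
#'   lists (i, j index matrices)
#' @export
structureCompare <- function(found, reference) {
  stopifnot(is(found, "JacobianStructure"),
            is(reference, "JacobianStructure"))
  if (!identical(found@labels, reference@labels))
    stop("structures must share an identical label order")
  offF <- found@mask & !diag(TRUE, nrow(found@mask))
  offR <- reference@mask & !diag(TRUE, nrow(reference@mask))
  pick <- function(m) which(m, arr.ind = TRUE)
  out <- list(added = sum(offF & !offR), missing = sum(!offF & offR),
              shared = sum(offF & offR),
              addedEntries = pick(offF & !offR),
              missingEntries = pick(!offF & offR),
              sharedEntries = pick(offF & offR),
              labels = found@labels)
  class(out) <- "structureComparison"
  out
}

#' @export
print.structureComparison <- function(x, ...) {
  cat("Structure comparison:", x$shared, "shared,", x$added, "added,",
      x$missing, "missing off-diagonal interactions\n")
  invisible(x)
}

#' Write a structure's mask and superpathway table as CSV
#'
#' \code{mask.csv}: labeled 0/1 matrix. \code{superpathways.csv}: one row per
#' off-diagonal interaction with columns from, to, cost, route and
#' contributing reaction ids (and their genes/enzymes when \code{model} is
#' given).
#'
#' @param structure a \linkS4class{JacobianStructure}
#' @param dir output directory (created if needed)
#' @param model optional \linkS4class{MetabolicModel} for gene annotation
#' @return invisibly, the two file paths
#' @export
writeStructureCsv <- function(structure, dir, model = NULL) {
  stopifnot(is(structure, "JacobianStructure"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maskPath <- file.path(dir, "mask.csv")
  M <- structure@mask + 0
  utils::write.csv(as.data.frame(M), maskPath, row.names = TRUE)
  geneOf <- function(rxIds) {
    if (is.null(model)) return("")
    g <- unlist(lapply(model@reactions, function(rx)
      if (rx$id %in% rxIds) rx$genes else NULL))
    paste(unique(g), collapse = "|")
  }
  rows <- lapply(names(structure@annotation), function(key) {
    p <- structure@annotation[[key]]
    rxs <- unique(unlist(p$reactions))
    data.frame(from = p$source, to = p$target, cost = p$cost,
               route = paste(p$route, collapse = ">"),
               reactions = paste(rxs, collapse = "|"),
               genes = geneOf(rxs), stringsAsFactors = FALSE)
  })
  spPath <- file.path(dir, "superpathways.csv")
  sp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), cost = numeric(),
               route = character(), reactions = character(),
               genes = character())
  utils::write.csv(sp, spPath, row.names = FALSE)
  invisible(c(maskPath, spPath))
}
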