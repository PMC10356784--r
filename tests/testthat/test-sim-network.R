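# tiny hand-built models for graph construction
simpleModel <- function(reactions, mets = NULL) {
  if (is.null(mets))
    mets <- sort(unique(unlist(lapply(reactions, function(r)
      names(r$stoichiometry)))))
  new("MetabolicModel",
      metabolites = data.frame(id = mets, name = mets, compartment = "",
                               stringsAsFactors = FALSE),
      reactions = reactions, organism = "")
}

test_that("graph construction applies the weighting and co-reactant rules", {
  # irreversible A + B -> C
  m <- simpleModel(list(list(id = "r1",
                             stoichiometry = c(A = -1, B = -1, C = 1),
                             reversible = FALSE, genes = character(0),
                             source = "custom")))
  g <- buildGraph(m, sides = character(0))
  e <- graphEdges(g)
  key <- paste(e$from, e$to)
  expect_setequal(key, c("A C", "B C", "A B", "B A"))
  expect_true(all(e$weight == 1))
  # reversible A <-> B, no thermodynamics: forward 1, reverse 2
  m2 <- simpleModel(list(list(id = "r2", stoichiometry = c(A = -1, B = 1),
                              reversible = TRUE, genes = character(0),
                              source = "custom")))
  e2 <- graphEdges(buildGraph(m2, sides = character(0)))
  expect_equal(e2$weight[e2$from == "A" & e2$to == "B"], 1)
  expect_equal(e2$weight[e2$from == "B" & e2$to == "A"], 2)
  # delta-G > 100 kcal/mol adds log10(deltaG) to the reverse weight
  thermo <- data.frame(reaction_id = "r2", delta_g = 5000,
                       direction_hint = "reversible",
                       stringsAsFactors = FALSE)
  e3 <- graphEdges(buildGraph(m2, thermo = thermo, sides = character(0)))
  expect_equal(e3$weight[e3$from == "B" & e3$to == "A"], 2 + log10(5000))
  # thermo below the cutoff leaves the reverse weight alone
  thermo$delta_g <- 50
  e4 <- graphEdges(buildGraph(m2, thermo = thermo, sides = character(0)))
  expect_equal(e4$weight[e4$from == "B" & e4$to == "A"], 2)
})

test_that("side metabolites are excluded and parallel edges collapse to min", {
  rx <- list(
    list(id = "r1", stoichiometry = c(A_c = -1, atp_c = -1, B_c = 1,
                                      adp_c = 1),
         reversible = FALSE, genes = character(0), source = "custom"),
    list(id = "r2", stoichiometry = c(A_c = -1, B_c = 1),
         reversible = TRUE, genes = character(0), source = "custom"))
  g <- buildGraph(simpleModel(rx), sides = c("atp", "adp"))
  e <- graphEdges(g)
  expect_false(any(c("atp", "adp") %in% graphNodes(g)))
  # A->B appears once (collapsed), with both reactions in provenance
  ab <- which(e$from == "A" & e$to == "B")
  expect_length(ab, 1L)
  expect_setequal(g@provenance[[ab]]$reaction, c("r1", "r2"))
  expect_equal(e$weight[ab], 1)
})

test_that("graph construction is independent of reaction iteration order", {
  rx <- list(
    list(id = "r1", stoichiometry = c(A = -1, B = 1), reversible = TRUE,
         genes = character(0), source = "custom"),
    list(id = "r2", stoichiometry = c(B = -1, C = 1), reversible = FALSE,
         genes = character(0), source = "custom"),
    list(id = "r3", stoichiometry = c(A = -1, C = 1), reversible = FALSE,
         genes = character(0), source = "custom"))
  g1 <- buildGraph(simpleModel(rx), sides = character(0))
  g2 <- buildGraph(simpleModel(rev(rx)), sides = character(0))
  expect_identical(graphEdges(g1), graphEdges(g2))
  expect_identical(g1@provenance, g2@provenance)
})

test_that("shortest paths match exhaustive enumeration and igraph on small graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    nV <- sample(4:8, 1)
    nodes <- LETTERS[seq_len(nV)]
    ne <- sample(6:14, 1)
    e <- unique(data.frame(
      from = sample(nodes, ne, replace = TRUE),
      to = sample(nodes, ne, replace = TRUE),
      stringsAsFactors = FALSE))
    e <- e[e$from != e$to, , drop = FALSE]
    e$weight <- round(stats::runif(nrow(e), 0.5, 3), 2)
    g <- new("ReactionGraph", nodes = nodes, edges = e,
             provenance = rep(list(data.frame(reaction = "r",
                                              direction = "forward",
                                              relation = "substrate->product",
                                              stringsAsFactors = FALSE)),
                              nrow(e)))
    paths <- shortestPaths(g, nodes)
    ig <- igraph::graph_from_data_frame(e, vertices = nodes)
    dmat <- igraph::distances(ig, mode = "out", weights = e$weight)
    for (s in nodes) for (t in nodes) {
      if (s == t) next
      p <- paths[[paste0(s, "->", t)]]
      brute <- enumerateShortestCost(e, s, t)
      if (is.finite(dmat[s, t])) {
        expect_equal(p$cost, dmat[s, t], tolerance = 1e-12)
        expect_equal(p$cost, brute, tolerance = 1e-12)
        # route cost equals the sum of its edge weights
        hops <- cbind(p$route[-length(p$route)], p$route[-1])
        w <- vapply(seq_len(nrow(hops)), function(h)
          e$weight[e$from == hops[h, 1] & e$to == hops[h, 2]], numeric(1))
        expect_equal(sum(w), p$cost, tolerance = 1e-12)
      } else {
        expect_null(p)
      }
    }
  }
})

test_that("equal-cost routes break ties lexicographically", {
  e <- data.frame(from = c("A", "A", "B", "C"),
                  to = c("B", "C", "D", "D"),
                  weight = 1, stringsAsFactors = FALSE)
  g <- new("ReactionGraph", nodes = c("A", "B", "C", "D"), edges = e,
           provenance = rep(list(data.frame(reaction = "r",
                                            direction = "forward",
                                            relation = "substrate->product",
                                            stringsAsFactors = FALSE)), 4))
  p <- shortestPaths(g, c("A", "D"))[["A->D"]]
  expect_identical(p$route, c("A", "B", "D"))
  expect_equal(p$cost, 2)
})

test_that("pruning discards costly routes and interior measured metabolites", {
  e <- data.frame(from = c("A", "B"), to = c("B", "C"), weight = 1,
                  stringsAsFactors = FALSE)
  g <- new("ReactionGraph", nodes = c("A", "B", "C"), edges = e,
           provenance = rep(list(data.frame(reaction = "r",
                                            direction = "forward",
                                            relation = "substrate->product",
                                            stringsAsFactors = FALSE)), 2))
  # targets {A, C}: route A->B->C (cost 2) kept, mask(C, A) set
  st <- pruneAndStructure(shortestPaths(g, c("A", "C")), c("A", "C"),
                          costThreshold = 3)
  expect_true(maskMatrix(st)["C", "A"])
  expect_false(maskMatrix(st)["A", "C"])
  # targets {A, B, C}: interior B is measured -> A->C discarded, steps kept
  st3 <- pruneAndStructure(shortestPaths(g, c("A", "B", "C")),
                           c("A", "B", "C"), costThreshold = 3)
  expect_false(maskMatrix(st3)["C", "A"])
  expect_true(maskMatrix(st3)["B", "A"])
  expect_true(maskMatrix(st3)["C", "B"])
  # threshold is strict: cost above discards, cost equal keeps
  st2 <- pruneAndStructure(shortestPaths(g, c("A", "C")), c("A", "C"),
                           costThreshold = 1.5)
  expect_false(maskMatrix(st2)["C", "A"])
  stEq <- pruneAndStructure(shortestPaths(g, c("A", "C")), c("A", "C"),
                            costThreshold = 2)
  expect_true(maskMatrix(stEq)["C", "A"])
})

test_that("threshold monotonicity and target-addition pruning invariants hold", {
  set.seed(7)
  nodes <- LETTERS[1:7]
  e <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  e <- e[e$from != e$to & stats::runif(nrow(e)) < 0.3, ]
  e$weight <- round(stats::runif(nrow(e), 0.5, 2), 2)
  g <- new("ReactionGraph", nodes = nodes, edges = e,
           provenance = rep(list(data.frame(reaction = "r",
                                            direction = "forward",
                                            relation = "substrate->product",
                                            stringsAsFactors = FALSE)),
                            nrow(e)))
  targets <- c("A", "C", "E")
  paths <- shortestPaths(g, targets)
  masks <- lapply(c(1, 2, 3, 4), function(th)
    maskMatrix(pruneAndStructure(paths, targets, th)))
  for (k in seq_len(length(masks) - 1))
    expect_true(all(masks[[k + 1]][masks[[k]]])) # t1 <= t2 => mask(t1) subset
  # adding a target never adds an interaction between the old targets
  targets2 <- c("A", "C", "E", "F")
  m3 <- maskMatrix(pruneAndStructure(shortestPaths(g, targets2), targets2))
  old <- maskMatrix(pruneAndStructure(paths, targets))
  expect_true(all(old[m3[1:3, 1:3]]))
})

test_that("interaction SBML export/import round-trips the mask", {
  labels <- c("A", "B", "C")
  mask <- matrix(c(TRUE, TRUE, FALSE,
                   FALSE, TRUE, TRUE,
                   FALSE, FALSE, TRUE), 3, 3, byrow = TRUE)
  ann <- list("1,2" = list(source = "B", target = "A", cost = 1.5,
                           route = c("B", "Q", "A"),
                           reactions = list("r9", "r2")),
              "2,3" = list(source = "C", target = "B", cost = 1,
                           route = c("C", "B"), reactions = list("r1")))
  st <- jacobianStructure(labels, mask, ann)
  f <- withr::local_tempfile(fileext = ".sbml")
  exportInteractionSbml(st, f)
  back <- importInteractionSbml(f)
  expect_identical(structureLabels(back), labels)
  expect_identical(maskMatrix(back), maskMatrix(st))
  a <- pathAnnotations(back)[["1,2"]]
  expect_equal(a$cost, 1.5)
  expect_identical(a$route, c("B", "Q", "A"))
  expect_setequal(a$reactions, c("r9", "r2"))
  # diagonal-only mask: species but zero interaction reactions
  st0 <- jacobianStructure(labels, diag(TRUE, 3))
  f0 <- withr::local_tempfile(fileext = ".sbml")
  exportInteractionSbml(st0, f0)
  doc <- xml2::read_xml(f0)
  expect_length(xml2::xml_find_all(doc, ".//*[local-name()='reaction']"), 0)
  expect_length(xml2::xml_find_all(doc, ".//*[local-name()='species']"), 3)
  # full 2x2 mask: 2 species, 2 interaction reactions
  stF <- jacobianStructure(c("A", "B"), matrix(TRUE, 2, 2))
  fF <- withr::local_tempfile(fileext = ".sbml")
  exportInteractionSbml(stF, fF)
  docF <- xml2::read_xml(fF)
  expect_length(xml2::xml_find_all(docF, ".//*[local-name()='reaction']"), 2)
})

test_that("structure comparison partitions off-diagonal entries", {
  labels <- c("A", "B", "C")
  m1 <- diag(TRUE, 3); m1[1, 2] <- m1[2, 3] <- TRUE
  m2 <- diag(TRUE, 3); m2[1, 2] <- m2[3, 1] <- m2[2, 1] <- TRUE
  cmp <- structureCompare(jacobianStructure(labels, m1),
                          jacobianStructure(labels, m2))
  expect_equal(cmp$shared, 1)
  expect_equal(cmp$added, 1)
  expect_equal(cmp$missing, 2)
  same <- structureCompare(jacobianStructure(labels, m1),
                           jacobianStructure(labels, m1))
  expect_equal(same$added + same$missing, 0)
  expect_error(structureCompare(jacobianStructure(labels, m1),
                                jacobianStructure(c("X", "Y", "Z"), m1)),
               "label")
})
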