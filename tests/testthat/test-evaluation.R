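test_that("top-k hits require exact set equality against the truth", {
  lab <- c("A", "B")
  mask <- matrix(TRUE, 2, 2)
  rel <- matrix(c(0.2, 1, 0.1, 0), 2, 2, dimnames = list(lab, lab))
  R <- new("RelevanceMatrix", labels = lab, rawLoss = 1 - rel,
           relevance = rel, mask = mask, nSamples = 1L, seed = 1L)
  truth <- matrix(1, 2, 2); truth[2, 1] <- 4   # single change at (2,1)
  expect_true(topkHit(R, truth, 1))
  truthElse <- matrix(1, 2, 2); truthElse[1, 2] <- 4
  expect_false(topkHit(R, truthElse, 1))
  # no change at all: warning and FALSE
  expect_warning(hit <- topkHit(R, matrix(1, 2, 2), 1), "no change")
  expect_false(hit)
  # k = 3 with only 2 matching of 3 is a miss (set equality, not overlap)
  truth3 <- matrix(1, 2, 2); truth3[2, 1] <- 4; truth3[1, 2] <- 3
  truth3[1, 1] <- 2
  rel3 <- matrix(c(1, 0.9, 0.1, 0.8), 2, 2, dimnames = list(lab, lab))
  R3 <- new("RelevanceMatrix", labels = lab, rawLoss = 1 - rel3,
            relevance = rel3, mask = mask, nSamples = 1L, seed = 1L)
  # truth top-3: (2,1), (1,2), (1,1); found top-3: (1,1), (2,1), (2,2)
  expect_false(topkHit(R3, truth3, 3))
})

test_that("replicability reaches the deterministic limit on a clean fixture", {
  fix <- getFixturePair(5)
  rep0 <- replicability(fix$pair, epsD = 0.001, nRepeats = 5, seed = 99,
                        nSamples = 60, kValues = 1L)
  expect_equal(unname(rep0$accuracy["top1"]), 1)
  expect_equal(unname(rep0$overlap["top1"]), 1)
  # identical pair: degenerate truth, accuracy 0 with warnings
  m <- chainKineticModel()
  pair0 <- makeConditionPair(m, c(conv = 1))
  w <- capture_warnings(
    repId <- replicability(pair0, epsD = 0.1, nRepeats = 2, seed = 1,
                           nSamples = 20, kValues = 1L))
  expect_match(w, "no change", all = FALSE)
  expect_equal(unname(repId$accuracy["top1"]), 0)
})

test_that("differential correlation is a zero-diagonal unit-invariant control", {
  fix <- getFixturePair(5)
  tr <- fix$truth
  Ch <- covarianceViaLyapunov(tr$Jh, 0.2, seed = 3)$C
  Cd <- covarianceViaLyapunov(tr$Jd, 0.2, seed = 4)$C
  dc <- differentialCorrelation(Ch, Cd)
  expect_equal(max(abs(diag(dc))), 0)
  expect_equal(max(abs(differentialCorrelation(Ch, Ch))), 0)
  # separate per-metabolite unit rescaling leaves it unchanged
  s <- diag(c(2, 0.5, 10, 1, 3))
  expect_equal(differentialCorrelation(s %*% Ch %*% s, s %*% Cd %*% s), dc,
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- Ch; bad[1, 1] <- 0
  expect_error(differentialCorrelation(bad, Cd), "zero variance")
  # reported alongside the scan as a negative control: rank correlation
  # between |diff corr| and |DJ - 1| carries no pass threshold
  off <- row(dc) != col(dc)
  rk <- suppressWarnings(
    stats::cor(abs(dc[off]), abs(tr$dj[off] - 1), method = "spearman"))
  expect_true(is.finite(rk))
})

test_that("variable importance is a -log10 Welch t-test score", {
  set.seed(6)
  h <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
  d <- h
  expect_equal(unname(variableImportance(h, d)), c(0, 0))  # identical: P = 1
  d2 <- d; d2[, 1] <- d2[, 1] + 10      # 10-sigma mean shift, n = 20
  vi <- variableImportance(h, d2)
  expect_gt(vi[["A"]], 3)
  expect_lt(vi[["B"]], 1)
  expect_error(variableImportance(h, d2[, 1, drop = FALSE]), "same")
  hz <- matrix(1, 5, 1); dz <- matrix(1, 5, 1)
  expect_warning(vz <- variableImportance(hz, dz), "zero variance")
  expect_equal(unname(vz), 0)
})

test_that("circular plots are written deterministically with sidecar tables", {
  fix <- getFixturePair(5)
  tr <- fix$truth
  Ch <- covarianceViaLyapunov(tr$Jh, 0.2, seed = 3)$C
  Cd <- covarianceViaLyapunov(tr$Jd, 0.2, seed = 4)$C
  R <- regressionLossScan(Ch, Cd, tr$structure, nSamples = 40, seed = 2)
  f <- file.path(withr::local_tempdir(), "plot.png")
  circularPlot(R, path = f)
  expect_true(file.exists(f))
  sidecar <- sub("\\.png$", "_edges.csv", f)
  expect_true(file.exists(sidecar))
  e1 <- utils::read.csv(sidecar)
  circularPlot(R, path = f)
  expect_identical(utils::read.csv(sidecar), e1)
  # zero relevance: no edge rows above any cutoff, file still written
  R0 <- regressionLossScan(Ch, Ch, tr$structure, nSamples = 20, seed = 2)
  f0 <- file.path(withr::local_tempdir(), "plot0.svg")
  circularPlot(R0, path = f0)
  expect_true(file.exists(f0))
  e0 <- utils::read.csv(sub("\\.svg$", "_edges.csv", f0))
  expect_true(all(e0$relevance == 0))
})

test_that("the config-driven workflow runs end to end and is reproducible", {
  cfg <- list(
    synthetic = list(n_species = 5, n_reactions = 7, seed = 11,
                     perturb = list(list(parameter = "outflow_3",
                                         factor = 5)),
                     eps_d = 0.2),
    algorithm = list(n_samples = 60, seed = 3))
  d1 <- withr::local_tempdir()
  suppressMessages(runWorkflow(cfg, outDir = d1))
  expect_true(all(file.exists(file.path(d1, c("relevance.csv",
                                              "raw_loss.csv",
                                              "manifest.json",
                                              "circular_plot.png",
                                              "log.txt")))))
  mf <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true(isTRUE(mf$top1_recovered))
  # rerun with the same config: identical relevance table
  d2 <- withr::local_tempdir()
  suppressMessages(runWorkflow(cfg, outDir = d2))
  expect_identical(readLines(file.path(d1, "relevance.csv")),
                   readLines(file.path(d2, "relevance.csv")))
  # validation precedes execution
  expect_error(suppressMessages(runWorkflow(list(algorithm = list()),
                                            outDir = withr::local_tempdir())),
               "covariance.*synthetic|synthetic")
})

test_that("the workflow consumes a model plus covariance files via Sim-Network", {
  # toy model: targets glc/g6p/f6p, structure from the reaction graph
  model <- makeToyModel()
  mpath <- withr::local_tempfile(fileext = ".json")
  writeGenomeScaleModel(model, mpath, "bigg_json")
  lab <- c("glc", "g6p", "f6p")
  set.seed(15)
  J <- matrix(c(-1, 0.8, 0, 0.3, -1.2, 0.9, 0.5, 0, -1.5), 3, 3,
              dimnames = list(lab, lab))
  Ch <- solveForwardLyapunov(J, diag(3))
  J2 <- J; J2[2, 1] <- J2[2, 1] * 0.2
  Cd <- solveForwardLyapunov(J2, diag(3))
  dimnames(Ch) <- dimnames(Cd) <- list(lab, lab)
  dir <- withr::local_tempdir()
  writeCovarianceCsv(Ch, file.path(dir, "ch.csv"))
  writeCovarianceCsv(Cd, file.path(dir, "cd.csv"))
  cfg <- list(
    model = list(format = "bigg_json", path = mpath),
    targets = c("glc_c", "g6p_c", "f6p_c"),
    network = list(cost_threshold = 3, reverse_weight = 2, thermo = FALSE),
    covariance = list(h = file.path(dir, "ch.csv"),
                      d = file.path(dir, "cd.csv")),
    algorithm = list(n_samples = 40, seed = 5))
  out <- withr::local_tempdir()
  suppressMessages(runWorkflow(cfg, outDir = out))
  expect_true(file.exists(file.path(out, "network.sbml")))
  expect_true(file.exists(file.path(out, "superpathways.csv")))
  rel <- as.matrix(utils::read.csv(file.path(out, "relevance.csv"),
                                   row.names = 1))
  expect_equal(dim(rel), c(3L, 3L))
})
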