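#' Top-k hit test against the true differential Jacobian
#'
#' The reference set is the k masked positions with the largest |DJ - 1|
#' (ties by (row, column) order; when fewer than k positions truly changed,
#' the reference is padded by the next-largest |DJ - 1| with a warning). The
#' scan hits iff its top-k positions equal the reference as a set (exact set
#' equality, not overlap).
#'
#' @param R a \linkS4class{RelevanceMatrix}
#' @param truth true differential Jacobian (n-by-n matrix)
#' @param k number of top components
#' @return logical; FALSE with a warning when the truth shows no change
#' @export
topkHit <- function(R, truth, k) {
  stopifnot(is(R, "RelevanceMatrix"))
  checkSquareLabeled(truth, "truth")
  if (!all(dim(truth) == dim(R@mask)))
    stop("truth dimension does not match the relevance matrix")
  pos <- maskPositions(R@mask)
  score <- abs(truth[pos] - 1)
  if (all(score == 0)) {
    warning("true differential Jacobian shows no change; hit undefined, ",
            "returning FALSE")
    return(FALSE)
  }
  if (sum(score > 0) < k)
    warning("fewer than k = ", k, " truly changed positions; reference ",
            "padded by next-largest |DJ - 1|")
  oTruth <- order(-score, pos[, 1L], pos[, 2L])[seq_len(k)]
  refSet <- sprintf("%d,%d", pos[oTruth, 1L], pos[oTruth, 2L])
  top <- rankComponents(R, k)
  foundSet <- sprintf("%d,%d", top$i, top$j)
  setequal(refSet, foundSet)
}

#' Replicability of the top differential-Jacobian components
#'
#' Repeats the full inference \code{nRepeats} times: per repeat, fresh seeded
#' covariances for both conditions are generated from the Lyapunov equation
#' with fluctuation randomness \code{epsD}, the regression-loss scan is run,
#' and the top-k hit is recorded for each k. \code{accuracy} is the exact
#' set-equality hit fraction (the strictest reading); the mean top-k overlap
#' fraction is reported alongside as \code{overlap}.
#'
#' @param pair a \linkS4class{ConditionPair}
#' @param epsD fluctuation randomness in [0, 1)
#' @param nRepeats number of repeats (default 100)
#' @param seed integer RNG seed
#' @param nSamples fluctuation samples per scan (default 100)
#' @param kValues top-k sizes (default 1, 3, 5)
#' @return list of class \code{replicabilityReport}: \code{accuracy} and
#'   \code{overlap} (named by k), \code{epsD}, \code{nRepeats}, \code{seed}
#' @export
replicability <- function(pair, epsD, nRepeats = 100L, seed,
                          nSamples = 100L, kValues = c(1L, 3L, 5L)) {
  stopifnot(is(pair, "ConditionPair"))
  truth <- conditionTruth(pair)
  seeds <- deriveSeeds(seed, 3L * nRepeats)
  hits <- matrix(FALSE, nRepeats, length(kValues),
                 dimnames = list(NULL, paste0("top", kValues)))
  overlap <- matrix(0, nRepeats, length(kValues),
                    dimnames = dimnames(hits))
  pos <- maskPositions(maskMatrix(truth$structure))
  score <- abs(truth$dj[pos] - 1)
  for (r in seq_len(nRepeats)) {
    Ch <- covarianceViaLyapunov(truth$Jh, epsD, seeds[3L * r - 2L])$C
    Cd <- covarianceViaLyapunov(truth$Jd, epsD, seeds[3L * r - 1L])$C
    R <- regressionLossScan(Ch, Cd, truth$structure, nSamples = nSamples,
                            seed = seeds[3L * r])
    for (ki in seq_along(kValues)) {
      k <- kValues[ki]
      hits[r, ki] <- topkHit(R, truth$dj, k)
      oT <- order(-score, pos[, 1L], pos[, 2L])[seq_len(k)]
      refSet <- sprintf("%d,%d", pos[oT, 1L], pos[oT, 2L])
      top <- rankComponents(R, k)
      overlap[r, ki] <- length(intersect(refSet,
                                         sprintf("%d,%d", top$i, top$j))) / k
    }
  }
  out <- list(accuracy = colMeans(hits), overlap = colMeans(overlap),
              epsD = epsD, nRepeats = nRepeats, seed = seed,
              kValues = kValues)
  class(out) <- "replicabilityReport"
  out
}

#' @export
print.replicabilityReport <- function(x, ...) {
  cat("Replicability over", x$nRepeats, "repeats (epsD =", x$epsD, "):\n")
  for (ki in seq_along(x$kValues))
    cat(sprintf("  Top %d: accuracy %.2f (overlap %.2f)\n",
                x$kValues[ki], x$accuracy[ki], x$overlap[ki]))
  invisible(x)
}

#' Differential correlation matrix (negative control)
#'
#' Elementwise difference of the two conditions' correlation matrices,
#' corr(Cd) - corr(Ch). Correlation differences alone cannot recover the
#' differential Jacobian; this is the baseline the covariance-based scan is
#' compared against.
#'
#' @param Ch,Cd covariance matrices with positive diagonals
#' @return n-by-n matrix (zero diagonal)
#' @export
differentialCorrelation <- function(Ch, Cd) {
  checkSquareLabeled(Ch); checkSquareLabeled(Cd)
  for (C in list(Ch, Cd)) {
    zero <- which(diag(C) <= 0)
    if (length(zero)) {
      lab <- matrixLabels(C, as.character(zero))[zero]
      stop("zero variance for metabolite(s): ", paste(lab, collapse = ", "))
    }
  }
  stats::cov2cor(Cd) - stats::cov2cor(Ch)
}

#' Per-metabolite variable importance from two sample sets
#'
#' Welch two-sample t-test per metabolite between conditions; the score is
#' -log10(P). Metabolites with zero variance in both groups score 0 with a
#' warning.
#'
#' @param samplesH,samplesD samples-by-metabolite matrices with matching
#'   columns
#' @return named numeric vector of -log10(P) scores
#' @export
variableImportance <- function(samplesH, samplesD) {
  if (ncol(samplesH) != ncol(samplesD))
    stop("sample matrices must have the same metabolite columns")
  if (nrow(samplesH) < 2L || nrow(samplesD) < 2L)
    stop("need at least 2 samples per condition")
  vapply(seq_len(ncol(samplesH)), function(j) {
    x <- samplesH[, j]; y <- samplesD[, j]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("zero variance in both groups for metabolite ", j,
              "; score set to 0")
      return(0)
    }
    p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    -log10(max(p, .Machine$double.xmin))
  }, numeric(1)) |> stats::setNames(colnames(samplesH))
}

#' Circular differential-interaction plot
#'
#' Metabolites are placed on a circle in label order (deterministic layout);
#' each off-diagonal relevance entry above \code{cutoff} is drawn as a curve
#' from j to i with width proportional to relevance, and node size is
#' proportional to \code{importance} (or to the diagonal relevance when no
#' importance vector is given). Superpathway annotations are written to a
#' sidecar CSV next to the figure.
#'
#' @param R a \linkS4class{RelevanceMatrix}
#' @param importance optional per-metabolite node score
#' @param annotations optional \linkS4class{JacobianStructure} whose path
#'   annotations feed the sidecar table
#' @param path output figure file (.png, .svg or .pdf)
#' @param cutoff minimum relevance for a drawn edge (default 0.5)
#' @return invisibly, the figure path
#' @export
circularPlot <- function(R, importance = NULL, annotations = NULL, path,
                         cutoff = 0.5) {
  stopifnot(is(R, "RelevanceMatrix"))
  n <- length(R@labels)
  if (!is.null(importance) && length(importance) != n)
    stop("importance length must match the label count")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = 900, height = 900, res = 120),
         svg = grDevices::svg(path, width = 8, height = 8),
         pdf = grDevices::pdf(path, width = 8, height = 8),
         stop("unsupported figure format: .", ext))
  on.exit(grDevices::dev.off())
  theta <- 2 * pi * (seq_len(n) - 1L) / n + pi / 2
  x <- cos(theta); y <- sin(theta)
  nodeScore <- if (!is.null(importance)) importance else diag(R@relevance)
  sizes <- 1 + 2.5 * nodeScore / max(nodeScore, 1e-12)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Differential metabolic interaction network")
  off <- maskPositions(R@mask)
  off <- off[off[, 1L] != off[, 2L], , drop = FALSE]
  if (nrow(off))
    for (k in seq_len(nrow(off))) {
      i <- off[k, 1L]; j <- off[k, 2L]
      w <- R@relevance[i, j]
      if (w < cutoff) next
      mx <- (x[i] + x[j]) / 2 * 0.35
      my <- (y[i] + y[j]) / 2 * 0.35
      graphics::xspline(c(x[j], mx, x[i]), c(y[j], my, y[i]),
                        shape = c(0, 0.8, 0), border = "#1f77b4cc",
                        lwd = 0.5 + 4 * w, open = TRUE)
    }
  graphics::points(x, y, pch = 21, bg = "#ff7f0e", cex = sizes)
  graphics::text(1.18 * x, 1.18 * y, R@labels, cex = 0.7,
                 srt = 0, xpd = NA)
  sidecar <- paste0(tools::file_path_sans_ext(path), "_edges.csv")
  ann <- if (!is.null(annotations)) annotations@annotation else list()
  rows <- lapply(seq_len(nrow(off)), function(k) {
    i <- off[k, 1L]; j <- off[k, 2L]
    p <- ann[[sprintf("%d,%d", i, j)]]
    data.frame(from = R@labels[j], to = R@labels[i],
               relevance = R@relevance[i, j],
               rawLoss = R@rawLoss[i, j],
               route = if (!is.null(p)) paste(p$route, collapse = ">") else "",
               reactions = if (!is.null(p))
                 paste(unique(unlist(p$reactions)), collapse = "|") else "",
               stringsAsFactors = FALSE)
  })
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), relevance = numeric(),
               rawLoss = numeric(), route = character(),
               reactions = character())
  utils::write.csv(edges, sidecar, row.names = FALSE)
  invisible(path)
}
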