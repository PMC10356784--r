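# Internal helpers shared across modules.

# vech row order: pairs (i, j) with i <= j, row-major in i then j.
vechPairs <- function(n) {
  i <- rep.int(seq_len(n), times = n - seq_len(n) + 1L)
  j <- unlist(lapply(seq_len(n), function(a) a:n), use.names = FALSE)
  cbind(i = i, j = j)
}

# row-major scan of TRUE mask entries -> L x 2 index matrix
maskPositions <- function(mask) {
  idx <- which(t(mask), arr.ind = TRUE)   # t() gives row-major order
  cbind(i = idx[, 2L], j = idx[, 1L])
}

checkSquareLabeled <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M))
    stop(what, " must be a square numeric matrix")
  invisible(M)
}

# symmetric to 1e-10 (relative), PSD to smallest eigenvalue >= -1e-8 * trace
checkCovariance <- function(C, what = "covariance matrix") {
  checkSquareLabeled(C, what)
  scale <- max(abs(C), 1)
  if (max(abs(C - t(C))) > 1e-10 * scale)
    stop(what, " must be symmetric (tolerance 1e-10)")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(C))
  if (min(ev) < -1e-8 * max(tr, 1))
    stop(what, " must be positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(C)
}

matrixLabels <- function(M, default = NULL) {
  l <- rownames(M)
  if (is.null(l)) l <- colnames(M)
  if (is.null(l)) l <- default
  l
}

# Sub-seeds derived from one user seed; kept below 2^31.
deriveSeeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

# Run fn with a local RNG state seeded at `seed`, restoring the global state.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Read / write a labeled square covariance matrix as CSV
#'
#' The CSV has a header row of metabolite labels and one labeled row per
#' metabolite (row names in the first column).
#'
#' @param path file path
#' @return \code{readCovarianceCsv}: a labeled numeric matrix
#' @export
readCovarianceCsv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
    stop("covariance CSV must be square with matching row/column labels")
  M
}

#' @rdname readCovarianceCsv
#' @param C labeled square matrix
#' @export
writeCovarianceCsv <- function(C, path) {
  checkSquareLabeled(C)
  utils::write.csv(as.data.frame(C), path, row.names = TRUE)
  invisible(path)
}
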