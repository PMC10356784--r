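#' Solve the forward Lyapunov equation J C + C J' = -2 D
#'
#' Near a stable steady state, the stationary covariance C of a linearized
#' stochastic system with Jacobian J and fluctuation (noise-covariance) matrix
#' D satisfies the continuous-time Lyapunov equation J C + C J' = -2 D. This
#' solves for C by the Kronecker vectorization
#' (I (x) J + J (x) I) vec(C) = vec(-2 D), followed by symmetrization and a
#' residual check.
#'
#' @param J n-by-n Jacobian matrix; must be Hurwitz-stable (all eigenvalue
#'   real parts < 0)
#' @param D n-by-n symmetric positive-semidefinite fluctuation matrix
#' @return n-by-n symmetric covariance matrix C with
#'   \eqn{\|J C + C J' + 2 D\|_F \le 10^{-8} \|D\|_F}
#' @examples
#' J <- diag(c(-1, -2))
#' solveForwardLyapunov(J, diag(2))   # diag(1, 0.5)
#' @export
solveForwardLyapunov <- function(J, D) {
  checkSquareLabeled(J, "Jacobian")
  checkSquareLabeled(D, "fluctuation matrix")
  n <- nrow(J)
  if (nrow(D) != n) stop("J and D must have the same dimension")
  re <- max(Re(eigen(J, only.values = TRUE)$values))
  if (!(re < 0))
    stop("Jacobian is not Hurwitz-stable: max eigenvalue real part = ",
         format(re))
  In <- diag(n)
  M <- kronecker(In, J) + kronecker(J, In)
  C <- matrix(solve(M, as.vector(-2 * D)), n, n)
  # one step of iterative refinement, then symmetrize
  R <- -2 * D - (J %*% C + C %*% t(J))
  C <- C + matrix(solve(M, as.vector(R)), n, n)
  C <- (C + t(C)) / 2
  resid <- norm(J %*% C + C %*% t(J) + 2 * D, "F")
  nD <- norm(D, "F")
  if (nD > 0 && resid > 1e-8 * nD)
    stop("Lyapunov solve failed residual check: ", format(resid / nD),
         " relative Frobenius residual")
  dimnames(C) <- dimnames(J)
  C
}

#' Vectorize the Lyapunov equation under a Jacobian sparsity structure
#'
#' Rewrites J C + C J' = -2 D as the linear system A q = b in the unknown
#' masked Jacobian entries q. Rows index unordered pairs (i, j) with i <= j
#' (m = n(n+1)/2 rows, row-major in i then j); columns index masked Jacobian
#' positions in row-major scan order. The coefficient of position (a, b) in
#' row (i, j) is \code{[i == a] C[b, j] + [j == a] C[i, b]}.
#'
#' @param C symmetric covariance matrix with the structure's label order
#' @param structure a \linkS4class{JacobianStructure}
#' @return a \linkS4class{LyapunovSystem}
#' @export
vectorizeCovariance <- function(C, structure) {
  stopifnot(is(structure, "JacobianStructure"))
  checkCovariance(C)
  n <- length(structure@labels)
  if (nrow(C) != n)
    stop("covariance dimension (", nrow(C), ") does not match structure (",
         n, ")")
  lab <- matrixLabels(C)
  if (!is.null(lab) && !identical(lab, structure@labels))
    stop("covariance labels do not match structure labels")
  pairs <- vechPairs(n)
  m <- nrow(pairs)
  # row id lookup for pair (i, j), i <= j
  rowId <- matrix(0L, n, n)
  rowId[cbind(pairs[, 1L], pairs[, 2L])] <- seq_len(m)
  pos <- maskPositions(structure@mask)
  L <- nrow(pos)
  if (L > m)
    warning("structure has more free entries (", L, ") than covariance ",
            "equations (", m, "); the system is underdetermined")
  A <- matrix(0, m, L)
  x <- seq_len(n)
  for (k in seq_len(L)) {
    a <- pos[k, 1L]; b <- pos[k, 2L]
    col <- numeric(m)
    # only rows whose pair contains a are nonzero: for pair {a, x}, x != a,
    # exactly one indicator fires and the coefficient is C[b, x] (= C[x, b]
    # by symmetry); for the diagonal pair (a, a) both fire: 2 C[a, b]
    rowsAX <- rowId[cbind(pmin(a, x), pmax(a, x))]
    col[rowsAX] <- C[b, ]
    col[rowsAX[a]] <- 2 * C[a, b]
    A[, k] <- col
  }
  new("LyapunovSystem", A = A, indexMap = pos, rowMap = pairs,
      labels = structure@labels)
}

#' Right-hand side of the vectorized Lyapunov system
#'
#' Stacks -2 D[i, j] over unordered pairs (i, j), i <= j, in the same row
#' order as \code{\link{vectorizeCovariance}}.
#'
#' @param D n-by-n symmetric fluctuation matrix
#' @return numeric vector of length n(n+1)/2
#' @export
buildB <- function(D) {
  checkSquareLabeled(D, "fluctuation matrix")
  pairs <- vechPairs(nrow(D))
  -2 * D[pairs]
}

#' Minimum-norm least squares with residual diagnostics
#'
#' Solves min ||b - A q|| by SVD (minimum-norm solution for rank-deficient A;
#' the normal-equations formula (A'A)^{-1} A' b defines the same minimizer but
#' squares the condition number, so it is not used for computation).
#'
#' @param A m-by-L matrix
#' @param b length-m vector
#' @return list with \code{qStar}, \code{residualNorm},
#'   \code{relativeResidual} (0 when ||b|| = 0) and \code{rank}
#' @export
regressionSolve <- function(A, b) {
  if (!is.matrix(A) || ncol(A) < 1L) stop("A must be a matrix with >= 1 column")
  if (any(!is.finite(A)) || any(!is.finite(b)))
    stop("non-finite entries in A or b")
  if (length(b) != nrow(A)) stop("length(b) must equal nrow(A)")
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  q <- if (r == 0L) numeric(ncol(A)) else
    sv$v[, seq_len(r), drop = FALSE] %*%
      ((crossprod(sv$u[, seq_len(r), drop = FALSE], b)) / sv$d[seq_len(r)])
  q <- drop(q)
  # residual b - A q* evaluated as the projection of b onto the orthogonal
  # complement of the column space: identical in exact arithmetic, but free
  # of the condition-number amplification that forming A q* incurs
  res <- if (r == 0L) b else {
    Ur <- sv$u[, seq_len(r), drop = FALSE]
    b - drop(Ur %*% crossprod(Ur, b))
  }
  rn <- sqrt(sum(res^2))
  nb <- sqrt(sum(b^2))
  list(qStar = q, residualNorm = rn,
       relativeResidual = if (nb > 0) rn / nb else 0, rank = r)
}

#' Condition number and numerical rank of a system matrix
#'
#' 2-norm condition number (ratio of extreme singular values) and rank at
#' tolerance \code{max(dim(A)) * eps * sigma_max}. A large condition number
#' destabilizes the regression solution q*, but not the regression residual.
#'
#' @param A numeric matrix
#' @return list with \code{conditionNumber} and \code{rank}
#' @export
conditionDiagnostics <- function(A) {
  if (any(!is.finite(A))) stop("A must be finite")
  d <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  list(conditionNumber = if (min(d) > 0) max(d) / min(d) else Inf,
       rank = sum(d > tol))
}

#' Construct a JacobianStructure
#'
#' From explicit labels and mask, or from the sparsity pattern of a numeric
#' Jacobian (nonzero entries plus the full diagonal).
#'
#' @param labels ordered metabolite ids
#' @param mask n-by-n logical matrix; the diagonal is forced TRUE
#' @param annotation optional named list of path records
#' @return a \linkS4class{JacobianStructure}
#' @export
jacobianStructure <- function(labels, mask, annotation = list()) {
  mask <- mask | diag(TRUE, length(labels))
  dimnames(mask) <- list(labels, labels)
  new("JacobianStructure", labels = labels, mask = mask,
      annotation = annotation)
}

#' @rdname jacobianStructure
#' @param J numeric Jacobian whose nonzero pattern defines the mask
#' @param tol entries with |J| > tol are masked TRUE
#' @export
structureFromJacobian <- function(J, tol = 0) {
  checkSquareLabeled(J, "Jacobian")
  labels <- matrixLabels(J, default = paste0("X", seq_len(nrow(J))))
  jacobianStructure(labels, abs(J) > tol)
}
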