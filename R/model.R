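#' Moore-Penrose pseudo-inverse
#'
#' Generalized inverse used throughout the steady-state model in place of
#' the ordinary inverse, because sparse regulatory networks can be rank
#' deficient.  Satisfies the four Penrose conditions and equals `solve(A)`
#' for nonsingular input.
#'
#' @param A square numeric matrix with finite entries.
#' @param tol relative tolerance below which singular values are treated as
#'   zero (passed to the underlying SVD-based computation).
#' @return The pseudo-inverse of `A`.
#' @examples
#' pseudoInverse(diag(3))
#' pseudoInverse(matrix(1, 2, 2))  # rank-1: all entries 0.25
#' @export
pseudoInverse <- function(A, tol = sqrt(.Machine$double.eps)) {
  .assertSquare(A, "A")
  MASS::ginv(A, tol = tol)
}

#' Steady-state response of a gene regulatory network to perturbation
#'
#' Under the linear steady-state model, the expression fold-change matrix is
#' \deqn{Y = -A^\dagger (P - F) + E,}
#' where \eqn{A} is the interaction matrix, \eqn{P} the intended
#' perturbation design, \eqn{F} the process error (variation in realized
#' perturbation, e.g. siRNA efficiency) and \eqn{E} the measurement error.
#'
#' @param net a [GeneNetwork-class].
#' @param P genes-by-experiments design matrix.
#' @param F_err,E_err optional process / measurement error matrices of the
#'   same shape as `P`; default zero.
#' @return The genes-by-experiments response matrix Y.
#' @export
steadyStateResponse <- function(net, P, F_err = NULL, E_err = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  A <- interactionMatrix(net)
  .assertFiniteMatrix(P, "P")
  if (nrow(P) != nrow(A))
    stop("P must have one row per gene of the network", call. = FALSE)
  if (is.null(F_err)) F_err <- matrix(0, nrow(P), ncol(P))
  if (is.null(E_err)) E_err <- matrix(0, nrow(P), ncol(P))
  if (!identical(dim(F_err), dim(P)) || !identical(dim(E_err), dim(P)))
    stop("F_err and E_err must match the shape of P", call. = FALSE)
  Y <- -pseudoInverse(A) %*% (P - F_err) + E_err
  dimnames(Y) <- dimnames(P)
  Y
}
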