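## Sparse estimators for -P = A Y.  The inference step deliberately ignores
## the error terms E and F (the estimators run in their native
## configuration); errors-in-variables enter only at validation time.

.dsMatrices <- function(ds) {
  stopifnot(is(ds, "PerturbationDataset"))
  list(Y = foldChanges(ds), P = designMatrix(ds))
}

.applyCutoff <- function(A, zeta) {
  # strict <: entries tied with the threshold are kept
  A[abs(A) < zeta] <- 0
  A
}

#' Least squares with cutoff (LSCO)
#'
#' Full least-squares estimate \eqn{\hat A = -P Y^\dagger} of the linear
#' steady-state model \eqn{-P = AY}, followed by a magnitude cutoff: entries
#' with \eqn{|\hat a_{ij}| < \zeta} are set to zero.  `zeta = 0` returns the
#' dense estimate.
#'
#' @param ds a [PerturbationDataset-class].
#' @param zeta nonnegative magnitude cutoff.
#' @return A [GeneNetwork-class] with method metadata.
#' @export
lscoNetwork <- function(ds, zeta = 0) {
  stopifnot(zeta >= 0)
  m <- .dsMatrices(ds)
  if (all(m$Y == 0)) stop("degenerate regression: Y is all zero",
                          call. = FALSE)
  A <- -m$P %*% MASS::ginv(m$Y)
  A <- .applyCutoff(A, zeta)
  GeneNetwork(A, genes = rownames(m$Y),
              metadata = list(method = "lsco", penalty = zeta))
}

## Per-row coordinate descent for min ||b - X a||^2 + lambda ||a||_1.
## G = X'X and c0 = X'b are precomputed; all gene rows share G = Y Y'.
## The sweep itself runs in compiled code (src/lasso.cpp).
.lassoRow <- function(G, c0, lambda, tol = 1e-8, maxit = 1e5) {
  .cdLassoRow(G, c0, lambda, tol, as.integer(maxit))
}

#' LASSO network inference
#'
#' For each gene row i, solves
#' \deqn{\min_a \|(-P_{i,\cdot})^\top - Y^\top a\|_2^2 + \lambda \|a\|_1}
#' by coordinate descent (no intercept, no standardization: fold changes are
#' already scaled around the control), assembling the rows into the
#' interaction matrix.  Convergence is declared when the largest coefficient
#' change in a sweep falls below 1e-8.
#'
#' @param ds a [PerturbationDataset-class].
#' @param lambda nonnegative L1 penalty on the summed-squares scale.
#' @return A [GeneNetwork-class].
#' @seealso [lambdaMax()] for the smallest penalty that empties the network.
#' @export
lassoNetwork <- function(ds, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  m <- .dsMatrices(ds)
  G <- m$Y %*% t(m$Y)
  A <- matrix(0, nrow(m$Y), nrow(m$Y))
  for (i in seq_len(nrow(m$Y))) {
    c0 <- as.vector(m$Y %*% (-m$P[i, ]))
    A[i, ] <- if (lambda == 0) {
      # exact least squares for the unpenalized case
      as.vector(-m$P[i, , drop = FALSE] %*% MASS::ginv(m$Y))
    } else .lassoRow(G, c0, lambda)
  }
  GeneNetwork(A, genes = rownames(m$Y),
              metadata = list(method = "lasso", penalty = lambda))
}

#' Smallest L1 penalty that yields an empty network
#'
#' For the row-wise objective \eqn{\|b - Xa\|^2 + \lambda\|a\|_1} the zero
#' solution is optimal when \eqn{\lambda \ge 2\max_j |X^\top b|_j}; this
#' returns the maximum of that bound over gene rows.
#'
#' @param ds a [PerturbationDataset-class].
#' @export
lambdaMax <- function(ds) {
  m <- .dsMatrices(ds)
  2 * max(abs(m$Y %*% t(-m$P)))
}

#' Total least squares with cutoff (TLSCO)
#'
#' Classical multivariate total-least-squares solution of
#' \eqn{Y^\top A^\top \approx (-P)^\top}, modeling error in both the
#' regressors and the responses.  The right singular subspace of the
#' augmented matrix \eqn{[Y^\top \mid (-P)^\top]} is partitioned
#' (Golub-Van Loan block formula) and \eqn{A^\top = -V_{12} V_{22}^{-1}};
#' the same magnitude cutoff as LSCO is then applied.
#'
#' @param ds a [PerturbationDataset-class]; fewer than 2N experiments
#'   triggers a warning (the smallest right singular subspace is then not
#'   determined by the data alone).
#' @param zeta nonnegative magnitude cutoff.
#' @return A [GeneNetwork-class].
#' @export
tlscoNetwork <- function(ds, zeta = 0) {
  stopifnot(zeta >= 0)
  m <- .dsMatrices(ds)
  N <- nrow(m$Y)
  if (ncol(m$Y) < 2 * N)
    warning("TLS with M < 2N experiments: solution may be poorly determined")
  Z <- cbind(t(m$Y), t(-m$P))
  # eigen of Z'Z gives all 2N right singular vectors even when M < 2N
  V <- eigen(crossprod(Z), symmetric = TRUE)$vectors
  V12 <- V[seq_len(N), N + seq_len(N), drop = FALSE]
  V22 <- V[N + seq_len(N), N + seq_len(N), drop = FALSE]
  if (abs(det(V22)) < 1e-300 || rcond(V22) < 1e-14)
    stop("total least squares failed: the V22 block is rank deficient",
         call. = FALSE)
  A <- t(-V12 %*% solve(V22))
  A <- .applyCutoff(A, zeta)
  GeneNetwork(A, genes = rownames(m$Y),
              metadata = list(method = "tlsco", penalty = zeta))
}

#' Constrained least-squares refit of a fixed topology
#'
#' Refits link weights while preserving a network's topology and link
#' signs: per gene row i, minimizes \eqn{\|P_{i,\cdot} + a_i Y\|^2} over the
#' coefficients restricted to the topology's support, subject to
#' \eqn{s_{ij} a_{ij} \ge 0} where \eqn{s_{ij}} is the topology's link sign.
#' Solved as a sign-flipped nonnegative least-squares problem
#' (Lawson-Hanson).  Entries outside the support stay exactly zero; a
#' supported coefficient whose unconstrained optimum violates its sign lands
#' exactly on the zero boundary.  This gives shuffled-topology null networks
#' the same standardized, fairly conservative weights as the network under
#' assessment.
#'
#' @param topology a [GeneNetwork-class] providing support and signs.
#' @param ds a [PerturbationDataset-class] to refit against.
#' @return A [GeneNetwork-class] with refit weights.
#' @export
clsRefit <- function(topology, ds) {
  stopifnot(is(topology, "GeneNetwork"))
  m <- .dsMatrices(ds)
  S <- interactionMatrix(topology)
  if (nrow(S) != nrow(m$Y))
    stop("topology and dataset differ in gene count", call. = FALSE)
  N <- nrow(S)
  A <- matrix(0, N, N)
  Yt <- t(m$Y)
  for (i in seq_len(N)) {
    supp <- which(abs(S[i, ]) > .ZERO_TOL)
    if (length(supp) == 0) next
    s <- sign(S[i, supp])
    X <- Yt[, supp, drop = FALSE] %*% diag(s, length(supp))
    u <- pracma::lsqnonneg(X, as.vector(-m$P[i, ]))$x
    A[i, supp] <- s * u
  }
  md <- networkMetadata(topology)
  md$refit <- "cls"
  GeneNetwork(A, genes = rownames(m$Y) %||% networkGenes(topology),
              metadata = md)
}

.inferNetwork <- function(ds, method, penalty) {
  switch(method,
         lsco = lscoNetwork(ds, penalty),
         lasso = lassoNetwork(ds, penalty),
         tlsco = tlscoNetwork(ds, penalty),
         stop("unknown method: ", method, call. = FALSE))
}

#' Penalty achieving a target native link density
#'
#' Returns the cutoff (LSCO/TLSCO) or L1 penalty (LASSO) at which the
#' method's native network carries about `links_per_gene` links per gene —
#' by default 3, the lower end of the 3-5 links/gene density commonly
#' observed in natural regulatory systems.  For the cutoff methods this is
#' a quantile of the dense estimate's magnitudes; for LASSO it is found by
#' bisection on the regularization path.
#'
#' @param ds a [PerturbationDataset-class].
#' @param method `"lsco"`, `"lasso"` or `"tlsco"`.
#' @param links_per_gene target native density.
#' @return A single penalty value.
#' @export
penaltyForDensity <- function(ds, method = c("lsco", "lasso", "tlsco"),
                              links_per_gene = 3) {
  method <- match.arg(method)
  N <- nrow(foldChanges(ds))
  target <- min(links_per_gene * N, N^2)
  if (method %in% c("lsco", "tlsco")) {
    dense <- suppressWarnings(.inferNetwork(ds, method, 0))
    return(unname(quantile(abs(interactionMatrix(dense)), 1 - target / N^2)))
  }
  lo <- 0; hi <- lambdaMax(ds)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    nl <- sparsityStats(lassoNetwork(ds, mid))$links
    if (nl > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sweep the sparsity penalty from empty to full network
#'
#' Chooses a penalty grid for the given method spanning the complete
#' sparsity range: the first returned network has 0 links and the last has
#' at least \eqn{0.9 N^2}.  LSCO/TLSCO penalties are quantiles of the dense
#' estimate's magnitudes; LASSO penalties are log-spaced below
#' [lambdaMax()] with 0 appended.
#'
#' @param ds a [PerturbationDataset-class].
#' @param method `"lsco"`, `"lasso"` or `"tlsco"`.
#' @param n_points number of grid points (>= 2).
#' @return List of `list(penalty=, network=)`, ordered by increasing link
#'   count.
#' @export
sparsitySweep <- function(ds, method = c("lsco", "lasso", "tlsco"),
                          n_points = 10) {
  method <- match.arg(method)
  stopifnot(n_points >= 2)
  if (method %in% c("lsco", "tlsco")) {
    dense <- suppressWarnings(.inferNetwork(ds, method, 0))
    v <- abs(interactionMatrix(dense))
    pen <- unname(quantile(v, seq(1, 0, length.out = n_points)))
    pen[1] <- max(v) * (1 + 1e-9) + 1e-12  # guarantee the empty endpoint
  } else {
    lmax <- lambdaMax(ds)
    pen <- c(lmax * (1 + 1e-9),
             exp(seq(log(lmax), log(lmax * 1e-4),
                     length.out = n_points - 2)),
             0)
  }
  nets <- lapply(pen, function(z) suppressWarnings(.inferNetwork(ds, method, z)))
  links <- vapply(nets, function(n) sparsityStats(n)$links, numeric(1))
  o <- order(links)
  lapply(o, function(k) list(penalty = pen[k], network = nets[[k]]))
}
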