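## Independent oracles and fixture builders shared across test files.

## Hand-derived 2-gene system: A = [[-1,0],[1,-1]], P = -I2.
## Solving -A Y = P column-wise gives Y = [[-1,0],[-1,-1]].
toyNet2 <- function() GeneNetwork(matrix(c(-1, 1, 0, -1), 2, 2),
                                  genes = c("gA", "gB"))
toyY2 <- function() matrix(c(-1, -1, 0, -1), 2, 2,
                           dimnames = list(c("gA", "gB"), c("e1", "e2")))
toyDataset2 <- function() {
  P <- diag(-1, 2)
  dimnames(P) <- dimnames(toyY2())
  PerturbationDataset(toyY2(), P)
}

## Simulated dataset with known truth at the given noise level.
simFixture <- function(n_genes = 10, links_per_gene = 3, replicates = 3,
                       snr = Inf, seed = 1) {
  net <- randomGRN(n_genes, links_per_gene, seed = seed)
  des <- makeDesign(n_genes, "single", replicates = replicates,
                    genes = networkGenes(net))
  list(net = net,
       ds = simulateDataset(net, des, snr = snr, seed = seed + 1000))
}

## Generic convex-solver oracle for the balanced-error minimax program:
## minimize max(||E||^2/||Y'||^2, ||P' + A(Y'-E)||^2/||P'||^2) over E,
## by BFGS on a softmax-smoothed objective with continuation on the
## smoothing parameter.  Entirely independent of the package's
## scalarization/bisection route.
minimaxOracle <- function(A, Yp, Pp) {
  alpha <- sum(Yp^2); beta <- sum(Pp^2)
  n <- nrow(Yp); m <- ncol(Yp)
  obj <- function(v, mu) {
    E <- matrix(v, n, m)
    f <- sum(E^2) / alpha
    g <- sum((Pp + A %*% (Yp - E))^2) / beta
    M <- max(f, g)
    M + mu * log(exp((f - M) / mu) + exp((g - M) / mu))
  }
  grad <- function(v, mu) {
    E <- matrix(v, n, m)
    f <- sum(E^2) / alpha
    R <- Pp + A %*% (Yp - E)
    g <- sum(R^2) / beta
    M <- max(f, g)
    wf <- exp((f - M) / mu); wg <- exp((g - M) / mu)
    as.vector((wf * (2 * E / alpha) + wg * (-2 * crossprod(A, R) / beta)) /
                (wf + wg))
  }
  v <- rep(0, n * m)
  for (mu in 10^seq(-2, -9, by = -1)) {
    v <- stats::optim(v, obj, grad, mu = mu, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))$par
  }
  E <- matrix(v, n, m)
  f <- sum(E^2) / alpha
  g <- sum((Pp + A %*% (Yp - E))^2) / beta
  list(E = E, t = max(f, g), Erel = sqrt(f), Frel = sqrt(g))
}

## Generic quadratic-programming oracle for the sign-constrained refit of
## one gene row: min ||c + X a||^2 subject to sign(a_j) = s_j, via the
## active-set QP solver in pracma (a different algorithm than the
## Lawson-Hanson route used by clsRefit).
qpClsRowOracle <- function(X, cvec, s) {
  k <- length(s)
  H <- 2 * crossprod(X)
  d <- as.vector(2 * crossprod(X, cvec))
  # constraints: -s_j a_j <= 0
  o <- pracma::quadprog(H, d, A = -diag(s, k), b = rep(0, k))
  o$xmin
}

## Full-network CLS oracle assembled row-by-row.
qpClsOracle <- function(topology, ds) {
  S <- interactionMatrix(topology)
  Y <- foldChanges(ds); P <- designMatrix(ds)
  A <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  for (i in seq_len(nrow(S))) {
    supp <- which(S[i, ] != 0)
    if (!length(supp)) next
    A[i, supp] <- qpClsRowOracle(t(Y)[, supp, drop = FALSE], P[i, ],
                                 sign(S[i, supp]))
  }
  A
}
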