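#' Generate a stable random sparse gene regulatory network
#'
#' Builds an interaction matrix with self-degradation (-1 on the diagonal)
#' and `round(n_genes * (links_per_gene - 1))` off-diagonal links placed
#' uniformly at random without duplication.  Off-diagonal magnitudes are
#' uniform in \[0.5, 1.5\], activating (+) with probability
#' `activating_fraction`.  The off-diagonal part is then shrunk by a common
#' factor (0.9 per iteration) until every eigenvalue has negative real part,
#' so the simulated steady state exists and is stable.  Natural regulatory
#' systems typically carry 3-5 links per gene, hence the default density.
#'
#' @param n_genes number of genes (>= 2).
#' @param links_per_gene target total links (self-links included) per gene,
#'   between 1 and `n_genes`.
#' @param activating_fraction probability that an off-diagonal link is
#'   activating (positive).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return A [GeneNetwork-class] whose metadata records the generator
#'   settings and the shrinkage factor applied.
#' @examples
#' net <- randomGRN(15, links_per_gene = 3, seed = 1)
#' sparsityStats(net)
#' @export
randomGRN <- function(n_genes, links_per_gene = 3, activating_fraction = 0.5,
                      seed = NULL) {
  stopifnot(n_genes >= 2)
  n_off <- round(n_genes * (links_per_gene - 1))
  if (links_per_gene < 1 || n_off > n_genes * (n_genes - 1))
    stop("infeasible link count: need 1 <= links_per_gene <= n_genes",
         call. = FALSE)
  withSeed(seed, {
    A <- diag(-1, n_genes)
    off <- which(row(A) != col(A))
    sel <- sample(off, n_off)
    mag <- runif(n_off, 0.5, 1.5)
    sgn <- ifelse(runif(n_off) < activating_fraction, 1, -1)
    A[sel] <- mag * sgn
    shrink <- 1
    while (max(Re(eigen(A, only.values = TRUE)$values)) >= 0) {
      shrink <- shrink * 0.9
      A[off] <- A[off] * 0.9
    }
    GeneNetwork(A, genes = sprintf("g%02d", seq_len(n_genes)),
                metadata = list(generator = "randomGRN",
                                links_per_gene = links_per_gene,
                                activating_fraction = activating_fraction,
                                shrink = shrink, seed = seed))
  })
}

#' Build a knockdown design matrix
#'
#' Single mode places one `-strength` entry per column, `replicates` columns
#' per gene (mirroring three experimental replicates per targeted
#' perturbation).  Pairs mode places two `-strength` entries per column, one
#' column per pair in single replicates (the independent double-knockdown
#' validation design).  The knockdown efficiency of an siRNA is unknown, so
#' unit strength is the convention; it does not affect inferred topology.
#'
#' @param n_genes number of genes.
#' @param mode `"single"` or `"pairs"`.
#' @param replicates columns per target in single mode.
#' @param pairs list of 2-vectors of gene indices or names; when absent in
#'   pairs mode, a random perfect matching over all genes is drawn.
#' @param strength magnitude of the intended perturbation (> 0).
#' @param genes optional gene identifiers.
#' @param seed seed for the random matching.
#' @return list with elements `P` (genes x experiments design matrix) and
#'   `targets` (list of targeted genes per experiment).
#' @export
makeDesign <- function(n_genes, mode = c("single", "pairs"), replicates = 3,
                       pairs = NULL, strength = 1, genes = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1, strength > 0)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n_genes))
  resolve <- function(g) {
    i <- if (is.character(g)) match(g, genes) else as.integer(g)
    if (any(is.na(i) | i < 1 | i > n_genes))
      stop("pair references unknown gene: ", paste(g, collapse = ","),
           call. = FALSE)
    i
  }
  if (mode == "single") {
    M <- n_genes * replicates
    P <- matrix(0, n_genes, M)
    tg <- vector("list", M)
    k <- 0
    for (i in seq_len(n_genes)) for (r in seq_len(replicates)) {
      k <- k + 1
      P[i, k] <- -strength
      tg[[k]] <- genes[i]
    }
    samples <- paste0(rep(genes, each = replicates), "_r",
                      rep(seq_len(replicates), n_genes))
  } else {
    if (is.null(pairs)) {
      if (n_genes %% 2 != 0)
        stop("random matching needs an even number of genes", call. = FALSE)
      perm <- withSeed(seed, sample(n_genes))
      pairs <- split(perm, rep(seq_len(n_genes / 2), each = 2))
    }
    P <- matrix(0, n_genes, length(pairs))
    tg <- vector("list", length(pairs))
    for (k in seq_along(pairs)) {
      ij <- resolve(pairs[[k]])
      if (length(ij) != 2) stop("each pair must name two genes", call. = FALSE)
      P[ij, k] <- -strength
      tg[[k]] <- genes[ij]
    }
    samples <- vapply(tg, paste, character(1), collapse = "+")
  }
  dimnames(P) <- list(genes, samples)
  list(P = P, targets = tg)
}

#' Simulate a knockdown perturbation dataset
#'
#' Draws i.i.d. zero-mean Gaussian process error F and measurement error E.
#' The per-element noise standard deviation is keyed to the weakest signal
#' direction, the convention of perturbation-design benchmarking: for each
#' error matrix,
#' \deqn{\sigma = \frac{\sigma_{\min}(S)}{snr \sqrt{\chi^2_{0.99}(NM)}},}
#' where S is the matrix the error corrupts (the design `P` for F, the
#' noiseless response \eqn{-A^\dagger P} for E) and
#' \eqn{\chi^2_{0.99}(NM)} the 0.99 quantile of the chi-square with one
#' degree of freedom per matrix element.  At `snr` above 1 every singular
#' direction of the signal stays above the expected noise level, so the
#' whole network remains identifiable; white noise scaled to a global
#' Frobenius ratio would instead drown all but the dominant directions of
#' an ill-conditioned network.  The response is
#' \eqn{Y = -A^\dagger(P - F) + E}; `snr = Inf` yields the exact noiseless
#' response.
#'
#' @param net generating [GeneNetwork-class].
#' @param design a list as returned by [makeDesign()], or a bare P matrix.
#' @param snr signal-to-noise ratio (> 0, possibly `Inf`).
#' @param seed integer seed.
#' @return A [PerturbationDataset-class] with `sigmaE`/`sigmaF` recorded in
#'   its metadata.
#' @export
simulateDataset <- function(net, design, snr = 10, seed = NULL) {
  stopifnot(is(net, "GeneNetwork"), snr > 0)
  if (is.list(design)) {
    P <- design$P; targets <- design$targets
  } else {
    P <- design; targets <- NULL
  }
  A <- interactionMatrix(net)
  if (nrow(P) != nrow(A)) stop("design does not match network size",
                               call. = FALSE)
  rownames(P) <- networkGenes(net)
  n <- nrow(P); m <- ncol(P)
  Y0 <- -pseudoInverse(A) %*% P
  withSeed(seed, {
    if (is.infinite(snr)) {
      sigmaF <- sigmaE <- 0
      F_err <- E_err <- matrix(0, n, m)
    } else {
      k <- sqrt(stats::qchisq(0.99, n * m))
      sigmaF <- min(svd(P)$d) / (snr * k)
      sigmaE <- min(svd(Y0)$d) / (snr * k)
      F_err <- matrix(rnorm(n * m, sd = sigmaF), n, m)
      E_err <- matrix(rnorm(n * m, sd = sigmaE), n, m)
    }
    Y <- -pseudoInverse(A) %*% (P - F_err) + E_err
    dimnames(Y) <- dimnames(P)
    PerturbationDataset(Y, P, targets = targets,
                        sigmaE = sigmaE, sigmaF = sigmaF)
  })
}

#' Shuffle a dataset to destroy gene-perturbation correspondence
#'
#' Independently permutes each gene row of Y across its experiment columns,
#' leaving the design P and replicate grouping untouched.  Each gene's
#' marginal fold-change distribution (row multiset, mean, variance) is
#' preserved exactly, while the link between perturbations and responses is
#' destroyed.  This is the data null used both for FDR estimation in the
#' nested bootstrap and for the shuffled-data wRSS null.
#'
#' @param ds a [PerturbationDataset-class].
#' @param seed integer seed.
#' @return A new [PerturbationDataset-class] with permuted rows of Y.
#' @export
shuffleDataset <- function(ds, seed = NULL) {
  stopifnot(is(ds, "PerturbationDataset"))
  Y <- foldChanges(ds)
  withSeed(seed, {
    for (i in seq_len(nrow(Y))) Y[i, ] <- Y[i, sample(ncol(Y))]
    PerturbationDataset(Y, designMatrix(ds), targets = targetList(ds),
                        sigmaE = S4Vectors::metadata(ds)$sigmaE,
                        sigmaF = S4Vectors::metadata(ds)$sigmaF)
  })
}
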