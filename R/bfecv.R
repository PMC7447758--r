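## Balanced Fitting of Errors under Cross-Validation (BFECV): assesses how
## well a network topology predicts knockdown data without a gold standard.
## The measurement error E (in Y) and process error F (in P) are balanced
## so that error is not silently pushed from one source to the other.

#' Balance measurement and process errors for a fixed network
#'
#' Solves the minimax program
#' \deqn{\min_E \max\left(\frac{\|E\|_F^2}{\|Y'\|_F^2},
#'       \frac{\|F\|_F^2}{\|P'\|_F^2}\right), \quad
#'       F = P' + A(Y' - E),}
#' i.e. minimize t subject to \eqn{\|E\|_F^2 \le t \|Y'\|_F^2} and
#' \eqn{\|F\|_F^2 \le t \|P'\|_F^2} under the steady-state model constraint
#' \eqn{-(P' - F) = A(Y' - E)}.  Relative (not absolute) errors are
#' compared because error scales with the degrees of freedom of each
#' matrix.  At an optimum where both error terms are nonzero, both
#' constraints are active, so the two relative errors are equal.
#'
#' The scalarized problem \eqn{\min_E \theta f + (1-\theta) g} has a closed
#' form (a ridge-type linear solve); \eqn{f - g} is monotone decreasing in
#' \eqn{\theta}, so the equalizing weight is found by bisection.
#'
#' @param net a [GeneNetwork-class] (kept square: all genes retained).
#' @param Yp,Pp the fold-change and design matrices with the left-out
#'   gene's experiments removed.
#' @param tol bisection tolerance on \eqn{f - g}.
#' @return List with `Ehat`, `Fhat`, `Erel`, `Frel` and the objective `t`.
#' @export
balanceErrors <- function(net, Yp, Pp, tol = 1e-14) {
  stopifnot(is(net, "GeneNetwork"))
  A <- interactionMatrix(net)
  .assertFiniteMatrix(Yp, "Yp"); .assertFiniteMatrix(Pp, "Pp")
  if (!identical(dim(Yp), dim(Pp)) || nrow(Yp) != nrow(A))
    stop("shapes of A, Y' and P' do not conform", call. = FALSE)
  alpha <- sum(Yp^2); beta <- sum(Pp^2)
  if (alpha == 0 || beta == 0)
    stop("relative error undefined: Y' or P' is all zero", call. = FALSE)
  R0 <- Pp + A %*% Yp                    # residual at E = 0
  if (sum(R0^2) / beta < 1e-24) {        # exact model: zero errors feasible
    Z <- matrix(0, nrow(Yp), ncol(Yp), dimnames = dimnames(Yp))
    return(list(Ehat = Z, Fhat = Z, Erel = 0, Frel = 0, t = 0))
  }
  # work in the eigenbasis of A'A: the scalarized solve becomes diagonal and
  # is well defined even for rank-deficient A (A'R0 has no component along
  # the null space of A')
  eg <- eigen(crossprod(A), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  B <- crossprod(eg$vectors, crossprod(A, R0))   # Q'A'R0, N x M'
  b <- rowSums(B^2)
  r0 <- sum(R0^2)
  fg <- function(theta) {
    w <- (1 - theta) / beta
    cc <- w / (theta / alpha + w * lam)
    # null-space directions of A' carry nothing (their b is round-off)
    cc[lam < max(lam[1], .Machine$double.xmin) * 1e-12 | b == 0] <- 0
    list(cc = cc,
         f = sum(cc^2 * b) / alpha,
         g = (r0 - 2 * sum(cc * b) + sum(lam * cc^2 * b)) / beta)
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  e_lo <- fg(lo)
  if (e_lo$f - e_lo$g <= 0) {
    # f never exceeds g: the process-error term dominates everywhere and the
    # optimum is the minimizer of g alone
    sol <- e_lo
  } else {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      e <- fg(mid)
      if (e$f - e$g > 0) lo <- mid else hi <- mid
      if (abs(e$f - e$g) < tol * max(e$f, e$g, 1e-300) || (hi - lo) < 1e-16)
        break
    }
    sol <- fg((lo + hi) / 2)
  }
  E <- eg$vectors %*% (sol$cc * B)
  F_ <- R0 - A %*% E                     # F = P' + A(Y' - E)
  dimnames(E) <- dimnames(F_) <- dimnames(Yp)
  list(Ehat = E, Fhat = F_,
       Erel = sqrt(max(sol$f, 0)), Frel = sqrt(max(sol$g, 0)),
       t = max(sol$f, sol$g))
}

#' Predict a left-out gene's experiments
#'
#' For each experiment column targeting gene g, predicts the response from
#' the intended perturbation, \eqn{\hat y = -A^\dagger p}, and the
#' perturbation from the observed response, \eqn{\hat p = -A y}; the
#' comparison targets are the intended perturbation and the observed
#' response.
#'
#' @param net a [GeneNetwork-class].
#' @param ds a [PerturbationDataset-class].
#' @param g gene index or name whose experiments are predicted.
#' @return List with matrices `Ypred` and `Ppred` over g's experiment
#'   columns (named `cols`).
#' @export
predictLeftout <- function(net, ds, g) {
  A <- interactionMatrix(net)
  genes <- networkGenes(net)
  if (is.character(g)) g <- match(g, genes)
  cols <- .experimentsOf(ds, genes[g])
  if (length(cols) == 0) stop("gene has no experiments", call. = FALSE)
  P <- designMatrix(ds)[, cols, drop = FALSE]
  Y <- foldChanges(ds)[, cols, drop = FALSE]
  list(Ypred = -pseudoInverse(A) %*% P, Ppred = -A %*% Y, cols = cols)
}

.experimentsOf <- function(ds, gene) {
  which(vapply(targetList(ds), function(t) gene %in% t, logical(1)))
}

#' Leave-one-gene-out balanced-error goodness of fit
#'
#' For each targeted gene g: all of g's experiment columns are removed, the
#' errors of the remaining data are balanced with [balanceErrors()] (the
#' network stays square), and g's experiments are predicted with
#' [predictLeftout()].  The individual gene predictions are assembled into
#' full predicted matrices and scored by the weighted residual sum of
#' squares
#' \deqn{wRSS = \sum_g w_E \|\hat y - y\|^2 + w_F \|\hat p - p\|^2,}
#' with weights the reciprocal mean per-element squared balanced errors
#' (floored at 1e-8 to guard the noiseless case), and by
#' \eqn{R^2 = 1 - \sum(\hat y - y)^2 / \sum(y - \bar y)^2} over response
#' entries.  \eqn{R^2} always uses the SVD-truncated network (so that
#' predictions stay bounded like the observations); wRSS uses it only when
#' `truncate = TRUE`.
#'
#' When several networks are compared on the same data (as in
#' [nullDistribution()]), the comparison is only fair if all of them are
#' scored with the same weights; pass the assessed network's weights via
#' `weights` for the competitors.
#'
#' @param net a [GeneNetwork-class].
#' @param ds a [PerturbationDataset-class]; every gene with experiments is
#'   left out in turn.
#' @param truncate apply [svdTruncate()] before the wRSS fit (default TRUE
#'   so that assessed and null networks are treated identically).
#' @param weights optional list with elements `wE` and `wF` overriding the
#'   internally derived wRSS weights (see [fitWeights()]).
#' @return A [FitResult-class].
#' @export
bfecv <- function(net, ds, truncate = TRUE, weights = NULL) {
  stopifnot(is(net, "GeneNetwork"), is(ds, "PerturbationDataset"))
  genes <- networkGenes(net)
  trunc_net <- svdTruncate(net, ds)
  fit_net <- if (truncate) trunc_net else net
  A <- interactionMatrix(fit_net)
  Y <- foldChanges(ds); P <- designMatrix(ds)
  folds <- Filter(function(g) length(.experimentsOf(ds, g)) > 0, genes)
  if (length(folds) < length(genes)) {
    skipped <- setdiff(genes, folds)
    warning("genes without experiments skipped: ",
            paste(skipped, collapse = ", "))
  }
  Ehat <- Fhat <- list()
  Erel <- Frel <- numeric(0)
  Ypred <- Y * NA; Ppred <- P * NA
  for (g in folds) {
    cols <- .experimentsOf(ds, g)
    bal <- balanceErrors(fit_net, Y[, -cols, drop = FALSE],
                         P[, -cols, drop = FALSE])
    Ehat[[g]] <- bal$Ehat; Fhat[[g]] <- bal$Fhat
    Erel <- c(Erel, bal$Erel); Frel <- c(Frel, bal$Frel)
    pr <- predictLeftout(fit_net, ds, g)
    Ypred[, cols] <- pr$Ypred
    Ppred[, cols] <- pr$Ppred
  }
  eps <- 1e-8
  if (is.null(weights)) {
    sig2E <- mean(vapply(Ehat, function(e) mean(e^2), numeric(1)))
    sig2F <- mean(vapply(Fhat, function(f) mean(f^2), numeric(1)))
    wE <- 1 / max(sig2E, eps); wF <- 1 / max(sig2F, eps)
  } else {
    wE <- weights$wE; wF <- weights$wF
  }
  pcols <- sort(unique(unlist(lapply(folds, .experimentsOf, ds = ds))))
  dy <- Ypred[, pcols] - Y[, pcols]
  dp <- Ppred[, pcols] - P[, pcols]
  wrss <- wE * sum(dy^2) + wF * sum(dp^2)
  # R2 always from the truncated network
  Yp2 <- Ypred
  if (!truncate) {
    Ai <- pseudoInverse(interactionMatrix(trunc_net))
    for (g in folds) {
      cols <- .experimentsOf(ds, g)
      Yp2[, cols] <- -Ai %*% P[, cols, drop = FALSE]
    }
  }
  yobs <- Y[, pcols]
  R2 <- 1 - sum((Yp2[, pcols] - yobs)^2) / sum((yobs - mean(yobs))^2)
  tm <- networkMetadata(trunc_net)
  new("FitResult", Ehat = Ehat, Fhat = Fhat, Erel = Erel, Frel = Frel,
      Ypred = Ypred, Ppred = Ppred, wRSS = wrss, R2 = min(R2, 1),
      truncated = isTRUE(truncate), rank = as.integer(tm$svd_rank))
}

#' wRSS weights of a fitted network
#'
#' The reciprocal mean per-element squared balanced errors, averaged over
#' folds and floored at 1e-8: `wE = 1/max(mean(E^2), 1e-8)` and likewise
#' `wF`.  Extract them from the assessed network's [FitResult-class] to
#' score its null competitors on the same scale.
#'
#' @param fit a [FitResult-class].
#' @return List with `wE` and `wF`.
#' @export
fitWeights <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  eps <- 1e-8
  list(wE = 1 / max(mean(vapply(fit@Ehat, function(e) mean(e^2),
                                numeric(1))), eps),
       wF = 1 / max(mean(vapply(fit@Fhat, function(f) mean(f^2),
                                numeric(1))), eps))
}

#' Truncate a network's small singular values
#'
#' Ill-conditioned interaction matrices inflate \eqn{-A^\dagger P} far
#' beyond the observed expression range; the small singular values largely
#' represent noise.  Candidate cutoffs iterate over the ascending singular
#' values of A; the largest retained set is chosen such that every entry of
#' the reconstructed prediction \eqn{-A^\dagger_k P} lies within
#' \eqn{[\min Y - \delta, \max Y + \delta]} with
#' \eqn{\delta = 0.1\,\mathrm{range}(Y)}.  The cutoff is set independently
#' for each network.  If no truncation satisfies the bound, rank 1 is
#' retained and flagged.
#'
#' @param net a [GeneNetwork-class].
#' @param ds a [PerturbationDataset-class] providing P and the Y range.
#' @param delta slack on the admissible prediction range, as a fraction of
#'   the observed expression range.
#' @return A [GeneNetwork-class] with metadata fields `svd_rank` and
#'   `svd_bound_met`.
#' @export
svdTruncate <- function(net, ds, delta = 0.1) {
  A <- interactionMatrix(net)
  Y <- foldChanges(ds); P <- designMatrix(ds)
  delta <- delta * (max(Y) - min(Y))
  lobnd <- min(Y) - delta; hibnd <- max(Y) + delta
  sv <- svd(A)
  N <- nrow(A)
  inRange <- function(k) {
    d <- sv$d[seq_len(k)]
    pos <- d > max(sv$d[1], 1) * 1e-14
    if (!any(pos)) return(list(ok = FALSE))
    U <- sv$u[, seq_len(k), drop = FALSE][, pos, drop = FALSE]
    V <- sv$v[, seq_len(k), drop = FALSE][, pos, drop = FALSE]
    pred <- -V %*% ((1 / d[pos]) * t(U)) %*% P
    list(ok = all(pred >= lobnd & pred <= hibnd),
         Ak = U %*% (d[pos] * t(V)))
  }
  for (k in rev(seq_len(N))) {
    r <- inRange(k)
    if (isTRUE(r$ok)) {
      md <- networkMetadata(net)
      md$svd_rank <- k; md$svd_bound_met <- TRUE
      Ak <- r$Ak
      dimnames(Ak) <- dimnames(A)
      return(GeneNetwork(Ak, metadata = md))
    }
  }
  r <- inRange(1)
  md <- networkMetadata(net)
  md$svd_rank <- 1L; md$svd_bound_met <- FALSE
  Ak <- r$Ak %||% A
  dimnames(Ak) <- dimnames(A)
  GeneNetwork(Ak, metadata = md)
}
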