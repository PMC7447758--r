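#' Degree-preserving topology shuffle
#'
#' Monte Carlo null for a network's topology: self-links (the diagonal)
#' stay in place; in each row the same number of off-diagonal incoming
#' links is redrawn, with source genes sampled without replacement with
#' probability proportional to their original out-degree + 1, so hubs stay
#' hubs.  Each moved link carries its original sign and weight.  Per-row
#' in-degree, the total link count, the sign counts and the multiset of
#' link weights are all preserved exactly.
#'
#' @param net a [GeneNetwork-class].
#' @param seed integer seed.
#' @param hub_preserving sample sources proportional to out-degree + 1
#'   (default); `FALSE` samples sources uniformly.
#' @return A shuffled [GeneNetwork-class].
#' @export
shuffleTopology <- function(net, seed = NULL, hub_preserving = TRUE) {
  A <- interactionMatrix(net)
  N <- nrow(A)
  offdeg <- colSums(abs(A) > .ZERO_TOL) - (abs(diag(A)) > .ZERO_TOL)
  w <- if (hub_preserving) offdeg + 1 else rep(1, N)
  withSeed(seed, {
    B <- diag(diag(A), N)
    for (i in seq_len(N)) {
      src <- setdiff(which(abs(A[i, ]) > .ZERO_TOL), i)
      k <- length(src)
      if (k == 0) next
      cand <- setdiff(seq_len(N), i)
      newsrc <- cand[sample.int(length(cand), k, prob = w[cand])]
      B[i, newsrc] <- A[i, src]
    }
    dimnames(B) <- dimnames(A)
    md <- networkMetadata(net)
    md$shuffled_topology <- TRUE
    GeneNetwork(B, metadata = md)
  })
}

#' Null distribution of the balanced-error goodness of fit
#'
#' Builds a wRSS null for an inferred network by repeatedly either (a)
#' shuffling its topology (degree-preserving) and refitting weights to the
#' original data by constrained least squares before scoring with
#' [bfecv()], or (b) shuffling the data row-wise and refitting the inferred
#' topology to the shuffled data before scoring it on that data.  For a
#' fair comparison the observed wRSS is computed identically — the assessed
#' network is itself CLS-refit before scoring — and every null replicate is
#' scored with the assessed network's wRSS weights ([fitWeights()]), so
#' that a poorly fitting topology cannot shrink its own penalty by
#' inflating its error-variance estimates.
#'
#' @param net the inferred [GeneNetwork-class] (topology and signs used).
#' @param ds a [PerturbationDataset-class].
#' @param kind `"shuffled_topology"` or `"shuffled_data"`.
#' @param n number of null replicates (>= 10; 100 is typical).
#' @param seed integer seed.
#' @param truncate passed to [bfecv()].
#' @return A [NullDistribution-class]; replicate-level failures are
#'   excluded and counted in `nFailed`.
#' @export
nullDistribution <- function(net, ds, kind = c("shuffled_topology",
                                               "shuffled_data"),
                             n = 100, seed = NULL, truncate = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n >= 10)
  seeds <- deriveSeeds(seed %||% sample.int(1e9, 1), n)
  refit <- clsRefit(net, ds)
  obsfit <- bfecv(refit, ds, truncate = truncate)
  observed <- wRSS(obsfit)
  w <- fitWeights(obsfit)
  samples <- numeric(0); failed <- 0L
  for (r in seq_len(n)) {
    s <- tryCatch({
      if (kind == "shuffled_topology") {
        nullnet <- shuffleTopology(net, seed = seeds[r])
        wRSS(bfecv(clsRefit(nullnet, ds), ds, truncate = truncate,
                   weights = w))
      } else {
        dshuf <- shuffleDataset(ds, seed = seeds[r])
        wRSS(bfecv(clsRefit(net, dshuf), dshuf, truncate = truncate,
                   weights = w))
      }
    }, error = function(e) NA_real_)
    if (is.na(s)) failed <- failed + 1L else samples <- c(samples, s)
  }
  if (failed > 0)
    warning(failed, " null replicate(s) failed and were excluded")
  cmp <- compareToNull(observed, samples)
  new("NullDistribution", kind = kind, samples = samples,
      observed = observed, ratioToMedian = cmp$ratio_to_median,
      empiricalP = cmp$empirical_p, nFailed = failed)
}

#' Compare an observed wRSS to a null sample
#'
#' @param observed observed wRSS.
#' @param null a [NullDistribution-class] or a numeric vector of null wRSS
#'   samples.
#' @return List with `ratio_to_median` (`Inf` when the null median is 0 and
#'   the observed value is positive) and the add-one empirical p-value
#'   \eqn{(1 + \#\{samples \le observed\})/(n + 1)}.
#' @export
compareToNull <- function(observed, null) {
  samples <- if (is(null, "NullDistribution")) nullSamples(null) else null
  stopifnot(length(samples) > 0)
  med <- median(samples)
  ratio <- if (med == 0) {
    if (observed == 0) 0 else Inf
  } else observed / med
  p <- (1 + sum(samples <= observed)) / (length(samples) + 1)
  list(ratio_to_median = ratio, empirical_p = p)
}
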