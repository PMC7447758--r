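## Nested bootstrapping: an inner bootstrap of experiments yields per-link
## support; outer (nested) repetitions measure reproducibility; supports
## from shuffled data provide the null against which FDR is estimated.

#' Bootstrap an inference method over experiment resamples
#'
#' Draws `n_boot` resamples of experiment columns with replacement,
#' stratified by perturbation target so that every target retains at least
#' one experiment in every resample (Y and P columns are resampled
#' jointly), and infers a network from each.
#'
#' @param ds a [PerturbationDataset-class].
#' @param method `"lsco"`, `"lasso"` or `"tlsco"`.
#' @param penalty the method's sparsity penalty.
#' @param n_boot number of bootstrap networks (>= 2).
#' @param seed integer seed.
#' @return List of [GeneNetwork-class] objects.
#' @export
bootstrapNetworks <- function(ds, method, penalty, n_boot = 25, seed = NULL) {
  stopifnot(n_boot >= 2)
  groups <- perturbationGroups(ds)
  Y <- foldChanges(ds); P <- designMatrix(ds)
  tg <- targetList(ds)
  withSeed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
      sub <- PerturbationDataset(Y[, idx, drop = FALSE],
                                 P[, idx, drop = FALSE],
                                 targets = tg[idx])
      suppressWarnings(.inferNetwork(sub, method, penalty))
    })
  })
}

#' Per-link bootstrap support from an ensemble of networks
#'
#' For each entry, the majority sign among nonzero occurrences is found
#' (ties broken toward +), and the support is the fraction of networks that
#' contain the link with that sign.  Sign is 0 exactly where support is 0.
#'
#' @param nets list of [GeneNetwork-class] with identical gene order.
#' @param source provenance label (`"measured"` or `"shuffled"`).
#' @param run_id nested-run index for bookkeeping.
#' @return A [SupportMatrix-class].
#' @export
linkSupport <- function(nets, source = "measured", run_id = NA_integer_) {
  stopifnot(length(nets) >= 2)
  g <- networkGenes(nets[[1]])
  for (n in nets) stopifnot(identical(networkGenes(n), g))
  N <- length(g)
  pos <- neg <- matrix(0, N, N)
  for (n in nets) {
    A <- interactionMatrix(n)
    pos <- pos + (A > .ZERO_TOL)
    neg <- neg + (A < -.ZERO_TOL)
  }
  maj <- ifelse(pos >= neg, 1, -1)          # tie -> +
  cnt <- ifelse(maj > 0, pos, neg)
  support <- cnt / length(nets)
  sgn <- ifelse(support == 0, 0L, maj)
  dimnames(support) <- dimnames(sgn) <- list(g, g)
  new("SupportMatrix", support = support, sign = matrix(as.integer(sgn), N, N,
                                                        dimnames = list(g, g)),
      source = source, run_id = as.integer(run_id),
      n_boot = length(nets))
}

#' Nested bootstrap support
#'
#' Runs `n_nested` independent inner bootstraps (each with its own derived
#' seed) and aggregates them: the consensus sign of each link is the sign
#' with the larger total support across runs (ties toward +), and the
#' aggregate support is the mean over runs of each run's support where its
#' sign matches the consensus (0 where it does not).  With
#' `shuffle = TRUE` each nested run first draws a fresh row-shuffled copy of
#' the data, producing the null support distribution.
#'
#' @param ds a [PerturbationDataset-class].
#' @param method,penalty inference method and penalty.
#' @param n_nested number of nested runs (>= 2).
#' @param n_boot inner bootstrap count.
#' @param shuffle run on freshly shuffled data per nested run.
#' @param seed integer seed.
#' @return List with `runs` (list of [SupportMatrix-class]) and `aggregate`
#'   (a [SupportMatrix-class] with source `"aggregate"`).
#' @export
nestedSupport <- function(ds, method, penalty, n_nested = 8, n_boot = 25,
                          shuffle = FALSE, seed = NULL) {
  stopifnot(n_nested >= 2)
  seeds <- deriveSeeds(seed %||% sample.int(1e9, 1), 2 * n_nested)
  src <- if (shuffle) "shuffled" else "measured"
  runs <- lapply(seq_len(n_nested), function(r) {
    d <- if (shuffle) shuffleDataset(ds, seed = seeds[n_nested + r]) else ds
    nets <- bootstrapNetworks(d, method, penalty, n_boot = n_boot,
                              seed = seeds[r])
    linkSupport(nets, source = src, run_id = r)
  })
  list(runs = runs, aggregate = .aggregateSupport(runs))
}

.aggregateSupport <- function(runs) {
  N <- nrow(runs[[1]]@support)
  posSum <- negSum <- matrix(0, N, N)
  for (r in runs) {
    posSum <- posSum + r@support * (r@sign > 0)
    negSum <- negSum + r@support * (r@sign < 0)
  }
  cons <- ifelse(posSum >= negSum, 1, -1)
  agg <- ifelse(cons > 0, posSum, negSum) / length(runs)
  sgn <- ifelse(agg == 0, 0L, cons)
  dimnames(agg) <- dimnames(sgn) <- dimnames(runs[[1]]@support)
  new("SupportMatrix", support = agg,
      sign = matrix(as.integer(sgn), N, N, dimnames = dimnames(agg)),
      source = "aggregate", run_id = NA_integer_,
      n_boot = runs[[1]]@n_boot)
}

#' Estimate the FDR curve from measured vs shuffled support
#'
#' For each support cutoff s, the estimated FDR is the number of links
#' whose *aggregate* shuffled support reaches s, divided by the number of
#' links whose aggregate measured support reaches s, clipped to \[0, 1\]
#' (1 by convention when no measured link reaches s).  Both sides are
#' aggregated across nested runs in the same sign-consistent way, which is
#' what gives the null its teeth: within a single shuffled run a spurious
#' link can ride one fixed shuffle to full bootstrap support, but because
#' every nested run draws a fresh shuffle, such links do not reproduce
#' across runs and their aggregate support collapses — while genuine links
#' keep full aggregate support on the measured side.  The selected cutoff
#' is the smallest grid value whose FDR is at or below `alpha` — e.g. the
#' 97.5% support cutoff at a nominal 5% FDR.
#'
#' @param measured aggregate measured [SupportMatrix-class].
#' @param shuffled_runs list of shuffled-data [SupportMatrix-class] runs
#'   (aggregated internally), or an already aggregated [SupportMatrix-class].
#' @param grid ascending cutoffs in \[0, 1\]; default 0 to 1 in steps of
#'   0.025 (matching the granularity of reported support cutoffs).
#' @param alpha nominal FDR level.
#' @return An [FDRCurve-class].
#' @export
fdrCurve <- function(measured, shuffled_runs, grid = seq(0, 1, by = 0.025),
                     alpha = 0.05) {
  stopifnot(is(measured, "SupportMatrix"), !is.unsorted(grid),
            all(grid >= 0 & grid <= 1))
  ms <- measured@support
  ss <- if (is(shuffled_runs, "SupportMatrix")) shuffled_runs@support
        else .aggregateSupport(shuffled_runs)@support
  fdr <- vapply(grid, function(s) {
    nm <- sum(ms >= s & (ms > 0 | s == 0))
    if (nm == 0) return(1)
    ns <- sum(ss >= s & (ss > 0 | s == 0))
    min(1, max(0, ns / nm))
  }, numeric(1))
  ok <- which(fdr <= alpha)
  cutoff <- if (length(ok)) grid[ok[1]] else NA_real_
  new("FDRCurve", grid = as.numeric(grid), fdr = fdr, alpha = alpha,
      cutoff = cutoff)
}

#' Select the FDR-controlled network
#'
#' Keeps links whose aggregate measured support reaches the FDR curve's
#' selected cutoff, carrying their consensus sign, and assigns weights by
#' constrained least squares ([clsRefit()]) on the full dataset.
#'
#' @param ds a [PerturbationDataset-class].
#' @param aggregate aggregate measured [SupportMatrix-class].
#' @param fdr an [FDRCurve-class] whose cutoff exists.
#' @param method,penalty recorded in the result's metadata.
#' @return A [GeneNetwork-class], or `NULL` (with a message) when no
#'   cutoff reaches the nominal FDR.
#' @export
selectNetwork <- function(ds, aggregate, fdr, method = NA, penalty = NA) {
  stopifnot(is(aggregate, "SupportMatrix"), is(fdr, "FDRCurve"))
  if (is.na(fdr@cutoff)) {
    message("no support cutoff reaches FDR <= ", fdr@alpha,
            ": no network passes")
    return(NULL)
  }
  keep <- aggregate@support >= fdr@cutoff & aggregate@support > 0
  S <- ifelse(keep, as.numeric(aggregate@sign), 0)
  dimnames(S) <- dimnames(aggregate@support)
  topo <- GeneNetwork(S, metadata = list(
    method = method, penalty = penalty, support_cutoff = fdr@cutoff,
    alpha = fdr@alpha,
    label = sprintf("%s_support%s", method, format(100 * fdr@cutoff))))
  net <- clsRefit(topo, ds)
  # a refit weight can land on the zero boundary; keep the support metadata
  md <- networkMetadata(net)
  md$aggregate_support <- aggregate@support
  GeneNetwork(interactionMatrix(net), metadata = md)
}

#' Jaccard overlap of nested runs across support cutoffs
#'
#' For each cutoff s, the mean pairwise Jaccard index of the link sets
#' \{(i,j): support >= s\} across nested runs; `NA` where all sets are
#' empty.  High overlap at high support signals reproducible links.
#'
#' @param runs list of [SupportMatrix-class] (>= 2).
#' @param grid ascending cutoffs.
#' @return Named numeric vector of mean Jaccard values per cutoff.
#' @export
overlapCurve <- function(runs, grid = seq(0, 1, by = 0.025)) {
  stopifnot(length(runs) >= 2)
  sets <- function(s) lapply(runs, function(r) which(r@support >= s &
                                                     (r@support > 0 | s == 0)))
  vapply(grid, function(s) {
    ls <- sets(s)
    pairs <- utils::combn(length(ls), 2)
    jac <- apply(pairs, 2, function(pr) {
      a <- ls[[pr[1]]]; b <- ls[[pr[2]]]
      u <- length(union(a, b))
      if (u == 0) NA_real_ else length(intersect(a, b)) / u
    })
    if (all(is.na(jac))) NA_real_ else mean(jac, na.rm = TRUE)
  }, numeric(1)) |> setNames(format(grid))
}

#' One-call nested bootstrap with FDR control
#'
#' Convenience driver: measured nested support, shuffled-data nested
#' support (one fresh shuffle per nested run), the FDR curve, and the
#' selected FDR-controlled network.
#'
#' @inheritParams nestedSupport
#' @inheritParams fdrCurve
#' @return List with `measured`, `shuffled`, `fdr` and `network` (possibly
#'   `NULL`).
#' @export
nestBoot <- function(ds, method, penalty, n_nested = 8, n_boot = 25,
                     alpha = 0.05, grid = seq(0, 1, by = 0.025),
                     seed = NULL) {
  seeds <- deriveSeeds(seed %||% sample.int(1e9, 1), 2)
  measured <- nestedSupport(ds, method, penalty, n_nested, n_boot,
                            shuffle = FALSE, seed = seeds[1])
  shuffled <- nestedSupport(ds, method, penalty, n_nested, n_boot,
                            shuffle = TRUE, seed = seeds[2])
  fdr <- fdrCurve(measured$aggregate, shuffled$runs, grid = grid,
                  alpha = alpha)
  net <- if (!is.na(fdr@cutoff))
    selectNetwork(ds, measured$aggregate, fdr, method, penalty) else NULL
  list(measured = measured, shuffled = shuffled, fdr = fdr, network = net)
}
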