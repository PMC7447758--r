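#' Knockdown quality control
#'
#' Per targeted gene, the mean log2 fold change of the target across its
#' replicate experiments and a one-sided (downregulation) one-sample t-test
#' against 0.  A target is flagged significant when p < `p_thresh` and the
#' mean log2 fold change is below `lfc_thresh` — the criterion under which
#' 31 of 40 siRNA targets pass in a typical screen of this design.
#' Single-replicate targets are reported with a missing p-value.
#'
#' @param ds a [PerturbationDataset-class] with replicate grouping.
#' @param p_thresh p-value threshold (default 0.1).
#' @param lfc_thresh log2 fold-change threshold (default -2).
#' @return data.frame with columns `gene`, `n_replicates`, `mean_lfc`,
#'   `t`, `p`, `significant`.
#' @export
knockdownQC <- function(ds, p_thresh = 0.1, lfc_thresh = -2) {
  Y <- foldChanges(ds)
  genes <- rownames(Y)
  targets <- sort(unique(unlist(targetList(ds))))
  rows <- lapply(targets, function(g) {
    cols <- .experimentsOf(ds, g)
    v <- Y[g, cols]
    if (length(v) >= 2 && sd(v) > 0) {
      tt <- stats::t.test(v, mu = 0, alternative = "less")
      tstat <- unname(tt$statistic); p <- tt$p.value
    } else if (length(v) >= 2 && sd(v) == 0) {
      tstat <- if (mean(v) == 0) 0 else -Inf * sign(mean(v))
      p <- if (mean(v) < 0) 0 else 1
    } else {
      tstat <- NA_real_; p <- NA_real_
    }
    data.frame(gene = g, n_replicates = length(v), mean_lfc = mean(v),
               t = tstat, p = p,
               significant = !is.na(p) && p < p_thresh && mean(v) < lfc_thresh)
  })
  do.call(rbind, rows)
}

.linkPairs <- function(A, genes, directed = TRUE) {
  idx <- which(abs(A) > .ZERO_TOL, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  if (directed) {
    paste(genes[idx[, 2]], genes[idx[, 1]], sep = "->")
  } else {
    unique(apply(cbind(genes[idx[, 2]], genes[idx[, 1]]), 1,
                 function(p) paste(sort(p), collapse = "--")))
  }
}

#' Hypergeometric overlap with a reference link set
#'
#' Tests whether a network shares more links with a reference set than
#' expected by chance when both are drawn from a universe of
#' `universe_size` possible links.  With `directed = FALSE` both link sets
#' are collapsed to unordered gene pairs (self-links kept as pairs) before
#' intersecting — appropriate when the reference resource is undirected.
#' The p-value is the upper-tail hypergeometric probability of at least
#' the observed overlap.
#'
#' @param net a [GeneNetwork-class].
#' @param reference character vector of reference links, formatted
#'   `"src->tgt"` (directed) or `"a--b"` (undirected, alphabetical), or a
#'   two-column matrix/data.frame of (source, target) pairs.
#' @param universe_size number of possible links in the universe.
#' @param directed compare directed links (default) or unordered pairs.
#' @return List with `overlap`, `n_net`, `n_reference` and `p`.
#' @export
networkOverlapTest <- function(net, reference, universe_size,
                               directed = TRUE) {
  if (universe_size <= 0) stop("universe_size must be positive",
                               call. = FALSE)
  genes <- networkGenes(net)
  netLinks <- .linkPairs(interactionMatrix(net), genes, directed)
  if (is.matrix(reference) || is.data.frame(reference)) {
    reference <- if (directed)
      paste(reference[, 1], reference[, 2], sep = "->")
    else unique(apply(reference[, 1:2], 1,
                      function(p) paste(sort(p), collapse = "--")))
  }
  reference <- unique(reference)
  if (universe_size < length(netLinks) || universe_size < length(reference))
    stop("universe_size smaller than a link set", call. = FALSE)
  ov <- length(intersect(netLinks, reference))
  p <- stats::phyper(ov - 1, length(reference),
                     universe_size - length(reference), length(netLinks),
                     lower.tail = FALSE)
  list(overlap = ov, n_net = length(netLinks),
       n_reference = length(reference), p = p)
}
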