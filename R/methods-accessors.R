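#' Accessors for perturbGRN classes
#'
#' `interactionMatrix()` returns the square regulatory-effect matrix of a
#' [GeneNetwork-class]; `networkGenes()` its gene identifiers;
#' `networkMetadata()` its provenance list.  `foldChanges()` and
#' `designMatrix()` return the Y and P assays of a
#' [PerturbationDataset-class]; `targetList()` the per-experiment targeted
#' genes; `perturbationGroups()` the experiment indices grouped by identical
#' target set (replicate groups).  `supportValues()`/`supportSigns()` read a
#' [SupportMatrix-class]; `fdrValues()`/`supportCutoff()` an
#' [FDRCurve-class]; `wRSS()` a [FitResult-class]; `nullSamples()` a
#' [NullDistribution-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("interactionMatrix", "GeneNetwork", function(x) x@A)

#' @rdname accessors
#' @export
setMethod("networkGenes", "GeneNetwork", function(x) rownames(x@A))

#' @rdname accessors
#' @export
setMethod("networkMetadata", "GeneNetwork", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("foldChanges", "PerturbationDataset",
  function(x) SummarizedExperiment::assay(x, "foldChange"))

#' @rdname accessors
#' @export
setMethod("designMatrix", "PerturbationDataset",
  function(x) SummarizedExperiment::assay(x, "design"))

#' @rdname accessors
#' @export
setMethod("targetList", "PerturbationDataset",
  function(x) as.list(SummarizedExperiment::colData(x)$targets))

#' @rdname accessors
#' @export
setMethod("perturbationGroups", "PerturbationDataset", function(x) {
  key <- vapply(targetList(x), function(t) paste(sort(t), collapse = "+"),
                character(1))
  split(seq_along(key), key)
})

#' @rdname accessors
#' @export
setMethod("supportValues", "SupportMatrix", function(x) x@support)

#' @rdname accessors
#' @export
setMethod("supportSigns", "SupportMatrix", function(x) x@sign)

#' @rdname accessors
#' @export
setMethod("fdrValues", "FDRCurve", function(x) x@fdr)

#' @rdname accessors
#' @export
setMethod("supportCutoff", "FDRCurve", function(x) x@cutoff)

#' @rdname accessors
#' @export
setMethod("wRSS", "FitResult", function(x) x@wRSS)

#' @rdname accessors
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)

setMethod("show", "GeneNetwork", function(object) {
  s <- sparsityStats(object)
  cat(sprintf("GeneNetwork: %d genes, %d links (%d self-links), %.1f links/gene\n",
              length(networkGenes(object)), s$links,
              sum(abs(diag(object@A)) > .ZERO_TOL), s$links_per_gene))
  md <- Filter(function(v) is.atomic(v) && length(v) == 1, object@metadata)
  if (length(md))
    cat("metadata:", paste(names(md), vapply(md, function(v)
      format(v, digits = 4), character(1)),
      sep = "=", collapse = "; "), "\n")
})

setMethod("show", "SupportMatrix", function(object) {
  cat(sprintf("SupportMatrix (%s, n_boot=%d): %d x %d, %d supported links\n",
              object@source, object@n_boot, nrow(object@support),
              ncol(object@support), sum(object@support > 0)))
})

setMethod("show", "FDRCurve", function(object) {
  cat(sprintf("FDRCurve: %d cutoffs, alpha=%.3g, selected cutoff=%s\n",
              length(object@grid), object@alpha,
              ifelse(is.na(object@cutoff), "none", format(object@cutoff))))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: wRSS=%.6g, R2=%.4f, truncated=%s (rank %d)\n",
              object@wRSS, object@R2, object@truncated, object@rank))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution (%s): n=%d, observed wRSS=%.6g, median=%.6g\n",
    object@kind, length(object@samples), object@observed,
    median(object@samples)))
  cat(sprintf("  ratio to median=%.4g, empirical p=%.4g, failed=%d\n",
              object@ratioToMedian, object@empiricalP, object@nFailed))
})

#' Network sparsity statistics
#'
#' Counts links (nonzero entries of the interaction matrix, self-links
#' included), genes incident to at least one link, and their ratio.  The
#' links-per-gene ratio uses linked genes as denominator, so a 125-link
#' network touching 39 of 40 genes reports 3.2 links/gene.
#'
#' @param x a [GeneNetwork-class].
#' @return A list with `links`, `linked_genes` and `links_per_gene`
#'   (0 for an empty network).
#' @export
setMethod("sparsityStats", "GeneNetwork", function(x) {
  A <- x@A
  nz <- abs(A) > .ZERO_TOL
  links <- sum(nz)
  inc <- which(nz, arr.ind = TRUE)
  linked <- length(unique(c(inc[, 1], inc[, 2])))
  list(links = links, linked_genes = linked,
       links_per_gene = if (linked == 0) 0 else links / linked)
})
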