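#' GeneNetwork: a signed, weighted gene regulatory network
#'
#' A square interaction matrix \eqn{A} whose element \eqn{a_{ij}} is the
#' regulatory effect of gene \eqn{j} on gene \eqn{i}, expressed as the log2
#' fold-change response per unit perturbation at steady state.  A link is any
#' nonzero entry; nonzero diagonal entries are self-links.  The metadata list
#' carries provenance (inference method, sparsity penalty, bootstrap support
#' cutoff, free text).
#'
#' @slot A numeric square matrix with genes on rows and columns.
#' @slot metadata named list of provenance fields.
#'
#' @seealso [GeneNetwork()], [interactionMatrix()], [sparsityStats()]
#' @export
setClass("GeneNetwork",
  representation(A = "matrix", metadata = "list"),
  validity = function(object) {
    A <- object@A
    if (!is.numeric(A)) return("A must be numeric")
    if (nrow(A) != ncol(A)) return("A must be square")
    if (!all(is.finite(A))) return("A must be finite")
    if (is.null(rownames(A)) || is.null(colnames(A)))
      return("A must carry gene names on both dimensions")
    if (!identical(rownames(A), colnames(A)))
      return("row and column gene names must agree")
    TRUE
  })

#' Construct a GeneNetwork
#'
#' @param A square numeric matrix of regulatory effects (target genes on
#'   rows, regulator genes on columns).
#' @param genes optional character vector of gene identifiers; defaults to
#'   `rownames(A)` or `g1..gN`.
#' @param metadata named list of provenance fields (method, penalty,
#'   support cutoff, ...).
#' @return A [GeneNetwork-class] object.
#' @examples
#' net <- GeneNetwork(diag(-1, 3), genes = c("MYC", "TP53", "BRD4"))
#' sparsityStats(net)
#' @export
GeneNetwork <- function(A, genes = NULL, metadata = list()) {
  .assertSquare(A, "A")
  if (is.null(genes)) genes <- rownames(A) %||% paste0("g", seq_len(nrow(A)))
  if (length(genes) != nrow(A))
    stop("length(genes) must equal nrow(A)", call. = FALSE)
  dimnames(A) <- list(genes, genes)
  new("GeneNetwork", A = A, metadata = metadata)
}

#' PerturbationDataset: paired fold-change and design matrices
#'
#' Holds a genes-by-experiments log2 fold-change matrix \eqn{Y} and the
#' matching perturbation design matrix \eqn{P} as two assays of a
#' [SummarizedExperiment::SummarizedExperiment-class].  A negative entry
#' \eqn{p_{im}} marks gene \eqn{i} as knocked down in experiment \eqn{m}.
#' Column metadata records which genes each experiment targeted; the object
#' metadata optionally records the noise scales `sigmaE` (measurement error)
#' and `sigmaF` (process error) used in simulation.
#'
#' @seealso [PerturbationDataset()], [foldChanges()], [designMatrix()]
#' @export
setClass("PerturbationDataset",
  contains = "SummarizedExperiment",
  validity = function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("foldChange", "design") %in% a))
      return("assays 'foldChange' and 'design' are required")
    P <- SummarizedExperiment::assay(object, "design")
    if (any(colSums(P != 0) < 1))
      return("every experiment column of the design must perturb >= 1 gene")
    TRUE
  })

#' Construct a PerturbationDataset
#'
#' @param Y genes-by-experiments numeric matrix of log2 fold changes.
#' @param P design matrix of the same shape; negative entries mark intended
#'   knockdowns.
#' @param targets optional list (one element per experiment) of targeted
#'   gene identifiers; inferred from the nonzero pattern of `P` when absent.
#' @param sigmaE,sigmaF optional nonnegative noise-scale estimates for the
#'   measurement error E and process error F.
#' @return A [PerturbationDataset-class] object.
#' @export
PerturbationDataset <- function(Y, P, targets = NULL,
                                sigmaE = NA_real_, sigmaF = NA_real_) {
  .assertFiniteMatrix(Y, "Y")
  .assertFiniteMatrix(P, "P")
  if (!identical(dim(Y), dim(P)))
    stop("Y and P must have identical dimensions", call. = FALSE)
  genes <- rownames(Y) %||% rownames(P) %||% paste0("g", seq_len(nrow(Y)))
  samples <- colnames(Y) %||% colnames(P) %||% paste0("s", seq_len(ncol(Y)))
  dimnames(Y) <- dimnames(P) <- list(genes, samples)
  if (is.null(targets))
    targets <- apply(P != 0, 2, function(m) genes[m], simplify = FALSE)
  names(targets) <- samples
  cd <- S4Vectors::DataFrame(targets = IRanges::CharacterList(targets),
                             row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(foldChange = Y, design = P), colData = cd,
    metadata = list(sigmaE = sigmaE, sigmaF = sigmaF))
  new("PerturbationDataset", se)
}

#' SupportMatrix: per-link bootstrap support fractions
#'
#' For each potential signed link, the fraction of bootstrap-inferred
#' networks that contain it with the majority sign, together with that sign.
#'
#' @slot support numeric matrix in \[0, 1\].
#' @slot sign integer matrix in \{-1, 0, +1\}; zero exactly where support is
#'   zero.
#' @slot source `"measured"`, `"shuffled"` or `"aggregate"`.
#' @slot run_id index of the nested run (NA for aggregates).
#' @slot n_boot inner bootstrap count.
#' @export
setClass("SupportMatrix",
  representation(support = "matrix", sign = "matrix", source = "character",
                 run_id = "integer", n_boot = "integer"),
  validity = function(object) {
    s <- object@support
    if (any(s < 0 | s > 1)) return("support values must lie in [0, 1]")
    if (!all(object@sign %in% c(-1, 0, 1))) return("signs must be -1, 0 or +1")
    if (!identical(dim(s), dim(object@sign)))
      return("support and sign must have the same shape")
    if (any((object@sign == 0) != (s == 0)))
      return("sign must be 0 exactly where support is 0")
    TRUE
  })

#' FDRCurve: estimated FDR as a function of bootstrap support cutoff
#'
#' @slot grid ascending support cutoffs in \[0, 1\].
#' @slot fdr estimated false discovery rate at each cutoff.
#' @slot alpha nominal FDR level.
#' @slot cutoff smallest grid value whose FDR is at or below `alpha`
#'   (`NA` when no cutoff reaches it).
#' @export
setClass("FDRCurve",
  representation(grid = "numeric", fdr = "numeric", alpha = "numeric",
                 cutoff = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@grid)) return("grid must be ascending")
    if (any(object@fdr < 0 | object@fdr > 1)) return("fdr must lie in [0, 1]")
    if (length(object@fdr) != length(object@grid))
      return("grid and fdr must have equal length")
    TRUE
  })

#' FitResult: balanced-error leave-one-gene-out goodness of fit
#'
#' @slot Ehat,Fhat per-fold balanced measurement / process error estimates
#'   (lists named by left-out gene; each the shape of the fold's data).
#' @slot Erel,Frel per-fold relative errors \eqn{\|E\|_F/\|Y'\|_F} and
#'   \eqn{\|F\|_F/\|P'\|_F}.
#' @slot Ypred,Ppred predicted response / perturbation matrices assembled
#'   over all left-out experiments.
#' @slot wRSS weighted residual sum of squares.
#' @slot R2 proportion of response variance explained.
#' @slot truncated whether the network was SVD-truncated before fitting.
#' @slot rank number of singular values retained.
#' @export
setClass("FitResult",
  representation(Ehat = "list", Fhat = "list", Erel = "numeric",
                 Frel = "numeric", Ypred = "matrix", Ppred = "matrix",
                 wRSS = "numeric", R2 = "numeric", truncated = "logical",
                 rank = "integer"),
  validity = function(object) {
    if (object@wRSS < 0) return("wRSS must be nonnegative")
    if (object@R2 > 1 + 1e-12) return("R2 cannot exceed 1")
    if (any(object@Erel < 0) || any(object@Frel < 0))
      return("relative errors must be nonnegative")
    TRUE
  })

#' NullDistribution: wRSS null samples and comparison statistics
#'
#' @slot kind `"shuffled_topology"` or `"shuffled_data"`.
#' @slot samples null wRSS values.
#' @slot observed observed wRSS of the assessed network.
#' @slot ratioToMedian observed / median(null).
#' @slot empiricalP add-one empirical p-value
#'   \eqn{(1 + \#\{samples \le observed\})/(n + 1)}.
#' @slot nFailed replicates excluded due to solver failure.
#' @export
setClass("NullDistribution",
  representation(kind = "character", samples = "numeric",
                 observed = "numeric", ratioToMedian = "numeric",
                 empiricalP = "numeric", nFailed = "integer"),
  validity = function(object) {
    if (length(object@samples) == 0) return("null samples must be nonempty")
    if (!object@kind %in% c("shuffled_topology", "shuffled_data"))
      return("kind must be 'shuffled_topology' or 'shuffled_data'")
    if (object@empiricalP <= 0 || object@empiricalP > 1)
      return("empirical p must lie in (0, 1]")
    TRUE
  })
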