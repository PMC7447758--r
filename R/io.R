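## TSV conventions: genes as rows, first column the gene identifier, header
## row the sample identifiers, '.' decimal, tab separation, no quoting.

.readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate gene IDs in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop(sprintf("non-numeric cells in %s (column %s)", path,
                 paste(names(df)[bad + 1], collapse = ", ")), call. = FALSE)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

.writeMatrixTSV <- function(m, path, id_col = "gene") {
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(x) sprintf("%.12g", x)),
                   check.names = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a perturbation dataset from TSV files
#'
#' Expects fold-change (Y) and design (P) matrices in genes-by-experiments
#' TSV layout.  Shapes and gene sets are validated; replicate groups are
#' inferred from the nonzero column patterns of P when no groups file is
#' given.  Gene and sample ordering follows the files.
#'
#' @param y_path,p_path TSV paths for Y and P.
#' @param groups_path optional two-column TSV (sample, comma-separated
#'   targets) overriding the inferred grouping.
#' @return A [PerturbationDataset-class].
#' @export
readDataset <- function(y_path, p_path, groups_path = NULL) {
  Y <- .readMatrixTSV(y_path)
  P <- .readMatrixTSV(p_path)
  if (!identical(rownames(Y), rownames(P))) {
    miss <- c(setdiff(rownames(Y), rownames(P)),
              setdiff(rownames(P), rownames(Y)))
    stop("gene mismatch between Y and P: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  if (!identical(dim(Y), dim(P)))
    stop("Y and P differ in shape", call. = FALSE)
  targets <- NULL
  if (!is.null(groups_path)) {
    g <- read.delim(groups_path, stringsAsFactors = FALSE)
    targets <- strsplit(g[[2]], ",")[match(colnames(Y), g[[1]])]
  }
  PerturbationDataset(Y, P, targets = targets)
}

#' Write a perturbation dataset to TSV files
#'
#' @param ds a [PerturbationDataset-class].
#' @param y_path,p_path output TSV paths.
#' @export
writeDataset <- function(ds, y_path, p_path) {
  .writeMatrixTSV(foldChanges(ds), y_path)
  .writeMatrixTSV(designMatrix(ds), p_path)
  invisible(c(y_path, p_path))
}

.networkEdges <- function(net) {
  A <- interactionMatrix(net)
  genes <- networkGenes(net)
  md <- networkMetadata(net)
  sup <- md$aggregate_support
  idx <- which(abs(A) > .ZERO_TOL, arr.ind = TRUE)
  data.frame(source = genes[idx[, 2]], target = genes[idx[, 1]],
             weight = A[idx], sign = sign(A[idx]),
             support = if (is.null(sup)) rep(NA_real_, nrow(idx))
                       else sup[idx])
}

#' Write a network to disk
#'
#' TSV is an edge list with columns source, target, weight, sign, support
#' (self-links included); JSON carries the full object including gene list
#' and metadata; SIF is the minimal format for graph viewers.
#'
#' @param net a [GeneNetwork-class].
#' @param path output path.
#' @param format `"tsv"`, `"json"` or `"sif"`.
#' @export
writeNetwork <- function(net, path, format = c("tsv", "json", "sif")) {
  format <- match.arg(format)
  edges <- .networkEdges(net)
  if (format == "tsv") {
    edges$weight <- sprintf("%.12g", edges$weight)
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(edges$sign > 0, "activates", "represses")
    write.table(data.frame(edges$source, rel, edges$target), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    md <- networkMetadata(net)
    md$aggregate_support <- NULL  # carried per edge instead
    jsonlite::write_json(
      list(genes = networkGenes(net), metadata = md, edges = edges),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a network from disk
#'
#' @param path file written by [writeNetwork()].
#' @param format `"tsv"` or `"json"`.
#' @param genes gene universe for TSV input (TSV edge lists do not carry
#'   isolated genes); defaults to the genes present in the edges.
#' @return A [GeneNetwork-class].
#' @export
readNetwork <- function(path, format = c("tsv", "json"), genes = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    genes <- j$genes
    edges <- j$edges
    md <- as.list(j$metadata)
  } else {
    edges <- read.delim(path, stringsAsFactors = FALSE)
    if (is.null(genes))
      genes <- sort(unique(c(edges$source, edges$target)))
    md <- list()
  }
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (NROW(edges) > 0) {
    i <- match(edges$target, genes); j <- match(edges$source, genes)
    if (any(is.na(i) | is.na(j)))
      stop("edge references gene absent from the gene universe",
           call. = FALSE)
    A[cbind(i, j)] <- as.numeric(edges$weight)
  }
  GeneNetwork(A, metadata = md)
}
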