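#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @export
setGeneric("networkMetadata", function(x) standardGeneric("networkMetadata"))

#' @export
setGeneric("sparsityStats", function(x) standardGeneric("sparsityStats"))

#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @export
setGeneric("targetList", function(x) standardGeneric("targetList"))

#' @export
setGeneric("perturbationGroups", function(x) standardGeneric("perturbationGroups"))

#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' @export
setGeneric("supportSigns", function(x) standardGeneric("supportSigns"))

#' @export
setGeneric("fdrValues", function(x) standardGeneric("fdrValues"))

#' @export
setGeneric("supportCutoff", function(x) standardGeneric("supportCutoff"))

#' @export
setGeneric("wRSS", function(x) standardGeneric("wRSS"))

#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))
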