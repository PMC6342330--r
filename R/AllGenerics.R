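# Accessor generics.

#' @export
setGeneric("cy3Image", function(x) standardGeneric("cy3Image"))
#' @export
setGeneric("cy5Image", function(x) standardGeneric("cy5Image"))
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @export
setGeneric("hLines", function(x) standardGeneric("hLines"))
#' @export
setGeneric("vLines", function(x) standardGeneric("vLines"))
#' @export
setGeneric("boundaryLines", function(x) standardGeneric("boundaryLines"))
#' @export
setGeneric("spotDiameter", function(x) standardGeneric("spotDiameter"))
#' @export
setGeneric("spotSize", function(x) standardGeneric("spotSize"))
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))
#' @export
setGeneric("costTrace", function(x) standardGeneric("costTrace"))
#' @export
setGeneric("segMask", function(x) standardGeneric("segMask"))
#' @export
setGeneric("spotQuant", function(x) standardGeneric("spotQuant"))
#' @export
setGeneric("refineReport", function(x) standardGeneric("refineReport"))
#' @export
setGeneric("pipelineStats", function(x) standardGeneric("pipelineStats"))
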