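#' @rdname NetworkSpec-accessors
#' @export
setGeneric("vertexNames", function(object) standardGeneric("vertexNames"))

#' @rdname NetworkSpec-accessors
#' @export
setGeneric("vertexCount", function(object) standardGeneric("vertexCount"))

#' @rdname NetworkSpec-accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname NetworkSpec-accessors
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname NetworkSpec-accessors
#' @export
setGeneric("edgeNames", function(object) standardGeneric("edgeNames"))

#' @rdname NetworkSpec-accessors
#' @export
setGeneric("vertexDegree", function(object, vertex) standardGeneric("vertexDegree"))

#' @rdname LabeledDataset-accessors
#' @export
setGeneric("dataMatrix", function(object) standardGeneric("dataMatrix"))

#' @rdname LabeledDataset-accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname LabeledDataset-accessors
#' @export
setGeneric("groupSizes", function(object) standardGeneric("groupSizes"))

#' @rdname ScoreDecomposition-accessors
#' @export
setGeneric("scoreVector", function(object) standardGeneric("scoreVector"))

#' @rdname ScoreDecomposition-accessors
#' @export
setGeneric("covarianceMatrix", function(object) standardGeneric("covarianceMatrix"))

#' @rdname TestResult-accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname TestResult-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname TestResult-accessors
#' @export
setGeneric("degreesOfFreedom", function(object) standardGeneric("degreesOfFreedom"))

#' @rdname TestResult-accessors
#' @export
setGeneric("methodLabel", function(object) standardGeneric("methodLabel"))
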