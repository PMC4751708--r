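#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData
#' @importFrom S4Vectors isEmpty
NULL

#' Construct a LabeledDataset
#'
#' @param X either a numeric samples x vertices matrix with vertex names
#'   as column names, or a
#'   \linkS4class{SummarizedExperiment} (features x samples; the assay is
#'   transposed and the label column is taken from \code{colData}).
#' @param y binary group labels, coded exactly 0 (control) / 1 (case).
#'   Any other coding is rejected rather than silently recoded.  For the
#'   SummarizedExperiment method, the name of the colData column holding
#'   the labels.
#' @param sampleIds optional sample identifiers (default: row names of X,
#'   or \code{sample1..sampleN}).
#' @param ... passed between methods.
#'
#' @return a [LabeledDataset-class].
#' @examples
#' X <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(NULL, paste0("g", 1:4)))
#' d <- LabeledDataset(X, rep(c(1, 0), each = 5))
#' groupSizes(d)
#' @export
setGeneric("LabeledDataset",
           function(X, y, ...) standardGeneric("LabeledDataset"))

#' @rdname LabeledDataset
#' @export
setMethod("LabeledDataset", signature(X = "matrix"),
          function(X, y, sampleIds = NULL, ...) {
  storage.mode(X) <- "double"
  if (is.logical(y)) stop("labels must be coded exactly 0/1")
  yi <- suppressWarnings(as.integer(y))
  if (anyNA(yi) || any(yi != y)) stop("labels must be coded exactly 0/1")
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(X))) rownames(X)
                 else paste0("sample", seq_len(nrow(X)))
  new("LabeledDataset", X = X, y = yi, sampleIds = as.character(sampleIds))
})

#' @rdname LabeledDataset
#' @export
setMethod("LabeledDataset", signature(X = "SummarizedExperiment"),
          function(X, y, ...) {
  stopifnot(is.character(y), length(y) == 1L)
  cd <- SummarizedExperiment::colData(X)
  if (!y %in% colnames(cd))
    stop("label column '", y, "' not found in colData")
  mat <- t(SummarizedExperiment::assay(X))
  LabeledDataset(mat, cd[[y]], sampleIds = colnames(X))
})

#' Accessors for LabeledDataset
#'
#' @param object a [LabeledDataset-class].
#' @return \code{dataMatrix}: the N x M numeric matrix; \code{groupLabels}:
#'   integer 0/1 labels; \code{groupSizes}: named vector
#'   \code{c(case = ..., control = ...)}.
#' @name LabeledDataset-accessors
#' @aliases dataMatrix groupLabels groupSizes
NULL

#' @rdname LabeledDataset-accessors
#' @export
setMethod("dataMatrix", "LabeledDataset", function(object) object@X)

#' @rdname LabeledDataset-accessors
#' @export
setMethod("groupLabels", "LabeledDataset", function(object) object@y)

#' @rdname LabeledDataset-accessors
#' @export
setMethod("groupSizes", "LabeledDataset", function(object)
  c(case = sum(object@y == 1L), control = sum(object@y == 0L)))

setMethod("show", "LabeledDataset", function(object) {
  gs <- groupSizes(object)
  cat("LabeledDataset:", nrow(object@X), "samples x", ncol(object@X),
      "vertices (", gs["case"], "cases /", gs["control"], "controls )\n")
})

#' Read a labeled data matrix from a delimited file
#'
#' Expects samples in rows and vertices in columns (use
#' \code{transpose = TRUE} for the features-in-rows orientation), a header
#' row of vertex names, and one column holding the 0/1 group labels.
#'
#' @param path path to the delimited file.
#' @param labelColumn name of the column holding the 0/1 labels.
#' @param delimiter field delimiter (default tab).
#' @param idColumn optional name of a sample-identifier column.
#' @param transpose if TRUE the file is vertices x samples and is
#'   transposed after reading (the label row is then taken from the
#'   transposed orientation's column).
#' @return a [LabeledDataset-class].
#' @export
loadLabeledData <- function(path, labelColumn, delimiter = "\t",
                            idColumn = NULL, transpose = FALSE) {
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (transpose) {
    rn <- tab[[1L]]
    tab <- as.data.frame(t(as.matrix(tab[, -1L])), stringsAsFactors = FALSE)
    colnames(tab) <- rn
    tab <- cbind(data.frame(.sample = rownames(tab),
                            stringsAsFactors = FALSE), tab)
    if (is.null(idColumn)) idColumn <- ".sample"
  }
  if (!labelColumn %in% colnames(tab))
    stop("label column '", labelColumn, "' not found")
  y <- tab[[labelColumn]]
  ids <- if (!is.null(idColumn)) {
    if (!idColumn %in% colnames(tab))
      stop("id column '", idColumn, "' not found")
    as.character(tab[[idColumn]])
  } else NULL
  drop <- c(labelColumn, idColumn)
  Xdf <- tab[, setdiff(colnames(tab), drop), drop = FALSE]
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  LabeledDataset(X, as.numeric(y), sampleIds = ids)
}
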