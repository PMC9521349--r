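#' Accessors for comutnet classes
#'
#' `patientIds()` and `panelGenes()` return the row/column identities of a
#' [MutationMatrix-class]; `mutationCalls()` the underlying 0/1 integer
#' matrix; `nPatients()`/`nGenes()` its dimensions. `dagNodes()` and
#' `dagParents()` expose a [GeneDag-class]'s structure, `dagEdges()` its
#' edge list as a two-column matrix (from, to).
#'
#' @param x a comutnet object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @rdname accessors
#' @export
setGeneric("mutationCalls", function(x) standardGeneric("mutationCalls"))
#' @rdname accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))
#' @rdname accessors
#' @export
setGeneric("dagParents", function(x) standardGeneric("dagParents"))
#' @rdname accessors
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))
#' @rdname accessors
#' @export
setGeneric("riskRatio", function(x) standardGeneric("riskRatio"))

#' @rdname accessors
setMethod("patientIds", "MutationMatrix", function(x) rownames(x@calls))
#' @rdname accessors
setMethod("panelGenes", "MutationMatrix", function(x) colnames(x@calls))
#' @rdname accessors
setMethod("mutationCalls", "MutationMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("nPatients", "MutationMatrix", function(x) nrow(x@calls))
#' @rdname accessors
setMethod("nGenes", "MutationMatrix", function(x) ncol(x@calls))

#' @rdname accessors
setMethod("dagNodes", "GeneDag", function(x) x@nodes)
#' @rdname accessors
setMethod("dagParents", "GeneDag", function(x) x@parents)
#' @rdname accessors
setMethod("dagEdges", "GeneDag", function(x) {
  from <- unlist(x@parents, use.names = FALSE)
  to <- rep(names(x@parents), lengths(x@parents))
  matrix(c(from, to), ncol = 2, dimnames = list(NULL, c("from", "to")))
})
#' @rdname accessors
setMethod("dagNodes", "PlantedModel", function(x) x@dag@nodes)
#' @rdname accessors
setMethod("riskRatio", "RiskEstimate", function(x) x@rr)

#' Coerce a RiskEstimate to a one-row data frame
#'
#' @param x a [RiskEstimate-class].
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return one-row `data.frame` matching the RR report column layout.
#' @export
as.data.frame.RiskEstimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(anchor = x@anchor,
             condition = paste(x@condition, collapse = ";"),
             direction = x@direction,
             numerator = x@numerator, denominator = x@denominator,
             rr = x@rr, method = x@method, converged = x@converged,
             flag = x@flag, stringsAsFactors = FALSE)
}
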