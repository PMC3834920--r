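#' @import methods
#' @importFrom stats predict coef rnorm runif .lm.fit
NULL

#' Generics for descriptor-table QSAR objects
#'
#' Accessor and computation generics shared by the S4 classes in this
#' package. See the class pages for method-specific details.
#'
#' @param object,model an object of one of the package classes.
#' @param ... passed to methods.
#' @name ermsel-generics
NULL

#' @rdname ermsel-generics
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname ermsel-generics
#' @export
setGeneric("descriptorNames", function(object) standardGeneric("descriptorNames"))

#' @rdname ermsel-generics
#' @export
setGeneric("descriptorMatrix", function(object) standardGeneric("descriptorMatrix"))

#' @rdname ermsel-generics
#' @export
setGeneric("response", function(object) standardGeneric("response"))

#' @rdname ermsel-generics
#' @export
setGeneric("responseName", function(object) standardGeneric("responseName"))

#' @rdname ermsel-generics
#' @export
setGeneric("responseTransform", function(object) standardGeneric("responseTransform"))

#' @rdname ermsel-generics
#' @export
setGeneric("constantDescriptors", function(object) standardGeneric("constantDescriptors"))

#' @rdname ermsel-generics
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' @rdname ermsel-generics
#' @export
setGeneric("poolSize", function(object) standardGeneric("poolSize"))

#' @rdname ermsel-generics
#' @export
setGeneric("subsetNames", function(object) standardGeneric("subsetNames"))

#' @rdname ermsel-generics
#' @export
setGeneric("modelS", function(object) standardGeneric("modelS"))

#' @rdname ermsel-generics
#' @export
setGeneric("modelR2", function(object) standardGeneric("modelR2"))

#' @rdname ermsel-generics
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' @rdname ermsel-generics
#' @export
setGeneric("searchTrace", function(object) standardGeneric("searchTrace"))

#' @rdname ermsel-generics
#' @export
setGeneric("nFits", function(object) standardGeneric("nFits"))

#' Evaluate a fitted model on a descriptor table
#'
#' Computes per-compound predictions on the raw response scale together with
#' the coefficient of determination \eqn{R^2 = 1 - RSS/TSS} (TSS about the
#' mean of the observed response) and a residual scale statistic S.
#'
#' @param model a [SubsetModel-class] or [AnnModel-class].
#' @param table a [DescriptorTable-class] whose descriptor columns cover the
#'   model inputs.
#' @return a list with elements `R2`, `S` and `predictions` (named by
#'   compound id).
#' @export
setGeneric("evaluateModel", function(model, table) standardGeneric("evaluateModel"))
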