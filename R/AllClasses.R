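#' DescriptorTable: compounds-by-descriptors matrix with a response
#'
#' The single data container used by every selection and modelling function
#' in the package. Rows are compounds, columns are named molecular
#' descriptors (the candidate pool), and `y` holds the response — the flux
#' enhancement ratio (ER), i.e. drug flux with the enhancer present divided
#' by flux without it, or log10(ER) when transformed.
#'
#' @slot compoundIds character, unique compound labels (row identity).
#' @slot descriptorNames character, unique descriptor labels (column
#'   identity); may embed units in parentheses, treated as opaque text.
#' @slot X numeric matrix, `length(compoundIds)` x `length(descriptorNames)`,
#'   finite descriptor values in their native physical units.
#' @slot y numeric, response values, one per compound.
#' @slot responseName character scalar, e.g. `"ER"`.
#' @slot responseTransform `"identity"` or `"log10"`.
#' @slot constantDescriptors character, names of descriptor columns flagged
#'   as constant by [validatePool()]; these are never selectable by the
#'   subset-search functions but are kept in place so column indexing still
#'   matches the user's file.
#'
#' @seealso [readDescriptorTable()], [validatePool()], [transformResponse()]
#' @export
setClass("DescriptorTable",
    representation(
        compoundIds = "character",
        descriptorNames = "character",
        X = "matrix",
        y = "numeric",
        responseName = "character",
        responseTransform = "character",
        constantDescriptors = "character"
    ),
    prototype(
        responseName = "ER",
        responseTransform = "identity",
        constantDescriptors = character(0)
    )
)

setValidity("DescriptorTable", function(object) {
    msg <- character(0)
    n <- length(object@compoundIds)
    p <- length(object@descriptorNames)
    if (!is.numeric(object@X))
        msg <- c(msg, "descriptor matrix X must be numeric")
    if (nrow(object@X) != n)
        msg <- c(msg, "number of compound ids must equal nrow(X)")
    if (ncol(object@X) != p)
        msg <- c(msg, "number of descriptor names must equal ncol(X)")
    if (length(object@y) != n)
        msg <- c(msg, "length of response y must equal nrow(X)")
    if (anyDuplicated(object@compoundIds))
        msg <- c(msg, "duplicate compound ids")
    if (anyDuplicated(object@descriptorNames))
        msg <- c(msg, "duplicate descriptor names")
    if (length(object@X) && !all(is.finite(object@X)))
        msg <- c(msg, "non-finite values in descriptor matrix")
    if (length(object@y) && !all(is.finite(object@y)))
        msg <- c(msg, "non-finite values in response")
    if (length(object@responseTransform) != 1L ||
        !object@responseTransform %in% c("identity", "log10"))
        msg <- c(msg, "responseTransform must be 'identity' or 'log10'")
    if (!all(object@constantDescriptors %in% object@descriptorNames))
        msg <- c(msg, "constantDescriptors not a subset of descriptorNames")
    if (length(msg)) msg else TRUE
})

#' SubsetModel: an ordinary least-squares fit on a descriptor subset
#'
#' Stores the intercept-containing OLS fit of the response on a fixed
#' descriptor subset, together with the two statistics that drive subset
#' selection: the residual standard deviation
#' \eqn{S = \sqrt{RSS/(n - d - 1)}} (response units; `d` descriptors plus
#' the intercept counted in the degrees of freedom) and
#' \eqn{R^2 = 1 - RSS/TSS}. `relativeErrors` are the dimensionless ratios
#' standard error / |coefficient| used by the replacement methods to pick
#' the "worst" descriptor; a zero coefficient gets `+Inf` so it always ranks
#' worst. The intercept is never ranked and never replaced.
#'
#' @slot subset character, descriptor names in model order (size d; may be
#'   empty for the intercept-only model).
#' @slot intercept numeric scalar.
#' @slot coefficients,stdErrors,relativeErrors numeric vectors of length d.
#' @slot S numeric scalar, residual standard deviation (>= 0).
#' @slot R2 numeric scalar (<= 1; 0 by convention for a constant response).
#' @slot nObs integer, number of observations used in the fit.
#'
#' @seealso [fitSubset()], [predict,SubsetModel-method],
#'   [writeSubsetModel()]
#' @export
setClass("SubsetModel",
    representation(
        subset = "character",
        intercept = "numeric",
        coefficients = "numeric",
        stdErrors = "numeric",
        relativeErrors = "numeric",
        S = "numeric",
        R2 = "numeric",
        nObs = "integer"
    )
)

setValidity("SubsetModel", function(object) {
    msg <- character(0)
    d <- length(object@subset)
    if (length(object@coefficients) != d ||
        length(object@stdErrors) != d ||
        length(object@relativeErrors) != d)
        msg <- c(msg, "coefficients, stdErrors and relativeErrors must match subset length")
    if (anyDuplicated(object@subset))
        msg <- c(msg, "duplicate descriptor names in subset")
    if (length(object@S) != 1L || (!is.na(object@S) && object@S < 0))
        msg <- c(msg, "S must be a single non-negative number (NA allowed for published models)")
    if (length(object@R2) != 1L || (!is.na(object@R2) && object@R2 > 1 + 1e-12))
        msg <- c(msg, "R2 must be a single number <= 1")
    if (length(msg)) msg else TRUE
})

#' SearchResult: outcome of a descriptor-subset search
#'
#' Wraps the best model found by one of the selection algorithms together
#' with the trace of states visited. For the replacement family and the
#' exhaustive oracle the returned model is best-ever: its S is no larger
#' than the S of any traced state.
#'
#' @slot method one of `"rm"`, `"mrm"`, `"erm"`, `"forward_stepwise"`,
#'   `"backward_elimination"`, `"exhaustive"`.
#' @slot bestModel the winning [SubsetModel-class].
#' @slot trace list of visited states, each a list with elements `subset`
#'   (character), `S` (numeric) and `stage` (a label such as `"path3"` or
#'   `"mrm"`, identifying which search phase produced the state).
#' @slot nFits integer, total number of OLS fits performed.
#' @slot seed integer or NA, the seed used for random initialisation.
#' @slot initSubset character, the initial subset (empty when none applies).
#'
#' @seealso [rmSelect()], [ermSelect()], [forwardStepwise()],
#'   [exhaustiveBestSubset()]
#' @export
setClass("SearchResult",
    representation(
        method = "character",
        bestModel = "SubsetModel",
        trace = "list",
        nFits = "integer",
        seed = "integer",
        initSubset = "character"
    ),
    prototype(seed = NA_integer_, initSubset = character(0))
)

setValidity("SearchResult", function(object) {
    msg <- character(0)
    known <- c("rm", "mrm", "erm", "forward_stepwise",
               "backward_elimination", "exhaustive")
    if (length(object@method) != 1L || !object@method %in% known)
        msg <- c(msg, paste("method must be one of:", paste(known, collapse = ", ")))
    bad <- vapply(object@trace, function(st)
        !is.list(st) || !all(c("subset", "S") %in% names(st)), logical(1))
    if (any(bad))
        msg <- c(msg, "each trace entry needs 'subset' and 'S'")
    if (length(msg)) msg else TRUE
})

#' ScalingParams: per-column min-max affine maps
#'
#' Column-wise affine maps onto the interval `[lo, hi]` (default
#' `[0.1, 0.9]`, the range conventionally used when feeding sigmoid
#' networks): \eqn{\hat x = (hi - lo)(x - min)/(max - min) + lo}, inverted
#' exactly by [invertScaling()]. A constant column (max == min) maps to the
#' midpoint of the interval and inverts to its constant value.
#'
#' @slot columnNames character, one per mapped column.
#' @slot mins,maxs numeric, observed column minima and maxima.
#' @slot lo,hi numeric scalars, target interval (lo < hi).
#'
#' @seealso [fitScaling()], [applyScaling()], [invertScaling()]
#' @export
setClass("ScalingParams",
    representation(
        columnNames = "character",
        mins = "numeric",
        maxs = "numeric",
        lo = "numeric",
        hi = "numeric"
    ),
    prototype(lo = 0.1, hi = 0.9)
)

setValidity("ScalingParams", function(object) {
    msg <- character(0)
    p <- length(object@columnNames)
    if (length(object@mins) != p || length(object@maxs) != p)
        msg <- c(msg, "mins and maxs must match columnNames in length")
    if (any(object@maxs < object@mins))
        msg <- c(msg, "each max must be >= its min")
    if (length(object@lo) != 1L || length(object@hi) != 1L ||
        object@lo >= object@hi)
        msg <- c(msg, "need scalar lo < hi")
    if (length(msg)) msg else TRUE
})

#' AnnModel: a small feed-forward network with attached scaling
#'
#' A single-hidden-layer feed-forward network mapping scaled descriptor
#' inputs to a scaled response: hidden activations
#' \eqn{h = \sigma(W_h \hat x + b_h)} with logistic
#' \eqn{\sigma(z) = 1/(1+e^{-z})}, then an output node
#' \eqn{\hat y = w_o \cdot h + b_o} (linear by default, optionally
#' sigmoid). The default geometry is 8:2:1 — eight descriptor inputs, two
#' hidden units, one output — deliberately small to avoid
#' over-parameterisation on short compound tables. Prediction runs the full
#' pipeline: min-max scale raw inputs, propagate, inverse-scale the output
#' back to response (ER) units.
#'
#' @slot inputNames character, descriptor names in input order (size n_in).
#' @slot WHidden numeric matrix, n_hidden x n_in hidden-layer weights.
#' @slot bHidden numeric, n_hidden hidden biases.
#' @slot WOut numeric, n_hidden output weights.
#' @slot bOut numeric scalar, output bias.
#' @slot activation character, hidden activation (`"sigmoid"`).
#' @slot outputActivation `"linear"` (default) or `"sigmoid"`.
#' @slot inputScaling,responseScaling [ScalingParams-class] fitted on the
#'   training inputs and response.
#'
#' @seealso [trainAnn()], [annPredict()], [hiddenPreactivation()]
#' @export
setClass("AnnModel",
    representation(
        inputNames = "character",
        WHidden = "matrix",
        bHidden = "numeric",
        WOut = "numeric",
        bOut = "numeric",
        activation = "character",
        outputActivation = "character",
        inputScaling = "ScalingParams",
        responseScaling = "ScalingParams"
    ),
    prototype(activation = "sigmoid", outputActivation = "linear")
)

setValidity("AnnModel", function(object) {
    msg <- character(0)
    nh <- nrow(object@WHidden)
    if (ncol(object@WHidden) != length(object@inputNames))
        msg <- c(msg, "ncol(WHidden) must equal the number of inputs")
    if (length(object@bHidden) != nh || length(object@WOut) != nh)
        msg <- c(msg, "bHidden and WOut must have one entry per hidden unit")
    if (length(object@bOut) != 1L)
        msg <- c(msg, "bOut must be scalar")
    if (!identical(object@activation, "sigmoid"))
        msg <- c(msg, "only the sigmoid hidden activation is supported")
    if (!object@outputActivation %in% c("linear", "sigmoid"))
        msg <- c(msg, "outputActivation must be 'linear' or 'sigmoid'")
    if (length(msg)) msg else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname ermsel-generics
#' @export
setMethod("compoundIds", "DescriptorTable", function(object) object@compoundIds)

#' @rdname ermsel-generics
#' @export
setMethod("descriptorNames", "DescriptorTable", function(object) object@descriptorNames)

#' @rdname ermsel-generics
#' @export
setMethod("descriptorMatrix", "DescriptorTable", function(object) {
    m <- object@X
    dimnames(m) <- list(object@compoundIds, object@descriptorNames)
    m
})

#' @rdname ermsel-generics
#' @export
setMethod("response", "DescriptorTable", function(object) {
    y <- object@y
    names(y) <- object@compoundIds
    y
})

#' @rdname ermsel-generics
#' @export
setMethod("responseName", "DescriptorTable", function(object) object@responseName)

#' @rdname ermsel-generics
#' @export
setMethod("responseTransform", "DescriptorTable", function(object) object@responseTransform)

#' @rdname ermsel-generics
#' @export
setMethod("constantDescriptors", "DescriptorTable", function(object) object@constantDescriptors)

#' @rdname ermsel-generics
#' @export
setMethod("nObs", "DescriptorTable", function(object) length(object@compoundIds))

#' @rdname ermsel-generics
#' @export
setMethod("poolSize", "DescriptorTable", function(object) length(object@descriptorNames))

#' @rdname ermsel-generics
#' @export
setMethod("nObs", "SubsetModel", function(object) object@nObs)

#' @rdname ermsel-generics
#' @export
setMethod("subsetNames", "SubsetModel", function(object) object@subset)

#' @rdname ermsel-generics
#' @export
setMethod("modelS", "SubsetModel", function(object) object@S)

#' @rdname ermsel-generics
#' @export
setMethod("modelR2", "SubsetModel", function(object) object@R2)

#' Coefficients of a subset model
#'
#' Returns the fitted coefficients, with the intercept first, named
#' `"(Intercept)"` followed by the subset descriptor names.
#'
#' @param object a [SubsetModel-class].
#' @param ... ignored.
#' @export
setMethod("coef", "SubsetModel", function(object, ...) {
    out <- c(object@intercept, object@coefficients)
    names(out) <- c("(Intercept)", object@subset)
    out
})

#' @rdname ermsel-generics
#' @export
setMethod("bestModel", "SearchResult", function(object) object@bestModel)

#' @rdname ermsel-generics
#' @export
setMethod("searchTrace", "SearchResult", function(object) object@trace)

#' @rdname ermsel-generics
#' @export
setMethod("nFits", "SearchResult", function(object) object@nFits)

#' @rdname ermsel-generics
#' @export
setMethod("subsetNames", "SearchResult", function(object) object@bestModel@subset)

#' @rdname ermsel-generics
#' @export
setMethod("modelS", "SearchResult", function(object) object@bestModel@S)

#' @rdname ermsel-generics
#' @export
setMethod("modelR2", "SearchResult", function(object) object@bestModel@R2)

## ---- show methods --------------------------------------------------------

setMethod("show", "DescriptorTable", function(object) {
    cat("DescriptorTable:", nObs(object), "compounds x",
        poolSize(object), "descriptors\n")
    cat("  response:", object@responseName,
        sprintf("(%s)", object@responseTransform),
        sprintf("range [%.4g, %.4g]\n", min(object@y), max(object@y)))
    nm <- object@descriptorNames
    shown <- paste(utils::head(nm, 4), collapse = ", ")
    if (length(nm) > 4) shown <- paste0(shown, ", ...")
    cat("  descriptors:", shown, "\n")
    if (length(object@constantDescriptors))
        cat("  flagged constant:",
            paste(object@constantDescriptors, collapse = ", "), "\n")
})

setMethod("show", "SubsetModel", function(object) {
    d <- length(object@subset)
    cat(sprintf("SubsetModel: %d descriptor%s, n = %d\n",
                d, if (d == 1) "" else "s", object@nObs))
    cat(sprintf("  S = %.6g, R2 = %.4f\n", object@S, object@R2))
    if (d) {
        tab <- data.frame(coefficient = object@coefficients,
                          std.error = object@stdErrors,
                          rel.error = object@relativeErrors,
                          row.names = object@subset)
        print(rbind(`(Intercept)` = c(object@intercept, NA, NA), tab))
    } else {
        cat(sprintf("  intercept-only model: %.6g\n", object@intercept))
    }
})

setMethod("show", "SearchResult", function(object) {
    cat(sprintf("SearchResult [%s]: %d OLS fits, %d states traced\n",
                object@method, object@nFits, length(object@trace)))
    cat("  best subset:", paste(object@bestModel@subset, collapse = ", "), "\n")
    cat(sprintf("  S = %.6g, R2 = %.4f\n",
                object@bestModel@S, object@bestModel@R2))
})

setMethod("show", "ScalingParams", function(object) {
    cat(sprintf("ScalingParams: %d column(s) -> [%g, %g]\n",
                length(object@columnNames), object@lo, object@hi))
    print(data.frame(min = object@mins, max = object@maxs,
                     row.names = object@columnNames))
})

setMethod("show", "AnnModel", function(object) {
    cat(sprintf("AnnModel: %d:%d:1 feed-forward network (%s hidden, %s output)\n",
                length(object@inputNames), nrow(object@WHidden),
                object@activation, object@outputActivation))
    cat("  inputs:", paste(object@inputNames, collapse = ", "), "\n")
})
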