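# OLS core: every selection algorithm in the package reduces to many small
# intercept-containing least-squares fits, ranked by the residual standard
# deviation S. The fast path (ols_rss) computes only RSS and rank via
# .lm.fit; the full path (fitSubset) adds coefficient covariance.

# Residual sum of squares of y on cbind(1, X[, idx]). Returns Inf for a
# rank-deficient design so search loops can treat collinear candidates as
# "never selected" without error handling overhead.
ols_rss <- function(X, y, idx) {
    Xd <- cbind(1, X[, idx, drop = FALSE])
    fit <- .lm.fit(Xd, y, tol = 1e-10)
    if (fit$rank < ncol(Xd)) return(Inf)
    sum(fit$residuals^2)
}

# S = sqrt(RSS / (n - d - 1)) for a subset of size d; Inf when singular.
ols_S <- function(X, y, idx) {
    rss <- ols_rss(X, y, idx)
    n <- length(y)
    d <- length(idx)
    if (!is.finite(rss)) return(Inf)
    sqrt(max(rss, 0) / (n - d - 1))
}

# Nested-model partial F. A big-model RSS that is zero to round-off
# (relative to the small model's) means a perfect fit: +Inf sentinel.
partial_F <- function(rssSmall, rssBig, dfBig) {
    if (rssBig <= 1e-12 * max(rssSmall, 1)) return(Inf)
    max(rssSmall - rssBig, 0) / (rssBig / dfBig)
}

# Largest/smallest singular value ratio of the design matrix.
design_condition <- function(Xd) {
    sv <- svd(Xd, nu = 0, nv = 0)$d
    if (min(sv) == 0) return(Inf)
    max(sv) / min(sv)
}

#' Fit an OLS model on a descriptor subset
#'
#' Fits the response on the named descriptors plus an intercept by ordinary
#' least squares and returns a [SubsetModel-class] carrying the selection
#' statistics: residual standard deviation
#' \eqn{S = \sqrt{RSS/(n - d - 1)}}, coefficient of determination
#' \eqn{R^2 = 1 - RSS/TSS} (TSS about the mean of the response), coefficient
#' standard errors from the OLS covariance, and relative errors
#' (std error / |coefficient|, `+Inf` for a zero coefficient). A constant
#' response yields \eqn{R^2 = 0} and zero coefficients by convention.
#'
#' Designs whose condition number (singular-value ratio) exceeds `1e10` are
#' rejected as singular; the search algorithms convert this into "candidate
#' not selectable".
#'
#' @param table a [DescriptorTable-class].
#' @param subset character vector of descriptor names (possibly empty, for
#'   the intercept-only model); must exist in the table, and
#'   `nObs >= length(subset) + 2`.
#' @return a [SubsetModel-class].
#' @examples
#' dt <- DescriptorTable(matrix(1:6, 6, 1, dimnames = list(NULL, "x")),
#'                       y = 2 * (1:6) + 1)
#' fitSubset(dt, "x")   # intercept 1, slope 2, S = 0, R2 = 1
#' @export
fitSubset <- function(table, subset = character(0)) {
    stopifnot(is(table, "DescriptorTable"))
    subset <- as.character(subset)
    idx <- match(subset, table@descriptorNames)
    if (anyNA(idx))
        stop("descriptor(s) not in pool: ",
             paste(subset[is.na(idx)], collapse = ", "))
    y <- table@y
    n <- length(y)
    d <- length(idx)
    if (n < d + 2L)
        stop("need at least ", d + 2L, " observations to fit ", d,
             " descriptors with an intercept; have ", n)

    tss <- sum((y - mean(y))^2)
    if (d == 0L) {
        rss <- tss
        return(new("SubsetModel", subset = character(0),
                   intercept = mean(y), coefficients = numeric(0),
                   stdErrors = numeric(0), relativeErrors = numeric(0),
                   S = sqrt(rss / (n - 1)), R2 = 0, nObs = as.integer(n)))
    }

    Xd <- cbind(1, table@X[, idx, drop = FALSE])
    if (design_condition(Xd) > 1e10)
        stop("singular design: descriptor subset {",
             paste(subset, collapse = ", "),
             "} is collinear (condition number > 1e10)")
    qrX <- qr(Xd)
    beta <- qr.coef(qrX, y)
    res <- y - Xd %*% beta
    rss <- sum(res^2)
    S <- sqrt(max(rss, 0) / (n - d - 1))
    XtXinv <- chol2inv(qr.R(qrX))
    se <- S * sqrt(pmax(diag(XtXinv), 0))

    coefs <- beta[-1L]
    if (tss == 0) {                     # constant response: degenerate fit
        coefs[] <- 0
        R2 <- 0
    } else {
        R2 <- 1 - rss / tss
    }
    relerr <- ifelse(coefs == 0, Inf, se[-1L] / abs(coefs))
    new("SubsetModel", subset = subset, intercept = unname(beta[1L]),
        coefficients = unname(coefs), stdErrors = unname(se[-1L]),
        relativeErrors = unname(relerr), S = S, R2 = R2,
        nObs = as.integer(n))
}

#' Predict the response from a subset model
#'
#' Evaluates \eqn{\hat y = a_0 + \sum_j a_j x_j} over the model's descriptor
#' subset. `newdata` may be a numeric vector aligned with
#' `subsetNames(object)`, a numeric matrix whose columns are (or are named
#' as) the subset descriptors, or a [DescriptorTable-class] containing them.
#'
#' @param object a [SubsetModel-class].
#' @param newdata descriptor values in raw units.
#' @param ... ignored.
#' @return predicted response value(s) in response (ER) units.
#' @export
setMethod("predict", "SubsetModel", function(object, newdata, ...) {
    d <- length(object@subset)
    if (is(newdata, "DescriptorTable")) {
        m <- descriptorMatrix(newdata)[, object@subset, drop = FALSE]
    } else if (is.matrix(newdata)) {
        m <- newdata
        if (!is.null(colnames(m))) m <- m[, object@subset, drop = FALSE]
        if (ncol(m) != d)
            stop("expected ", d, " descriptor columns, got ", ncol(m))
    } else {
        if (length(newdata) != d)
            stop("expected ", d, " descriptor values (order: ",
                 paste(object@subset, collapse = ", "), "), got ",
                 length(newdata))
        m <- matrix(as.numeric(newdata), nrow = 1L)
    }
    drop(object@intercept + m %*% object@coefficients)
})

#' Partial F statistic for adding or removing one descriptor
#'
#' The nested-model F-ratio that gates forward-stepwise entry and backward
#' elimination:
#' \deqn{F = \frac{RSS_{small} - RSS_{big}}{RSS_{big} / (n - d_{big} - 1)}}
#' where the "big" model contains the candidate descriptor and the "small"
#' model omits it. With `direction = "enter"` the big model is
#' `baseSubset + candidate`; with `"remove"` it is `baseSubset` itself.
#' A perfect big model (`RSS_big = 0`) returns `+Inf`. A singular big-model
#' design (e.g. the candidate duplicates a base descriptor) raises an
#' error, which the stepwise drivers convert to "candidate rejected".
#'
#' @param table a [DescriptorTable-class].
#' @param baseSubset character, current descriptor subset.
#' @param candidate a single descriptor name (outside `baseSubset` for
#'   `"enter"`, inside it for `"remove"`).
#' @param direction `"enter"` or `"remove"`.
#' @return the F statistic (non-negative; possibly `+Inf`).
#' @export
fToChange <- function(table, baseSubset, candidate,
                      direction = c("enter", "remove")) {
    stopifnot(is(table, "DescriptorTable"), length(candidate) == 1L)
    direction <- match.arg(direction)
    baseSubset <- as.character(baseSubset)
    pool <- table@descriptorNames
    if (!candidate %in% pool) stop("unknown descriptor: ", candidate)
    if (anyNA(match(baseSubset, pool)))
        stop("baseSubset contains names not in the pool")
    if (direction == "enter") {
        if (candidate %in% baseSubset)
            stop("candidate already in baseSubset")
        small <- baseSubset
        big <- c(baseSubset, candidate)
    } else {
        if (!candidate %in% baseSubset)
            stop("candidate not in baseSubset")
        big <- baseSubset
        small <- setdiff(baseSubset, candidate)
    }
    X <- table@X
    y <- table@y
    n <- length(y)
    rssSmall <- if (length(small)) ols_rss(X, y, match(small, pool))
                else sum((y - mean(y))^2)
    rssBig <- ols_rss(X, y, match(big, pool))
    if (!is.finite(rssBig))
        stop("singular design when fitting {",
             paste(big, collapse = ", "), "}")
    if (!is.finite(rssSmall))
        stop("singular design when fitting {",
             paste(small, collapse = ", "), "}")
    dfBig <- n - length(big) - 1L
    if (dfBig < 1L) stop("no residual degrees of freedom for the big model")
    partial_F(rssSmall, rssBig, dfBig)
}

#' @describeIn evaluateModel predictions, \eqn{R^2} and residual standard
#'   deviation \eqn{S = \sqrt{RSS/(n - d - 1)}} of a linear subset model on
#'   any table containing its descriptors.
#' @export
setMethod("evaluateModel", c("SubsetModel", "DescriptorTable"),
    function(model, table) {
        pred <- predict(model, table)
        y <- table@y
        n <- length(y)
        rss <- sum((y - pred)^2)
        tss <- sum((y - mean(y))^2)
        R2 <- if (tss == 0) 0 else 1 - rss / tss
        dfree <- n - length(model@subset) - 1L
        S <- if (dfree >= 1L) sqrt(rss / dfree) else NA_real_
        names(pred) <- table@compoundIds
        list(R2 = R2, S = S, predictions = pred)
    })

## ---- JSON serialization --------------------------------------------------

#' Serialize a subset model to JSON
#'
#' Writes a flat JSON document (subset names, intercept, coefficients,
#' standard errors, S, R2, n_obs) so fitted or published linear models can
#' be stored and re-evaluated. Unknown fields in a published model (e.g.
#' standard errors never printed) are stored as `null` and read back as NA.
#'
#' @param model a [SubsetModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readSubsetModel()]
#' @export
writeSubsetModel <- function(model, path) {
    stopifnot(is(model, "SubsetModel"))
    doc <- list(type = "SubsetModel",
                subset = as.list(model@subset),
                intercept = model@intercept,
                coefficients = as.list(model@coefficients),
                std_errors = as.list(model@stdErrors),
                S = model@S, R2 = model@R2, n_obs = model@nObs)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
    invisible(path)
}

#' Read a subset model from JSON
#'
#' @param path a JSON file written by [writeSubsetModel()] (or hand-written
#'   in the same layout, e.g. a published model).
#' @return a [SubsetModel-class].
#' @export
readSubsetModel <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    subset <- as.character(doc$subset)
    d <- length(subset)
    num <- function(x, len) {
        if (is.null(x)) return(rep(NA_real_, len))
        out <- as.numeric(x)
        if (length(out) != len) stop("field length mismatch in ", path)
        out
    }
    coefs <- num(doc$coefficients, d)
    se <- num(doc$std_errors, d)
    relerr <- ifelse(is.na(se) | is.na(coefs), NA_real_,
                     ifelse(coefs == 0, Inf, se / abs(coefs)))
    new("SubsetModel", subset = subset,
        intercept = as.numeric(doc$intercept),
        coefficients = coefs, stdErrors = se, relativeErrors = relerr,
        S = if (is.null(doc$S)) NA_real_ else as.numeric(doc$S),
        R2 = if (is.null(doc$R2)) NA_real_ else as.numeric(doc$R2),
        nObs = if (is.null(doc$n_obs)) NA_integer_ else as.integer(doc$n_obs))
}
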