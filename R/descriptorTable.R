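#' Construct a descriptor table from a matrix and a response
#'
#' Builds and validates a [DescriptorTable-class] directly from in-memory
#' objects. Most users will instead load a CSV with
#' [readDescriptorTable()] or simulate one with [generateDataset()].
#'
#' @param X numeric matrix, compounds in rows and descriptors in columns.
#'   Column names are used as descriptor names when `descriptorNames` is
#'   missing; row names as compound ids when `compoundIds` is missing.
#' @param y numeric response vector (one value per compound), typically the
#'   flux enhancement ratio ER.
#' @param compoundIds,descriptorNames optional character labels.
#' @param responseName name of the response column, default `"ER"`.
#' @param responseTransform `"identity"` or `"log10"`; records how `y` is
#'   expressed, it does not transform.
#' @return a validated [DescriptorTable-class].
#' @examples
#' X <- matrix(rnorm(20), 10, 2,
#'             dimnames = list(paste0("c", 1:10), c("logP", "dipole")))
#' dt <- DescriptorTable(X, rowSums(X) + 1)
#' dt
#' @export
DescriptorTable <- function(X, y, compoundIds = rownames(X),
                            descriptorNames = colnames(X),
                            responseName = "ER",
                            responseTransform = c("identity", "log10")) {
    responseTransform <- match.arg(responseTransform)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(compoundIds)) compoundIds <- sprintf("compound_%03d", seq_len(nrow(X)))
    if (is.null(descriptorNames)) descriptorNames <- sprintf("descriptor_%02d", seq_len(ncol(X)))
    new("DescriptorTable",
        compoundIds = as.character(compoundIds),
        descriptorNames = as.character(descriptorNames),
        X = unname(X),
        y = as.numeric(y),
        responseName = responseName,
        responseTransform = responseTransform)
}

#' Read a descriptor table from CSV
#'
#' Expects a comma-separated file with a header row: the first column holds
#' compound identifiers, one column (named by `responseColumn`) holds the
#' response, and every other column is a numeric molecular descriptor.
#' Decimal point is `"."`; scientific notation is accepted. The file's
#' descriptor column order is preserved.
#'
#' @param path path to a CSV file.
#' @param responseColumn name of the response column, default `"ER"`.
#' @return a validated [DescriptorTable-class].
#' @seealso [writeDescriptorTable()] for the inverse operation.
#' @export
readDescriptorTable <- function(path, responseColumn = "ER") {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
    if (ncol(raw) < 2L)
        stop("descriptor CSV needs an id column, descriptors and a response")
    idCol <- names(raw)[1L]
    if (!responseColumn %in% names(raw))
        stop("response column '", responseColumn, "' not found in ", path)
    if (responseColumn == idCol)
        stop("response column cannot be the identifier column")
    ids <- raw[[idCol]]
    if (anyDuplicated(ids))
        stop("duplicate compound ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    descCols <- setdiff(names(raw), c(idCol, responseColumn))
    if (anyDuplicated(names(raw)))
        stop("duplicate column names in ", path)

    parseNum <- function(txt, column) {
        txt <- trimws(txt)
        out <- suppressWarnings(as.numeric(txt))
        bad <- which(is.na(out) | txt == "")
        if (length(bad))
            stop("non-numeric value in column '", column, "', row ",
                 bad[1L], " (compound '", ids[bad[1L]], "'): '",
                 txt[bad[1L]], "'")
        out
    }
    X <- vapply(descCols, function(cn) parseNum(raw[[cn]], cn),
                numeric(nrow(raw)))
    if (nrow(raw) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, descCols))
    y <- parseNum(raw[[responseColumn]], responseColumn)
    DescriptorTable(X, y, compoundIds = ids, descriptorNames = descCols,
                    responseName = responseColumn)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [readDescriptorTable()]: first column `compound`, then the
#' descriptor columns in table order, then the response column. Values are
#' written with full double precision (up to 17 significant digits) so a
#' read/write round trip reproduces the table.
#'
#' @param table a [DescriptorTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDescriptorTable <- function(table, path) {
    stopifnot(is(table, "DescriptorTable"))
    fmt <- function(v) formatC(v, format = "g", digits = 17)
    df <- data.frame(compound = table@compoundIds, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (j in seq_along(table@descriptorNames))
        df[[table@descriptorNames[j]]] <- fmt(table@X[, j])
    df[[table@responseName]] <- fmt(table@y)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Validate a descriptor pool against an intended subset size
#'
#' Checks that asking for `M` descriptors out of this table is statistically
#' sensible, and flags degenerate descriptor columns. Constant-valued
#' columns are flagged in the returned table (slot `constantDescriptors`) —
#' not dropped, so column indexing still matches the source file — and the
#' subset-search functions treat flagged names as never selectable. A
#' warning is issued when `M` exceeds one fifth of the number of compounds
#' (the usual guard against chance correlation in QSAR work: with 61
#' compounds, 8 descriptors pass since 8 < 61/5); an error is raised when
#' `M >= nObs - 1`, where an intercept-containing fit runs out of degrees
#' of freedom.
#'
#' @param table a [DescriptorTable-class].
#' @param subsetSize intended subset size M (>= 1).
#' @return the table, with `constantDescriptors` populated.
#' @export
validatePool <- function(table, subsetSize) {
    stopifnot(is(table, "DescriptorTable"))
    M <- as.integer(subsetSize)
    if (is.na(M) || M < 1L) stop("subsetSize must be a positive integer")
    n <- nObs(table)
    if (M >= n - 1L)
        stop("subset size ", M, " cannot be fitted with only ", n,
             " compounds (need M <= nObs - 2)")
    if (M > n / 5)
        warning("subset size ", M, " exceeds one fifth of the ", n,
                " compounds; selected models risk chance correlation",
                call. = FALSE)
    rng <- apply(table@X, 2L, function(col) diff(range(col)))
    flagged <- table@descriptorNames[rng == 0]
    if (length(flagged))
        warning("constant descriptor column(s) flagged as unselectable: ",
                paste(flagged, collapse = ", "), call. = FALSE)
    table@constantDescriptors <- flagged
    validObject(table)
    table
}

#' Transform the response of a descriptor table
#'
#' Returns a new table whose response is either unchanged (`"identity"`) or
#' replaced by its base-10 logarithm (`"log10"`), with the transform
#' recorded in the object. Modelling log10(ER) instead of ER is a common
#' convention in the skin-permeation literature. The log10 transform
#' requires every response value to be strictly positive. Applying a
#' transform to an already-transformed table is refused rather than
#' silently compounded.
#'
#' @param table a [DescriptorTable-class] with `responseTransform ==
#'   "identity"`.
#' @param mode `"identity"` or `"log10"`.
#' @return a new [DescriptorTable-class].
#' @export
transformResponse <- function(table, mode = c("identity", "log10")) {
    stopifnot(is(table, "DescriptorTable"))
    mode <- match.arg(mode)
    if (mode == "identity") return(table)
    if (table@responseTransform != "identity")
        stop("response already transformed (", table@responseTransform, ")")
    bad <- which(table@y <= 0)
    if (length(bad))
        stop("log10 transform needs strictly positive responses; offending compound(s): ",
             paste(table@compoundIds[bad], collapse = ", "))
    table@y <- log10(table@y)
    table@responseTransform <- "log10"
    validObject(table)
    table
}

#' Restrict a descriptor table to a descriptor subset
#'
#' Keeps only the named descriptor columns (in the given order). Useful for
#' handing the selected subset to [trainAnn()].
#'
#' @param table a [DescriptorTable-class].
#' @param subset character vector of descriptor names present in the table.
#' @return a new [DescriptorTable-class] with `length(subset)` columns.
#' @export
selectDescriptors <- function(table, subset) {
    stopifnot(is(table, "DescriptorTable"))
    idx <- match(subset, table@descriptorNames)
    if (anyNA(idx))
        stop("unknown descriptor(s): ",
             paste(subset[is.na(idx)], collapse = ", "))
    table@X <- table@X[, idx, drop = FALSE]
    table@descriptorNames <- table@descriptorNames[idx]
    table@constantDescriptors <- intersect(table@constantDescriptors, subset)
    validObject(table)
    table
}
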