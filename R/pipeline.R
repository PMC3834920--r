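# End-to-end orchestration: load a descriptor table, run several selection
# methods at a common subset size, render the method-comparison table
# (one row per pool descriptor, one column per method), then train and
# evaluate the refinement network on the winning subset. The single run
# seed fans out to stage-specific sub-seeds so each stage is independently
# reproducible.

#' Read a pipeline run configuration from JSON
#'
#' Recognised fields (all optional unless noted): `input` (CSV path,
#' required for file-based runs), `response` (default `"ER"`),
#' `response_transform` (`"identity"`/`"log10"`), `subset_size` (default
#' 8), `methods` (default erm, rm, forward_stepwise), `f_enter`,
#' `f_remove`, `train_fraction`, `max_iterations`, `seed`, `out_dir`.
#'
#' @param path JSON file.
#' @return a named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(input = doc$input,
         response = doc$response %||% "ER",
         responseTransform = doc$response_transform %||% "identity",
         subsetSize = as.integer(doc$subset_size %||% 8L),
         methods = as.character(doc$methods %||%
                                c("erm", "rm", "forward_stepwise")),
         FEnter = as.numeric(doc$f_enter %||% 4.0),
         FRemove = as.numeric(doc$f_remove %||% 4.0),
         trainFraction = as.numeric(doc$train_fraction %||% 0.75),
         maxIterations = as.integer(doc$max_iterations %||% 150L),
         seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed),
         outDir = doc$out_dir)
}

#' Run several selection methods and build a comparison report
#'
#' Applies each requested method to the table at subset size `M` and
#' assembles the conventional comparison layout: header rows for
#' \eqn{R^2}, intercept, S and N, then one row per pool descriptor with the
#' fitted coefficient in each method's column (blank where the method did
#' not select the descriptor).
#'
#' @param table a [DescriptorTable-class] (or a CSV path, read with the
#'   `response` column).
#' @param M subset size (default 8).
#' @param methods methods to run (see [recoveryExperiment()] for names).
#' @param seed run seed; fanned out per stage.
#' @param FEnter,FRemove stepwise thresholds.
#' @param response response column name when `table` is a path.
#' @param responseTransform `"identity"` or `"log10"`.
#' @return a list of class `"selectionReport"`: `results` (named list of
#'   [SearchResult-class]), `stats` (data.frame of R2/intercept/S/N per
#'   method), `coefficients` (descriptor-by-method data.frame), `M`,
#'   `seed`.
#' @export
runSelectionReport <- function(table, M = 8L,
                               methods = c("erm", "rm", "forward_stepwise"),
                               seed = NULL, FEnter = 4.0, FRemove = 4.0,
                               response = "ER",
                               responseTransform = c("identity", "log10")) {
    responseTransform <- match.arg(responseTransform)
    if (is.character(table))
        table <- readDescriptorTable(table, responseColumn = response)
    stopifnot(is(table, "DescriptorTable"))
    table <- withCallingHandlers(
        validatePool(table, M),
        warning = function(w) {
            message("note: ", conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    table <- transformResponse(table, responseTransform)

    results <- list()
    for (k in seq_along(methods)) {
        m <- methods[k]
        message("stage ", m, ": selecting ", M, " of ", poolSize(table),
                " descriptors")
        res <- run_selection_method(table, m, M,
                                    seed = derive_seed(seed, k),
                                    FEnter = FEnter, FRemove = FRemove)
        message("stage ", m, ": S = ", format(modelS(res), digits = 6),
                ", R2 = ", format(modelR2(res), digits = 4),
                " (", nFits(res), " fits)")
        results[[m]] <- res
    }

    stats <- data.frame(
        method = names(results),
        R2 = vapply(results, modelR2, numeric(1)),
        intercept = vapply(results, function(r) r@bestModel@intercept,
                           numeric(1)),
        S = vapply(results, modelS, numeric(1)),
        N = vapply(results, function(r) nObs(r@bestModel), numeric(1)),
        row.names = NULL)

    coefTab <- data.frame(row.names = descriptorNames(table))
    for (m in names(results)) {
        mod <- results[[m]]@bestModel
        col <- rep(NA_real_, poolSize(table))
        col[match(mod@subset, descriptorNames(table))] <- mod@coefficients
        coefTab[[m]] <- col
    }

    structure(list(results = results, stats = stats,
                   coefficients = coefTab, M = M, seed = seed,
                   response = responseName(table),
                   responseTransform = responseTransform(table)),
              class = "selectionReport")
}

#' @export
print.selectionReport <- function(x, digits = 4, ...) {
    cat("Descriptor-selection comparison (M =", x$M, ")\n\n")
    hdr <- t(x$stats[, c("R2", "intercept", "S", "N")])
    colnames(hdr) <- x$stats$method
    print(round(hdr, digits))
    cat("\nCoefficients (blank = descriptor not selected):\n")
    fmt <- format(round(x$coefficients, digits))
    fmt[is.na(x$coefficients)] <- ""
    print(fmt)
    invisible(x)
}

#' Write a selection report to a directory
#'
#' Writes one `SearchResult` JSON per method, a combined `report.json`
#' (stats plus the descriptor-by-method coefficient table), and a rendered
#' plain-text `report.txt`.
#'
#' @param report a `"selectionReport"` from [runSelectionReport()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSelectionReport <- function(report, dir) {
    stopifnot(inherits(report, "selectionReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(report$results))
        writeSearchResult(report$results[[m]],
                          file.path(dir, paste0("selection_", m, ".json")))
    doc <- list(type = "selectionReport", M = report$M,
                seed = report$seed,
                response = report$response,
                response_transform = report$responseTransform,
                stats = report$stats,
                descriptors = rownames(report$coefficients),
                coefficients = report$coefficients)
    jsonlite::write_json(doc, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns", pretty = TRUE)
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(dir, "report.txt"))
    invisible(dir)
}

#' Train and evaluate the refinement network on a selected subset
#'
#' Restricts the table to the selected descriptors, splits compounds into
#' training and testing partitions, trains the feed-forward network on the
#' training partition, and reports train/test \eqn{R^2} for both the
#' network and the OLS model refitted on the same training partition,
#' together with per-compound predicted-versus-observed pairs.
#'
#' @param table a [DescriptorTable-class] containing the selected
#'   descriptors.
#' @param selected a [SearchResult-class], a [SubsetModel-class], or a
#'   character vector of descriptor names.
#' @param config an [annTrainConfig()]; its `trainFraction` and `seed`
#'   drive the split (seed offset by one stage) and the weight
#'   initialisation.
#' @return a list of class `"annReport"`: `model` (the [AnnModel-class]),
#'   `history`, `iterations`, `trainR2`, `testR2`, `trainR2Linear`,
#'   `testR2Linear`, `nTrain`, `nTest`, and `predictions` (data.frame:
#'   compound, observed, predicted, predictedLinear, partition).
#' @export
runAnnReport <- function(table, selected, config = annTrainConfig()) {
    stopifnot(is(table, "DescriptorTable"))
    subset <- if (is(selected, "SearchResult")) subsetNames(selected)
              else if (is(selected, "SubsetModel")) selected@subset
              else as.character(selected)
    tab <- selectDescriptors(table, subset)
    parts <- splitTrainTest(tab, trainFraction = config$trainFraction,
                            seed = derive_seed(config$seed, 1L))
    fit <- trainAnn(parts$train, config)
    linear <- fitSubset(parts$train, subset)

    evTrain <- evaluateModel(fit$model, parts$train)
    evTest <- evaluateModel(fit$model, parts$test)
    evTrainLin <- evaluateModel(linear, parts$train)
    evTestLin <- evaluateModel(linear, parts$test)

    preds <- rbind(
        data.frame(compound = compoundIds(parts$train),
                   observed = unname(response(parts$train)),
                   predicted = unname(evTrain$predictions),
                   predictedLinear = unname(evTrainLin$predictions),
                   partition = "train"),
        data.frame(compound = compoundIds(parts$test),
                   observed = unname(response(parts$test)),
                   predicted = unname(evTest$predictions),
                   predictedLinear = unname(evTestLin$predictions),
                   partition = "test"))

    structure(list(model = fit$model, history = as.numeric(fit$history),
                   iterations = length(fit$history),
                   trainR2 = evTrain$R2, testR2 = evTest$R2,
                   trainR2Linear = evTrainLin$R2,
                   testR2Linear = evTestLin$R2,
                   nTrain = nObs(parts$train), nTest = nObs(parts$test),
                   subset = subset, predictions = preds),
              class = "annReport")
}

#' @export
print.annReport <- function(x, digits = 4, ...) {
    cat(sprintf("ANN refinement report (%d:%d:1 network)\n",
                length(x$subset), nrow(x$model@WHidden)))
    cat(sprintf("  partitions: %d train / %d test\n", x$nTrain, x$nTest))
    cat(sprintf("  iterations: %d\n", x$iterations))
    cat(sprintf("  train R2: %.4f (ANN) vs %.4f (linear)\n",
                x$trainR2, x$trainR2Linear))
    cat(sprintf("  test  R2: %.4f (ANN) vs %.4f (linear)\n",
                x$testR2, x$testR2Linear))
    invisible(x)
}

#' Write an ANN report to a directory
#'
#' Writes the trained network (`ann_model.json`), the per-iteration MSE
#' history (`ann_history.csv`) and the per-compound
#' predicted-versus-observed pairs with partition labels
#' (`ann_predictions.csv`), plus a combined `ann_report.json`.
#'
#' @param report an `"annReport"` from [runAnnReport()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAnnReport <- function(report, dir) {
    stopifnot(inherits(report, "annReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeAnnModel(report$model, file.path(dir, "ann_model.json"))
    utils::write.csv(data.frame(iteration = seq_along(report$history),
                                mse = report$history),
                     file.path(dir, "ann_history.csv"), row.names = FALSE)
    utils::write.csv(report$predictions,
                     file.path(dir, "ann_predictions.csv"),
                     row.names = FALSE)
    doc <- list(type = "annReport", subset = as.list(report$subset),
                iterations = report$iterations,
                n_train = report$nTrain, n_test = report$nTest,
                train_R2 = report$trainR2, test_R2 = report$testR2,
                train_R2_linear = report$trainR2Linear,
                test_R2_linear = report$testR2Linear)
    jsonlite::write_json(doc, file.path(dir, "ann_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    invisible(dir)
}
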