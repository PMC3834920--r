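# The seeded instances here use the synthetic generator at small geometry
# so the exhaustive oracle can certify the heuristics' answers in-test.

small_instance <- function(seed, nObs = 25, nPool = 8, k = 2,
                           noise = 0.1) {
    spec <- syntheticSpec(nObs = nObs, nPool = nPool, trueSubsetSize = k,
                          trueCoefficients = rep(1, k), noiseSd = noise,
                          seed = seed)
    generateDataset(spec)$table
}

test_that("RM with no freedom returns the single possible subset", {
    tab <- random_table(n = 20, p = 3, seed = 4)
    res <- rmSelect(tab, 3, seed = 1)
    expect_setequal(subsetNames(res), c("d1", "d2", "d3"))
    direct <- fitSubset(tab, subsetNames(res))
    expect_equal(modelS(res), modelS(direct))
})

test_that("RM attains the exhaustive optimum on the pinned instance", {
    tab <- small_instance(seed = 7)
    rm <- rmSelect(tab, 2, seed = 7)
    oracle <- exhaustiveBestSubset(tab, 2)
    expect_equal(modelS(rm), modelS(oracle), tolerance = 1e-12)
})

test_that("RM path traces are monotone non-increasing in S", {
    for (seed in c(3, 7, 19)) {
        tab <- small_instance(seed = seed, noise = 0.5)
        res <- rmSelect(tab, 2, seed = seed)
        stages <- vapply(searchTrace(res), `[[`, character(1), "stage")
        for (p in unique(stages)) {
            Ss <- vapply(searchTrace(res)[stages == p], `[[`,
                         numeric(1), "S")
            expect_false(is.unsorted(rev(Ss)),
                         info = paste("seed", seed, p))
        }
        # best-ever contract: the returned S bounds every traced S
        allS <- vapply(searchTrace(res), `[[`, numeric(1), "S")
        expect_lte(modelS(res), min(allS) + 1e-12)
    }
})

test_that("MRM forces uphill moves and stops on subset recurrence", {
    # seed chosen (by scanning the generator) to exhibit a forced move
    # that increases S and a return to a visited subset
    tab <- small_instance(seed = 1, noise = 0.5)
    rm <- rmSelect(tab, 2, seed = 1)
    mr <- mrmSelect(tab, 2, initSubset = subsetNames(rm))
    Ss <- vapply(searchTrace(mr), `[[`, numeric(1), "S")
    expect_true(any(diff(Ss) > 0))            # at least one uphill move
    keys <- vapply(searchTrace(mr), function(s)
        paste(sort(s$subset), collapse = "|"), character(1))
    # recurrence terminated the walk: only the final state repeats
    expect_false(anyDuplicated(keys[-length(keys)]) > 0)
    expect_true(keys[length(keys)] %in% keys[-length(keys)] ||
                length(Ss) - 1L <= 2L * 2L)   # ... or maxCycles hit
    # best-ever contract despite wandering
    expect_lte(modelS(mr), min(Ss) + 1e-12)
})

test_that("MRM started at the optimum still reports the optimum", {
    tab <- small_instance(seed = 7)
    oracle <- exhaustiveBestSubset(tab, 2)
    mr <- mrmSelect(tab, 2, initSubset = subsetNames(oracle))
    expect_equal(modelS(mr), modelS(oracle), tolerance = 1e-12)
})

test_that("ERM dominates RM and matches the oracle on the pinned instance", {
    for (seed in c(1, 7, 23)) {
        tab <- small_instance(seed = seed, noise = 0.5)
        rm <- rmSelect(tab, 2, seed = seed)
        erm <- ermSelect(tab, 2, seed = seed)
        expect_lte(modelS(erm), modelS(rm) + 1e-12)
    }
    tab <- small_instance(seed = 7)
    erm <- ermSelect(tab, 2, seed = 7)
    oracle <- exhaustiveBestSubset(tab, 2)
    expect_equal(modelS(erm), modelS(oracle), tolerance = 1e-12)
})

test_that("single-descriptor pool reduces ERM to a direct fit", {
    tab <- random_table(n = 15, p = 1, seed = 2)
    erm <- ermSelect(tab, 1, seed = 2)
    expect_equal(subsetNames(erm), "d1")
    expect_equal(modelS(erm), modelS(fitSubset(tab, "d1")))
})

test_that("search results are deterministic given table, M and seed", {
    tab <- small_instance(seed = 9, nPool = 10, k = 3, noise = 0.5)
    a <- ermSelect(tab, 3, seed = 17)
    b <- ermSelect(tab, 3, seed = 17)
    expect_identical(subsetNames(a), subsetNames(b))
    expect_identical(searchTrace(a), searchTrace(b))
    expect_identical(nFits(a), nFits(b))
})

test_that("flagged constant descriptors are never selected", {
    tab <- random_table(n = 30, p = 5, seed = 6)
    X <- descriptorMatrix(tab)
    X[, "d2"] <- 1
    tab2 <- suppressWarnings(validatePool(DescriptorTable(X, response(tab)), 2))
    for (res in list(rmSelect(tab2, 2, seed = 3),
                     ermSelect(tab2, 2, seed = 3),
                     forwardStepwise(tab2, 2),
                     exhaustiveBestSubset(tab2, 2)))
        expect_false("d2" %in% subsetNames(res))
    expect_error(rmSelect(tab2, 2, initSubset = c("d1", "d2")),
                 "constant")
})

test_that("forward stepwise picks the true predictor first and nests", {
    X <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(NULL, paste0("d", 1:4)))
    tab <- DescriptorTable(X, 3 * X[, "d3"])          # noiseless
    res <- forwardStepwise(tab, 3)
    first <- searchTrace(res)[[2]]$subset
    expect_identical(first, "d3")
    # strictly nested, growing by one
    sizes <- vapply(searchTrace(res), function(s) length(s$subset),
                    integer(1))
    expect_identical(sizes, seq_along(sizes) - 1L)
    for (i in seq_len(length(searchTrace(res)) - 1L))
        expect_true(all(searchTrace(res)[[i]]$subset %in%
                        searchTrace(res)[[i + 1]]$subset))
})

test_that("forward stepwise returns the empty model when no F qualifies", {
    set.seed(99)
    X <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(NULL, paste0("d", 1:5)))
    y <- rnorm(30)
    tab <- DescriptorTable(X, y)
    # compute every first-step F directly and pick a threshold above them
    allF <- vapply(paste0("d", 1:5), function(d)
        fToChange(tab, character(0), d, "enter"), numeric(1))
    res <- forwardStepwise(tab, 5, FEnter = max(allF) + 1)
    expect_length(subsetNames(res), 0)
    expect_equal(modelR2(res), 0)
})

test_that("backward elimination drops noise before signal", {
    set.seed(12)
    X <- matrix(rnorm(30 * 3), 30, 3,
                dimnames = list(NULL, c("signal", "noise1", "noise2")))
    tab <- DescriptorTable(X, 4 * X[, "signal"] + rnorm(30, 0, 0.1))
    start <- c("signal", "noise1", "noise2")
    fs <- vapply(start, function(d) fToChange(tab, start, d, "remove"),
                 numeric(1))
    res <- backwardEliminate(tab, start, FRemove = 4)
    firstRemoved <- setdiff(start, searchTrace(res)[[2]]$subset)
    expect_identical(firstRemoved, names(which.min(fs)))
    expect_true("signal" %in% subsetNames(res))

    # a perfect predictor has infinite F and survives any threshold
    perfect <- DescriptorTable(X, 2 * X[, "signal"])
    keep <- backwardEliminate(perfect, "signal", FRemove = 1e6)
    expect_identical(subsetNames(keep), "signal")
    # F threshold zero removes nothing
    res0 <- backwardEliminate(tab, start, FRemove = 0)
    expect_setequal(subsetNames(res0), start)
})

test_that("exhaustive enumeration counts fits and respects its budget", {
    tab <- random_table(n = 20, p = 5, seed = 14)
    res <- exhaustiveBestSubset(tab, 2)
    expect_identical(nFits(res), 10L)            # C(5,2)
    expect_error(exhaustiveBestSubset(tab, 2, budget = 5), "budget")
    # global-minimum contract against every heuristic
    for (heur in list(rmSelect(tab, 2, seed = 1),
                      ermSelect(tab, 2, seed = 1),
                      forwardStepwise(tab, 2, FEnter = 1e-6)))
        expect_lte(modelS(res), modelS(heur) + 1e-12)
})

test_that("search result JSON serialization is complete", {
    tab <- random_table(n = 20, p = 4, seed = 16)
    res <- ermSelect(tab, 2, seed = 5)
    path <- tempfile(fileext = ".json")
    writeSearchResult(res, path)
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_identical(doc$method, "erm")
    expect_equal(doc$S, modelS(res))
    expect_identical(as.character(doc$subset), subsetNames(res))
    expect_equal(doc$n_fits, nFits(res))
    expect_true(length(doc$trace$S) >= 1)
})
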