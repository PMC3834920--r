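test_that("CSV reading preserves shape, order and values", {
    csv <- tempfile(fileext = ".csv")
    writeLines(c("compound,logP,dipole,ER",
                 "cpd1,1.5,0.2,3.1",
                 "cpd2,-0.4,1.1,0.9",
                 "cpd3,2.25,0.05,7.4"), csv)
    tab <- readDescriptorTable(csv)
    expect_s4_class(tab, "DescriptorTable")
    expect_equal(nObs(tab), 3L)
    expect_equal(poolSize(tab), 2L)
    expect_equal(descriptorNames(tab), c("logP", "dipole"))
    expect_equal(compoundIds(tab), c("cpd1", "cpd2", "cpd3"))
    expect_equal(unname(response(tab)), c(3.1, 0.9, 7.4))
    expect_equal(descriptorMatrix(tab)["cpd3", "logP"], 2.25)
})

test_that("CSV parse and validation errors identify the offender", {
    csv <- tempfile(fileext = ".csv")
    writeLines(c("compound,logP,ER", "cpd1,1.5,3.1", "cpd2,,0.9"), csv)
    expect_error(readDescriptorTable(csv), "logP.*row 2|row 2.*logP")

    writeLines(c("compound,logP,ER", "cpd1,1.5,3.1", "cpd1,0.4,0.9"), csv)
    expect_error(readDescriptorTable(csv), "duplicate compound ids")

    writeLines(c("compound,logP,ER", "cpd1,1.5,3.1"), csv)
    expect_error(readDescriptorTable(csv, responseColumn = "flux"),
                 "response column 'flux'")
})

test_that("write/read round trip reproduces a seeded table bit-identically", {
    tab <- random_table(n = 15, p = 4, seed = 42)
    csv <- tempfile(fileext = ".csv")
    writeDescriptorTable(tab, csv)
    back <- readDescriptorTable(csv)
    expect_identical(descriptorMatrix(back), descriptorMatrix(tab))
    expect_identical(response(back), response(tab))
    expect_identical(descriptorNames(back), descriptorNames(tab))
})

test_that("construction rejects inconsistent or non-finite input", {
    X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(DescriptorTable(X, y = 1:2), "response")
    Xbad <- X; Xbad[2, 1] <- NA
    expect_error(DescriptorTable(Xbad, y = 1:3), "non-finite")
    expect_error(DescriptorTable(X, y = 1:3,
                                 descriptorNames = c("a", "a")),
                 "duplicate")
})

test_that("validatePool applies the one-fifth rule and flags constants", {
    big <- random_table(n = 61, p = 10, seed = 3)
    expect_silent(validatePool(big, 8))          # 8 < 61/5
    small <- random_table(n = 30, p = 10, seed = 3)
    expect_warning(validatePool(small, 8), "one fifth")
    expect_error(validatePool(small, 29), "compounds")

    X <- descriptorMatrix(big)
    X[, "d4"] <- 7
    const <- DescriptorTable(X, response(big))
    flagged <- suppressWarnings(validatePool(const, 3))
    expect_identical(constantDescriptors(flagged), "d4")
    # flagging never mutates the data
    expect_identical(descriptorMatrix(flagged), descriptorMatrix(const))
    expect_identical(response(flagged), response(const))
})

test_that("response transform is exact, recorded, and guarded", {
    X <- matrix(rnorm(3), 3, 1, dimnames = list(NULL, "d1"))
    tab <- DescriptorTable(X, c(1, 10, 100))
    lg <- transformResponse(tab, "log10")
    expect_equal(unname(response(lg)), c(0, 1, 2))
    expect_identical(responseTransform(lg), "log10")
    expect_identical(response(transformResponse(tab, "identity")),
                     response(tab))
    bad <- DescriptorTable(X, c(1, 0, 100),
                           compoundIds = c("ok1", "zero", "ok2"))
    expect_error(transformResponse(bad, "log10"), "zero")
    expect_error(transformResponse(lg, "log10"), "already transformed")
})

test_that("selectDescriptors subsets columns in the requested order", {
    tab <- random_table(p = 4)
    sub <- selectDescriptors(tab, c("d3", "d1"))
    expect_equal(descriptorNames(sub), c("d3", "d1"))
    expect_equal(descriptorMatrix(sub)[, "d3"],
                 descriptorMatrix(tab)[, "d3"])
    expect_error(selectDescriptors(tab, "nope"), "unknown descriptor")
})
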