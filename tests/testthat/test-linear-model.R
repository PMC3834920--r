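test_that("a noiseless line is fitted exactly", {
    m <- fitSubset(line_table(), "x")
    expect_equal(m@intercept, 1, tolerance = 1e-10)
    expect_equal(m@coefficients, 2, tolerance = 1e-10)
    expect_lt(modelS(m), 1e-10)
    expect_equal(modelR2(m), 1, tolerance = 1e-12)
})

test_that("fit matches the normal-equations oracle on seeded tables", {
    for (seed in c(2, 9, 31)) {
        tab <- random_table(n = 20, p = 3, seed = seed)
        m <- fitSubset(tab, c("d1", "d2", "d3"))
        o <- normal_equations(tab, c("d1", "d2", "d3"))
        expect_equal(m@intercept, o$intercept, tolerance = 1e-8)
        expect_equal(m@coefficients, unname(o$coefficients),
                     tolerance = 1e-8)
        expect_equal(modelS(m), o$S, tolerance = 1e-8)
        expect_equal(modelR2(m), o$R2, tolerance = 1e-8)
        expect_equal(m@stdErrors, unname(o$se), tolerance = 1e-8)
        expect_equal(m@relativeErrors,
                     unname(o$se) / abs(m@coefficients), tolerance = 1e-8)
    }
})

test_that("degenerate and erroneous fits behave by convention", {
    X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
    const <- DescriptorTable(X, rep(5, 6))
    m <- fitSubset(const, c("a", "b"))
    expect_equal(modelR2(m), 0)
    expect_equal(m@coefficients, c(0, 0))

    dup <- DescriptorTable(cbind(X, c = X[, "a"]), rnorm(6))
    expect_error(fitSubset(dup, c("a", "c")), "singular|collinear")
    expect_error(fitSubset(const, "missing"), "not in pool")
    tiny <- DescriptorTable(X[1:3, ], rnorm(3))
    expect_error(fitSubset(tiny, c("a", "b")), "observations")
})

test_that("prediction is the stored affine map and self-consistent", {
    tab <- random_table(n = 25, p = 3, seed = 5)
    m <- fitSubset(tab, c("d2", "d3"))
    # on its own training rows, residuals reproduce RSS
    pred <- predict(m, tab)
    rss <- sum((unname(response(tab)) - pred)^2)
    expect_equal(sqrt(rss / (25 - 2 - 1)), modelS(m), tolerance = 1e-10)
    # zero-coefficient model returns the intercept
    m0 <- m; m0@coefficients <- c(0, 0)
    expect_equal(unname(predict(m0, c(3, -2))), m0@intercept)
    expect_error(predict(m, c(1, 2, 3)), "expected 2")
})

test_that("partial F agrees with an explicit two-fit computation", {
    tab <- random_table(n = 30, p = 4, seed = 11, coefs = c(2, 0, 0, 1))
    base <- c("d1", "d2")
    for (cand in c("d3", "d4")) {
        small <- fitSubset(tab, base)
        big <- fitSubset(tab, c(base, cand))
        rssS <- sum((unname(response(tab)) - predict(small, tab))^2)
        rssB <- sum((unname(response(tab)) - predict(big, tab))^2)
        fOracle <- (rssS - rssB) / (rssB / (30 - 3 - 1))
        expect_equal(fToChange(tab, base, cand, "enter"), fOracle,
                     tolerance = 1e-8)
        expect_equal(fToChange(tab, c(base, cand), cand, "remove"),
                     fOracle, tolerance = 1e-8)
    }
})

test_that("partial F handles collinear and perfect candidates", {
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    dup <- DescriptorTable(cbind(X, a2 = X[, "a"]), X[, 1] + rnorm(20))
    expect_error(fToChange(dup, "a", "a2", "enter"), "singular")
    perfect <- DescriptorTable(X, 3 * X[, "b"] - 1)
    expect_identical(fToChange(perfect, character(0), "b", "enter"), Inf)
})

test_that("residuals are orthogonal to every design column", {
    tab <- random_table(n = 40, p = 5, seed = 13)
    m <- fitSubset(tab, paste0("d", 1:5))
    r <- unname(response(tab)) - predict(m, tab)
    for (j in paste0("d", 1:5)) {
        x <- descriptorMatrix(tab)[, j]
        expect_lt(abs(sum(r * x)),
                  1e-8 * sqrt(sum(r^2)) * sqrt(sum(x^2)))
    }
    expect_lt(abs(sum(r)), 1e-8 * sqrt(sum(r^2)) * sqrt(40))
})

test_that("RSS never increases when a descriptor is added", {
    for (seed in 1:5) {
        tab <- random_table(n = 25, p = 6, seed = 100 + seed)
        subset <- sample(paste0("d", 1:6), 3)
        extra <- setdiff(paste0("d", 1:6), subset)[1]
        rss <- function(s) {
            m <- fitSubset(tab, s)
            sum((unname(response(tab)) - predict(m, tab))^2)
        }
        expect_lte(rss(c(subset, extra)), rss(subset) + 1e-10)
    }
})

test_that("S and R2 are invariant under affine descriptor rescaling", {
    tab <- random_table(n = 30, p = 3, seed = 21)
    m0 <- fitSubset(tab, c("d1", "d2"))
    X <- descriptorMatrix(tab)
    X[, "d1"] <- 100 * X[, "d1"] - 7
    tab2 <- DescriptorTable(X, response(tab))
    m1 <- fitSubset(tab2, c("d1", "d2"))
    expect_equal(modelS(m1), modelS(m0), tolerance = 1e-8)
    expect_equal(modelR2(m1), modelR2(m0), tolerance = 1e-8)
    expect_equal(m1@coefficients[1], m0@coefficients[1] / 100,
                 tolerance = 1e-8)
})

test_that("subset models survive a JSON round trip", {
    tab <- random_table(n = 20, p = 3, seed = 8)
    m <- fitSubset(tab, c("d1", "d3"))
    path <- tempfile(fileext = ".json")
    writeSubsetModel(m, path)
    back <- readSubsetModel(path)
    expect_equal(back@intercept, m@intercept)
    expect_equal(back@coefficients, m@coefficients)
    expect_equal(back@subset, m@subset)
    expect_equal(modelS(back), modelS(m))
})
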