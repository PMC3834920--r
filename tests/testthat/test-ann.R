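test_that("min-max scaling maps endpoints exactly and round-trips", {
    set.seed(31)
    v <- rnorm(25, 10, 4)
    sp <- fitScaling(v, columnNames = "v")
    sv <- applyScaling(sp, v)
    expect_equal(min(sv), 0.1)
    expect_equal(max(sv), 0.9)
    expect_equal(invertScaling(sp, sv), v, tolerance = 1e-10)

    M <- cbind(a = rnorm(10), b = runif(10, -5, 5))
    spm <- fitScaling(M)
    expect_equal(invertScaling(spm, applyScaling(spm, M)), M,
                 tolerance = 1e-10)

    const <- fitScaling(rep(3, 5), columnNames = "c")
    expect_equal(unname(applyScaling(const, c(3, 3))), c(0.5, 0.5))
    expect_equal(unname(invertScaling(const, c(0.5, 0.2))), c(3, 3))
})

test_that("printed slope/minimum scaling form reproduces published maps", {
    sp <- scalingFromSlopes("ER", slopes = 0.012, mins = 0.63)
    expect_equal(unname(applyScaling(sp, 0.63)), 0.1)
    # slope recovered: scaled value at min + 1 is lo + slope
    expect_equal(unname(applyScaling(sp, 1.63)), 0.1 + 0.012,
                 tolerance = 1e-12)
})

test_that("train/test split follows round-half-up and partitions exactly", {
    tab <- generateDataset(syntheticSpec(seed = 5))$table   # 61 compounds
    parts <- splitTrainTest(tab, 0.75, seed = 2)
    expect_equal(nObs(parts$train), 46)     # round(45.75) half up
    expect_equal(nObs(parts$test), 15)
    expect_length(intersect(compoundIds(parts$train),
                            compoundIds(parts$test)), 0)
    expect_setequal(c(compoundIds(parts$train), compoundIds(parts$test)),
                    compoundIds(tab))
    again <- splitTrainTest(tab, 0.75, seed = 2)
    expect_identical(compoundIds(again$train), compoundIds(parts$train))
    expect_error(splitTrainTest(tab, 0.001), "degenerate")
})

test_that("the network learns a noiseless linear map almost exactly", {
    set.seed(77)
    X <- matrix(runif(40, -2, 2), 40, 1, dimnames = list(NULL, "x"))
    tab <- DescriptorTable(X, 3 * X[, 1] - 1)
    fit <- trainAnn(tab, annTrainConfig(seed = 4))
    expect_gte(evaluateModel(fit$model, tab)$R2, 0.99)
})

test_that("training respects the iteration budget and best-ever contract", {
    tab <- selectDescriptors(
        generateDataset(syntheticSpec(nonlinearWeight = 2, noiseSd = 1,
                                      seed = 8))$table,
        generateDataset(syntheticSpec(seed = 8))$truth$subset)
    cfg <- annTrainConfig(seed = 10)
    fit <- trainAnn(tab, cfg)
    expect_lte(length(fit$history), 150)
    expect_lte(min(fit$history), attr(fit$history, "initial"))
    # final stored weights achieve the best MSE seen
    ys <- applyScaling(fit$model@responseScaling, unname(response(tab)))
    pred <- annPredict(fit$model, tab)
    mse <- mean((applyScaling(fit$model@responseScaling, pred) - ys)^2)
    expect_lte(mse, min(fit$history) + 1e-12)
})

test_that("training is deterministic under a fixed seed", {
    tab <- selectDescriptors(
        generateDataset(syntheticSpec(seed = 21))$table,
        paste0(c("Log P", "Kappa 2")))
    cfg <- annTrainConfig(seed = 33, maxIterations = 40)
    a <- trainAnn(tab, cfg)
    b <- trainAnn(tab, cfg)
    expect_identical(a$model@WHidden, b$model@WHidden)
    expect_identical(a$model@WOut, b$model@WOut)
    expect_identical(a$history, b$history)
})

test_that("gradient-descent rule also reduces the training loss", {
    set.seed(55)
    X <- matrix(runif(30, -1, 1), 30, 1, dimnames = list(NULL, "x"))
    tab <- DescriptorTable(X, X[, 1] + 0.2 * X[, 1]^2)
    fit <- trainAnn(tab, annTrainConfig(learningRule = "gradient_descent",
                                        seed = 3, nStarts = 1L))
    expect_lt(tail(fit$history, 1), attr(fit$history, "initial"))
})

test_that("prediction is monotone through positive-weight paths", {
    sp <- fitScaling(matrix(seq(0, 10, length.out = 5), 5, 1,
                            dimnames = list(NULL, "x")))
    ys <- scalingFromSlopes("y", slopes = 1, mins = 0)
    net <- new("AnnModel", inputNames = "x",
               WHidden = matrix(c(1.2, 0.7), 2, 1),
               bHidden = c(0.1, -0.3), WOut = c(0.8, 0.5), bOut = 0.2,
               activation = "sigmoid", outputActivation = "linear",
               inputScaling = sp, responseScaling = ys)
    xs <- seq(0, 10, length.out = 21)
    preds <- vapply(xs, function(x) annPredict(net, x), numeric(1))
    expect_false(is.unsorted(preds))
})

test_that("stored published hidden unit evaluates to its printed terms", {
    net <- readAnnModel(extdata("published_db1_ann_hidden_unit.json"))
    expect_equal(unname(hiddenPreactivation(net, rep(0, 8))), 23.4289)
    w <- c(-22.7143, 31.7314, 32.634, 8.81476, 0.274705, -62.4769,
           20.5876, -32.0392)
    # independent hand summation of the printed coefficients at 0.1
    expect_equal(unname(hiddenPreactivation(net, rep(0.1, 8))),
                 23.4289 + sum(w * 0.1), tolerance = 1e-12)
    expect_error(hiddenPreactivation(net, rep(0, 3)), "expected 8")
})

test_that("network models survive a JSON round trip", {
    tab <- selectDescriptors(
        generateDataset(syntheticSpec(seed = 2))$table,
        c("Log P", "Kappa 2"))
    fit <- trainAnn(tab, annTrainConfig(seed = 9, maxIterations = 30))
    path <- tempfile(fileext = ".json")
    writeAnnModel(fit$model, path)
    back <- readAnnModel(path)
    expect_equal(back@WHidden, fit$model@WHidden)
    expect_equal(back@bHidden, fit$model@bHidden)
    x <- descriptorMatrix(tab)[3, ]
    expect_equal(annPredict(back, x), annPredict(fit$model, x),
                 tolerance = 1e-12)
})

test_that("training end-quality matches an independent reference trainer", {
    skip_if_not_installed("nnet")
    gen <- generateDataset(syntheticSpec(nonlinearWeight = 2, noiseSd = 1,
                                         seed = 7))
    tab <- selectDescriptors(gen$table, gen$truth$subset)
    parts <- splitTrainTest(tab, 0.75, seed = 7)
    fit <- trainAnn(parts$train, annTrainConfig(seed = 7))
    ours <- evaluateModel(fit$model, parts$train)$R2

    # same architecture and scaled data, trained by nnet's BFGS
    Xs <- applyScaling(fit$model@inputScaling,
                       descriptorMatrix(parts$train))
    ys <- applyScaling(fit$model@responseScaling,
                       unname(response(parts$train)))
    set.seed(7)
    ref <- nnet::nnet(Xs, ys, size = 2, linout = TRUE, maxit = 500,
                      trace = FALSE)
    refPred <- invertScaling(fit$model@responseScaling,
                             drop(predict(ref, Xs)))
    y <- unname(response(parts$train))
    refR2 <- 1 - sum((y - refPred)^2) / sum((y - mean(y))^2)
    expect_gte(ours, refR2 - 0.05)
})

test_that("evaluateModel reports R2 on the raw response scale", {
    tab <- random_table(n = 20, p = 2, seed = 41, noise = 0)
    m <- fitSubset(tab, c("d1", "d2"))
    ev <- evaluateModel(m, tab)
    expect_equal(ev$R2, 1, tolerance = 1e-10)
    expect_length(ev$predictions, 20)
    # a constant predictor scores R2 <= 0, reported as computed
    m0 <- m; m0@coefficients <- c(0, 0); m0@intercept <- 100
    expect_lte(evaluateModel(m0, tab)$R2, 0)
})
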