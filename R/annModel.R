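# Min-max scaling and the small feed-forward network used to refine the
# selected linear model. The network is deliberately tiny (two hidden
# sigmoid units by default) and trained full-batch; the damped Gauss-Newton
# (Levenberg-Marquardt) rule is the default optimiser because a network
# this small converges in a few dozen iterations under it, a plain
# fixed-rate gradient-descent rule is available for comparison.

sigm <- function(z) 1 / (1 + exp(-z))

#' Fit per-column min-max scaling onto an interval
#'
#' Learns the affine maps \eqn{\hat x = (hi-lo)(x - min)/(max - min) + lo}
#' sending each column's observed minimum to `lo` and maximum to `hi`
#' (default `[0.1, 0.9]`). A constant column is mapped to the interval
#' midpoint and inverts back to its constant value.
#'
#' @param values numeric matrix (columns are scaled independently) or a
#'   numeric vector (treated as one column).
#' @param lo,hi target interval bounds, `lo < hi`.
#' @param columnNames optional names; default taken from `colnames(values)`.
#' @return a [ScalingParams-class].
#' @export
fitScaling <- function(values, lo = 0.1, hi = 0.9, columnNames = NULL) {
    if (is.null(dim(values)))
        values <- matrix(as.numeric(values), ncol = 1L,
                         dimnames = list(NULL, columnNames %||% "value"))
    cn <- columnNames %||% colnames(values) %||%
        sprintf("column_%d", seq_len(ncol(values)))
    new("ScalingParams", columnNames = as.character(cn),
        mins = apply(values, 2L, min), maxs = apply(values, 2L, max),
        lo = lo, hi = hi)
}

#' Build scaling parameters from printed slope/minimum form
#'
#' Published scaling maps are often reported as
#' \eqn{\hat x = s (x - x_{min}) + lo}; this constructor recovers the
#' equivalent min-max parameters, taking `max = min + (hi - lo)/s`.
#'
#' @param columnNames character names.
#' @param slopes printed slopes s (> 0), one per column.
#' @param mins printed anchor values (the column minima).
#' @param lo,hi target interval.
#' @return a [ScalingParams-class].
#' @export
scalingFromSlopes <- function(columnNames, slopes, mins, lo = 0.1, hi = 0.9) {
    stopifnot(all(slopes > 0),
              length(slopes) == length(columnNames),
              length(mins) == length(columnNames))
    new("ScalingParams", columnNames = as.character(columnNames),
        mins = as.numeric(mins),
        maxs = as.numeric(mins) + (hi - lo) / as.numeric(slopes),
        lo = lo, hi = hi)
}

scaling_cols <- function(params, values) {
    if (is.null(dim(values))) {
        if (length(params@columnNames) == 1L)
            values <- matrix(as.numeric(values), ncol = 1L,
                             dimnames = list(NULL, params@columnNames))
        else values <- matrix(as.numeric(values), nrow = 1L,
                              dimnames = list(NULL, params@columnNames))
    }
    if (!is.null(colnames(values))) {
        miss <- setdiff(params@columnNames, colnames(values))
        if (length(miss))
            stop("missing column(s): ", paste(miss, collapse = ", "))
        values <- values[, params@columnNames, drop = FALSE]
    } else if (ncol(values) != length(params@columnNames)) {
        stop("expected ", length(params@columnNames), " columns, got ",
             ncol(values))
    }
    values
}

#' Apply a fitted min-max scaling
#'
#' Values outside the fitted [min, max] range scale outside `[lo, hi]` and
#' are passed through unclipped, so test-set compounds more extreme than
#' any training compound keep their ordering.
#'
#' @param params a [ScalingParams-class].
#' @param values numeric vector or matrix in raw units (columns matched by
#'   name when present).
#' @return scaled values with the same shape.
#' @export
applyScaling <- function(params, values) {
    stopifnot(is(params, "ScalingParams"))
    single <- is.null(dim(values))
    m <- scaling_cols(params, values)
    rng <- params@maxs - params@mins
    span <- params@hi - params@lo
    out <- m
    for (j in seq_len(ncol(m))) {
        out[, j] <- if (rng[j] == 0) (params@lo + params@hi) / 2
                    else span * (m[, j] - params@mins[j]) / rng[j] + params@lo
    }
    if (single) drop(out) else out
}

#' Invert a fitted min-max scaling
#'
#' Exact inverse of [applyScaling()] (to floating-point round-off); a
#' constant column inverts to its constant.
#'
#' @inheritParams applyScaling
#' @param values scaled values.
#' @return values in raw units.
#' @export
invertScaling <- function(params, values) {
    stopifnot(is(params, "ScalingParams"))
    single <- is.null(dim(values))
    m <- scaling_cols(params, values)
    rng <- params@maxs - params@mins
    span <- params@hi - params@lo
    out <- m
    for (j in seq_len(ncol(m))) {
        out[, j] <- if (rng[j] == 0) params@mins[j]
                    else (m[, j] - params@lo) * rng[j] / span + params@mins[j]
    }
    if (single) drop(out) else out
}

#' Split a descriptor table into training and testing partitions
#'
#' Shuffles the compounds with the given seed and assigns the first
#' `round(trainFraction * nObs)` (round half up) to the training set, the
#' rest to testing. The partitions are disjoint and exhaustive, and the
#' same seed always reproduces the same split.
#'
#' @param table a [DescriptorTable-class] with at least 4 compounds.
#' @param trainFraction fraction of compounds to train on, in (0, 1);
#'   default 0.75.
#' @param seed integer seed for the shuffle.
#' @return a list with [DescriptorTable-class] elements `train` and `test`.
#' @export
splitTrainTest <- function(table, trainFraction = 0.75, seed = NULL) {
    stopifnot(is(table, "DescriptorTable"))
    n <- nObs(table)
    if (n < 4L) stop("need at least 4 compounds to split")
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must lie strictly between 0 and 1")
    nTrain <- floor(trainFraction * n + 0.5)     # round half up
    if (nTrain < 2L || nTrain > n - 1L)
        stop("trainFraction = ", trainFraction, " gives a degenerate split (",
             nTrain, "/", n - nTrain, ")")
    perm <- with_seed(seed, sample.int(n))
    takeRows <- function(rows) {
        table@compoundIds <- table@compoundIds[rows]
        table@X <- table@X[rows, , drop = FALSE]
        table@y <- table@y[rows]
        validObject(table)
        table
    }
    list(train = takeRows(perm[seq_len(nTrain)]),
         test = takeRows(perm[(nTrain + 1L):n]))
}

#' Training configuration for the feed-forward network
#'
#' @param maxIterations iteration cap (default 150).
#' @param patience consecutive iterations without an MSE improvement of at
#'   least `tol` before training stops early (default 10; must be smaller
#'   than `maxIterations`).
#' @param tol minimum MSE improvement counted as progress (default 1e-8).
#' @param learningRule `"gauss_newton"` (damped Gauss-Newton /
#'   Levenberg-Marquardt, the default) or `"gradient_descent"` (full-batch,
#'   fixed rate).
#' @param learningRate step size for the gradient-descent rule (default
#'   0.05; ignored by Gauss-Newton).
#' @param nHidden hidden-layer width (default 2).
#' @param outputActivation `"linear"` (default) or `"sigmoid"`.
#' @param nStarts number of seeded random restarts sharing the iteration
#'   budget (default 5). Each start is burned in for `burnIn` iterations;
#'   the start with the lowest MSE then consumes the remaining budget, so
#'   the total number of iterations never exceeds `maxIterations`.
#' @param burnIn burn-in iterations per start (default 10).
#' @param trainFraction fraction of compounds used for training when a
#'   caller also performs the split (default 0.75).
#' @param seed integer seed for weight initialisation.
#' @return a list of class `"annTrainConfig"`.
#' @export
annTrainConfig <- function(maxIterations = 150L, patience = 10L,
                           tol = 1e-8,
                           learningRule = c("gauss_newton",
                                            "gradient_descent"),
                           learningRate = 0.05, nHidden = 2L,
                           outputActivation = c("linear", "sigmoid"),
                           nStarts = 5L, burnIn = 10L,
                           trainFraction = 0.75, seed = NULL) {
    learningRule <- match.arg(learningRule)
    outputActivation <- match.arg(outputActivation)
    maxIterations <- as.integer(maxIterations)
    patience <- as.integer(patience)
    nStarts <- as.integer(nStarts)
    burnIn <- as.integer(burnIn)
    stopifnot(maxIterations >= 1L, patience >= 1L,
              patience < maxIterations,
              trainFraction > 0, trainFraction < 1,
              nHidden >= 1L, learningRate > 0, tol >= 0,
              nStarts >= 1L, burnIn >= 1L)
    # the multi-start burn-in may use at most half the iteration budget
    while (nStarts > 1L && nStarts * burnIn > maxIterations %/% 2L) {
        if (burnIn > 1L) burnIn <- burnIn - 1L else nStarts <- nStarts - 1L
    }
    structure(list(maxIterations = maxIterations, patience = patience,
                   tol = tol, learningRule = learningRule,
                   learningRate = learningRate,
                   nHidden = as.integer(nHidden),
                   outputActivation = outputActivation,
                   nStarts = nStarts, burnIn = burnIn,
                   trainFraction = trainFraction, seed = seed),
              class = "annTrainConfig")
}

# Parameter vector layout: [vec(W1) row-major by hidden unit | b1 | w2 | b2]
ann_unpack <- function(theta, nh, nin) {
    W1 <- matrix(theta[seq_len(nh * nin)], nrow = nh, byrow = TRUE)
    off <- nh * nin
    list(W1 = W1, b1 = theta[off + seq_len(nh)],
         w2 = theta[off + nh + seq_len(nh)], b2 = theta[off + 2L * nh + 1L])
}

ann_forward <- function(theta, Xhat, nh, outputSigmoid) {
    p <- ann_unpack(theta, nh, ncol(Xhat))
    A <- sweep(Xhat %*% t(p$W1), 2L, p$b1, "+")
    H <- sigm(A)
    pre <- drop(H %*% p$w2) + p$b2
    yhat <- if (outputSigmoid) sigm(pre) else pre
    list(H = H, pre = pre, yhat = yhat, p = p)
}

# Jacobian of predictions w.r.t. theta (n x P), same layout as ann_unpack.
ann_jacobian <- function(fw, Xhat, nh, outputSigmoid) {
    n <- nrow(Xhat)
    nin <- ncol(Xhat)
    H <- fw$H
    Hp <- H * (1 - H)
    outScale <- if (outputSigmoid) fw$yhat * (1 - fw$yhat) else rep(1, n)
    J <- matrix(0, n, nh * nin + 2L * nh + 1L)
    for (k in seq_len(nh)) {
        gk <- outScale * fw$p$w2[k] * Hp[, k]
        J[, (k - 1L) * nin + seq_len(nin)] <- gk * Xhat
        J[, nh * nin + k] <- gk                  # hidden bias
        J[, nh * nin + nh + k] <- outScale * H[, k]  # output weight
    }
    J[, nh * nin + 2L * nh + 1L] <- outScale     # output bias
    J
}

#' Train the feed-forward network on a descriptor table
#'
#' Fits the scaling maps on the training table only (inputs and response
#' onto `[0.1, 0.9]`), initialises all weights from a seeded
#' uniform(-0.5, 0.5), and minimises the mean squared error of the scaled
#' response. With `nStarts > 1` several seeded initialisations are burned
#' in for a few iterations each and the most promising one receives the
#' rest of the iteration budget — a guard against the poor local minima
#' that single-start training of tiny sigmoid networks is prone to; the
#' total number of iterations across all starts never exceeds
#' `maxIterations`. Training stops early as soon as the best MSE has not
#' improved by at least `tol` for `patience` consecutive iterations; the
#' returned network carries the best weights seen, not the last ones.
#'
#' The table handed in should contain only the selected input descriptors
#' (e.g. the eight ERM picks) — see [selectDescriptors()].
#'
#' @param train a [DescriptorTable-class]; its response must not be
#'   constant.
#' @param config an [annTrainConfig()] list.
#' @return a list with elements `model` (an [AnnModel-class]) and `history`
#'   (numeric, MSE on the scaled response after each completed iteration;
#'   `attr(history, "initial")` holds the MSE at the initial weights).
#' @export
trainAnn <- function(train, config = annTrainConfig()) {
    stopifnot(is(train, "DescriptorTable"),
              inherits(config, "annTrainConfig"))
    if (diff(range(train@y)) == 0)
        stop("constant response: nothing to train on")
    nh <- config$nHidden
    nin <- poolSize(train)
    inScale <- fitScaling(descriptorMatrix(train))
    outScale <- fitScaling(train@y, columnNames = train@responseName)
    Xhat <- applyScaling(inScale, descriptorMatrix(train))
    yhat <- applyScaling(outScale, train@y)
    outputSigmoid <- config$outputActivation == "sigmoid"

    P <- nh * nin + 2L * nh + 1L
    mseOf <- function(th) {
        fw <- ann_forward(th, Xhat, nh, outputSigmoid)
        mean((fw$yhat - yhat)^2)
    }

    # One optimisation run of at most nIter iterations from theta; returns
    # the current and best-ever state plus the per-iteration MSE history.
    # Rejected Gauss-Newton iterations keep the weights and count as
    # stalls, so a converged run stops after `patience` flat iterations.
    run_opt <- function(theta, nIter, lambda = 1e-2) {
        mse <- mseOf(theta)
        bestTheta <- theta
        bestMse <- mse
        history <- numeric(0)
        stall <- 0L
        for (it in seq_len(nIter)) {
            fw <- ann_forward(theta, Xhat, nh, outputSigmoid)
            r <- fw$yhat - yhat
            J <- ann_jacobian(fw, Xhat, nh, outputSigmoid)
            if (config$learningRule == "gradient_descent") {
                theta <- theta - config$learningRate * 2 *
                    drop(crossprod(J, r)) / length(r)
                mse <- mseOf(theta)
            } else {
                JtJ <- crossprod(J)
                Jtr <- drop(crossprod(J, r))
                damp <- pmax(diag(JtJ), 1e-12)
                for (try in 1:15) {
                    step <- tryCatch(
                        solve(JtJ + lambda * diag(damp, nrow = P), Jtr),
                        error = function(e) NULL)
                    if (!is.null(step)) {
                        cand <- theta - step
                        candMse <- mseOf(cand)
                        if (is.finite(candMse) && candMse < mse) {
                            theta <- cand
                            mse <- candMse
                            lambda <- max(lambda / 10, 1e-12)
                            break
                        }
                    }
                    lambda <- lambda * 10
                }
            }
            if (!is.finite(mse))
                stop("non-finite training loss at iteration ", it)
            history <- c(history, mse)
            if (mse < bestMse - config$tol) {
                bestMse <- mse
                bestTheta <- theta
                stall <- 0L
            } else {
                if (mse < bestMse) { bestMse <- mse; bestTheta <- theta }
                stall <- stall + 1L
                if (stall >= config$patience) break
            }
        }
        list(theta = theta, mse = mse, bestTheta = bestTheta,
             bestMse = bestMse, history = history, lambda = lambda)
    }

    # All starting weights come from one seeded uniform(-0.5, 0.5) stream;
    # each start is burned in briefly and the most promising one receives
    # the remaining iteration budget, keeping the total number of
    # iterations within maxIterations.
    nStarts <- config$nStarts %||% 1L
    burnIn <- if (nStarts > 1L) config$burnIn else 0L
    thetas <- with_seed(config$seed,
                        lapply(seq_len(nStarts),
                               function(i) runif(P, -0.5, 0.5)))
    initMse <- mseOf(thetas[[1L]])
    if (nStarts > 1L) {
        burns <- lapply(thetas, run_opt, nIter = burnIn)
        spent <- sum(vapply(burns, function(b) length(b$history),
                            integer(1)))
        win <- which.min(vapply(burns, function(b) b$bestMse, numeric(1)))
        cont <- run_opt(burns[[win]]$bestTheta,
                        nIter = max(config$maxIterations - spent, 0L),
                        lambda = burns[[win]]$lambda)
        history <- c(burns[[win]]$history, cont$history)
        if (cont$bestMse <= burns[[win]]$bestMse) {
            bestTheta <- cont$bestTheta
        } else {
            bestTheta <- burns[[win]]$bestTheta
        }
    } else {
        res <- run_opt(thetas[[1L]], config$maxIterations)
        history <- res$history
        bestTheta <- res$bestTheta
    }

    p <- ann_unpack(bestTheta, nh, nin)
    model <- new("AnnModel", inputNames = train@descriptorNames,
                 WHidden = p$W1, bHidden = p$b1, WOut = p$w2, bOut = p$b2,
                 activation = "sigmoid",
                 outputActivation = config$outputActivation,
                 inputScaling = inScale, responseScaling = outScale)
    attr(history, "initial") <- initMse
    list(model = model, history = history)
}

#' Hidden-layer pre-activations of a network
#'
#' Returns \eqn{W_h \hat x + b_h}, the affine combinations entering the
#' hidden sigmoids, for a single already-scaled input vector. Useful for
#' inspecting stored networks whose hidden combinations were published.
#'
#' @param model an [AnnModel-class].
#' @param scaledInputs numeric vector of scaled inputs (length = number of
#'   network inputs).
#' @return numeric vector, one pre-activation per hidden unit.
#' @export
hiddenPreactivation <- function(model, scaledInputs) {
    stopifnot(is(model, "AnnModel"))
    if (length(scaledInputs) != length(model@inputNames))
        stop("expected ", length(model@inputNames), " scaled inputs")
    drop(model@WHidden %*% as.numeric(scaledInputs) + model@bHidden)
}

#' Predict the response from a trained network
#'
#' Runs the full pipeline: min-max scale the raw descriptor values with the
#' training scaling, propagate through the hidden sigmoids and output node,
#' and inverse-scale the output back to response (ER) units.
#'
#' @param model an [AnnModel-class].
#' @param values a numeric vector over `model@inputNames`, a matrix with
#'   those columns, or a [DescriptorTable-class] containing them.
#' @return predicted response value(s) in raw units.
#' @export
annPredict <- function(model, values) {
    stopifnot(is(model, "AnnModel"))
    if (is(values, "DescriptorTable")) values <- descriptorMatrix(values)
    single <- is.null(dim(values))
    if (single) {
        if (length(values) != length(model@inputNames))
            stop("expected ", length(model@inputNames), " descriptor values")
        values <- matrix(as.numeric(values), nrow = 1L,
                         dimnames = list(NULL, model@inputNames))
    }
    Xhat <- applyScaling(model@inputScaling, values)
    if (is.null(dim(Xhat))) Xhat <- matrix(Xhat, nrow = nrow(values))
    A <- sweep(Xhat %*% t(model@WHidden), 2L, model@bHidden, "+")
    pre <- drop(sigm(A) %*% model@WOut) + model@bOut
    yhat <- if (model@outputActivation == "sigmoid") sigm(pre) else pre
    out <- invertScaling(model@responseScaling, yhat)
    if (single) drop(out) else out
}

#' @describeIn evaluateModel predictions, \eqn{R^2} and root-mean-square
#'   error (reported as `S`; the network has no OLS degrees-of-freedom
#'   convention) of a trained network on any table containing its inputs.
#' @export
setMethod("evaluateModel", c("AnnModel", "DescriptorTable"),
    function(model, table) {
        pred <- annPredict(model, table)
        y <- table@y
        rss <- sum((y - pred)^2)
        tss <- sum((y - mean(y))^2)
        R2 <- if (tss == 0) 0 else 1 - rss / tss
        pred <- as.numeric(pred)
        names(pred) <- table@compoundIds
        list(R2 = R2, S = sqrt(rss / length(y)), predictions = pred)
    })

## ---- JSON serialization --------------------------------------------------

scaling_to_list <- function(s)
    list(column_names = as.list(s@columnNames), mins = as.list(s@mins),
         maxs = as.list(s@maxs), lo = s@lo, hi = s@hi)

scaling_from_list <- function(doc) {
    cn <- as.character(doc$column_names)
    lo <- as.numeric(doc$lo %||% 0.1)
    hi <- as.numeric(doc$hi %||% 0.9)
    mins <- as.numeric(doc$mins)
    maxs <- if (!is.null(doc$maxs)) as.numeric(doc$maxs)
            else mins + (hi - lo) / as.numeric(doc$slopes)
    new("ScalingParams", columnNames = cn, mins = mins, maxs = maxs,
        lo = lo, hi = hi)
}

#' Serialize a trained network to JSON
#'
#' Stores input names, the weight matrices and biases, the activation
#' choices, and both scaling maps. Scaling blocks may equivalently carry
#' `slopes` instead of `maxs` (the printed-slope form handled by
#' [scalingFromSlopes()]).
#'
#' @param model an [AnnModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readAnnModel()]
#' @export
writeAnnModel <- function(model, path) {
    stopifnot(is(model, "AnnModel"))
    doc <- list(type = "AnnModel",
                input_names = as.list(model@inputNames),
                W_hidden = apply(model@WHidden, 1L, as.list,
                                 simplify = FALSE),
                b_hidden = as.list(model@bHidden),
                W_out = as.list(model@WOut),
                b_out = model@bOut,
                activation = model@activation,
                output_activation = model@outputActivation,
                input_scaling = scaling_to_list(model@inputScaling),
                response_scaling = scaling_to_list(model@responseScaling))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' Read a network from JSON
#'
#' @param path a JSON file in the layout written by [writeAnnModel()].
#' @return an [AnnModel-class].
#' @export
readAnnModel <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    W <- doc$W_hidden
    if (is.list(W)) W <- do.call(rbind, lapply(W, as.numeric))
    if (is.null(dim(W))) W <- matrix(as.numeric(W), nrow = 1L)
    new("AnnModel",
        inputNames = as.character(doc$input_names),
        WHidden = W,
        bHidden = as.numeric(doc$b_hidden),
        WOut = as.numeric(doc$W_out),
        bOut = as.numeric(doc$b_out),
        activation = doc$activation %||% "sigmoid",
        outputActivation = doc$output_activation %||% "linear",
        inputScaling = scaling_from_list(doc$input_scaling),
        responseScaling = scaling_from_list(doc$response_scaling))
}
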