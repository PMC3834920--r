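# Subset-search algorithms. All of them minimise the residual standard
# deviation S of an intercept-containing OLS fit over fixed-size descriptor
# subsets; they differ only in how they move through subset space.
#
# Internals operate on integer column indices into table@X; descriptor
# names appear only at the API boundary and in traces.

# Full OLS fit on column indices: coefficients, relative errors, S.
# Counts one fit. Returns NULL for a singular design.
ols_info <- function(X, y, idx, counter) {
    counter$n <- counter$n + 1L
    Xd <- cbind(1, X[, idx, drop = FALSE])
    fit <- .lm.fit(Xd, y, tol = 1e-10)
    if (fit$rank < ncol(Xd)) return(NULL)
    rss <- sum(fit$residuals^2)
    n <- length(y)
    d <- length(idx)
    S <- sqrt(max(rss, 0) / (n - d - 1))
    R <- qr.R(structure(list(qr = fit$qr, rank = fit$rank,
                             qraux = fit$qraux, pivot = fit$pivot,
                             tol = fit$tol), class = "qr"))
    XtXinv <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(XtXinv)) return(NULL)
    se <- S * sqrt(pmax(diag(XtXinv), 0))
    coefs <- fit$coefficients[order(fit$pivot)][-1L]
    sec <- se[order(fit$pivot)][-1L]
    relerr <- ifelse(coefs == 0, Inf, sec / abs(coefs))
    list(S = S, relerr = relerr)
}

# Best replacement for position j of subset idx: scan every pool column not
# currently in the subset, in increasing pool-index order (which is the
# deterministic tie-break), and return the candidate with strictly smallest
# S. Singular candidates score S = Inf. NULL when there is no candidate or
# every candidate is singular.
best_replacement <- function(X, y, poolIdx, idx, j, counter) {
    cand <- setdiff(poolIdx, idx)
    if (!length(cand)) return(NULL)
    bestS <- Inf
    bestW <- NA_integer_
    trial <- idx
    for (w in cand) {
        trial[j] <- w
        counter$n <- counter$n + 1L
        s <- ols_S(X, y, trial)
        if (s < bestS) { bestS <- s; bestW <- w }
    }
    if (!is.finite(bestS)) return(NULL)
    list(w = bestW, S = bestS)
}

# One RM path: start from subset idx, first replace position `firstPos`,
# then cycle on the worst-relative-error descriptor. Replacements are
# accepted only when they strictly lower S, so the path trace is monotone
# non-increasing. The descriptor accepted in the immediately preceding
# cycle is excluded from the relative-error ranking for exactly one cycle;
# when a sweep under that exclusion stalls, one final unrestricted sweep
# decides termination.
rm_path <- function(X, y, poolIdx, idx, firstPos, counter, names, stage) {
    info <- ols_info(X, y, idx, counter)
    if (is.null(info))
        stop("singular design for the initial subset {",
             paste(names[idx], collapse = ", "), "}")
    S <- info$S
    trace <- list(list(subset = names[idx], S = S, stage = stage))
    lastAccepted <- NA_integer_

    rep1 <- best_replacement(X, y, poolIdx, idx, firstPos, counter)
    if (!is.null(rep1) && rep1$S < S) {
        idx[firstPos] <- rep1$w
        S <- rep1$S
        lastAccepted <- rep1$w
        trace[[length(trace) + 1L]] <- list(subset = names[idx], S = S,
                                            stage = stage)
    }

    repeat {
        info <- ols_info(X, y, idx, counter)
        if (is.null(info)) break
        sweep_once <- function(excluded) {
            ord <- order(info$relerr, decreasing = TRUE)
            ord <- ord[!idx[ord] %in% excluded]
            for (j in ord) {
                rep <- best_replacement(X, y, poolIdx, idx, j, counter)
                if (!is.null(rep) && rep$S < S) return(list(j = j, rep = rep))
            }
            NULL
        }
        hit <- sweep_once(lastAccepted)
        if (is.null(hit) && !is.na(lastAccepted))
            hit <- sweep_once(integer(0))       # exclusion lasts one cycle
        if (is.null(hit)) break
        idx[hit$j] <- hit$rep$w
        S <- hit$rep$S
        lastAccepted <- hit$rep$w
        trace[[length(trace) + 1L]] <- list(subset = names[idx], S = S,
                                            stage = stage)
    }
    list(idx = idx, S = S, trace = trace)
}

# Shared argument validation; returns integer indices of the eligible pool
# (flagged constant columns removed) and the initial subset.
prepare_search <- function(table, M, initSubset, seed, requireInit = FALSE) {
    stopifnot(is(table, "DescriptorTable"))
    M <- as.integer(M)
    names <- table@descriptorNames
    eligible <- which(!names %in% table@constantDescriptors)
    if (is.na(M) || M < 1L) stop("M must be a positive integer")
    if (M > length(eligible))
        stop("M = ", M, " exceeds the ", length(eligible),
             " selectable descriptors")
    if (nObs(table) < M + 2L)
        stop("need at least ", M + 2L, " compounds for M = ", M)
    if (is.null(initSubset)) {
        if (requireInit) stop("initSubset is required")
        initIdx <- with_seed(seed, sort(sample(eligible, M)))
    } else {
        initSubset <- as.character(initSubset)
        if (length(initSubset) != M || anyDuplicated(initSubset))
            stop("initSubset must hold ", M, " distinct descriptor names")
        initIdx <- match(initSubset, names)
        if (anyNA(initIdx))
            stop("initSubset names not in pool: ",
                 paste(initSubset[is.na(initIdx)], collapse = ", "))
        if (any(initSubset %in% table@constantDescriptors))
            stop("initSubset contains flagged constant descriptor(s)")
    }
    list(M = M, names = names, eligible = eligible, initIdx = initIdx)
}

#' Replacement-method (RM) descriptor selection
#'
#' The replacement method improves an arbitrary initial set \eqn{V} of `M`
#' descriptors drawn from the pool \eqn{W} by repeated single-descriptor
#' substitution. For each of the `M` "paths" (one per starting position):
#' the path's designated descriptor is first replaced by every candidate in
#' \eqn{W - V} and the substitution giving the smallest residual standard
#' deviation S is accepted if it lowers S; each subsequent cycle targets the
#' descriptor whose coefficient has the greatest relative error (standard
#' error / |coefficient|), excluding the descriptor optimised in the
#' preceding cycle, and again accepts the best substitution only when it
#' strictly decreases S. A path terminates when a full sweep leaves the
#' subset unchanged. The best model over all `M` paths is returned.
#'
#' Within each path the trace of accepted states is monotone non-increasing
#' in S. Collinear candidate subsets are scored `S = +Inf` and thus never
#' accepted. Ties between equally good replacements go to the candidate
#' earliest in pool order, making runs fully deterministic given the table,
#' `M`, initial subset and seed.
#'
#' @param table a [DescriptorTable-class] (run [validatePool()] first to
#'   flag constant columns).
#' @param M subset size.
#' @param initSubset optional character vector of `M` starting descriptor
#'   names, shared by all paths; when `NULL` a random `M`-subset is drawn
#'   using `seed`.
#' @param seed integer seed for the random initial subset (ignored when
#'   `initSubset` is given).
#' @return a [SearchResult-class] with `method = "rm"`.
#' @references the replacement / enhanced-replacement family of QSAR
#'   variable-selection heuristics built around residual-standard-deviation
#'   minimisation.
#' @export
rmSelect <- function(table, M, initSubset = NULL, seed = NULL) {
    prep <- prepare_search(table, M, initSubset, seed)
    X <- table@X
    y <- table@y
    counter <- new.env(parent = emptyenv())
    counter$n <- 0L

    bestS <- Inf
    bestIdx <- prep$initIdx
    trace <- list()
    for (p in seq_len(prep$M)) {
        res <- rm_path(X, y, prep$eligible, prep$initIdx, p, counter,
                       prep$names, sprintf("path%d", p))
        trace <- c(trace, res$trace)
        if (res$S < bestS) { bestS <- res$S; bestIdx <- res$idx }
    }
    model <- fitSubset(table, prep$names[bestIdx])
    counter$n <- counter$n + 1L
    new("SearchResult", method = "rm", bestModel = model, trace = trace,
        nFits = counter$n,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        initSubset = prep$names[prep$initIdx])
}

#' Modified replacement method (MRM) with forced moves
#'
#' Follows the same worst-descriptor replacement strategy as [rmSelect()]
#' but the substitution is applied in every step even when it does not
#' reduce S — the forced move lets the search climb out of the local minima
#' where RM stalls. The trajectory may therefore wander; the returned model
#' is the best ever visited, not the final state. The search terminates
#' when a subset recurs (a memo of visited subsets detects the cycle) or
#' after `maxCycles` forced moves.
#'
#' @param table a [DescriptorTable-class].
#' @param M subset size.
#' @param initSubset required starting subset of size `M` (ERM hands over
#'   the RM winner here).
#' @param maxCycles cap on forced moves; default `2 * M`.
#' @return a [SearchResult-class] with `method = "mrm"`.
#' @export
mrmSelect <- function(table, M, initSubset, maxCycles = 2L * as.integer(M)) {
    prep <- prepare_search(table, M, initSubset, seed = NULL,
                           requireInit = TRUE)
    X <- table@X
    y <- table@y
    names <- prep$names
    counter <- new.env(parent = emptyenv())
    counter$n <- 0L

    idx <- prep$initIdx
    info <- ols_info(X, y, idx, counter)
    if (is.null(info))
        stop("singular design for the initial subset")
    S <- info$S
    trace <- list(list(subset = names[idx], S = S, stage = "mrm"))
    bestS <- S
    bestIdx <- idx
    seen <- new.env(parent = emptyenv())
    assign(subset_key(names[idx]), TRUE, envir = seen)
    lastAccepted <- NA_integer_

    for (cycle in seq_len(max(1L, as.integer(maxCycles)))) {
        ord <- order(info$relerr, decreasing = TRUE)
        eligiblePos <- ord[!idx[ord] %in% lastAccepted]
        if (!length(eligiblePos)) eligiblePos <- ord
        moved <- FALSE
        for (j in eligiblePos) {
            rep <- best_replacement(X, y, prep$eligible, idx, j, counter)
            if (is.null(rep)) next       # all candidates singular here
            idx[j] <- rep$w              # forced: applied even if S rises
            S <- rep$S
            lastAccepted <- rep$w
            moved <- TRUE
            break
        }
        if (!moved) break
        trace[[length(trace) + 1L]] <- list(subset = names[idx], S = S,
                                            stage = "mrm")
        if (S < bestS) { bestS <- S; bestIdx <- idx }
        key <- subset_key(names[idx])
        if (exists(key, envir = seen, inherits = FALSE)) break
        assign(key, TRUE, envir = seen)
        info <- ols_info(X, y, idx, counter)
        if (is.null(info)) break
    }
    model <- fitSubset(table, names[bestIdx])
    counter$n <- counter$n + 1L
    new("SearchResult", method = "mrm", bestModel = model, trace = trace,
        nFits = counter$n, seed = NA_integer_,
        initSubset = names[prep$initIdx])
}

#' Enhanced replacement method (ERM)
#'
#' Runs the sequence RM, MRM, RM: [rmSelect()] finds a first minimum, the
#' forced-move [mrmSelect()] perturbs it out of the basin, and a final
#' [rmSelect()] polishes the perturbed subset. The returned model is the
#' best encountered across all three stages, so
#' \eqn{S_{ERM} \le S_{RM}} always holds for identical inputs. The trace
#' concatenates the three stage traces with stage labels `"rm1:*"`,
#' `"mrm"`, `"rm2:*"`.
#'
#' @inheritParams rmSelect
#' @param maxCycles forced-move cap for the MRM stage; default `2 * M`.
#' @return a [SearchResult-class] with `method = "erm"`.
#' @export
ermSelect <- function(table, M, initSubset = NULL, seed = NULL,
                      maxCycles = 2L * as.integer(M)) {
    r1 <- rmSelect(table, M, initSubset = initSubset, seed = seed)
    mr <- mrmSelect(table, M, initSubset = subsetNames(r1),
                    maxCycles = maxCycles)
    r2 <- rmSelect(table, M, initSubset = subsetNames(mr))
    stages <- list(rm1 = r1, mrm = mr, rm2 = r2)
    Ss <- vapply(stages, modelS, numeric(1))
    best <- stages[[which.min(Ss)]]@bestModel
    relabel <- function(res, prefix) {
        lapply(res@trace, function(st) {
            st$stage <- if (identical(prefix, st$stage)) prefix
                        else paste0(prefix, ":", st$stage)
            st
        })
    }
    trace <- c(relabel(r1, "rm1"), relabel(mr, "mrm"), relabel(r2, "rm2"))
    new("SearchResult", method = "erm", bestModel = best, trace = trace,
        nFits = r1@nFits + mr@nFits + r2@nFits,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        initSubset = r1@initSubset)
}

#' Forward-stepwise descriptor selection by partial F
#'
#' Starts from the intercept-only model and, at each step, adds the
#' candidate descriptor with the largest partial F-to-enter (see
#' [fToChange()]), provided that F exceeds `FEnter`. Stops when no
#' candidate qualifies or the subset reaches `MMax`. Singular candidates
#' are skipped. Subsets along the trace are strictly nested, growing by
#' one descriptor per step.
#'
#' @param table a [DescriptorTable-class].
#' @param MMax maximum subset size.
#' @param FEnter F-to-enter threshold (> 0); default 4.0, the common
#'   rule-of-thumb roughly matching a 5\% single-coefficient test.
#' @return a [SearchResult-class] with `method = "forward_stepwise"`.
#' @export
forwardStepwise <- function(table, MMax, FEnter = 4.0) {
    stopifnot(is(table, "DescriptorTable"))
    MMax <- as.integer(MMax)
    if (is.na(MMax) || MMax < 1L) stop("MMax must be >= 1")
    if (FEnter <= 0) stop("FEnter must be positive")
    names <- table@descriptorNames
    eligible <- which(!names %in% table@constantDescriptors)
    X <- table@X
    y <- table@y
    n <- length(y)
    nfits <- 0L

    base <- integer(0)
    rssBase <- sum((y - mean(y))^2)
    trace <- list(list(subset = character(0),
                       S = sqrt(rssBase / (n - 1)), stage = "step0"))
    step <- 0L
    while (length(base) < MMax && n - length(base) - 2L >= 1L) {
        step <- step + 1L
        cand <- setdiff(eligible, base)
        if (!length(cand)) break
        dfBig <- n - (length(base) + 1L) - 1L
        bestF <- -Inf
        bestW <- NA_integer_
        bestRss <- NA_real_
        for (w in cand) {
            nfits <- nfits + 1L
            rssBig <- ols_rss(X, y, c(base, w))
            if (!is.finite(rssBig)) next
            f <- partial_F(rssBase, rssBig, dfBig)
            if (f > bestF) { bestF <- f; bestW <- w; bestRss <- rssBig }
        }
        if (!is.finite(bestW) || bestF <= FEnter) break
        base <- c(base, bestW)
        rssBase <- bestRss
        trace[[length(trace) + 1L]] <-
            list(subset = names[base],
                 S = sqrt(max(bestRss, 0) / (n - length(base) - 1L)),
                 stage = sprintf("step%d", step))
    }
    model <- fitSubset(table, names[base])
    nfits <- nfits + 1L
    new("SearchResult", method = "forward_stepwise", bestModel = model,
        trace = trace, nFits = nfits, seed = NA_integer_,
        initSubset = character(0))
}

#' Backward elimination by partial F
#'
#' Starts from `startSubset` and repeatedly deletes the member descriptor
#' with the smallest partial F-to-remove while that F stays below
#' `FRemove`; stops when deleting any remaining descriptor would give up an
#' F-ratio of at least the threshold. A perfectly predictive descriptor has
#' infinite F and is never removed; `FRemove = 0` removes nothing.
#'
#' @param table a [DescriptorTable-class].
#' @param startSubset character, the full starting subset (must be
#'   fittable).
#' @param FRemove F-to-remove threshold; default 4.0.
#' @return a [SearchResult-class] with `method = "backward_elimination"`.
#' @export
backwardEliminate <- function(table, startSubset, FRemove = 4.0) {
    stopifnot(is(table, "DescriptorTable"))
    startSubset <- as.character(startSubset)
    names <- table@descriptorNames
    idx <- match(startSubset, names)
    if (anyNA(idx))
        stop("startSubset names not in pool: ",
             paste(startSubset[is.na(idx)], collapse = ", "))
    X <- table@X
    y <- table@y
    n <- length(y)
    nfits <- 1L
    rssCur <- ols_rss(X, y, idx)
    if (!is.finite(rssCur))
        stop("singular design for the starting subset")
    trace <- list(list(subset = names[idx],
                       S = sqrt(max(rssCur, 0) / (n - length(idx) - 1L)),
                       stage = "step0"))
    step <- 0L
    while (length(idx) > 0L) {
        step <- step + 1L
        dfBig <- n - length(idx) - 1L
        worstF <- Inf
        worstJ <- NA_integer_
        worstRss <- NA_real_
        for (j in seq_along(idx)) {
            small <- idx[-j]
            nfits <- nfits + 1L
            rssSmall <- if (length(small)) ols_rss(X, y, small)
                        else sum((y - mean(y))^2)
            if (!is.finite(rssSmall)) next
            f <- partial_F(rssSmall, rssCur, dfBig)
            if (f < worstF) { worstF <- f; worstJ <- j; worstRss <- rssSmall }
        }
        if (!is.finite(worstJ) || worstF >= FRemove) break
        idx <- idx[-worstJ]
        rssCur <- worstRss
        trace[[length(trace) + 1L]] <-
            list(subset = names[idx],
                 S = sqrt(max(rssCur, 0) / max(n - length(idx) - 1L, 1L)),
                 stage = sprintf("step%d", step))
    }
    model <- fitSubset(table, names[idx])
    nfits <- nfits + 1L
    new("SearchResult", method = "backward_elimination", bestModel = model,
        trace = trace, nFits = nfits, seed = NA_integer_,
        initSubset = startSubset)
}

#' Exhaustive best-subset enumeration (oracle)
#'
#' Fits every `M`-subset of the selectable pool and returns the global
#' minimum-S model. Intended as the ground-truth oracle against which the
#' heuristics are judged; refuses to run when `choose(poolSize, M)` exceeds
#' `budget` fits. Ties are broken in favour of the subset whose sorted
#' descriptor-name list is lexicographically smallest. The trace records
#' the successive incumbents (each strict improvement), so the best model's
#' S bounds every traced S from below.
#'
#' @param table a [DescriptorTable-class].
#' @param M subset size.
#' @param budget maximum number of OLS fits allowed (default `2e5`).
#' @return a [SearchResult-class] with `method = "exhaustive"`.
#' @export
exhaustiveBestSubset <- function(table, M, budget = 2e5) {
    stopifnot(is(table, "DescriptorTable"))
    M <- as.integer(M)
    names <- table@descriptorNames
    eligible <- which(!names %in% table@constantDescriptors)
    if (is.na(M) || M < 1L || M > length(eligible))
        stop("M must lie in 1..", length(eligible))
    if (nObs(table) < M + 2L)
        stop("need at least ", M + 2L, " compounds for M = ", M)
    total <- choose(length(eligible), M)
    if (total > budget)
        stop("exhaustive enumeration would need ", format(total, big.mark = ","),
             " fits, above the budget of ", format(budget, big.mark = ","))
    # enumerate over alphabetically ordered names so that keeping the first
    # strict minimum implements the lexicographic tie-break
    ordPool <- eligible[order(names[eligible])]
    X <- table@X
    y <- table@y
    bestS <- Inf
    bestIdx <- NULL
    trace <- list()
    nfits <- 0L
    combos <- utils::combn(ordPool, M)
    for (k in seq_len(ncol(combos))) {
        idx <- combos[, k]
        nfits <- nfits + 1L
        s <- ols_S(X, y, idx)
        if (s < bestS) {
            bestS <- s
            bestIdx <- idx
            trace[[length(trace) + 1L]] <-
                list(subset = names[idx], S = s, stage = "incumbent")
        }
    }
    if (is.null(bestIdx))
        stop("every candidate subset was singular")
    model <- fitSubset(table, names[bestIdx])
    nfits <- nfits + 1L
    # n_fits reports the enumeration count, excluding the final refit
    new("SearchResult", method = "exhaustive", bestModel = model,
        trace = trace, nFits = nfits - 1L, seed = NA_integer_,
        initSubset = character(0))
}

#' Serialize a search result to JSON
#'
#' Writes method, best subset, coefficients, S, R2, number of fits and
#' (optionally) the visited-state trace.
#'
#' @param result a [SearchResult-class].
#' @param path output path.
#' @param includeTrace include the full trace (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSearchResult <- function(result, path, includeTrace = TRUE) {
    stopifnot(is(result, "SearchResult"))
    m <- result@bestModel
    doc <- list(type = "SearchResult",
                method = result@method,
                subset = as.list(m@subset),
                intercept = m@intercept,
                coefficients = as.list(m@coefficients),
                S = m@S, R2 = m@R2, n_obs = m@nObs,
                n_fits = result@nFits,
                seed = result@seed,
                init_subset = as.list(result@initSubset))
    if (includeTrace)
        doc$trace <- lapply(result@trace, function(st)
            list(subset = as.list(st$subset), S = st$S,
                 stage = st$stage %||% ""))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}
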