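# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the published-model JSON fixtures under extdata.

# Small random table with named descriptors and a linear signal.
random_table <- function(n = 20, p = 3, seed = 1, coefs = rep(1, p),
                         noise = 0.3) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("c%02d", 1:n), paste0("d", 1:p)))
    y <- drop(X %*% coefs) + rnorm(n, 0, noise)
    DescriptorTable(X, y)
}

# Noiseless y = 2x + 1 over x = 1..6.
line_table <- function() {
    DescriptorTable(matrix(1:6, 6, 1, dimnames = list(NULL, "x")),
                    y = 2 * (1:6) + 1)
}

extdata <- function(file) {
    path <- system.file("extdata", file, package = "ermsel")
    if (!nzchar(path)) stop("missing extdata fixture: ", file)
    path
}

# Independent OLS oracle via the normal equations.
normal_equations <- function(table, subset) {
    X <- descriptorMatrix(table)[, subset, drop = FALSE]
    y <- unname(response(table))
    Xd <- cbind(1, X)
    beta <- solve(crossprod(Xd), crossprod(Xd, y))
    res <- y - Xd %*% beta
    rss <- sum(res^2)
    n <- length(y)
    d <- length(subset)
    S <- sqrt(rss / (n - d - 1))
    se <- S * sqrt(diag(solve(crossprod(Xd))))
    list(intercept = beta[1], coefficients = drop(beta[-1]),
         S = S, R2 = 1 - rss / sum((y - mean(y))^2), se = se[-1])
}
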