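# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never perturb the
# user's RNG stream. seed = NULL runs expr unseeded (still restoring state
# if one existed).
with_seed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    if (!is.null(seed)) {
        seed <- as.integer(seed)
        if (is.na(seed)) stop("seed must be coercible to integer")
        set.seed(seed)
    }
    force(expr)
}

# Canonical key for a descriptor subset (order-free), used by the MRM
# visited-set memo.
subset_key <- function(subset) paste(sort(subset), collapse = "\r")

# Stage-wise seed fan-out: derive independent, reproducible sub-seeds from a
# single user seed while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
    if (is.null(seed) || is.na(seed)) return(NULL)
    as.integer((as.numeric(seed) + 99991 * offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
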