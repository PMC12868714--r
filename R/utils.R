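## Internal helpers shared across modules.

.assertCount <- function(x, name, min = 0L) {
    if (length(x) != 1L || is.na(x) || x < min || x != floor(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
    as.integer(x)
}

.assertProb <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
    as.numeric(x)
}

## Deterministic child seed for a named stage, so toggling one stage does not
## shift another stage's random stream. Kept below 2^31.
.stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

## Evaluate `expr` with a locally-set RNG seed, restoring the caller's stream.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(seed)
        return(expr)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## Dense row variance for a (possibly sparse) matrix.
.rowVars <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- Matrix::rowMeans(m)
    (Matrix::rowMeans(m^2) - mu^2) * n / (n - 1)
}

.geneNames <- function(n_genes) sprintf("g%05d", seq_len(n_genes))
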