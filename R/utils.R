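# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Derive reproducible per-replicate sub-seeds from one master seed.
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Build a logistic design matrix (with intercept) from a covariate table.
# Factors and character columns are expanded to indicator columns.
covariateDesign <- function(covariates, n = NULL) {
    if (is.null(covariates) || NCOL(covariates) == 0L) {
        stopifnot(!is.null(n))
        return(matrix(1, nrow = n, ncol = 1L,
                      dimnames = list(NULL, "(Intercept)")))
    }
    df <- as.data.frame(covariates, stringsAsFactors = TRUE)
    for (j in seq_along(df))
        if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    model.matrix(~ ., data = df)
}

# Rank check used before every logistic fit; errors name the first
# redundant column, mirroring what a collinearity failure should report.
assertFullRank <- function(X, context = "design") {
    q <- qr(X)
    if (q$rank < ncol(X)) {
        dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
        stop(sprintf("collinear %s: rank %d < %d columns; redundant term(s): %s",
                     context, q$rank, ncol(X),
                     paste(dropped, collapse = ", ")), call. = FALSE)
    }
    invisible(TRUE)
}

# TRUE when adding `col` to X does not increase numerical rank.
isCollinearWith <- function(X, col) {
    qr(cbind(X, col))$rank <= qr(X)$rank
}
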