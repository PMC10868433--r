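## Internal helpers shared across modules.

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so generators are reproducible
#' without clobbering the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            },
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    expr
}

## Coerce a position argument to an n x 3 numeric matrix.
asPositionMatrix <- function(pos) {
    if (is.numeric(pos) && is.null(dim(pos))) {
        if (length(pos) %% 3L != 0L) {
            stop("'pos' must be a length-3 vector or an n x 3 matrix")
        }
        pos <- matrix(pos, ncol = 3L, byrow = TRUE)
    }
    pos <- as.matrix(pos)
    if (ncol(pos) != 3L) stop("'pos' must have 3 columns (x, y, z)")
    if (!all(is.finite(pos))) stop("positions must be finite")
    storage.mode(pos) <- "double"
    pos
}

stopifnotScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
        stop(sprintf("'%s' must be a single finite number", name))
    }
    if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
    if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
    invisible(x)
}
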