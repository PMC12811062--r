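## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state (the global .Random.seed is restored on exit).
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

.assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(name, " must be a single finite number", call. = FALSE)
    if ((strict_lower && x <= lower) || (!strict_lower && x < lower) ||
        x > upper)
        stop(name, " out of range", call. = FALSE)
    invisible(x)
}

## round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
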