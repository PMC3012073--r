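## RNG plumbing: seed locally, restore the caller's stream on exit, and
## derive deterministic per-stage sub-seeds from one master seed.

.localSeed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    function() {
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    }
}

## Deterministic sub-stream seeds, kept below 2^31 - 1.  Arithmetic is done
## in doubles (exact far beyond these magnitudes).
.stageSeed <- function(master, stage) {
    m <- as.double(master) %% 2147483647
    as.integer((m * 2099 + as.double(stage) * 7919 + 1) %% 2147483629)
}

.isCount <- function(x) length(x) == 1L && !is.na(x) && x >= 1 &&
    x == as.integer(x)
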