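DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `U` is treated
#' as `T`; `N` maps to `N`.
#'
#' @param x character vector of DNA (or RNA) sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
    x <- chartr("U", "T", toupper(x))
    comp <- chartr("ACGTN", "TGCAN", x)
    vapply(strsplit(comp, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Random A/C/G/T sequences with lengths drawn uniformly from an inclusive
# range. Uses the current RNG state.
random_seq <- function(n, len_range) {
    lens <- if (len_range[1] == len_range[2]) {
        rep(len_range[1], n)
    } else {
        sample(len_range[1]:len_range[2], n, replace = TRUE)
    }
    vapply(lens, function(L) {
        paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
}

# Deterministic per-stage seed derived from a user seed; kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
    as.integer((as.numeric(seed) + offset) %% 2147483646L + 1L)
}

# Errors attributable to user input (bad flags, malformed files) carry their
# own condition class so the CLI can map them to exit code 1 rather than 2.
user_error <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("pirnakit_user_error", "pirnakit_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
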