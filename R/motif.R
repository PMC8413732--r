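all_substrings <- function(s, L) {
    n <- nchar(s)
    if (n < L) return(character())
    unique(substring(s, 1:(n - L + 1L), L:n))
}

#' Longest common substring motifs
#'
#' Finds all maximal-length substrings present verbatim in at least
#' `ceil(min_support_frac * n)` of the input sequences. The search walks
#' lengths downward from the longest length hosted by enough sequences and
#' stops at the first length with a supported candidate, so the reported
#' motifs are maximal; ties are reported in lexicographic order.
#'
#' @param seqs character vector of at least 2 uppercase A/C/G/T sequences
#'   (named or not).
#' @param min_support_frac minimum fraction of sequences that must contain
#'   the motif (default 1: all).
#' @param min_len shortest motif length worth reporting (default 6).
#' @return a `motif_result`: data.frame with `motif`, `length`, `support`,
#'   plus an `offsets` attribute (list, per motif, of named 1-based first
#'   occurrence offsets in each supporting sequence).
#' @export
longest_common_substring <- function(seqs, min_support_frac = 1,
                                     min_len = 6L) {
    if (length(seqs) < 2L)
        user_error("need at least 2 sequences")
    if (min_support_frac <= 0 || min_support_frac > 1)
        user_error("min_support_frac must lie in (0, 1]")
    seqs <- toupper(seqs)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    n <- length(seqs)
    need <- as.integer(ceiling(min_support_frac * n))
    lens <- sort(nchar(seqs), decreasing = TRUE)
    Lmax <- lens[need]        # longest length hosted by `need` sequences
    empty <- data.frame(motif = character(), length = integer(),
                        support = integer(), stringsAsFactors = FALSE)
    if (Lmax < min_len) {
        class(empty) <- c("motif_result", "data.frame")
        return(empty)
    }
    for (L in seq(Lmax, min_len, by = -1L)) {
        cand <- sort(unique(unlist(lapply(seqs, all_substrings, L = L))))
        if (!length(cand)) next
        support <- vapply(cand, function(m) {
            sum(vapply(seqs, function(s) grepl(m, s, fixed = TRUE),
                       logical(1)))
        }, integer(1))
        hit <- support >= need
        if (any(hit)) {
            motifs <- cand[hit]
            offsets <- lapply(motifs, function(m) {
                p <- regexpr(m, seqs, fixed = TRUE)
                setNames(as.integer(p[p > 0]), names(seqs)[p > 0])
            })
            out <- data.frame(motif = motifs, length = L,
                              support = unname(support[hit]),
                              stringsAsFactors = FALSE)
            attr(out, "offsets") <- setNames(offsets, motifs)
            class(out) <- c("motif_result", "data.frame")
            return(out)
        }
    }
    class(empty) <- c("motif_result", "data.frame")
    empty
}

#' Ungapped consensus around an anchor motif
#'
#' Left-aligns all sequences on the first occurrence of `anchor_motif`
#' (which must be present in every sequence), pads flanks with `-`, and
#' reports the per-column majority base and agreement fraction (computed
#' over non-gap characters; base ties resolve lexicographically).
#'
#' @param seqs character vector of sequences, all containing the motif.
#' @param anchor_motif the anchoring motif string.
#' @return list with `alignment` (padded strings), `consensus`,
#'   `agreement` (numeric per column), and `motif_cols` (1-based column
#'   range occupied by the motif).
#' @export
ungapped_consensus <- function(seqs, anchor_motif) {
    anchor_motif <- toupper(anchor_motif)
    seqs <- toupper(seqs)
    off <- regexpr(anchor_motif, seqs, fixed = TRUE)
    if (any(off < 0))
        user_error("anchor motif absent from sequence %s",
                   which(off < 0)[1])
    shift <- max(off) - off
    padded <- paste0(strrep("-", shift), seqs)
    width <- max(nchar(padded))
    padded <- paste0(padded, strrep("-", width - nchar(padded)))
    mat <- do.call(rbind, strsplit(padded, "", fixed = TRUE))
    cons <- character(width)
    agree <- numeric(width)
    for (j in seq_len(width)) {
        col <- mat[, j]
        col <- col[col != "-"]
        if (!length(col)) { cons[j] <- "-"; agree[j] <- 0; next }
        tab <- table(col)
        cons[j] <- sort(names(tab)[tab == max(tab)])[1]
        agree[j] <- max(tab) / length(col)
    }
    list(alignment = padded, consensus = paste(cons, collapse = ""),
         agreement = agree,
         motif_cols = seq(max(off), max(off) + nchar(anchor_motif) - 1L))
}
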