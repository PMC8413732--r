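#' Read gene sets in GMT format
#'
#' Tab-separated lines: set id, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `description` attribute
#'   (named character vector).
#' @export
read_gmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        user_error("malformed GMT line %d in %s (need id, description, genes)",
                   bad[1], path)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L),
                                          names(sets))
    sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of the
#' observed overlap with the query (the same core as [overlap_test()]),
#' BH-adjusted across sets. Query genes outside the universe are dropped
#' with a message.
#'
#' @param query character vector of genes of interest.
#' @param gmt named list of gene sets (see [read_gmt()]).
#' @param universe background gene set; defaults to the union of all GMT
#'   genes.
#' @return data.frame sorted by p: `set_id`, `set_name`, `k`, `K`, `n`,
#'   `N`, `p`, `q_bh`, with an `n_dropped` attribute.
#' @export
ora <- function(query, gmt, universe = NULL) {
    if (!length(gmt)) user_error("gmt must contain at least one set")
    if (is.null(universe)) universe <- unique(unlist(gmt))
    universe <- unique(universe)
    query <- unique(query)
    dropped <- setdiff(query, universe)
    if (length(dropped)) {
        message(length(dropped), " query gene(s) outside the universe dropped")
        query <- intersect(query, universe)
    }
    if (!length(query)) user_error("no query genes left inside the universe")
    desc <- attr(gmt, "description") %||%
        setNames(names(gmt), names(gmt))
    rows <- lapply(names(gmt), function(sid) {
        set <- intersect(gmt[[sid]], universe)
        ot <- overlap_test(set, query, universe)
        data.frame(set_id = sid, set_name = unname(desc[sid]), k = ot$k,
                   K = ot$K, n = ot$n, N = ot$N, p = ot$p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_bh <- adjust_bh(out$p)
    out <- out[order(out$p, out$set_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- length(dropped)
    out
}
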