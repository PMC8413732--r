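#' Predict piRNA target sites on one sequence
#'
#' Implements the 5'-anchored complementarity rule: the 5'-most 20 nt of the
#' piRNA (positions 1-20) are compared against the reverse complement of
#' every 20-nt window of the target (an antiparallel duplex); a site is
#' reported when the number of non-Watson-Crick positions is at most
#' `max_mismatch` (i.e. fewer than 3 mismatches at the default) and, when
#' `anchor_match` is on, piRNA position 1 pairs perfectly. G:U wobble is not
#' allowed; ambiguous bases (N) always count as mismatches. For short
#' targets (`target_kind = "mirna"`) that cannot host a 20-nt duplex, the
#' window is truncated to the target length and the mismatch budget scaled
#' proportionally (`floor(max_mismatch * w / 20)`); set
#' `skip_short = TRUE` to drop such targets instead.
#'
#' @param pirna piRNA sequence (>= 20 nt; U is treated as T).
#' @param target target sequence (mRNA transcript or miRNA).
#' @param max_mismatch maximum mismatches inside the window (default 2).
#' @param anchor_match require a perfect Watson-Crick pair at piRNA
#'   position 1 (default on).
#' @param target_kind `"mrna"` or `"mirna"` (controls short-target
#'   handling).
#' @param skip_short for miRNA targets shorter than 20 nt, return no sites
#'   instead of truncating the window.
#' @return data.frame of sites sorted by (mismatches, start): `start`
#'   (0-based on the target; the site occupies `[start, start + w)`),
#'   `mismatches`, `width`.
#' @export
find_targets <- function(pirna, target, max_mismatch = 2L,
                         anchor_match = TRUE,
                         target_kind = c("mrna", "mirna"),
                         skip_short = FALSE) {
    target_kind <- match.arg(target_kind)
    pirna <- chartr("U", "T", toupper(pirna))
    target <- chartr("U", "T", toupper(target))
    if (nchar(pirna) < 20L)
        user_error("piRNA must be at least 20 nt (got %d)", nchar(pirna))
    w <- 20L
    mm_cap <- as.integer(max_mismatch)
    if (nchar(target) < 20L) {
        if (target_kind != "mirna" || skip_short)
            return(data.frame(start = integer(), mismatches = integer(),
                              width = integer()))
        w <- nchar(target)
        mm_cap <- as.integer(floor(max_mismatch * w / 20))
    }
    window <- substr(pirna, 1L, w)
    hits <- cpp_find_sites(window, target, mm_cap, anchor_match)
    out <- data.frame(start = hits$start, mismatches = hits$mismatches,
                      width = rep(w, length(hits$start)))
    out[order(out$mismatches, out$start), , drop = FALSE]
}

#' Build a bipartite piRNA -> target map
#'
#' Applies [find_targets()] over the cross-product of the supplied piRNA set
#' (typically the DE piRNAs of one contrast) and target set, keeping the
#' best site per pair (fewest mismatches, then smallest start).
#'
#' @param pirnas named character vector, id -> sequence.
#' @param targets named character vector, id -> sequence.
#' @param kind `"mrna"` or `"mirna"`.
#' @param max_mismatch,anchor_match,skip_short passed to [find_targets()].
#' @return an object of class `target_map`: list with `edges` (data.frame:
#'   pirna_id, target_id, kind, start, mismatches, width) and `kind`.
#' @export
build_target_map <- function(pirnas, targets, kind = c("mrna", "mirna"),
                             max_mismatch = 2L, anchor_match = TRUE,
                             skip_short = FALSE) {
    kind <- match.arg(kind)
    pirnas <- chartr("U", "T", toupper(pirnas))
    targets <- chartr("U", "T", toupper(targets))
    if (any(nchar(pirnas) < 20L))
        user_error("all piRNAs must be at least 20 nt")
    ep <- et <- character(); es <- em <- ew <- integer()
    tlen <- nchar(targets)
    for (pid in names(pirnas)) {
        window20 <- substr(pirnas[[pid]], 1L, 20L)
        for (ti in seq_along(targets)) {
            w <- 20L; mm_cap <- as.integer(max_mismatch)
            if (tlen[ti] < 20L) {
                if (kind != "mirna" || skip_short) next
                w <- tlen[ti]
                mm_cap <- as.integer(floor(max_mismatch * w / 20))
            }
            win <- if (w == 20L) window20 else substr(pirnas[[pid]], 1L, w)
            hits <- cpp_find_sites(win, targets[[ti]], mm_cap, anchor_match)
            if (length(hits$start)) {
                b <- which.min(hits$mismatches)   # earliest start wins ties
                ep <- c(ep, pid); et <- c(et, names(targets)[ti])
                es <- c(es, hits$start[b]); em <- c(em, hits$mismatches[b])
                ew <- c(ew, w)
            }
        }
    }
    edges <- data.frame(pirna_id = ep, target_id = et,
                        kind = rep(kind, length(ep)), start = es,
                        mismatches = em, width = ew,
                        stringsAsFactors = FALSE)
    structure(list(edges = edges, kind = kind), class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
    cat(sprintf("target_map (%s): %d edges, %d piRNAs, %d targets\n",
                x$kind, nrow(x$edges), length(unique(x$edges$pirna_id)),
                length(unique(x$edges$target_id))))
    invisible(x)
}

#' Targets of one piRNA / piRNAs hitting one target
#'
#' @param map a `target_map`.
#' @param id feature id.
#' @return character vector of ids on the other side of the map.
#' @export
targets_of <- function(map, id) {
    unique(map$edges$target_id[map$edges$pirna_id == id])
}

#' @rdname targets_of
#' @export
pirnas_hitting <- function(map, id) {
    unique(map$edges$pirna_id[map$edges$target_id == id])
}

#' Export a target map as SIF and GraphML
#'
#' SIF lines take the form `pirna_id pt target_id`. The GraphML file types
#' nodes (`pirna` / `mrna` / `mirna`), carries mismatch counts as an edge
#' attribute, and optionally per-node DE directions.
#'
#' @param map a `target_map`.
#' @param sif_path,graphml_path output paths (either may be `NULL` to skip).
#' @param de_directions optional named character vector (feature id ->
#'   `"up"` / `"down"`) stored as a node attribute.
#' @return invisibly, the written paths.
#' @export
export_network <- function(map, sif_path = NULL, graphml_path = NULL,
                           de_directions = NULL) {
    e <- map$edges
    out <- character()
    if (!is.null(sif_path)) {
        writeLines(if (nrow(e)) paste(e$pirna_id, "pt", e$target_id)
                   else character(), sif_path)
        out["sif"] <- sif_path
    }
    if (!is.null(graphml_path)) {
        nodes <- data.frame(
            name = c(unique(e$pirna_id), unique(e$target_id)),
            type = c(rep("pirna", length(unique(e$pirna_id))),
                     rep(map$kind, length(unique(e$target_id)))),
            stringsAsFactors = FALSE)
        nodes$direction <- if (is.null(de_directions)) "" else {
            d <- de_directions[nodes$name]
            ifelse(is.na(d), "", d)
        }
        g <- igraph::graph_from_data_frame(
            e[, c("pirna_id", "target_id", "mismatches")],
            directed = TRUE, vertices = nodes)
        igraph::write_graph(g, graphml_path, format = "graphml")
        out["graphml"] <- graphml_path
    }
    invisible(out)
}

#' Write / read a target edge list as TSV
#'
#' @param map a `target_map`.
#' @param path TSV path.
#' @return `write_target_map()`: the path invisibly; `read_target_map()`:
#'   a `target_map`.
#' @export
write_target_map <- function(map, path) {
    write.table(map$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname write_target_map
#' @export
read_target_map <- function(path) {
    e <- read.delim(path, stringsAsFactors = FALSE)
    kind <- if (nrow(e)) e$kind[1] else "mrna"
    structure(list(edges = e, kind = kind), class = "target_map")
}
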