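#' Reference sequence bundle
#'
#' A named collection of reference sequence sets, one per small-RNA class,
#' consumed by the read matcher ([match_reference()]) and the target
#' predictor ([build_target_map()]). Classes are kept in the hierarchical
#' matching order used throughout: miRNA, rRNA, tRNA, piRNA, then mRNA
#' (mRNA transcripts are target space only and are never matched against
#' small reads).
#'
#' @param pirna,mirna,mrna,rrna,trna named character vectors of uppercase
#'   A/C/G/T(/N) sequences; names are feature ids, unique across the whole
#'   bundle.
#' @return an object of class `reference_bundle`: a named list of named
#'   character vectors, in matching order.
#' @export
reference_bundle <- function(pirna = character(), mirna = character(),
                             mrna = character(), rrna = character(),
                             trna = character()) {
    sets <- list(mirna = mirna, rrna = rrna, trna = trna,
                 pirna = pirna, mrna = mrna)
    for (cls in names(sets)) {
        s <- sets[[cls]]
        if (length(s)) {
            if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
                user_error("all %s sequences must be named", cls)
            if (any(nchar(s) == 0))
                user_error("empty sequence in class %s", cls)
            sets[[cls]] <- setNames(toupper(s), names(s))
        }
    }
    ids <- unlist(lapply(sets, names), use.names = FALSE)
    if (anyDuplicated(ids))
        user_error("feature ids must be unique across the bundle")
    structure(sets, class = "reference_bundle")
}

#' @export
print.reference_bundle <- function(x, ...) {
    cat("reference_bundle:",
        paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
    invisible(x)
}

#' Write a reference bundle to FASTA files
#'
#' One FASTA file per non-empty class, named `<class>.fa`.
#'
#' @param bundle a [reference_bundle()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (cls in names(bundle)) {
        if (!length(bundle[[cls]])) next
        p <- file.path(dir, paste0(cls, ".fa"))
        Biostrings::writeXStringSet(
            Biostrings::DNAStringSet(bundle[[cls]]), p)
        paths[cls] <- p
    }
    invisible(paths)
}

#' Read a reference bundle from a directory of FASTA files
#'
#' Expects files `<class>.fa` (class in mirna, rrna, trna, pirna, mrna);
#' missing classes are left empty.
#'
#' @param dir directory written by [write_reference_bundle()] (or assembled
#'   by hand).
#' @return a [reference_bundle()].
#' @export
read_reference_bundle <- function(dir) {
    args <- list()
    for (cls in c("mirna", "rrna", "trna", "pirna", "mrna")) {
        p <- file.path(dir, paste0(cls, ".fa"))
        if (file.exists(p)) {
            ss <- Biostrings::readDNAStringSet(p)
            args[[cls]] <- setNames(as.character(ss), names(ss))
        }
    }
    do.call(reference_bundle, args)
}
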