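#' Feature x sample count matrix with design and clean-read totals
#'
#' The basic container for quantified small-RNA (or mRNA) counts: an integer
#' matrix plus the sample -> group design and the per-sample total clean
#' read counts that serve as the tags-per-million denominator.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param design data.frame with columns `sample` and `group`; must cover
#'   every column of `counts`.
#' @param total_clean named per-sample totals of clean reads; defaults to
#'   the column sums (every clean read quantified).
#' @param feature_class optional named character vector mapping feature ids
#'   to classes (pirna, mirna, mrna, rrna, trna).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design,
                         total_clean = colSums(counts),
                         feature_class = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        user_error("counts must have feature and sample dimnames")
    if (any(counts < 0)) user_error("counts must be non-negative")
    if (!all(c("sample", "group") %in% names(design)))
        user_error("design needs columns 'sample' and 'group'")
    if (!setequal(design$sample, colnames(counts)))
        user_error("design samples must match count matrix columns")
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
    rownames(design) <- NULL
    if (is.null(names(total_clean)))
        names(total_clean) <- colnames(counts)
    total_clean <- total_clean[colnames(counts)]
    if (anyNA(total_clean))
        user_error("total_clean must cover every sample")
    structure(list(counts = counts, design = design,
                   total_clean = total_clean,
                   feature_class = feature_class),
              class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
    cat(sprintf("count_matrix: %d features x %d samples (groups: %s)\n",
                nrow(x$counts), ncol(x$counts),
                paste(unique(x$design$group), collapse = ", ")))
    invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Restrict a count matrix to one feature class
#'
#' @param cm a [count_matrix()] carrying a `feature_class` map.
#' @param class feature class to keep (e.g. `"pirna"`).
#' @return a [count_matrix()]; `total_clean` is carried through unchanged
#'   (it stays the whole-library denominator).
#' @export
subset_class <- function(cm, class) {
    if (is.null(cm$feature_class))
        user_error("count matrix carries no feature_class map")
    keep <- names(cm$feature_class)[cm$feature_class == class]
    keep <- intersect(rownames(cm$counts), keep)
    count_matrix(cm$counts[keep, , drop = FALSE], cm$design,
                 cm$total_clean, cm$feature_class[keep])
}

#' Write / read a count matrix as TSV
#'
#' `write_count_matrix()` writes `<prefix>_counts.tsv` (feature_id + one
#' column per sample) and `<prefix>_design.tsv` (sample, group, total_clean,
#' optional class map in `<prefix>_classes.tsv`); `read_count_matrix()`
#' reads them back.
#'
#' @param cm a [count_matrix()].
#' @param prefix path prefix (directory part must exist or is created).
#' @return `write_count_matrix()`: the paths, invisibly;
#'   `read_count_matrix()`: a [count_matrix()].
#' @export
write_count_matrix <- function(cm, prefix) {
    dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
    pc <- paste0(prefix, "_counts.tsv")
    pd <- paste0(prefix, "_design.tsv")
    write.table(data.frame(feature_id = rownames(cm$counts), cm$counts,
                           check.names = FALSE),
                pc, sep = "\t", quote = FALSE, row.names = FALSE)
    d <- cm$design
    d$total_clean <- cm$total_clean[d$sample]
    write.table(d, pd, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(counts = pc, design = pd)
    if (!is.null(cm$feature_class)) {
        pk <- paste0(prefix, "_classes.tsv")
        write.table(data.frame(feature_id = names(cm$feature_class),
                               class = unname(cm$feature_class)),
                    pk, sep = "\t", quote = FALSE, row.names = FALSE)
        paths["classes"] <- pk
    }
    invisible(paths)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
    if (!file.exists(paste0(prefix, "_counts.tsv")))
        user_error("no count matrix at prefix '%s'", prefix)
    cnt <- read.delim(paste0(prefix, "_counts.tsv"), check.names = FALSE)
    m <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(m) <- cnt$feature_id
    storage.mode(m) <- "integer"
    d <- read.delim(paste0(prefix, "_design.tsv"))
    fc <- NULL
    pk <- paste0(prefix, "_classes.tsv")
    if (file.exists(pk)) {
        k <- read.delim(pk)
        fc <- setNames(k$class, k$feature_id)
    }
    count_matrix(m, d[c("sample", "group")],
                 setNames(d$total_clean, d$sample), fc)
}
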