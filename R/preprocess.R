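# Strict 4-line FASTQ parser. Errors carry the 1-based line number of the
# offending record so malformed files are easy to locate.
read_fastq <- function(path) {
    lines <- readLines(path)
    n <- length(lines)
    if (n == 0)
        return(data.frame(id = character(), seq = character(),
                          qual = character(), stringsAsFactors = FALSE))
    if (n %% 4L != 0L)
        user_error("truncated FASTQ record starting at line %d in %s",
                   (n %/% 4L) * 4L + 1L, path)
    hd <- lines[seq(1L, n, by = 4L)]
    sq <- lines[seq(2L, n, by = 4L)]
    pl <- lines[seq(3L, n, by = 4L)]
    ql <- lines[seq(4L, n, by = 4L)]
    bad <- which(!startsWith(hd, "@"))
    if (length(bad))
        user_error("missing '@' header at line %d in %s", (bad[1] - 1L) * 4L + 1L,
                   path)
    bad <- which(!startsWith(pl, "+"))
    if (length(bad))
        user_error("missing '+' separator at line %d in %s",
                   (bad[1] - 1L) * 4L + 3L, path)
    bad <- which(nchar(sq) != nchar(ql))
    if (length(bad))
        user_error("sequence/quality length mismatch at line %d in %s",
                   (bad[1] - 1L) * 4L + 2L, path)
    data.frame(id = sub("\\s.*", "", substring(hd, 2L)), seq = toupper(sq),
               qual = ql, stringsAsFactors = FALSE)
}

mean_phred <- function(qual) {
    vapply(qual, function(q) {
        if (nchar(q) == 0) return(0)
        mean(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
}

#' Filter raw small-RNA reads
#'
#' Trims the 3' adapter (detected by the first exact occurrence of its first
#' 8 nt), then drops reads failing the mean base-quality threshold or lying
#' outside the accepted length window. The number of retained reads is the
#' `total_clean` denominator used by TPM normalisation.
#'
#' @param fastq path to a FASTQ file, or a data.frame with columns
#'   `id`, `seq`, `qual`.
#' @param adapter optional 3' adapter sequence (length >= 8); `NULL` skips
#'   trimming.
#' @param min_len,max_len accepted insert length window (nt).
#' @param min_mean_qual minimum mean Phred quality of the (trimmed) insert.
#' @return an object of class `clean_reads`: list with `reads` (id, seq,
#'   qual), `stats` (input, adapter_trimmed, quality_failed, length_failed,
#'   retained) and `total_clean`.
#' @export
filter_reads <- function(fastq, adapter = NULL, min_len = 16L, max_len = 30L,
                         min_mean_qual = 20) {
    reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
    input <- nrow(reads)
    trimmed <- 0L
    if (input > 0 && !is.null(adapter)) {
        adapter <- toupper(adapter)
        if (nchar(adapter) < 8L)
            user_error("adapter must be at least 8 nt")
        seed <- substr(adapter, 1L, 8L)
        pos <- regexpr(seed, reads$seq, fixed = TRUE)
        hit <- pos > 0L
        trimmed <- sum(hit)
        reads$seq[hit] <- substr(reads$seq[hit], 1L, pos[hit] - 1L)
        reads$qual[hit] <- substr(reads$qual[hit], 1L, pos[hit] - 1L)
    }
    if (input > 0) {
        qual_ok <- mean_phred(reads$qual) >= min_mean_qual
        len <- nchar(reads$seq)
        len_ok <- len >= min_len & len <= max_len
        quality_failed <- sum(!qual_ok)
        length_failed <- sum(qual_ok & !len_ok)
        reads <- reads[qual_ok & len_ok, , drop = FALSE]
        rownames(reads) <- NULL
    } else {
        quality_failed <- length_failed <- 0L
    }
    structure(list(reads = reads,
                   stats = c(input = input, adapter_trimmed = trimmed,
                             quality_failed = quality_failed,
                             length_failed = length_failed,
                             retained = nrow(reads)),
                   total_clean = nrow(reads)),
              class = "clean_reads")
}

#' Assign clean reads to reference classes hierarchically
#'
#' A read matches a reference when it is a contiguous substring of it with
#' at most `max_mismatch` Hamming mismatches. Classes are tried in the fixed
#' exclusion order miRNA, rRNA, tRNA, piRNA; a read claimed by an earlier
#' class is never passed on, so miRNA/rRNA/tRNA reads are excluded from the
#' piRNA count set. Within a class the best hit has the fewest mismatches,
#' ties broken by the lexicographically smallest feature id.
#'
#' @param reads a `clean_reads` object from [filter_reads()].
#' @param refs a [reference_bundle()].
#' @param max_mismatch maximum Hamming mismatches (default 1).
#' @param revcomp_reads also try the reverse complement of each read
#'   (default off: stranded sense libraries).
#' @return an object of class `read_assignments`: data.frame with columns
#'   `read_id`, `seq`, `class`, `feature_id`, `mismatches` (class
#'   `"unassigned"` and NA feature for unmatched reads), with the
#'   `total_clean` of the input attached as an attribute.
#' @export
match_reference <- function(reads, refs, max_mismatch = 1L,
                            revcomp_reads = FALSE) {
    if (!inherits(reads, "clean_reads"))
        user_error("reads must come from filter_reads()")
    if (!inherits(refs, "reference_bundle"))
        user_error("refs must be a reference_bundle")
    seqs <- reads$reads$seq
    uniq <- unique(seqs)
    cls <- rep("unassigned", length(uniq))
    fid <- rep(NA_character_, length(uniq))
    mm <- rep(NA_integer_, length(uniq))
    pending <- seq_along(uniq)
    queries <- uniq
    if (revcomp_reads && length(uniq)) rc <- revcomp(uniq)
    for (class in c("mirna", "rrna", "trna", "pirna")) {
        if (!length(pending) || !length(refs[[class]])) next
        ord <- order(names(refs[[class]]))
        ref_seq <- unname(refs[[class]])[ord]
        ref_ids <- names(refs[[class]])[ord]
        hits <- cpp_match_class(queries[pending], ref_seq, max_mismatch)
        if (revcomp_reads) {
            hits_rc <- cpp_match_class(rc[pending], ref_seq, max_mismatch)
            better <- !is.na(hits_rc[, 2]) &
                (is.na(hits[, 2]) | hits_rc[, 2] < hits[, 2])
            hits[better, ] <- hits_rc[better, ]
        }
        found <- which(!is.na(hits[, 1]))
        if (length(found)) {
            idx <- pending[found]
            cls[idx] <- class
            fid[idx] <- ref_ids[hits[found, 1]]
            mm[idx] <- hits[found, 2]
            pending <- pending[-found]
        }
    }
    take <- match(seqs, uniq)
    out <- data.frame(read_id = reads$reads$id, seq = seqs,
                      class = cls[take], feature_id = fid[take],
                      mismatches = mm[take], stringsAsFactors = FALSE)
    structure(out, class = c("read_assignments", "data.frame"),
              total_clean = reads$total_clean)
}

#' Quantify per-feature counts from read assignments
#'
#' @param assignments named list (sample id -> `read_assignments`); each
#'   element carries its `total_clean` attribute from [match_reference()].
#' @param design data.frame with columns `sample`, `group` covering every
#'   assignment.
#' @param features character vector of feature ids forming the full row
#'   index (features with zero assigned reads keep a zero row).
#' @param class which assignment class to count (default `"pirna"`).
#' @return a [count_matrix()] with per-sample `total_clean` carried through.
#' @export
quantify <- function(assignments, design, features, class = "pirna") {
    if (is.null(names(assignments)))
        user_error("assignments must be a named list (sample -> assignments)")
    unknown <- setdiff(names(assignments), design$sample)
    if (length(unknown))
        user_error("sample '%s' absent from the design table", unknown[1])
    samples <- design$sample
    m <- matrix(0L, nrow = length(features), ncol = length(samples),
                dimnames = list(features, samples))
    tc <- setNames(rep(0, length(samples)), samples)
    for (smp in names(assignments)) {
        a <- assignments[[smp]]
        tc[smp] <- attr(a, "total_clean") %||% nrow(a)
        a <- a[a$class == class & a$feature_id %in% features, , drop = FALSE]
        if (nrow(a)) {
            tab <- table(a$feature_id)
            m[names(tab), smp] <- m[names(tab), smp] + as.integer(tab)
        }
    }
    count_matrix(m, design, total_clean = tc,
                 feature_class = setNames(rep(class, length(features)),
                                          features))
}

#' Tags-per-million normalisation
#'
#' `tpm[f, s] = count[f, s] / total_clean[s] * 1e6`, with the per-sample
#' total of clean reads (not the class-specific sum) as the denominator.
#'
#' @param cm a [count_matrix()] with positive `total_clean` for every
#'   sample.
#' @return a numeric matrix of the same shape.
#' @export
tpm_normalize <- function(cm) {
    if (any(cm$total_clean <= 0))
        user_error("total_clean must be positive for every sample")
    sweep(cm$counts, 2L, cm$total_clean, "/") * 1e6
}

# Minimal BED reader (0-based half-open; chrom, start, end, name[, ...]).
read_bed <- function(x) {
    if (is.data.frame(x)) {
        names(x)[1:3] <- c("chrom", "start", "end")
        if (ncol(x) < 4L) x$name <- paste0(x$chrom, ":", x$start, "-", x$end)
        names(x)[4] <- "name"
        return(x[, 1:4])
    }
    lines <- readLines(x)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        user_error("malformed BED line %d in %s (fewer than 3 fields)",
                   bad[1], x)
    start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
    if (length(bad))
        user_error("malformed BED line %d in %s (bad coordinates)", bad[1], x)
    chrom <- vapply(parts, `[`, "", 1L)
    name <- vapply(parts, function(p) if (length(p) >= 4L) p[4] else NA_character_,
                   "")
    name[is.na(name)] <- paste0(chrom, ":", start, "-", end)[is.na(name)]
    data.frame(chrom = chrom, start = start, end = end, name = name,
               stringsAsFactors = FALSE)
}

#' Annotate piRNA loci with genomic context classes
#'
#' Each locus receives the highest-priority annotation class it overlaps by
#' at least one base; loci overlapping nothing are called `"genomic"`.
#' Repeat subclasses are encoded in the annotation name column as
#' `repeat:<subclass>` (e.g. `repeat:LINE1`) and are reported separately
#' within the `repeat` class.
#'
#' @param loci BED file path or data.frame of piRNA positions (0-based
#'   half-open).
#' @param annotation BED file path or data.frame whose name column holds the
#'   class label (`exon`, `promoter`, `intron`, `repeat:<subclass>`).
#' @param priority class precedence, highest first.
#' @return list with `loci` (per-locus assigned class; repeat loci keep the
#'   full `repeat:<subclass>` label), `class_freq` (base classes incl.
#'   `genomic`) and `repeat_freq` (subclass table within repeats).
#' @export
annotate_genomic_context <- function(loci, annotation,
                                     priority = c("exon", "promoter",
                                                  "intron", "repeat")) {
    lb <- read_bed(loci)
    ab <- read_bed(annotation)
    # BED is 0-based half-open; IRanges is 1-based closed
    gl <- GenomicRanges::GRanges(lb$chrom,
                                 IRanges::IRanges(lb$start + 1L, lb$end))
    ga <- GenomicRanges::GRanges(ab$chrom,
                                 IRanges::IRanges(ab$start + 1L, ab$end))
    ov <- GenomicRanges::findOverlaps(gl, ga, minoverlap = 1L)
    assigned <- rep("genomic", nrow(lb))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
        labels <- ab$name[sh[qh == i]]
        base <- sub(":.*$", "", labels)
        rank <- match(base, priority)
        if (all(is.na(rank))) next
        best <- which(rank == min(rank, na.rm = TRUE))
        assigned[i] <- sort(labels[best])[1]   # deterministic subclass tie
    }
    base_class <- sub(":.*$", "", assigned)
    rep_sub <- sub("^repeat:", "", assigned[base_class == "repeat"])
    list(loci = data.frame(lb, class = assigned, stringsAsFactors = FALSE),
         class_freq = table(base_class),
         repeat_freq = table(rep_sub))
}
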