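# Independent brute-force oracles. These deliberately use different
# algorithms and data representations (character vectors / raw bytes /
# exhaustive enumeration) from the package implementation they check.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# All-positions scan for antiparallel complementarity sites: the expected
# site content is the reverse complement of the window, so mismatches are
# plain Hamming distance between each target window and that string.
oracle_sites <- function(pirna, target, max_mm, anchor) {
    w <- min(20L, nchar(target))
    win <- strsplit(substr(pirna, 1, w), "")[[1]]
    rcw <- rev(unname(COMP[win]))
    tch <- strsplit(target, "")[[1]]
    L <- length(tch)
    if (L < w) return(data.frame(start = integer(), mismatches = integer()))
    starts <- 0:(L - w)
    mism <- vapply(starts, function(s) sum(tch[(s + 1):(s + w)] != rcw),
                   integer(1))
    keep <- mism <= max_mm
    if (anchor) keep <- keep & vapply(starts, function(s)
        tch[s + w] == COMP[[win[1]]], logical(1))
    data.frame(start = starts[keep], mismatches = mism[keep])
}

# Best-in-reference-set match for one read: all positions, all references,
# fewest mismatches, ties to the lexicographically smallest id. Raw-byte
# embedding keeps it vectorised but structurally unlike the C++ scan.
oracle_match_best <- function(read, refs, max_mm) {
    rr <- charToRaw(read)
    lr <- length(rr)
    best_id <- NA_character_
    best_mm <- max_mm + 1L
    for (id in sort(names(refs))) {
        rt <- charToRaw(refs[[id]])
        L <- length(rt)
        if (L < lr) next
        np <- L - lr + 1L
        idx <- outer(0:(np - 1L), seq_len(lr), "+")
        mm <- rowSums(matrix(rt[idx], nrow = np) !=
                          matrix(rr, np, lr, byrow = TRUE))
        if (min(mm) < best_mm) {
            best_mm <- as.integer(min(mm))
            best_id <- id
        }
    }
    if (is.na(best_id)) NULL else list(id = best_id, mm = best_mm)
}

# Hierarchical oracle for match_reference: classes in exclusion order.
oracle_assign <- function(read, bundle, max_mm) {
    for (cls in c("mirna", "rrna", "trna", "pirna")) {
        if (!length(bundle[[cls]])) next
        hit <- oracle_match_best(read, bundle[[cls]], max_mm)
        if (!is.null(hit)) return(list(class = cls, id = hit$id, mm = hit$mm))
    }
    list(class = "unassigned", id = NA_character_, mm = NA_integer_)
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of B
# and count overlaps with A = first K universe elements.
oracle_hyper_upper <- function(N, K, n, k) {
    if (n == 0L) return(if (k <= 0) 1 else 0)
    draws <- utils::combn(N, n)
    ov <- colSums(draws <= K)
    mean(ov >= k)
}

# Brute-force common substrings: enumerate every substring of every length,
# count support, report the longest supported set.
oracle_lcs <- function(seqs, min_support_frac = 1, min_len = 6L) {
    n <- length(seqs)
    need <- ceiling(min_support_frac * n)
    subs <- unique(unlist(lapply(seqs, function(s) {
        L <- nchar(s)
        unlist(lapply(seq_len(L), function(a)
            substring(s, a, a:L)))
    })))
    subs <- subs[nchar(subs) >= min_len]
    if (!length(subs)) return(character())
    sup <- vapply(subs, function(m)
        sum(vapply(seqs, function(s) grepl(m, s, fixed = TRUE), logical(1))),
        integer(1))
    ok <- subs[sup >= need]
    if (!length(ok)) return(character())
    sort(ok[nchar(ok) == max(nchar(ok))])
}
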