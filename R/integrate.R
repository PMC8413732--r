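#' Hypergeometric set-overlap test
#'
#' Upper-tail probability of observing at least `|a intersect b|` common
#' elements when sets of sizes `|a|` and `|b|` are drawn without replacement
#' from a shared universe.
#'
#' @param a,b character vectors (subsets of `universe`).
#' @param universe character vector of all eligible elements.
#' @return list (class `overlap_result`): `k` (overlap), `K` (`|a|`), `n`
#'   (`|b|`), `N` (`|universe|`), `overlap` (the common ids), `p`
#'   (`P(X >= k)`, `X ~ Hypergeom(N, K, n)`).
#' @export
overlap_test <- function(a, b, universe) {
    a <- unique(a); b <- unique(b); universe <- unique(universe)
    if (length(universe) < 1L) user_error("universe must be non-empty")
    if (!all(a %in% universe) || !all(b %in% universe))
        user_error("a and b must be subsets of the universe")
    k <- length(intersect(a, b))
    K <- length(a); n <- length(b); N <- length(universe)
    p <- if (k == 0) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    structure(list(k = k, K = K, n = n, N = N,
                   overlap = sort(intersect(a, b)), p = p),
              class = "overlap_result")
}

#' Fold-change correlation between piRNAs and their predicted targets
#'
#' One point per (piRNA, predicted target) edge: the piRNA's normalised
#' log2 fold change against the target's. Pairs with a missing target (or
#' piRNA) fold change are dropped and counted. Pearson by default; the
#' two-sided p-value comes from `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param pirna_lfc named numeric vector, piRNA id -> log2 fold change
#'   (typically `sets$lfc` from [call_de()] for the DE piRNAs).
#' @param map a `target_map` whose edges define the pairs.
#' @param target_lfc named numeric vector, target id -> log2 fold change.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list (class `correlation_result`): `r`, `p`, `n_pairs`,
#'   `n_dropped`, `testable`, `pairs` (the paired table).
#' @export
fc_correlation <- function(pirna_lfc, map, target_lfc,
                           method = c("pearson", "spearman")) {
    method <- match.arg(method)
    e <- map$edges
    e <- e[e$pirna_id %in% names(pirna_lfc), , drop = FALSE]
    x <- pirna_lfc[e$pirna_id]
    y <- target_lfc[e$target_id]
    ok <- !is.na(x) & !is.na(y)
    n_dropped <- sum(!ok)
    pairs <- data.frame(pirna_id = e$pirna_id[ok], target_id = e$target_id[ok],
                        pirna_lfc = unname(x[ok]), target_lfc = unname(y[ok]),
                        stringsAsFactors = FALSE)
    if (nrow(pairs) < 3L) {
        return(structure(list(r = NA_real_, p = NA_real_,
                              n_pairs = nrow(pairs), n_dropped = n_dropped,
                              testable = FALSE, pairs = pairs),
                         class = "correlation_result"))
    }
    ct <- suppressWarnings(cor.test(pairs$pirna_lfc, pairs$target_lfc,
                                    method = method))
    structure(list(r = unname(ct$estimate), p = ct$p.value,
                   n_pairs = nrow(pairs), n_dropped = n_dropped,
                   testable = TRUE, pairs = pairs),
              class = "correlation_result")
}

#' Identify reversal piRNAs
#'
#' A reversal piRNA is differentially expressed in one direction under the
#' drug contrast and in the opposite direction under the treatment contrast:
#' `R_plus = up(drug) intersect down(reversal)` and
#' `R_minus = down(drug) intersect up(reversal)`.
#'
#' @param drug_sets `contrast_sets` for the drug contrast (e.g. CS vs SS).
#' @param reversal_sets `contrast_sets` for the reversal contrast (e.g. MC
#'   vs CS), computed on a shared universe.
#' @return list with `R_plus`, `R_minus`, `all` (their union) and
#'   `universe` (intersection of the two tested universes).
#' @export
find_reversed <- function(drug_sets, reversal_sets) {
    list(R_plus = sort(intersect(drug_sets$up, reversal_sets$down)),
         R_minus = sort(intersect(drug_sets$down, reversal_sets$up)),
         all = sort(union(intersect(drug_sets$up, reversal_sets$down),
                          intersect(drug_sets$down, reversal_sets$up))),
         universe = intersect(drug_sets$universe, reversal_sets$universe))
}

#' Reversal target genes
#'
#' Genes targeted by a reversal piRNA whose direction under the reversal
#' contrast is opposite to that piRNA's: a gene must itself be DE in the
#' reversal contrast to be reported. Multiplicity is kept, so a hub gene
#' targeted by several reversal piRNAs appears with all its supporting
#' piRNAs.
#'
#' @param reversed output of [find_reversed()].
#' @param map a piRNA -> mRNA `target_map`.
#' @param mrna_sets `contrast_sets` for the mRNAs under the reversal
#'   contrast.
#' @return list with `table` (gene_id, gene_direction, pirna_id, one row per
#'   supporting edge) and `support` (named count of supporting piRNAs per
#'   gene, decreasing).
#' @export
reversal_target_genes <- function(reversed, map, mrna_sets) {
    # R_plus piRNAs are down under the reversal contrast, R_minus up
    pir_dir <- c(setNames(rep("down", length(reversed$R_plus)),
                          reversed$R_plus),
                 setNames(rep("up", length(reversed$R_minus)),
                          reversed$R_minus))
    e <- map$edges[map$edges$pirna_id %in% names(pir_dir), , drop = FALSE]
    gene_dir <- c(setNames(rep("up", length(mrna_sets$up)), mrna_sets$up),
                  setNames(rep("down", length(mrna_sets$down)),
                           mrna_sets$down))
    gd <- gene_dir[e$target_id]
    keep <- !is.na(gd) & gd != pir_dir[e$pirna_id]
    tab <- data.frame(gene_id = e$target_id[keep],
                      gene_direction = unname(gd[keep]),
                      pirna_id = e$pirna_id[keep], stringsAsFactors = FALSE)
    tab <- unique(tab[order(tab$gene_id, tab$pirna_id), , drop = FALSE])
    rownames(tab) <- NULL
    support <- sort(table(tab$gene_id), decreasing = TRUE)
    list(table = tab, support = support)
}

#' miRNA -> mRNA targets by the canonical 7-mer seed rule
#'
#' An mRNA is a target of a miRNA when it contains an exact match of the
#' reverse complement of the miRNA seed (positions 2-8).
#'
#' @param mirnas named character vector, id -> sequence.
#' @param mrnas named character vector, id -> sequence.
#' @return data.frame: `mirna_id`, `mrna_id`.
#' @export
seed_match_targets <- function(mirnas, mrnas) {
    out <- list()
    for (mid in names(mirnas)) {
        seed <- revcomp(substr(chartr("U", "T", toupper(mirnas[[mid]])),
                               2L, 8L))
        hit <- names(mrnas)[grepl(seed, mrnas, fixed = TRUE)]
        if (length(hit))
            out[[mid]] <- data.frame(mirna_id = mid, mrna_id = hit,
                                     stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(mirna_id = character(), mrna_id = character(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' piRNA -> miRNA -> mRNA cascade triples
#'
#' Emits every triple in which (i) a DE piRNA targets a DE miRNA whose
#' expression changed in the same direction, and (ii) that miRNA targets an
#' mRNA that changed in the opposite direction. All directions are taken
#' from one contrast.
#'
#' @param pirna_sets,mirna_sets,mrna_sets `contrast_sets` for the same
#'   contrast.
#' @param pirna_mirna_map a piRNA -> miRNA `target_map`.
#' @param mirna_mrna optional data.frame (`mirna_id`, `mrna_id`); when
#'   `NULL`, the built-in seed rule is applied to `mirna_seqs` /
#'   `mrna_seqs` (both then required).
#' @param mirna_seqs,mrna_seqs named sequence vectors for the seed rule.
#' @return data.frame (`pirna_id`, `mirna_id`, `mrna_id`, `pirna_direction`,
#'   `mirna_direction`, `mrna_direction`), deduplicated and sorted.
#' @export
cascade <- function(pirna_sets, mirna_sets, mrna_sets, pirna_mirna_map,
                    mirna_mrna = NULL, mirna_seqs = NULL, mrna_seqs = NULL) {
    if (is.null(mirna_mrna)) {
        if (is.null(mirna_seqs) || is.null(mrna_seqs))
            user_error(paste("provide a mirna_mrna table or sequences for",
                             "the built-in seed rule"))
        mirna_mrna <- seed_match_targets(mirna_seqs, mrna_seqs)
    }
    dir_of <- function(sets) c(setNames(rep("up", length(sets$up)), sets$up),
                               setNames(rep("down", length(sets$down)),
                                        sets$down))
    pd <- dir_of(pirna_sets); md <- dir_of(mirna_sets)
    gd <- dir_of(mrna_sets)
    e <- pirna_mirna_map$edges
    e <- e[e$pirna_id %in% names(pd) & e$target_id %in% names(md), ,
           drop = FALSE]
    same <- pd[e$pirna_id] == md[e$target_id]
    e <- e[!is.na(same) & same, , drop = FALSE]
    if (!nrow(e))
        return(data.frame(pirna_id = character(), mirna_id = character(),
                          mrna_id = character(), pirna_direction = character(),
                          mirna_direction = character(),
                          mrna_direction = character(),
                          stringsAsFactors = FALSE))
    tri <- merge(e[, c("pirna_id", "target_id")], mirna_mrna,
                 by.x = "target_id", by.y = "mirna_id")
    names(tri)[names(tri) == "target_id"] <- "mirna_id"
    opp <- gd[tri$mrna_id]
    keep <- !is.na(opp) & opp != md[tri$mirna_id]
    tri <- tri[keep, , drop = FALSE]
    out <- data.frame(pirna_id = tri$pirna_id, mirna_id = tri$mirna_id,
                      mrna_id = tri$mrna_id,
                      pirna_direction = unname(pd[tri$pirna_id]),
                      mirna_direction = unname(md[tri$mirna_id]),
                      mrna_direction = unname(gd[tri$mrna_id]),
                      stringsAsFactors = FALSE)
    out <- unique(out[order(out$pirna_id, out$mirna_id, out$mrna_id), ,
                      drop = FALSE])
    rownames(out) <- NULL
    out
}
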