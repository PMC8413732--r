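#' Configuration for a full pipeline run
#'
#' Bundles the simulation config, contrast list, thresholds and stage
#' toggles consumed by [run_all()]. The default contrasts follow the
#' four-group design: drug vs baseline (CS:SS), treatment vs baseline
#' (MS:SS) and combined vs drug (MC:CS) - the reversal contrast.
#'
#' @param outdir output directory for all stage files.
#' @param seed integer seed forwarded to the simulation config.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param contrasts list of 2-vectors; the first is treated as the drug
#'   contrast and the last as the reversal contrast.
#' @param q_threshold,gate DE calling parameters (see [call_de()]).
#' @param max_mismatch,anchor_match target-rule parameters (see
#'   [find_targets()]).
#' @param use_reads simulate raw FASTQ and run the read-level preprocess
#'   stage (piRNA/miRNA counts are then re-quantified from reads; mRNA
#'   counts always come from the count simulation since mRNAs are not
#'   part of a small-RNA library).
#' @param adapter,frac_short,frac_lowqual read-simulation knobs.
#' @param gmt optional GMT file path for the enrichment stage.
#' @param stages named logical vector toggling stages; disabling a stage a
#'   later enabled stage depends on is an error.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, sim = sim_config(seed = seed),
                       contrasts = list(c("CS", "SS"), c("MS", "SS"),
                                        c("MC", "CS")),
                       q_threshold = 0.05, gate = "bh", max_mismatch = 2L,
                       anchor_match = TRUE, use_reads = FALSE,
                       adapter = NULL, frac_short = 0, frac_lowqual = 0,
                       gmt = NULL,
                       stages = c(simulate = TRUE, preprocess = use_reads,
                                  de = TRUE, targets = TRUE,
                                  integrate = TRUE, motif = TRUE,
                                  enrich = !is.null(gmt))) {
    groups <- sim$groups
    for (ct in contrasts) {
        if (!all(ct %in% groups))
            user_error("contrast %s references undeclared groups",
                       paste(ct, collapse = ":"))
    }
    structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                   contrasts = contrasts, q_threshold = q_threshold,
                   gate = gate, max_mismatch = as.integer(max_mismatch),
                   anchor_match = anchor_match, use_reads = use_reads,
                   adapter = adapter, frac_short = frac_short,
                   frac_lowqual = frac_lowqual, gmt = gmt,
                   stages = stages),
              class = "run_config")
}

contrast_name <- function(ct) paste0(ct[1], "vs", ct[2])

check_stage_deps <- function(stages) {
    deps <- list(preprocess = "simulate", de = "simulate",
                 targets = c("simulate", "de"),
                 integrate = c("de", "targets"), motif = "integrate",
                 enrich = "integrate")
    for (st in names(deps)) {
        if (isTRUE(stages[st]) && !all(stages[deps[[st]]]))
            user_error("stage '%s' requires stage(s): %s", st,
                       paste(deps[[st]][!stages[deps[[st]]]], collapse = ", "))
    }
}

#' Run the full simulated analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, de, targets,
#' integrate, motif, enrich), writes per-stage files under
#' `config$outdir`, and returns a machine-readable report (also written as
#' `report.json`). The report includes planted-truth recovery scores and is
#' a pure function of the configuration: identical seed and config yield an
#' identical `run_digest`.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a nested list).
#' @export
run_all <- function(config) {
    if (!inherits(config, "run_config"))
        user_error("config must come from run_config()")
    stages <- config$stages
    check_stage_deps(stages)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    report <- list(package = "pirnakit",
                   seed = config$seed,
                   stages = as.list(stages),
                   parameters = list(
                       q_threshold = config$q_threshold, gate = config$gate,
                       max_mismatch = config$max_mismatch,
                       anchor_match = config$anchor_match,
                       depth = config$sim$depth, phi = config$sim$phi,
                       delta = config$sim$delta, rho = config$sim$rho,
                       beta = config$sim$beta, gamma = config$sim$gamma))
    files <- character()

    ## -- simulate ---------------------------------------------------------
    gen <- NULL; counts <- NULL
    if (isTRUE(stages["simulate"])) {
        gen <- generate_references(config$sim)
        counts <- simulate_counts(gen$truth, config$sim)
        files <- c(files, write_reference_bundle(gen$refs,
                                                 file.path(config$outdir, "refs")))
        files <- c(files, write_truth(gen$truth,
                                      file.path(config$outdir, "truth")))
        files <- c(files, write_count_matrix(counts,
                                             file.path(config$outdir, "sim")))
        if (config$use_reads) {
            files <- c(files, simulate_reads(
                counts, gen$refs, config$sim,
                file.path(config$outdir, "fastq"),
                adapter = config$adapter, frac_short = config$frac_short,
                frac_lowqual = config$frac_lowqual))
        }
    }

    ## -- preprocess -------------------------------------------------------
    de_counts <- counts
    if (isTRUE(stages["preprocess"]) && config$use_reads) {
        asn <- list()
        stats <- list()
        for (smp in counts$design$sample) {
            clean <- filter_reads(file.path(config$outdir, "fastq",
                                            paste0(smp, ".fastq")),
                                  adapter = config$adapter)
            asn[[smp]] <- match_reference(clean, gen$refs)
            stats[[smp]] <- as.list(clean$stats)
        }
        small <- list()
        for (cls in c("pirna", "mirna")) {
            small[[cls]] <- quantify(asn, counts$design,
                                     names(gen$refs[[cls]]), class = cls)
            files <- c(files, write_count_matrix(
                small[[cls]], file.path(config$outdir, paste0("quant_", cls))))
        }
        # splice re-quantified small-RNA rows over the simulated matrix and
        # adopt the observed clean totals as the TPM/DE denominator
        m <- counts$counts
        m[rownames(small$pirna$counts), ] <- small$pirna$counts
        m[rownames(small$mirna$counts), ] <- small$mirna$counts
        de_counts <- count_matrix(m, counts$design,
                                  total_clean = small$pirna$total_clean,
                                  feature_class = counts$feature_class)
        report$preprocess <- stats
    }

    ## -- differential expression ------------------------------------------
    de <- list()
    if (isTRUE(stages["de"])) {
        for (cls in c("pirna", "mirna", "mrna")) {
            de[[cls]] <- list()
            for (ct in config$contrasts) {
                cn <- contrast_name(ct)
                de[[cls]][[cn]] <- de_analysis(de_counts, ct, class = cls,
                                               q_threshold = config$q_threshold,
                                               gate = config$gate)
                p <- file.path(config$outdir,
                               sprintf("de_%s_%s.tsv", cls, cn))
                write.table(de[[cls]][[cn]]$result, p, sep = "\t",
                            quote = FALSE, row.names = FALSE)
                files <- c(files, p)
            }
        }
        report$de_counts <- lapply(de, function(x) lapply(x, function(d)
            list(up = length(d$sets$up), down = length(d$sets$down),
                 tested = length(d$sets$universe))))
    }

    ## -- target prediction -------------------------------------------------
    maps <- list()
    if (isTRUE(stages["targets"])) {
        de_pir <- sort(unique(unlist(lapply(de$pirna, function(d)
            c(d$sets$up, d$sets$down)))))
        pir_seq <- gen$refs$pirna[de_pir]
        maps$mrna <- build_target_map(pir_seq, gen$refs$mrna, "mrna",
                                      config$max_mismatch,
                                      config$anchor_match)
        maps$mirna <- build_target_map(pir_seq, gen$refs$mirna, "mirna",
                                       config$max_mismatch,
                                       config$anchor_match)
        for (kind in names(maps)) {
            p <- file.path(config$outdir, sprintf("targets_%s.tsv", kind))
            files <- c(files, write_target_map(maps[[kind]], p))
        }
        report$targets <- list(
            n_de_pirnas = length(de_pir),
            mrna_edges = nrow(maps$mrna$edges),
            mirna_edges = nrow(maps$mirna$edges))
    }

    ## -- integrate ----------------------------------------------------------
    reversed <- NULL; rev_genes <- NULL
    if (isTRUE(stages["integrate"])) {
        drug <- contrast_name(config$contrasts[[1]])
        revc <- contrast_name(config$contrasts[[length(config$contrasts)]])
        pir_drug <- de$pirna[[drug]]$sets
        pir_rev <- de$pirna[[revc]]$sets
        shared <- intersect(pir_drug$universe, pir_rev$universe)
        # direction-resolved overlap tests: the two directions are tested
        # separately (a reading of the paired p-values, flagged as such)
        ov <- list(
            up_drug_down_rev = overlap_test(
                intersect(pir_drug$up, shared), intersect(pir_rev$down, shared),
                shared),
            down_drug_up_rev = overlap_test(
                intersect(pir_drug$down, shared), intersect(pir_rev$up, shared),
                shared))
        report$overlaps <- lapply(ov, function(o)
            list(k = o$k, K = o$K, n = o$n, N = o$N, p = o$p))
        report$overlaps$interpretation <-
            "up- and down-sets tested separately (interpretive choice)"
        reversed <- find_reversed(pir_drug, pir_rev)
        rev_genes <- reversal_target_genes(reversed, maps$mrna,
                                           de$mrna[[revc]]$sets)
        de_pir_lfc <- pir_drug$lfc[c(pir_drug$up, pir_drug$down)]
        cor_mrna <- fc_correlation(de_pir_lfc, maps$mrna,
                                   de$mrna[[drug]]$sets$lfc)
        cor_mirna <- fc_correlation(de_pir_lfc, maps$mirna,
                                    de$mirna[[drug]]$sets$lfc)
        tri <- cascade(pir_drug, de$mirna[[drug]]$sets, de$mrna[[drug]]$sets,
                       maps$mirna, mirna_seqs = gen$refs$mirna,
                       mrna_seqs = gen$refs$mrna)
        p <- file.path(config$outdir, "cascade.tsv")
        write.table(tri, p, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, p)
        p <- file.path(config$outdir, "reversal_genes.tsv")
        write.table(rev_genes$table, p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, p)
        # reversal subnetwork (SIF) and a Sankey-ready three-column table
        rev_map <- maps$mrna
        rev_map$edges <- rev_map$edges[
            rev_map$edges$pirna_id %in% reversed$all &
                rev_map$edges$target_id %in% rev_genes$table$gene_id, ,
            drop = FALSE]
        files <- c(files, export_network(
            rev_map, sif_path = file.path(config$outdir, "reversal.sif")))
        report$integrate <- list(
            n_reversed = length(reversed$all),
            R_plus = length(reversed$R_plus),
            R_minus = length(reversed$R_minus),
            n_reversal_genes = length(unique(rev_genes$table$gene_id)),
            top_gene = if (length(rev_genes$support))
                names(rev_genes$support)[1] else NA,
            top_gene_support = if (length(rev_genes$support))
                unname(rev_genes$support[1]) else 0L,
            cor_pirna_mrna = list(r = cor_mrna$r, p = cor_mrna$p,
                                  n = cor_mrna$n_pairs),
            cor_pirna_mirna = list(r = cor_mirna$r, p = cor_mirna$p,
                                   n = cor_mirna$n_pairs),
            n_cascade_triples = nrow(tri))
        report$cascade <- tri
    }

    ## -- motif --------------------------------------------------------------
    if (isTRUE(stages["motif"])) {
        motifs <- NULL
        if (!is.null(rev_genes) && length(rev_genes$support) &&
            rev_genes$support[1] >= 2) {
            top <- names(rev_genes$support)[1]
            sup <- rev_genes$table$pirna_id[rev_genes$table$gene_id == top]
            motifs <- longest_common_substring(gen$refs$pirna[sup])
            p <- file.path(config$outdir, "motif.tsv")
            write.table(motifs, p, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            files <- c(files, p)
        }
        report$motif <- if (!is.null(motifs) && nrow(motifs))
            list(motif = motifs$motif[1], length = motifs$length[1],
                 support = motifs$support[1]) else list()
    }

    ## -- enrichment ---------------------------------------------------------
    if (isTRUE(stages["enrich"]) && !is.null(config$gmt)) {
        gmt <- read_gmt(config$gmt)
        genes <- unique(rev_genes$table$gene_id)
        enr <- ora(genes, gmt)
        p <- file.path(config$outdir, "enrichment.tsv")
        write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, p)
        # Sankey-ready: piRNA -> gene -> best-enriched pathway of that gene
        top_sets <- enr$set_id[enr$q_bh <= 0.25]
        sank <- do.call(rbind, lapply(seq_len(nrow(rev_genes$table)),
                                      function(i) {
            g <- rev_genes$table$gene_id[i]
            in_sets <- top_sets[vapply(top_sets, function(s)
                g %in% gmt[[s]], logical(1))]
            if (!length(in_sets)) return(NULL)
            data.frame(pirna_id = rev_genes$table$pirna_id[i], gene_id = g,
                       pathway = in_sets[1], stringsAsFactors = FALSE)
        }))
        if (!is.null(sank)) {
            p <- file.path(config$outdir, "sankey.tsv")
            write.table(sank, p, sep = "\t", quote = FALSE, row.names = FALSE)
            files <- c(files, p)
        }
        report$enrich <- list(n_sets = length(gmt),
                              top_set = enr$set_id[1], top_p = enr$p[1])
    }

    ## -- planted-truth recovery --------------------------------------------
    if (isTRUE(stages["simulate"]) && isTRUE(stages["de"])) {
        drug <- contrast_name(config$contrasts[[1]])
        called <- c(de$pirna[[drug]]$sets$up, de$pirna[[drug]]$sets$down)
        truth_pos <- gen$truth$responsive$pirna_id
        tp <- length(intersect(called, truth_pos))
        rec <- list(
            de_precision = if (length(called)) tp / length(called) else NA,
            de_recall = tp / length(truth_pos))
        if (!is.null(reversed)) {
            rec$reversal_recovery <-
                length(intersect(reversed$all, gen$truth$reversal_pirnas)) /
                max(1L, length(gen$truth$reversal_pirnas))
        }
        if (length(maps)) {
            planted <- gen$truth$edges
            planted <- planted[planted$pirna_id %in%
                                   unique(c(maps$mrna$edges$pirna_id,
                                            maps$mirna$edges$pirna_id,
                                            called)), , drop = FALSE]
            found <- c(paste(maps$mrna$edges$pirna_id,
                             maps$mrna$edges$target_id),
                       paste(maps$mirna$edges$pirna_id,
                             maps$mirna$edges$target_id))
            rec$edge_recovery <- if (nrow(planted))
                mean(paste(planted$pirna_id, planted$target_id) %in% found)
            else NA
        }
        if (!is.null(report$cascade)) {
            planted_tri <- paste(gen$truth$cascade$pirna_id,
                                 gen$truth$cascade$mirna_id,
                                 gen$truth$cascade$mrna_id)
            found_tri <- paste(report$cascade$pirna_id,
                               report$cascade$mirna_id,
                               report$cascade$mrna_id)
            rec$cascade_recovery <- mean(planted_tri %in% found_tri)
        }
        report$recovery <- rec
    }
    report$cascade <- NULL   # kept only for recovery scoring above

    ## -- digests -------------------------------------------------------------
    files <- files[file.exists(files)]
    md5 <- tools::md5sum(files)
    report$digests <- setNames(unname(md5), basename(names(md5)))
    report$run_digest <- unname(tools::md5sum(
        tempfile_with(jsonlite::toJSON(
            report[setdiff(names(report), "run_digest")],
            auto_unbox = TRUE, digits = NA, null = "null"))))
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(report)
}

# write a string to a temp file and return its path (md5 helper)
tempfile_with <- function(x) {
    p <- tempfile()
    writeLines(as.character(x), p)
    p
}

#' Validate a pipeline report against the published structure
#'
#' Checks the required top-level fields and their types (the JSON schema
#' shipped in `inst/extdata/report_schema.json` documents the same
#' structure).
#'
#' @param report a report list from [run_all()] or parsed from
#'   `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
    need <- c("package", "seed", "stages", "parameters", "digests",
              "run_digest")
    miss <- setdiff(need, names(report))
    if (length(miss))
        user_error("report lacks required field '%s'", miss[1])
    if (!identical(as.character(report$package), "pirnakit"))
        user_error("report package field is wrong")
    if (!is.numeric(report$seed)) user_error("seed must be numeric")
    if (!is.list(report$stages)) user_error("stages must be an object")
    if (!is.list(report$parameters)) user_error("parameters must be an object")
    if (!is.character(unlist(report$run_digest)))
        user_error("run_digest must be a string")
    invisible(TRUE)
}
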