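#' Configuration for the synthetic four-group small-RNA study
#'
#' Describes a 4-group (SS, CS, MS, MC) x 3-replicate small-RNA study with
#' planted drug effects, treatment reversal, complementarity-satisfying
#' target sites, and a shared motif across the piRNAs converging on one hub
#' gene. Defaults emulate a cocaine / l-methionine conditioned-place-
#' preference design: cocaine (CS vs SS) shifts a fraction of piRNAs by
#' `delta` log2 units, the combined treatment (MC vs CS) reverses the shift
#' scaled by `rho`, targeted mRNAs move opposite-sign scaled by `beta`, and
#' targeted miRNAs move same-sign scaled by `gamma`.
#'
#' @param seed integer seed; fixes every generator output bit-for-bit.
#' @param n_pirna,n_mirna,n_mrna,n_rrna_trna reference set sizes.
#' @param pirna_len,mirna_len,mrna_len,rrna_trna_len inclusive length ranges
#'   (nt).
#' @param groups ordered group labels; the first is the baseline, the second
#'   carries the drug effect, the fourth the reversal.
#' @param replicates libraries per group.
#' @param depth expected clean reads per library.
#' @param phi negative-binomial dispersion, `Var = mu + phi * mu^2`; 0 gives
#'   the Poisson limit.
#' @param delta planted |log2 fold change| for drug-responsive piRNAs.
#' @param rho reversal strength multiplier for the MC vs CS contrast.
#' @param beta opposite-sign effect scale for targeted mRNAs (multiplies
#'   `delta`).
#' @param gamma same-sign effect scale for targeted miRNAs (multiplies
#'   `delta`).
#' @param frac_responsive fraction of piRNAs that are drug-responsive.
#' @param edges_per_pirna inclusive range of planted mRNA target edges per
#'   responsive (non-hub) piRNA.
#' @param hub_motif fixed motif carried verbatim in the 5' window of every
#'   hub piRNA; at most 20 nt.
#' @param hub_pirna_count number of hub piRNAs, all targeting one hub gene.
#' @param n_cascade number of responsive piRNAs given a planted miRNA target
#'   (each such miRNA in turn seed-matches one mRNA, forming a cascade
#'   triple).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_pirna = 500L, n_mirna = 150L, n_mrna = 300L,
                       n_rrna_trna = 40L,
                       pirna_len = c(26L, 31L), mirna_len = c(20L, 23L),
                       mrna_len = c(500L, 2000L),
                       rrna_trna_len = c(70L, 150L),
                       groups = c("SS", "CS", "MS", "MC"), replicates = 3L,
                       depth = 1e6, phi = 0.1, delta = 1.5, rho = 1,
                       beta = 0.8, gamma = 0.8, frac_responsive = 0.1,
                       edges_per_pirna = c(1L, 3L),
                       hub_motif = "GTCTCTCCAGCCACCTT",
                       hub_pirna_count = 6L, n_cascade = 10L) {
    cfg <- list(seed = as.integer(seed), n_pirna = as.integer(n_pirna),
                n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
                n_rrna_trna = as.integer(n_rrna_trna),
                pirna_len = as.integer(pirna_len),
                mirna_len = as.integer(mirna_len),
                mrna_len = as.integer(mrna_len),
                rrna_trna_len = as.integer(rrna_trna_len),
                groups = groups, replicates = as.integer(replicates),
                depth = depth, phi = phi, delta = delta, rho = rho,
                beta = beta, gamma = gamma,
                frac_responsive = frac_responsive,
                edges_per_pirna = as.integer(edges_per_pirna),
                hub_motif = toupper(hub_motif),
                hub_pirna_count = as.integer(hub_pirna_count),
                n_cascade = as.integer(n_cascade))
    ranges <- c("pirna_len", "mirna_len", "mrna_len", "rrna_trna_len",
                "edges_per_pirna")
    for (r in ranges) {
        v <- cfg[[r]]
        if (length(v) != 2L || v[1] > v[2] || v[1] < 1L)
            user_error("%s must be an ordered positive pair", r)
    }
    if (cfg$frac_responsive <= 0 || cfg$frac_responsive >= 1)
        user_error("frac_responsive must lie in (0, 1)")
    if (cfg$delta <= 0 || cfg$beta <= 0 || cfg$gamma <= 0 || cfg$phi < 0 ||
        cfg$rho < 0)
        user_error("delta, beta, gamma must be > 0; phi, rho must be >= 0")
    if (length(cfg$groups) != 4L || anyDuplicated(cfg$groups))
        user_error("groups must be 4 distinct labels")
    if (grepl("[^ACGT]", cfg$hub_motif))
        user_error("hub_motif must be A/C/G/T only")
    if (nchar(cfg$hub_motif) > 20L || nchar(cfg$hub_motif) > cfg$pirna_len[1])
        user_error("hub_motif must fit inside the 20-nt piRNA 5' window")
    n_resp <- round(cfg$frac_responsive * cfg$n_pirna)
    if (cfg$hub_pirna_count > n_resp)
        user_error("hub_pirna_count exceeds the responsive piRNA count (%d)",
                   n_resp)
    if (cfg$n_cascade > n_resp - cfg$hub_pirna_count)
        user_error("n_cascade exceeds the non-hub responsive piRNA count")
    if (cfg$mrna_len[1] < 20L || cfg$mirna_len[1] < 20L)
        user_error("planted 20-nt sites need targets of length >= 20 nt")
    structure(cfg, class = "sim_config")
}

# draw one element of a vector (safe for length-1 vectors, unlike sample())
sample1 <- function(v) v[sample.int(length(v), 1L)]

# insert the reverse complement of `window`, corrupted at `mm` window
# positions drawn from 2..w (the position-1 anchor is never corrupted), into
# `target` at 0-based `start0`. Window position j pairs with site position
# w - j + 1 (antiparallel duplex).
plant_site <- function(target, window, mm, start0) {
    w <- nchar(window)
    if (start0 < 0 || start0 + w > nchar(target))
        user_error("planted site [%d, %d) does not fit the target", start0,
                   start0 + w)
    site <- revcomp(window)
    if (mm > 0) {
        for (j in sample(2:w, mm)) {
            p <- w - j + 1L
            old <- substr(site, p, p)
            substr(site, p, p) <- sample1(setdiff(DNA_BASES, old))
        }
    }
    substr(target, start0 + 1L, start0 + w) <- site
    target
}

#' Generate synthetic references with planted regulatory structure
#'
#' Draws random reference sequences for all classes, then plants the
#' regulatory structure described by the configuration: every responsive
#' piRNA receives 1-3 mRNA target sites satisfying the 5'-anchored
#' complementarity rule (reverse complement of the piRNA's 5' 20-mer with
#' 0-2 corruptions, never at the anchor); the hub piRNAs carry the hub motif
#' inside their 5' window and all target one hub gene; a subset of
#' responsive piRNAs additionally target a miRNA whose 7-mer seed is planted
#' into a further mRNA, forming piRNA -> miRNA -> mRNA cascade triples.
#'
#' @param config a [sim_config()].
#' @return a list with elements `refs` (a [reference_bundle()]) and `truth`
#'   (a `planted_truth` object; see Details).
#' @details The `planted_truth` object records: `features` (id/class table),
#'   `group_lfc` (feature x group planted log2 fold change relative to the
#'   baseline group), `responsive` (piRNA id, sign, delta), `reversal_pirnas`,
#'   `edges` (pirna_id, target_id, kind, mismatches, 0-based start),
#'   `hub_gene`, `hub_pirnas`, `hub_motif` and `cascade`
#'   (pirna_id, mirna_id, mrna_id).
#' @export
generate_references <- function(config) {
    if (!inherits(config, "sim_config")) user_error("config must be a sim_config")
    set.seed(derive_seed(config$seed, 0L))
    n_rr <- config$n_rrna_trna %/% 2L
    n_tr <- config$n_rrna_trna - n_rr

    pir <- setNames(random_seq(config$n_pirna, config$pirna_len),
                    sprintf("pir%04d", seq_len(config$n_pirna)))
    mir <- setNames(random_seq(config$n_mirna, config$mirna_len),
                    sprintf("mir%04d", seq_len(config$n_mirna)))
    mrn <- setNames(random_seq(config$n_mrna, config$mrna_len),
                    sprintf("gene%04d", seq_len(config$n_mrna)))
    rrn <- setNames(random_seq(n_rr, config$rrna_trna_len),
                    sprintf("rrna%03d", seq_len(n_rr)))
    trn <- setNames(random_seq(n_tr, config$rrna_trna_len),
                    sprintf("trna%03d", seq_len(n_tr)))

    n_resp <- round(config$frac_responsive * config$n_pirna)
    resp_ids <- sort(sample(names(pir), n_resp))
    hub_pirnas <- sort(sample(resp_ids, config$hub_pirna_count))
    sign <- setNames(sample(c(-1, 1), n_resp, replace = TRUE), resp_ids)
    sign[hub_pirnas] <- -1   # hub piRNAs: down under drug, up after reversal

    # embed the motif inside each hub piRNA's 5' 20-nt window
    mlen <- nchar(config$hub_motif)
    for (id in hub_pirnas) {
        off <- sample1(0:(20L - mlen))
        s <- pir[[id]]
        substr(s, off + 1L, off + mlen) <- config$hub_motif
        pir[id] <- s
    }

    # hub gene = longest mRNA, so the non-overlapping hub sites always fit
    hub_gene <- names(mrn)[which.max(nchar(mrn))]
    if (nchar(mrn[[hub_gene]]) < 20L * config$hub_pirna_count)
        user_error("longest mRNA too short to host %d hub sites",
                   config$hub_pirna_count)
    cascade_src <- sort(sample(setdiff(resp_ids, hub_pirnas),
                               config$n_cascade))
    cascade_mirnas <- sort(sample(names(mir), config$n_cascade))
    cascade_mrnas <- sort(sample(setdiff(names(mrn), hub_gene),
                                 config$n_cascade))
    free_pool <- setdiff(names(mrn), c(hub_gene, cascade_mrnas))

    edges <- list()
    add_edge <- function(pid, tid, kind, mm, start0) {
        edges[[length(edges) + 1L]] <<- data.frame(
            pirna_id = pid, target_id = tid, kind = kind,
            mismatches = mm, start = start0, stringsAsFactors = FALSE)
    }

    # hub edges: non-overlapping 20-nt slots on the hub gene
    slots <- seq(0L, nchar(mrn[[hub_gene]]) - 20L, by = 20L)
    hub_starts <- sort(sample(slots, config$hub_pirna_count))
    for (i in seq_along(hub_pirnas)) {
        pid <- hub_pirnas[i]
        mm <- sample1(0:2)
        mrn[hub_gene] <- plant_site(mrn[[hub_gene]],
                                    substr(pir[[pid]], 1L, 20L),
                                    mm, hub_starts[i])
        add_edge(pid, hub_gene, "mrna", mm, hub_starts[i])
    }

    # one to three dedicated mRNA targets per remaining responsive piRNA
    for (pid in setdiff(resp_ids, hub_pirnas)) {
        k <- sample1(config$edges_per_pirna[1]:config$edges_per_pirna[2])
        if (k > length(free_pool))
            user_error("mRNA pool exhausted; increase n_mrna")
        tids <- sample(free_pool, k)
        free_pool <- setdiff(free_pool, tids)
        for (tid in tids) {
            mm <- sample1(0:2)
            start0 <- sample1(0:(nchar(mrn[[tid]]) - 20L))
            mrn[tid] <- plant_site(mrn[[tid]], substr(pir[[pid]], 1L, 20L),
                                   mm, start0)
            add_edge(pid, tid, "mrna", mm, start0)
        }
    }

    # cascade: piRNA -> miRNA site, then the miRNA's 2-8 seed into an mRNA
    cascade <- data.frame(pirna_id = character(), mirna_id = character(),
                          mrna_id = character(), stringsAsFactors = FALSE)
    for (i in seq_len(config$n_cascade)) {
        pid <- cascade_src[i]; mid <- cascade_mirnas[i]; gid <- cascade_mrnas[i]
        mm <- sample1(0:2)
        start0 <- sample1(0:(nchar(mir[[mid]]) - 20L))
        mir[mid] <- plant_site(mir[[mid]], substr(pir[[pid]], 1L, 20L),
                               mm, start0)
        add_edge(pid, mid, "mirna", mm, start0)
        seed7 <- revcomp(substr(mir[[mid]], 2L, 8L))
        gstart <- sample1(0:(nchar(mrn[[gid]]) - 7L))
        g <- mrn[[gid]]
        substr(g, gstart + 1L, gstart + 7L) <- seed7
        mrn[gid] <- g
        cascade <- rbind(cascade, data.frame(
            pirna_id = pid, mirna_id = mid, mrna_id = gid,
            stringsAsFactors = FALSE))
    }

    refs <- reference_bundle(pirna = pir, mirna = mir, mrna = mrn,
                             rrna = rrn, trna = trn)

    # planted log2 fold changes per group, relative to the baseline group
    features <- data.frame(
        feature_id = c(names(mir), names(rrn), names(trn), names(pir),
                       names(mrn)),
        class = rep(c("mirna", "rrna", "trna", "pirna", "mrna"),
                    c(length(mir), length(rrn), length(trn), length(pir),
                      length(mrn))),
        stringsAsFactors = FALSE)
    g <- config$groups   # g[1]=baseline, g[2]=drug, g[3]=treat-only, g[4]=both
    lfc <- matrix(0, nrow = nrow(features), ncol = 4L,
                  dimnames = list(features$feature_id, g))
    d <- config$delta
    lfc[resp_ids, g[2]] <- sign * d
    lfc[resp_ids, g[4]] <- sign * d * (1 - config$rho)
    lfc[cascade_mirnas, g[2]] <- sign[cascade_src] * d * config$gamma
    lfc[cascade_mirnas, g[4]] <- sign[cascade_src] * d * config$gamma *
        (1 - config$rho)
    edges_df <- do.call(rbind, edges)
    mrna_edges <- edges_df[edges_df$kind == "mrna", ]
    src_sign <- sign[mrna_edges$pirna_id]
    lfc[mrna_edges$target_id, g[2]] <- -src_sign * d * config$beta
    lfc[mrna_edges$target_id, g[4]] <- -src_sign * d * config$beta *
        (1 - config$rho)
    # cascade mRNAs move opposite to their miRNA (hence opposite the piRNA)
    lfc[cascade$mrna_id, g[2]] <- -sign[cascade$pirna_id] * d * config$beta
    lfc[cascade$mrna_id, g[4]] <- -sign[cascade$pirna_id] * d * config$beta *
        (1 - config$rho)

    truth <- structure(list(
        features = features,
        group_lfc = lfc,
        responsive = data.frame(pirna_id = resp_ids, sign = unname(sign),
                                delta = d, stringsAsFactors = FALSE),
        reversal_pirnas = if (config$rho > 0) resp_ids else character(),
        edges = edges_df,
        hub_gene = hub_gene, hub_pirnas = hub_pirnas,
        hub_motif = config$hub_motif,
        cascade = cascade,
        config = config), class = "planted_truth")
    list(refs = refs, truth = truth)
}

#' Planted per-contrast effect table
#'
#' Converts the generator's per-group planted log2 fold changes into
#' per-contrast effects. Rows for non-responsive, non-targeted features are
#' all zero.
#'
#' @param truth a `planted_truth` object from [generate_references()].
#' @param contrasts list of 2-vectors `c(numerator_group, denominator_group)`;
#'   defaults to drug vs baseline, treatment vs baseline and combined vs
#'   drug, taken from the config's group order.
#' @return data.frame: feature_id, class, then one `lfc_<num>vs<den>` column
#'   per contrast.
#' @export
planted_effects <- function(truth, contrasts = NULL) {
    if (is.null(contrasts)) {
        g <- truth$config$groups
        contrasts <- list(c(g[2], g[1]), c(g[3], g[1]), c(g[4], g[2]))
    }
    out <- truth$features
    for (ct in contrasts) {
        out[[sprintf("lfc_%svs%s", ct[1], ct[2])]] <-
            truth$group_lfc[out$feature_id, ct[1]] -
            truth$group_lfc[out$feature_id, ct[2]]
    }
    out
}

#' Simulate a count matrix from planted truth
#'
#' Per feature i and sample s in group g, counts are drawn
#' `NB(mean = depth * baseline_i * 2^lfc(i, g), Var = mu + phi * mu^2)`;
#' `phi = 0` gives the Poisson limit. Baselines are log-normal(0, 1),
#' normalised to sum to one, so per-sample expected totals are close to
#' `depth`. Fully determined by `config$seed`.
#'
#' @param truth a `planted_truth`.
#' @param config the same [sim_config()] used to generate it.
#' @return a [count_matrix()] over all features (samples named
#'   `<group>_<replicate>`).
#' @export
simulate_counts <- function(truth, config) {
    set.seed(derive_seed(config$seed, 1L))
    nf <- nrow(truth$features)
    baseline <- rlnorm(nf, 0, 1)
    baseline <- baseline / sum(baseline)
    groups <- rep(config$groups, each = config$replicates)
    samples <- paste0(groups, "_", rep(seq_len(config$replicates), 4L))
    mu <- config$depth * baseline *
        2^truth$group_lfc[truth$features$feature_id, groups, drop = FALSE]
    counts <- matrix(0L, nrow = nf, ncol = length(samples),
                     dimnames = list(truth$features$feature_id, samples))
    for (j in seq_along(samples)) {
        counts[, j] <- if (config$phi > 0) {
            rnbinom(nf, mu = mu[, j], size = 1 / config$phi)
        } else {
            rpois(nf, lambda = mu[, j])
        }
    }
    storage.mode(counts) <- "integer"
    count_matrix(counts,
                 design = data.frame(sample = samples, group = groups,
                                     stringsAsFactors = FALSE),
                 feature_class = setNames(truth$features$class,
                                          truth$features$feature_id))
}

#' Simulate per-sample FASTQ files
#'
#' Each small-RNA feature (piRNA, miRNA, rRNA, tRNA; mRNA rows are not
#' sequenced) emits `count` reads equal to its reference sequence, optionally
#' suffixed with a 3' adapter. Configurable fractions of short (8-15 nt) and
#' low-quality contaminant reads are injected so downstream filters are
#' exercised. Qualities are Phred+33: `I` (Q40) for genuine reads, `#` (Q2)
#' for low-quality contaminants.
#'
#' @param counts a [count_matrix()] from [simulate_counts()].
#' @param refs the matching [reference_bundle()].
#' @param config the [sim_config()] (supplies the seed).
#' @param outdir directory for the FASTQ files (created if needed).
#' @param adapter optional 3' adapter sequence appended to every genuine
#'   read.
#' @param frac_short,frac_lowqual expected contaminant reads per genuine
#'   read (binomial draws).
#' @return named character vector of FASTQ paths, invisibly.
#' @export
simulate_reads <- function(counts, refs, config, outdir, adapter = NULL,
                           frac_short = 0, frac_lowqual = 0) {
    set.seed(derive_seed(config$seed, 2L))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seqs <- unlist(unname(lapply(refs[c("mirna", "rrna", "trna", "pirna")],
                                 identity)))
    keep <- intersect(rownames(counts$counts), names(seqs))
    paths <- character()
    for (smp in counts$design$sample) {
        cnt <- counts$counts[keep, smp]
        rd <- rep(unname(seqs[keep]), cnt)
        ids <- paste0(rep(keep, cnt), ":", smp, ":",
                      sequence(cnt))
        if (!is.null(adapter)) rd <- paste0(rd, toupper(adapter))
        qual <- strrep("I", nchar(rd))
        n_real <- length(rd)
        n_short <- rbinom(1L, n_real, frac_short)
        n_lq <- rbinom(1L, n_real, frac_lowqual)
        if (n_short > 0) {
            s <- random_seq(n_short, c(8L, 15L))
            rd <- c(rd, s); qual <- c(qual, strrep("I", nchar(s)))
            ids <- c(ids, paste0("short:", smp, ":", seq_len(n_short)))
        }
        if (n_lq > 0) {
            s <- random_seq(n_lq, c(18L, 30L))
            rd <- c(rd, s); qual <- c(qual, strrep("#", nchar(s)))
            ids <- c(ids, paste0("lowq:", smp, ":", seq_len(n_lq)))
        }
        ord <- sample.int(length(rd))
        p <- file.path(outdir, paste0(smp, ".fastq"))
        writeLines(as.vector(rbind(paste0("@", ids[ord]), rd[ord], "+",
                                   qual[ord])), p)
        paths[smp] <- p
    }
    invisible(paths)
}

#' Write planted truth tables as TSV
#'
#' Emits `effects.tsv` (per-contrast planted log2 fold changes),
#' `edges.tsv` (planted target sites), `cascade.tsv` and `hub.tsv`, so
#' downstream scoring never needs the in-memory object.
#'
#' @param truth a `planted_truth`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- c(effects = file.path(dir, "effects.tsv"),
           edges = file.path(dir, "edges.tsv"),
           cascade = file.path(dir, "cascade.tsv"),
           hub = file.path(dir, "hub.tsv"))
    write.table(planted_effects(truth), p["effects"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth$edges, p["edges"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth$cascade, p["cascade"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(hub_gene = truth$hub_gene,
                           hub_pirna = truth$hub_pirnas,
                           hub_motif = truth$hub_motif),
                p["hub"], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(p)
}
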