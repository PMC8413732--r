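test_that("generator output is a pure function of the seed", {
    g1 <- generate_references(tiny_config(seed = 3))
    g2 <- generate_references(tiny_config(seed = 3))
    expect_identical(g1$refs, g2$refs)
    expect_identical(g1$truth$edges, g2$truth$edges)
    g3 <- generate_references(tiny_config(seed = 4))
    expect_false(identical(g1$refs$pirna, g3$refs$pirna))

    d1 <- tempfile(); d2 <- tempfile()
    write_reference_bundle(g1$refs, d1)
    write_reference_bundle(g2$refs, d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
})

test_that("hub piRNAs embed the motif and target the hub gene", {
    gen <- generate_references(tiny_config(seed = 5))
    truth <- gen$truth
    expect_length(truth$hub_pirnas, 6L)
    windows <- substr(gen$refs$pirna[truth$hub_pirnas], 1, 20)
    expect_true(all(grepl(truth$hub_motif, windows, fixed = TRUE)))
    hub_edges <- truth$edges[truth$edges$target_id == truth$hub_gene, ]
    expect_setequal(hub_edges$pirna_id, truth$hub_pirnas)
})

test_that("every planted edge satisfies the complementarity rule exactly", {
    gen <- generate_references(tiny_config(seed = 6))
    e <- gen$truth$edges
    for (i in seq_len(nrow(e))) {
        tgt <- if (e$kind[i] == "mrna") gen$refs$mrna[[e$target_id[i]]]
               else gen$refs$mirna[[e$target_id[i]]]
        sites <- find_targets(gen$refs$pirna[[e$pirna_id[i]]], tgt,
                              target_kind = e$kind[i])
        hit <- sites[sites$start == e$start[i], , drop = FALSE]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$mismatches, e$mismatches[i])
    }
    # effect table rows of unplanted features are all zero
    eff <- planted_effects(gen$truth)
    planted <- unique(c(gen$truth$responsive$pirna_id, e$target_id,
                        gen$truth$cascade$mrna_id))
    zero <- !eff$feature_id %in% planted
    expect_true(all(eff$lfc_CSvsSS[zero] == 0 & eff$lfc_MCvsCS[zero] == 0))
})

test_that("count simulation is seeded, Poisson-limited and effect-consistent", {
    cfg <- tiny_config(seed = 7)
    gen <- generate_references(cfg)
    expect_identical(simulate_counts(gen$truth, cfg),
                     simulate_counts(gen$truth, cfg))

    # phi -> 0, no effects: sample counts within 3*sqrt(mean) of their mean
    cfg0 <- tiny_config(seed = 7, phi = 0)
    gen0 <- generate_references(cfg0)
    gen0$truth$group_lfc[] <- 0
    cm0 <- simulate_counts(gen0$truth, cfg0)
    mu <- rowMeans(cm0$counts)
    expect_gt(cor(mu, rowMeans(cm0$counts[, 1:3])), 0.99)
    dev <- abs(cm0$counts[, 1] - mu)
    expect_lt(mean(dev > 3 * sqrt(pmax(mu, 1))), 0.02)

    # planted reversal effect recovered on average (depth 1e6 world)
    big <- sim_config(seed = 8, n_pirna = 100, n_mirna = 30, n_mrna = 60,
                      mrna_len = c(150L, 400L), n_rrna_trna = 10,
                      frac_responsive = 0.2, n_cascade = 4, depth = 1e6)
    genb <- generate_references(big)
    cmb <- simulate_counts(genb$truth, big)
    up <- genb$truth$responsive$pirna_id[genb$truth$responsive$sign > 0]
    cs <- rowMeans(cmb$counts[up, paste0("CS_", 1:3), drop = FALSE])
    ss <- rowMeans(cmb$counts[up, paste0("SS_", 1:3), drop = FALSE])
    mc <- rowMeans(cmb$counts[up, paste0("MC_", 1:3), drop = FALSE])
    # per-feature empirical lfc has sd ~0.38 at phi = 0.1; the mean over
    # planted features is covered well inside +/-0.3
    expect_lt(abs(mean(log2(cs / ss)) - big$delta), 0.3)
    expect_lt(abs(mean(log2(mc / cs)) + big$delta * big$rho), 0.3)
})

test_that("read simulation is an identity pipeline without contaminants", {
    cfg <- tiny_config(seed = 9, depth = 2e3)
    gen <- generate_references(cfg)
    cm <- simulate_counts(gen$truth, cfg)
    dir <- tempfile()
    fq <- simulate_reads(cm, gen$refs, cfg, dir)
    expect_length(fq, 12L)
    smp <- "CS_2"
    reads <- read_fastq(fq[[smp]])
    seqs <- c(gen$refs$mirna, gen$refs$rrna, gen$refs$trna, gen$refs$pirna)
    expected <- rep(unname(seqs), cm$counts[names(seqs), smp])
    expect_identical(sort(reads$seq), sort(expected))
})

test_that("contaminant injection and adapters behave as configured", {
    cfg <- tiny_config(seed = 10, depth = 5e3)
    gen <- generate_references(cfg)
    cm <- simulate_counts(gen$truth, cfg)
    dir <- tempfile()
    adapter <- "AGATCGGAAGAGC"
    fq <- simulate_reads(cm, gen$refs, cfg, dir, adapter = adapter,
                         frac_short = 0.05, frac_lowqual = 0.02)
    reads <- read_fastq(fq[["SS_1"]])
    short <- nchar(reads$seq) < 16
    n_real <- sum(!short & !startsWith(reads$id, "lowq"))
    # binomial check: short-read count within 4 sd of the expectation
    expect_lt(abs(sum(startsWith(reads$id, "short")) - 0.05 * n_real),
              4 * sqrt(0.05 * 0.95 * n_real) + 1)
    genuine <- !startsWith(reads$id, "short") & !startsWith(reads$id, "lowq")
    expect_true(all(endsWith(reads$seq[genuine], adapter)))
    expect_true(all(substr(reads$qual[startsWith(reads$id, "lowq")], 1, 1) == "#"))
})

test_that("config validation rejects impossible worlds", {
    expect_error(sim_config(frac_responsive = 0), "frac_responsive")
    expect_error(sim_config(hub_motif = "GTCTCTCCAGCCACCTTGTCA"), "window")
    expect_error(sim_config(hub_motif = "GUCUNN"), "A/C/G/T")
    expect_error(sim_config(pirna_len = c(31, 26)), "ordered")
    expect_error(sim_config(n_pirna = 30, frac_responsive = 0.1),
                 "hub_pirna_count")
    expect_error(tiny_config(mirna_len = c(18L, 19L)), "20 nt")
})

test_that("truth tables round-trip to TSV", {
    gen <- generate_references(tiny_config(seed = 12))
    dir <- tempfile()
    p <- write_truth(gen$truth, dir)
    edges <- read.delim(p[["edges"]])
    expect_equal(nrow(edges), nrow(gen$truth$edges))
    eff <- read.delim(p[["effects"]])
    expect_true(all(c("lfc_CSvsSS", "lfc_MSvsSS", "lfc_MCvsCS") %in%
                        names(eff)))
})
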