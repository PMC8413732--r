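test_that("overlap_test matches exact enumeration on worked examples", {
    U <- paste0("g", 1:10)
    a <- U[1:5]; b <- U[2:5]          # k = 4, K = 5, n = 4, N = 10
    ot <- overlap_test(a, b, U)
    expect_equal(ot$k, 4L)
    expect_equal(ot$p, 5 / 210)       # C(5,4)*C(5,0)/C(10,4)
    expect_equal(overlap_test(character(), b, U)$p, 1)
    expect_error(overlap_test(c(a, "zz"), b, U), "subsets")
})

test_that("overlap_test equals brute-force enumeration on random instances", {
    set.seed(701)
    for (trial in 1:30) {
        N <- sample(3:12, 1)
        U <- paste0("e", 1:N)
        K <- sample(0:N, 1); n <- sample(0:N, 1)
        a <- sample(U, K); b <- sample(U, n)
        ot <- overlap_test(a, b, U)
        expect_equal(ot$p, oracle_hyper_upper(N, K, n, ot$k),
                     tolerance = 1e-12)
    }
})

test_that("fc_correlation computes Pearson r with t-based p", {
    map <- structure(list(edges = data.frame(
        pirna_id = c("p1", "p2", "p3"), target_id = c("g1", "g2", "g3"),
        kind = "mrna", start = 0L, mismatches = 0L, width = 20L),
        kind = "mrna"), class = "target_map")
    r <- fc_correlation(c(p1 = 1, p2 = 2, p3 = 3), map,
                        c(g1 = -1, g2 = -2, g3 = -3))
    expect_equal(r$r, -1)
    expect_true(r$testable)

    # missing target fold changes are dropped and counted
    r2 <- fc_correlation(c(p1 = 1, p2 = 2, p3 = 3), map,
                         c(g1 = -1, g2 = -2))
    expect_false(r2$testable)
    expect_equal(r2$n_dropped, 1L)
    expect_equal(r2$n_pairs, 2L)

    # permuted fold changes give small |r| on a larger map
    set.seed(702)
    n <- 60
    big <- structure(list(edges = data.frame(
        pirna_id = paste0("p", 1:n), target_id = paste0("g", 1:n),
        kind = "mrna", start = 0L, mismatches = 0L, width = 20L),
        kind = "mrna"), class = "target_map")
    x <- rnorm(n)
    rp <- fc_correlation(setNames(x, paste0("p", 1:n)), big,
                         setNames(sample(-x), paste0("g", 1:n)))
    expect_lt(abs(rp$r), 0.45)
})

test_that("find_reversed implements the sign-flip intersections", {
    drug <- list(up = c("a", "b", "c"), down = c("d", "e"),
                 universe = letters[1:8])
    revc <- list(up = c("d", "f"), down = c("a", "c", "g"),
                 universe = letters[1:8])
    r <- find_reversed(drug, revc)
    expect_setequal(r$R_plus, c("a", "c"))   # up then down
    expect_setequal(r$R_minus, "d")          # down then up
    expect_false("b" %in% r$all)             # up in drug only
    # mirrored contrast returns every DE feature
    mirror <- list(up = drug$down, down = drug$up, universe = drug$universe)
    rm <- find_reversed(drug, mirror)
    expect_setequal(rm$all, c(drug$up, drug$down))
})

test_that("reversal_target_genes keeps opposite-direction genes with support", {
    reversed <- list(R_plus = "p1", R_minus = c("p2", "p3"))
    map <- structure(list(edges = data.frame(
        pirna_id = c("p1", "p2", "p3", "p3"),
        target_id = c("gUp", "gDown", "gDown", "gNone"),
        kind = "mrna", start = 0L, mismatches = 0L, width = 20L),
        kind = "mrna"), class = "target_map")
    mrna_sets <- list(up = "gUp", down = "gDown", universe = c("gUp", "gDown",
                                                               "gNone"))
    rg <- reversal_target_genes(reversed, map, mrna_sets)
    # p1 (down in reversal) targets gUp (up): reported
    expect_true(any(rg$table$gene_id == "gUp" & rg$table$pirna_id == "p1"))
    # p2/p3 (up) target gDown (down): reported with multiplicity 2
    expect_equal(unname(rg$support["gDown"]), 2L)
    # gNone has no DE change: absent
    expect_false("gNone" %in% rg$table$gene_id)
})

test_that("cascade emits same-direction piRNA-miRNA with opposite mRNA", {
    pset <- list(up = "p1", down = "p9", universe = c("p1", "p9"))
    mset <- list(up = c("m1", "m2"), down = character(),
                 universe = c("m1", "m2"))
    gset <- list(up = character(), down = "g1", universe = "g1")
    pm <- structure(list(edges = data.frame(
        pirna_id = c("p1", "p9"), target_id = c("m1", "m2"), kind = "mirna",
        start = 0L, mismatches = 0L, width = 20L), kind = "mirna"),
        class = "target_map")
    mg <- data.frame(mirna_id = c("m1", "m2"), mrna_id = "g1")
    tri <- cascade(pset, mset, gset, pm, mirna_mrna = mg)
    expect_equal(nrow(tri), 1L)              # p9 is down while m2 is up
    expect_equal(tri$pirna_id, "p1")
    expect_equal(tri$mrna_id, "g1")
    expect_equal(tri$mrna_direction, "down")
    expect_error(cascade(pset, mset, gset, pm), "seed rule")
})

test_that("seed_match_targets finds exact 7-mer seed complements", {
    mir <- c(miR = "UAGCUUAUCAGACUGAUGUUGA")
    seed_rc <- revcomp(substr(chartr("U", "T", mir[[1]]), 2, 8))
    mrna <- c(hit = paste0(strrep("A", 30), seed_rc, strrep("C", 30)),
              miss = strrep("AC", 40))
    tab <- seed_match_targets(mir, mrna)
    expect_equal(tab$mrna_id, "hit")
})

test_that("integration recovers the planted regulatory structure", {
    cfg <- tiny_config(seed = 16, depth = 1e5)
    gen <- generate_references(cfg)
    cm <- simulate_counts(gen$truth, cfg)
    de_p_drug <- de_analysis(cm, "CS:SS", class = "pirna")$sets
    de_p_rev <- de_analysis(cm, "MC:CS", class = "pirna")$sets
    de_g_drug <- de_analysis(cm, "CS:SS", class = "mrna")$sets
    de_m_drug <- de_analysis(cm, "CS:SS", class = "mirna")$sets

    r <- find_reversed(de_p_drug, de_p_rev)
    expect_gte(length(intersect(r$all, gen$truth$reversal_pirnas)) /
                   length(gen$truth$reversal_pirnas), 0.8)

    de_pir <- c(de_p_drug$up, de_p_drug$down)
    maps_m <- build_target_map(gen$refs$pirna[de_pir], gen$refs$mrna, "mrna")
    corr <- fc_correlation(de_p_drug$lfc[de_pir], maps_m, de_g_drug$lfc)
    expect_lt(corr$r, 0)                     # piRNA represses its mRNA target
    expect_lt(corr$p, 0.01)

    maps_mi <- build_target_map(gen$refs$pirna[de_pir], gen$refs$mirna,
                                "mirna")
    corr2 <- fc_correlation(de_p_drug$lfc[de_pir], maps_mi, de_m_drug$lfc)
    expect_gt(corr2$r, 0)                    # piRNA moves with its miRNA

    tri <- cascade(de_p_drug, de_m_drug, de_g_drug, maps_mi,
                   mirna_seqs = gen$refs$mirna, mrna_seqs = gen$refs$mrna)
    planted <- paste(gen$truth$cascade$pirna_id, gen$truth$cascade$mirna_id,
                     gen$truth$cascade$mrna_id)
    expect_true(all(planted %in% paste(tri$pirna_id, tri$mirna_id,
                                       tri$mrna_id)))
})
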