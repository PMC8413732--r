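test_that("filter_reads applies adapter, quality and length rules", {
    adapter <- "AGATCGGAAGAGC"
    insert <- paste(rep("ACGT", 6), collapse = "")   # 24 nt
    fq <- write_fastq_file(
        ids = c("keep", "adap", "short", "lowq", "long"),
        seqs = c(insert,
                 paste0(substr(insert, 1, 22), adapter),
                 "ACGTACGTACGTACG",                   # 15 nt
                 insert,
                 strrep("ACGT", 10)),                 # 40 nt
        quals = c(strrep("I", 24), strrep("I", 22 + nchar(adapter)),
                  strrep("I", 15), strrep("#", 24), strrep("I", 40)))
    cl <- filter_reads(fq, adapter = adapter)
    expect_equal(unname(cl$stats["input"]), 5L)
    expect_equal(unname(cl$stats["adapter_trimmed"]), 1L)
    expect_equal(unname(cl$stats["quality_failed"]), 1L)
    expect_equal(unname(cl$stats["length_failed"]), 2L)
    expect_setequal(cl$reads$id, c("keep", "adap"))
    expect_equal(cl$reads$seq[cl$reads$id == "adap"], substr(insert, 1, 22))
    expect_equal(cl$total_clean, 2L)
    # 16-nt read is kept: the bound is inclusive
    cl16 <- filter_reads(data.frame(id = "r", seq = strrep("A", 16),
                                    qual = strrep("I", 16)))
    expect_equal(cl16$total_clean, 1L)
})

test_that("filter_reads handles empty and malformed FASTQ", {
    empty <- tempfile(); writeLines(character(), empty)
    cl <- filter_reads(empty)
    expect_equal(cl$total_clean, 0L)
    expect_equal(nrow(cl$reads), 0L)

    bad <- tempfile()
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), bad)
    expect_error(filter_reads(bad), "line 5")
    bad2 <- tempfile()
    writeLines(c("@r1", "ACGT", "x", "IIII"), bad2)
    expect_error(filter_reads(bad2), "line 3")
    bad3 <- tempfile()
    writeLines(c("@r1", "ACGTA", "+", "III"), bad3)
    expect_error(filter_reads(bad3), "line 2")
})

test_that("match_reference follows the class hierarchy and mismatch cap", {
    pir <- c(pirA = "ACGTACGTACGTACGTACGTACGTAC")
    mir <- c(mirA = "TTTTGGGGCCCCAAAATTTTGG")
    bundle <- reference_bundle(pirna = pir, mirna = mir)

    # exact piRNA match
    a <- match_reference(as_clean_reads(pir[[1]]), bundle)
    expect_equal(a$class, "pirna")
    expect_equal(a$feature_id, "pirA")
    expect_equal(a$mismatches, 0L)

    # two mismatches: unassigned at the 1-mismatch cap
    r2 <- pir[[1]]
    substr(r2, 3, 3) <- "T"; substr(r2, 10, 10) <- "G"
    a2 <- match_reference(as_clean_reads(r2), bundle)
    expect_equal(a2$class, "unassigned")
    expect_true(is.na(a2$feature_id))

    # a read matching miRNA with 1 mm and a piRNA with 0 mm goes to miRNA
    near_mir <- mir[[1]]
    substr(near_mir, 5, 5) <- "C"           # 1 mismatch vs mirA
    b2 <- reference_bundle(pirna = c(pirB = paste0(near_mir, "AAAA")),
                           mirna = mir)
    a3 <- match_reference(as_clean_reads(near_mir), b2)
    expect_equal(a3$class, "mirna")
    expect_equal(a3$mismatches, 1L)

    # lexicographic tie-break between equally good piRNA hits
    twins <- c(pirZ = pir[[1]], pirA = pir[[1]])
    a4 <- match_reference(as_clean_reads(pir[[1]]),
                          reference_bundle(pirna = twins))
    expect_equal(a4$feature_id, "pirA")
})

test_that("match_reference agrees with the hierarchical brute-force oracle", {
    set.seed(401)
    bundle <- reference_bundle(
        pirna = setNames(rand_dna(25, c(26, 31)), sprintf("p%02d", 1:25)),
        mirna = setNames(rand_dna(6, c(20, 23)), sprintf("m%02d", 1:6)),
        rrna = setNames(rand_dna(3, c(60, 90)), sprintf("r%02d", 1:3)),
        trna = setNames(rand_dna(3, c(60, 90)), sprintf("t%02d", 1:3)))
    pool <- c(bundle$pirna, bundle$mirna, bundle$rrna, bundle$trna)
    reads <- character(60)
    for (i in seq_along(reads)) {
        if (i %% 2 == 0) {
            reads[i] <- rand_dna(1, c(16, 30))
        } else {
            src <- pool[[sample.int(length(pool), 1)]]
            L <- sample(16:min(30, nchar(src)), 1)
            s <- sample.int(nchar(src) - L + 1L, 1)
            rd <- substr(src, s, s + L - 1L)
            for (j in sample.int(L, sample(0:2, 1)))
                substr(rd, j, j) <- sample(c("A", "C", "G", "T"), 1)
            reads[i] <- rd
        }
    }
    got <- match_reference(as_clean_reads(reads), bundle)
    for (i in seq_along(reads)) {
        want <- oracle_assign(reads[i], bundle, 1L)
        expect_equal(got$class[i], want$class, info = reads[i])
        expect_equal(got$feature_id[i], want$id, info = reads[i])
        expect_equal(got$mismatches[i], want$mm, info = reads[i])
    }
})

test_that("quantify builds complete matrices and validates samples", {
    design <- data.frame(sample = c("s1", "s2"), group = c("A", "B"))
    feats <- c("pA", "pB")
    a1 <- structure(data.frame(read_id = "r1", seq = "x", class = "pirna",
                               feature_id = "pA", mismatches = 0L),
                    total_clean = 5L)
    a0 <- structure(data.frame(read_id = character(), seq = character(),
                               class = character(), feature_id = character(),
                               mismatches = integer()),
                    total_clean = 0L)
    cm <- quantify(list(s1 = a1, s2 = a0), design, feats)
    expect_equal(cm$counts["pA", "s1"], 1L)
    expect_equal(sum(cm$counts), 1L)
    expect_equal(unname(cm$total_clean["s1"]), 5)
    expect_error(quantify(list(zz = a1), design, feats), "design")
})

test_that("tpm_normalize matches the formula and conserves totals", {
    m <- matrix(c(5L, 999995L, 0L, 1000000L), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    cm <- count_matrix(m, data.frame(sample = c("s1", "s2"),
                                     group = c("A", "B")),
                       total_clean = c(s1 = 1e6, s2 = 1e6))
    tpm <- tpm_normalize(cm)
    expect_identical(tpm["f1", "s1"], 5)        # count/total * 1e6
    expect_identical(tpm["f1", "s2"], 0)
    expect_equal(unname(colSums(tpm)), c(1e6, 1e6))  # all reads counted

    cm$total_clean["s1"] <- 0
    expect_error(tpm_normalize(cm), "positive")
})

test_that("TPM column sums never exceed 1e6 for partial quantification", {
    set.seed(402)
    for (rep in 1:5) {
        m <- matrix(rpois(20, 50), 4, 5,
                    dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
        cm <- count_matrix(m, data.frame(sample = paste0("s", 1:5),
                                         group = "A"),
                           total_clean = colSums(m) + rpois(5, 20))
        expect_true(all(colSums(tpm_normalize(cm)) <= 1e6 + 1e-6))
    }
})

test_that("filter-match-quantify round trip reproduces the simulated counts", {
    cfg <- tiny_config(seed = 11)
    gen <- generate_references(cfg)
    counts <- simulate_counts(gen$truth, cfg)
    fq <- simulate_reads(counts, gen$refs, cfg, tempfile())
    asn <- list()
    for (smp in counts$design$sample) {
        # max_len 31 admits the full 26-31 nt piRNA range (see vignette)
        clean <- filter_reads(fq[[smp]], max_len = 31L)
        asn[[smp]] <- match_reference(clean, gen$refs)
    }
    qp <- quantify(asn, counts$design, names(gen$refs$pirna), "pirna")
    expect_identical(qp$counts, subset_class(counts, "pirna")$counts)
    qm <- quantify(asn, counts$design, names(gen$refs$mirna), "mirna")
    expect_identical(qm$counts, subset_class(counts, "mirna")$counts)
})

test_that("genomic context annotation follows priority and reports repeats", {
    loci <- data.frame(chrom = "chr1",
                       start = c(100L, 500L, 900L, 5000L),
                       end = c(130L, 530L, 930L, 5030L),
                       name = paste0("L", 1:4))
    annot <- data.frame(
        chrom = "chr1",
        start = c(50L, 480L, 890L, 905L),
        end = c(200L, 560L, 920L, 940L),
        name = c("exon", "repeat:LINE1", "repeat:LTR/ERVK", "exon"))
    res <- annotate_genomic_context(loci, annot)
    expect_equal(res$loci$class, c("exon", "repeat:LINE1", "exon", "genomic"))
    expect_equal(as.integer(res$class_freq[c("exon", "repeat", "genomic")]),
                 c(2L, 1L, 1L))
    expect_equal(names(res$repeat_freq), "LINE1")

    bad <- tempfile()
    writeLines(c("chr1\t1\t10\tx", "chr1\tfoo\t10\ty"), bad)
    expect_error(annotate_genomic_context(bad, annot), "line 2")
})
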