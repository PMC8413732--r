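# Scaled-down study configuration used across tests: same stated world,
# smaller reference sets and depth so the suite stays fast. Exactness
# properties (round trips, oracle agreement) do not depend on scale.
tiny_config <- function(seed = 11L, ...) {
    defaults <- list(seed = seed, n_pirna = 80L, n_mirna = 30L,
                     n_mrna = 60L, n_rrna_trna = 10L,
                     mrna_len = c(150L, 400L), depth = 2e4,
                     frac_responsive = 0.15, n_cascade = 4L)
    over <- list(...)
    defaults[names(over)] <- over
    do.call(sim_config, defaults)
}

rand_dna <- function(n, len_range) {
    vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
           function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                             collapse = ""),
           character(1))
}

# Build a clean_reads object directly (bypasses FASTQ round trip when the
# test is about matching, not filtering).
as_clean_reads <- function(seqs, ids = paste0("r", seq_along(seqs))) {
    structure(list(reads = data.frame(id = ids, seq = seqs,
                                      qual = strrep("I", nchar(seqs)),
                                      stringsAsFactors = FALSE),
                   stats = c(input = length(seqs), adapter_trimmed = 0L,
                             quality_failed = 0L, length_failed = 0L,
                             retained = length(seqs)),
                   total_clean = length(seqs)),
              class = "clean_reads")
}

write_fastq_file <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
    path
}
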