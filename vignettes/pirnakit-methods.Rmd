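---
title: "pirnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## The problem

PIWI-interacting RNAs (piRNAs, 26–31 nt) are increasingly implicated in
neuronal gene regulation. A recurring study design asks whether a drug
exposure shifts the piRNA-ome and whether a counteracting treatment
*reverses* those shifts, with downstream consequences for the mRNAs (and
miRNAs) the piRNAs target by sequence complementarity. `pirnakit`
implements that whole analysis as a reproducible desk-scale pipeline over
a four-group design — baseline (SS), drug (CS), treatment (MS), and
treatment + drug (MC), three libraries per group:

1. read filtering and hierarchical class assignment (miRNA → rRNA → tRNA →
   piRNA, ≤ 1 mismatch),
2. tags-per-million normalisation and MA-plot random-sampling differential
   expression on pooled libraries, with Benjamini–Hochberg and Storey
   q-values,
3. piRNA target prediction on mRNA and miRNA by a 5′-anchored
   complementarity rule,
4. integration: reversal piRNAs, set-overlap significance, fold-change
   correlations, and the piRNA → miRNA → mRNA cascade,
5. common-substring motif extraction for piRNAs converging on one gene,
6. hypergeometric over-representation analysis against user-supplied GMT
   sets.

Because the real deposited data and database snapshots behind any given
study are not reproducible at desk scale, the package ships a first-class
synthetic-data generator that plants the regulatory structure the analysis
assumes, so that every stage can be scored against known truth.

## The differential expression model

Replicates are pooled by summation per group; the test is the two-library
MA-plot random-sampling (MARS) model. With pooled counts $c_1, c_2$ and
pooled library totals $n_1, n_2$,

$$M = \log_2 c_1 - \log_2 c_2, \qquad A = \tfrac12(\log_2 c_1 + \log_2 c_2),$$

and under random sampling of reads, with
$\hat p = \min(\max(2^A/\sqrt{n_1 n_2},\,\varepsilon),\,1-\varepsilon)$,
$\varepsilon = 10^{-12}$:

$$E[M \mid A] = \log_2 (n_1/n_2), \qquad
  \operatorname{Var}[M \mid A] =
  \frac{(1-\hat p)(n_1+n_2)}{\ln^2\!2 \; n_1 n_2 \hat p},$$

giving $z = (M - E[M\mid A])/\sqrt{\operatorname{Var}[M\mid A]}$ and a
two-sided normal p-value. Features absent in both groups are dropped;
a zero on one side only is replaced by 0.5 inside the logarithms.
`norm_log2fc` $= M - \log_2(n_1/n_2)$ carries the direction.

Both adjustments are reported: BH
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$) and Storey with a single fixed
$\lambda = 0.5$,
$\hat\pi_0 = \min(1, \#\{p_i > \lambda\}/((1-\lambda)m))$, floored at
$1/m$ when the estimate is zero. A feature is DE when the gated q-value is
$\le 0.05$ (inclusive); the default gate is BH, the stricter of the two
(since $\hat\pi_0 \le 1$, $q^{\text{Storey}} \le q^{\text{BH}}$
elementwise). Volcano-style raw `p < .05` lists are deliberately *not* an
alternative gate.

### A known, deliberate limitation

The MARS model prices in sampling noise only. When libraries carry
biological (negative-binomial) dispersion — the generator's default is
$\phi = 0.1$, $\operatorname{Var} = \mu + \phi\mu^2$ — pooling replicates
does not remove the extra variance: for a feature with pooled per-group
count $c$ the true $\operatorname{Var}(M)$ is approximately
$(2/\ln^2 2)(1/c + \phi/3)$ while the model uses $(2/\ln^2 2)(1/c)$. At
depth $10^6$ this inflates $|z|$ severalfold for abundant features, so
null features are heavily over-called: *recall* of planted effects is
essentially perfect, *precision* is not. This is the documented
anti-conservativeness of replicate-free DEGseq-style tests; the package
reproduces the procedure faithfully rather than silently replacing it with
a replicate-aware model (which is out of scope). The acceptance test for
planted-truth precision is accordingly expected to fail, and does so
loudly, while the binomial-null calibration test — where the generative
model matches the test's sampling assumptions — passes with type-I error
at the nominal level.

## The target rule

A target site is an antiparallel duplex between the piRNA's 5′-most 20 nt
(positions 1–20) and a 20-nt window of the target: window position $j$
pairs with site position $21-j$. A site is reported when at most 2
positions fail Watson–Crick pairing and (by default) position 1 — the 5′
anchor — pairs perfectly. The anchor requirement is an interpretive choice:
the underlying rule ("pairing at the 5′ end, fewer than 3 mismatches in the
20-nt window") is ambiguous about whether the 5′ nucleotide is scored
inside the window or must pair. Both behaviours are implemented
(`anchor_match`), the anchored one is the default, and neither is asserted
to be the behaviour of any external database. G:U wobble is not allowed;
`N` never pairs. miRNA targets shorter than 20 nt truncate the window to
the target length with a proportionally scaled mismatch budget
($\lfloor 2w/20 \rfloor$); `skip_short` drops them instead.

The scanner is implemented in C++ and is property-tested against an
independent brute-force oracle (all positions, reverse-complement Hamming
distance) across mismatch budgets and both anchor settings.

## The synthetic world

The generator's defaults *are* the stated study design: 500 piRNAs
(26–31 nt), 150 miRNAs (20–23 nt), 300 mRNAs (0.5–2 kb), 40 rRNA/tRNA
decoys, 4 groups × 3 replicates at $10^6$ expected clean reads per
library (a tenfold scale-down of the original study's average depth,
applied uniformly). Planted structure:

* 10% of piRNAs are drug-responsive: $\pm\delta$ with $\delta = 1.5$
  log2 units in CS vs SS, reversed with strength $\rho = 1$ in MC vs CS.
* Each responsive piRNA receives 1–3 dedicated mRNA target sites
  satisfying the rule exactly (0–2 corruptions, drawn from window
  positions 2–20 so the anchor is never corrupted); targeted mRNAs move
  opposite-sign with scale $\beta = 0.8$ (i.e. $\mp\delta\beta$).
* Six hub piRNAs carry the 17-mer `GTCTCTCCAGCCACCTT` verbatim inside
  their 5′ window and all target the single hub gene (the longest mRNA,
  non-overlapping slots), emulating the multi-piRNA/one-gene convergence
  pattern the analysis is designed to surface.
* Ten responsive piRNAs additionally target a miRNA (same-sign effect,
  scale $\gamma = 0.8$), and each such miRNA's 2–8 seed is planted into a
  further mRNA with an opposite-sign effect — the cascade triples.
* Counts are NB with $\operatorname{Var}=\mu+\phi\mu^2$, $\phi = 0.1$
  ($\phi = 0$ recovers Poisson); baselines are log-normal(0, 1)
  normalised to sum to one, giving heavy-tailed abundances like real
  small-RNA libraries.

Everything is a pure function of the seed; per-stage seeds are derived so
references, counts and reads are independently reproducible.

What the generator does **not** emulate: pooling of animals within a
library (each library is one sample), genomic multi-mapping ambiguity, UMI
or duplication artifacts, adapter chemistry beyond a fixed suffix, and
quality-score structure beyond two fixed levels. A green planted-truth
test therefore establishes that the pipeline's logic recovers the
structure it assumes — not that the statistical models are adequate for
any particular real library.

## Numerical and interface choices

* **Read filter**: adapter trimming keys on the first exact occurrence of
  the adapter's first 8 nt; mean Phred ≥ 20 defines "low quality"
  (unquantified in the source procedure); insert length window 16–30 nt
  inclusive. Note a deliberate tension: the piRNA reference range extends
  to 31 nt while the filter window ends at 30, mirroring the source
  protocol's gel window. Round-trip identity tests therefore pass
  `max_len = 31` explicitly; the default is unchanged.
* **Matcher**: a read must be a contiguous substring of a reference with
  ≤ 1 Hamming mismatch; classes tried in the exclusion order miRNA, rRNA,
  tRNA, piRNA; ties broken by fewest mismatches then lexicographically
  smallest id, so multi-mapping is deterministic. Reverse-complement
  matching is off by default (stranded sense libraries).
* **TPM**: denominator is the per-sample total of clean reads, exactly as
  the normalisation formula reads — not the class-specific sum. Column
  sums of TPM equal $10^6$ exactly if and only if every clean read is
  quantified.
* **Overlap universe**: Venn/overlap tests between two contrasts use the
  intersection of the two tested universes; the two directions
  (up∩down, down∩up) are tested separately, flagged in the report as an
  interpretive choice.
* **Correlation**: Pearson on normalised log2 fold changes (Spearman
  behind a flag); two-sided p from the $t$ transform; fewer than 3 usable
  pairs yields a not-testable result rather than a p-value.
* **miRNA→mRNA table**: user-supplied, or the canonical 7-mer seed rule
  (exact reverse complement of miRNA positions 2–8) when absent.
* **LCS motifs**: exact common-substring semantics replace gapped multiple
  alignment; the reported product of interest is a contiguous k-mer, which
  LCS recovers deterministically (ties in lexicographic order). Both the
  full-identity motif and a majority consensus view
  (`ungapped_consensus`) are emitted, since either could be meant by an
  alignment-derived "common sequence".
* **BH rounding guard**: $p \cdot m / m$ can round one ulp below $p$;
  q-values are clamped with `pmax(p, ...)` so the $q \ge p$ invariant
  holds exactly.
* **Run config file**: JSON rather than TOML/YAML — the target environment
  ships no TOML/YAML parser, and `jsonlite` is already a dependency.
* **Report digests**: `run_digest` is the MD5 of the path-free report
  content, so identical seed + config give identical digests across
  machines and directories.

## Known limitations

* The DE stage's precision pathology under biological dispersion,
  discussed above, is intrinsic to the replicate-free model.
* Hypergeometric ORA is plain upper-tail (no EASE-style adjustment), so
  its p-values are not comparable to DAVID's.
* The matcher is a desk-scale substring matcher, not a genome aligner;
  class percentages are per-read with deterministic tie-breaking, which a
  genome-scale multi-mapping pipeline would not guarantee.
* Three-way overlaps are reported as chained two-way tests plus the raw
  triple intersection; no three-way null is defined.
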