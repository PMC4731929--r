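# aluexon

Alu elements are ~300-nt primate-specific SINE retrotransposons with more
than a million copies in the human genome. Splice-site-creating mutations
inside intronic copies can recruit Alu sequence into internal cassette
exons ("exonization"), and a subset of these exons may contribute peptides
to the proteome. `aluexon` implements, in R, a proteotranscriptomic
pipeline for weighing that evidence, aimed at computational biologists
working with gene models, junction-level RNA-seq/Ribo-seq counts, peptide
libraries and RNA-editing count tables:

1. **Annotation** — extract Alu-derived internal exons from gene models and
   a repeat track (a single repeat copy must cover ≥ 25 bp and > 50 % of
   the exon), classify each exon's mRNA region (5'UTR / CDS / 3'UTR),
   rebuild the exon-inclusion ORF, and apply the NMD 50-nt rule: a stop
   codon more than 50 nt upstream of the last exon–exon junction is a
   premature termination codon (PTC).
2. **Splicing quantification** — per cassette exon, three 54-bp junction
   sequences (last 27 bp of the 5' exon + first 27 bp of the 3' exon);
   reads are matched ungapped with ≤ 2 mismatches and unique best hits.
   Percent-spliced-in is estimated as

   Ψ = I / (I + S),  I = (UJC + DJC) / 2,  S = SJC

   from the upstream/downstream/skipping junction counts, gated at ≥ 10
   reads on one junction. Exons pass with Ψ ≥ 0.33 in one sample or
   |ΔΨ| ≥ 0.10 at FDR < 10 % between a sample pair (a Fisher-exact
   stand-in for likelihood-based differential splicing).
3. **Translation** — the same Ψ estimator on ribosome-profiling junction
   footprints (first 30 nt of each read), compared with matched RNA-seq.
4. **Peptide evidence** — a peptide library (≥ 6 aa, exact matching) is
   searched against inclusion-isoform ORFs plus the background proteome;
   only peptides mapping to exactly one location count, classified as
   exon-body or junction-spanning. A negative-control exon set gives an
   upper bound on the false-discovery rate.
5. **Differential A-to-I editing** — per-site edited/unedited counts in a
   3-condition × 3-replicate design: per-replicate Fisher exact tests
   against control, combined by Fisher's method (χ² = −2Σln p, 6 df), BH
   FDR, and a high-confidence isoform-specificity rule (FDR ≤ 10 % for one
   isoform, ≥ 90 % for the other).
6. **Synthetic data** — seeded generators for genomes with planted
   exonization events, junction counts/reads, peptide libraries and
   editing tables, each with machine-readable ground truth.

## Worked example

```r
library(aluexon)

sim <- simulate_genome(sim_config(seed = 7))
sim
#> <alu_simulation> 40 gene(s), 26 Alu insertion(s), 13 exonized, seed 7

rec <- find_alu_exons(sim$transcripts, sim$repeats)
cls <- classify_alu_exons(rec, sim$transcripts, sim$genome)
cts <- simulate_junction_counts(sim, depth = 10000, exact = TRUE)
alu_exon_report(cls, cts)
#> Alu exon discovery funnel
#>   Alu-derived internal exons : 13
#>   located in the CDS         : 13
#>   non-PTC (putative coding)  : 10
#>   high inclusion (psi gate)  : 9
#>   differentially spliced     : 10
#>   combined list              : 10
```

Thirteen planted exonization events are all recovered; ten survive the NMD
filter (the planted non-PTC events), and the Ψ filters select those whose
true inclusion reaches 0.33 in a tissue or differs by ≥ 0.10 between
tissues. Desk-scale statistics reproduce the reference arithmetic
directly from counts:

```r
frame_divisibility_test(c(rep(3, 182), rep(4, 80)),
                        c(rep(3, 159), rep(4, 490)))$p
#> [1] 2.132666e-36
negative_control_fdr(262, 85, 649, 47)
#> $background_rate        0.0724191
#> $expected_false_positives       19
#> $fdr_upper_bound        0.2235294
log2_odds_fold_change(5.29, 9.46)
#> [1] 18.00094
```

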