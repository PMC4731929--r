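---
title: "Assessing the protein-coding contribution of Alu exons"
author: "aluexon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the protein-coding contribution of Alu exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluexon)
```

## The scientific problem

Alu elements are primate-specific SINE retrotransposons, roughly 300 nt
long, present in over a million genomic copies, most of them intronic.
Occasionally point mutations create splice sites inside an intronic copy
and recruit part of it into a spliced internal exon. Whether such exons
merely add untranslated sequence — or are degraded through
nonsense-mediated decay (NMD) — or genuinely contribute peptides to
proteins is an empirical question that requires combining several data
types: gene models and repeat tracks (which exons are Alu-derived),
junction-level RNA-seq (are they spliced in at appreciable levels),
ribosome profiling (are the inclusion isoforms translated), peptide
databases (is there direct proteomic evidence), and, for individual genes
whose isoforms differ functionally, downstream functional readouts such as
transcriptome-wide A-to-I editing for an RNA-editing enzyme. `aluexon`
implements this entire chain as composable, individually testable
functions, with a synthetic-data generator that plants known truth for
every stage.

## Annotation model

An exon is *Alu-derived* when a single repeat copy covers at least 25 bp
of it and more than half of its length (strict inequality); when several
copies overlap, the one with the largest intersection is used and the
thresholds apply to that copy alone. Only internal (neither first nor
last) exons are considered, because a cassette exon needs both flanking
junctions. Coordinates are 0-based half-open everywhere inside the
package; GTF (1-based closed) and BED (0-based half-open) are converted at
the reader/writer boundary, which confines off-by-one risk to two
functions.

Region classification is deliberately permissive: an exon overlapping the
CDS by even 1 bp is classified CDS. The boundary-straddling case is
genuinely ambiguous in any annotation-derived count, and the permissive
rule keeps every exon that could alter the protein; the per-record overlap
statistics let a user re-filter.

The inclusion ORF is rebuilt mechanically: the candidate exon is spliced
between its flanking exons, the mature mRNA assembled on the sense strand
(minus-strand transcripts are reverse-complemented), and translation runs
from the annotated start codon to the first in-frame stop. An exon whose
length is not a multiple of 3 shifts the downstream frame; if no stop is
reached the ORF is flagged `stop_lost` rather than discarded. The NMD
classifier then applies the canonical 50-nt rule: a stop codon more than
50 nt upstream of the last exon–exon junction is a premature termination
codon (PTC). The distance is measured between the end of the stop codon
and the last junction in mature-mRNA coordinates, which makes the
classification invariant to adding 5'UTR exons.

## Splicing quantification

Each cassette exon defines three junction sequences — upstream,
downstream, skipping — each the last 27 bp of the 5' exon concatenated
with the first 27 bp of the 3' exon (54 bp total; shorter exons truncate
the segment and are flagged). Reads are matched ungapped at every offset
covering the splice boundary with at least one nucleotide on each side,
with at most two mismatches, and must have a unique best hit across the
whole library; ties are discarded as multi-mapped. The boundary-overlap
rule is the package's explicit stand-in for whatever partial-overlap
behaviour a short-read aligner would exhibit at junction ends.

Inclusion is estimated as

$$\Psi = \frac{I}{I+S}, \qquad I = \frac{UJC + DJC}{2}, \qquad S = SJC.$$

Averaging the two inclusion junctions corrects the count imbalance that
arises because the inclusion isoform carries two junctions while the
skipping isoform carries one; with all junctions the same length, no
length normalization is needed. Ψ is undefined when $I+S=0$, and a
coverage gate requires ≥ 10 reads on at least one junction before an
estimate is trusted. Exons qualify as actively spliced if Ψ ≥ 0.33 in at
least one covered sample, or if some sample pair shows |ΔΨ| ≥ 0.10 at
BH FDR < 10 %. The differential test is a two-sided Fisher exact test on
the 2×2 table of rounded-I versus S per sample — a declared, deliberately
simple stand-in for likelihood-based differential-splicing models, not
claimed equivalent to them; BH correction is applied over all
(exon, pair) hypotheses jointly, the most conservative natural family.

## Translational evidence

Ribosome footprints are matched with their first 30 nt (36-nt reads
sequence into adapter), against the same junction libraries, and Ψ is
computed identically. Evidence flags (non-zero Ψ, strong translation at
Ψ ≥ 0.15, higher-in-Ribo-seq) are set only for exons with the coverage
gate satisfied in *both* assays. Enrichment of strong translation among
putative coding exons relative to NMD-inducing controls uses a one-sided
Fisher exact test. The truncation of footprints downstream of a stop
codon is treated as a property of the data — the simulator generates no
footprints 3' of an isoform's stop — not as an extra filter in the
pipeline.

## Peptide evidence and its negative control

The protein search space is the background proteome (all annotated ORF
translations) plus one inclusion-isoform translation per candidate exon,
each annotated with the exon's amino-acid span; a codon straddling the
exon boundary is assigned to the exon, so a peptide covering it plus at
least one flanking residue counts as junction-spanning. Matching is exact
string matching of peptides ≥ 6 aa (no I/L equivalence, no modifications),
and a peptide must occur at exactly one location in the whole space —
repetitive Alu-derived sequence makes the uniqueness rule the central
safeguard. Junction-spanning hits are the strongest evidence because
flanking exons are generally non-repetitive.

Because a peptide search against many candidate ORFs will produce some
spurious hits, the hit rate observed in a negative-control exon set
(NMD-inducing exons, conservatively assumed all true negatives) is
extrapolated to the candidate set: expected false positives
= round(n_candidates × control rate, half-up), and the FDR upper bound is
that count over the observed candidate hits. With the reference counts
(85/262 candidates vs 47/649 controls) this yields 19 expected false
positives and a 22 % upper bound, reproduced in the test suite from the
raw counts.

## Differential A-to-I editing

Editing sites arrive as per-site edited/unedited counts across nine
libraries (empty-vector control plus two protein-isoform conditions,
three replicates each). Sites are kept only if some library has ≥ 5
edited reads and every group has coverage in at least one replicate.
Group-level editing is the pooled fraction Σe/(Σe+Σu); global comparisons
between groups use a paired two-tailed Wilcoxon signed-rank test over
shared sites with pooled coverage ≥ 50 (paired, because the same sites are
compared; exact null for ≤ 25 untied differences, normal approximation
with continuity correction otherwise).

Differential calling follows a replicate-respecting scheme: replicate *k*
of the treatment is compared with replicate *k* of the control by a
two-sided Fisher exact test (index pairing keeps three independent tests
and hence 6 degrees of freedom in Fisher's method; a pooled-control
variant is available as an option), the three p-values are combined with
χ² = −2Σln p, and BH correction is applied per isoform across all
retained sites. Sites at FDR ≤ 10 % are differential; a site is
*high-confidence isoform-specific* when one isoform reaches FDR ≤ 10 %
while the other sits at FDR ≥ 90 %, a deliberately stringent two-sided
guard against calling specificity from noise. Zero-coverage replicate
pairs contribute p = 1 with a flag; p-values are floored at the smallest
representable positive double before the logarithm.

## What the simulator emulates — and what it does not

The generator plants, under a single seed that fully determines every
output: multi-exon genes (defaults: 40 genes, 5–8 exons of 90–180 bp,
introns of 700–1200 bp) on both strands; one mutated copy (2 %
substitutions) of a bundled synthetic 300-nt Alu-like consensus in 70 % of
genes; exonization of 60 % of copies with canonical AG/GT splice-site
dinucleotides, half as frame-preserving NON_PTC events (length divisible
by 3, reading frame sanitized of stops) and half as PTC events (an
in-frame stop planted inside the exon, > 50 nt from the last junction);
true per-tissue Ψ from Beta(2, 2) over four tissues; and a Ribo-seq
translation factor of 0.3 for PTC isoforms. All planted exons sit inside
the CDS — UTR placement would require additional UTR exon architecture,
so the 5'UTR/3'UTR classifier is exercised with constructed transcripts
in the unit tests instead. Subfamily labels (AluSx/AluJb/AluY at
0.60/0.25/0.15) are metadata, not sequence-derived.

Junction counts are sampled by isoform abundance: a read lands on an
inclusion junction with probability $2a/(2a+b)$ where $a = \psi t$ and
$b = 1-\psi$, because the inclusion isoform contributes two junctions.
This choice makes the averaged-junction Ψ estimator consistent
($\hat\Psi \to \psi$), which is the property the estimator is designed to
have; sampling inclusion *events* directly at rate ψ would build a factor
of two into the truth and break any unbiasedness check. An `exact` mode
replaces sampling by rounded expected counts — the noiseless limit used
for exact funnel-recovery tests. Editing tables use Beta(2, 6) baselines,
logit-scale group effects (default |δ| = 1.5), and negative-binomial
coverage (mean 100, size 10; sensitivity analyses use mean 200 as their
stated condition).

The simulator does *not* model sequencing errors, quality scores,
positional read-start biases, fragment-length effects, overlapping genes,
alternative transcription starts, or genuinely repetitive backgrounds
beyond the single shared consensus. Consequently, passing tests
demonstrate the correctness of the algorithms and estimators under the
stated statistical model, not robustness to alignment artefacts or
annotation errors in real data.

## Numerical choices and degenerate inputs

* Fisher's exact test (two-sided) uses the point-probability rule, the
  convention of mainstream statistical software; tests verify it against
  full hypergeometric enumeration.
* `round` operations on expected counts are half-up, matching the worked
  arithmetic 262 × 7.2 % → 19.
* Degenerate 2×2 tables (an empty margin) contribute p = 1 in screening
  contexts and raise errors in the bare kernel.
* Undefined Ψ (no informative reads) propagates as `NA` and can never
  satisfy a selection rule; stop-lost ORFs classify as NON_PTC with a
  warning flag.
* Problem sizes in the test and acceptance runs — depth 500 with 100
  replicates for estimator bias, 50 null runs of 150 sites for FDR
  control, 300 sites at coverage 200 for sensitivity, exhaustive oracles
  up to margins of 10 — were chosen as the smallest sizes at which the
  statistical claims are meaningfully testable.

## Known limitations

* The differential-splicing stand-in ignores estimation uncertainty in Ψ
  beyond the counts themselves and is less powerful than hierarchical
  models; it exists to make the |ΔΨ| ∧ FDR selection rule executable and
  testable.
* Peptide matching is exact; real search engines score spectra, handle
  modifications and tolerate I/L ambiguity.
* One transcript per gene is assumed in the simulator; multi-isoform
  interactions (e.g. a candidate exon that is constitutive in another
  transcript) are not modelled.
* The editing module consumes count tables; it does not re-align reads or
  discover sites.
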