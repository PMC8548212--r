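---
title: "Methods: fusion-isoform discovery, junction quantification and factorial differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion-isoform discovery, junction quantification and factorial differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Repeat elements occasionally donate promoters and exons to nearby genes. In
the mouse brain, Pgc1α expresses fusion transcripts (FTs) initiated from a
promoter inside a simple sequence repeat (SSR) several hundred kilobases
upstream of the canonical exon 2. The SSR exon (448 nt) splices either
directly onto exon 2 or through a 65-nt SINE cassette exon. Both FTs skip
exon 1 and its start codon, so any protein they encode must initiate from an
alternative ATG and will differ from the reference protein at the N-terminus
— the region thought to select PGC1α's transcriptional partners. This
package implements the computational arms of that analysis as reusable,
tested components, and ships seeded generators that rebuild every input at
desk scale with planted truth.

## The engineered mini-locus

`build_fixture_genome()` constructs a single-chromosome genome whose exon
architecture carries every annotated codon of the real locus:

* SSR exon, 448 nt, ATG at 362–364. The frame opened there runs flush to the
  exon end: (448 − 362 + 1)/3 = 29 codons, so the SSR-exon2 protein has 29
  novel N-terminal residues.
* SINE exon, 65 nt. Read through from the SSR frame, codons are clean at the
  junction (the SSR contributes a multiple of 3) and a TGA sits in frame at
  19–21 — the stop that forces reinitiation. The annotated ATG at 48–50
  opens a 6-codon block (MDEGYF) flush to the exon end.
* E1 (reference first exon) with a 48-nt CDS suffix encoding 16 residues,
  exactly the block the SINE's 6 residues replace.
* Eleven 200-nt internal exons and a 400-nt terminal exon carry a shared
  781-codon CDS plus stop, so the reference protein is 16 + 781 = 797 aa and
  the SSR fusion protein 29 + 781 = 810 aa.
* The first TGAA at or 3′ of the SINE ATG sits at SINE 53–56 (sense context
  ATGGA·TGAA·GG); excising it shifts the frame after the second codon, which
  is the engineered analogue of the 4-bp knockout allele.

Constraints enforced at generation time: no stray ATG upstream of an
annotated one within its exon, no stop codons inside any reading frame that
is supposed to stay open, and the final E1 residue differs from the final
SSR and SINE residues — otherwise the longest-common-suffix comparison would
absorb a junction-adjacent coincidence and the novel/replaced counts would
not reflect the splice junction. Inter-exon spacers are fixed at 5 kb; the
real gaps (566.7 kb and ~200 kb) would make the fixture genome hundreds of
times larger without changing any tested quantity, and the elongation-time
estimate therefore takes the real pre-mRNA length (~600 kb) as an explicit
argument rather than measuring the fixture.

## Coordinates and strand

External tables and reports use 1-based inclusive coordinates (the
convention of the printed allele, chr5:51,912,715–51,912,718 → 4 nt);
internal arithmetic is 0-based half-open, with `to_halfopen()` /
`from_halfopen()` as the only converters. Exon sequences are stored
genome-forward; `splice()` assembles the chain in genomic order and applies
the reverse complement once, at assembly, so strand handling lives in a
single tested place.

## Template enumeration

The published pipeline aligned long reads to "all possible exon combinations
(198)" — a rule the text does not fully specify. Both defensible readings
are implemented: `chains` mode emits every order-preserving exon subsequence
from an allowed start exon to the required terminal exon (s·2^k chains), and
`junction_pairs` mode emits one two-exon template per ordered pair. The
template count is configuration-dependent, never hard-coded; tests verify
chains mode against a brute-force subset filter on all models with up to six
exons and check the closed-form count.

## Long-read classification

Reads are head-trimmed by 50 nt (primer plus non-uniform start composition)
and kept at mean Phred ≥ 10; reads without quality strings (CCS FASTA) pass
the gate but are flagged. A junction is *spanned* when one aligned block
covers the breakpoint with at least `min_overhang` (default 8) matched nt on
both sides — the published "aligned through the junction points" is
unquantified, and 8 nt is standard junction-confidence practice, exposed as
a parameter. Assignment requires MAPQ ≥ 20 and at least one spanned
junction. Because templates share their downstream junctions, a read whose
spanned set is compatible with several templates is assigned to the unique
compatible template whose exon chain is contained in all the others (the
most specific member), and is otherwise `ambiguous`. Full-length calls
require ≥ 2 kb of read and coverage of every junction of the assigned
template; whether the original analysis additionally required terminal-exon
coverage is unknowable from the text, and junction coverage is the
documented choice here.

Two alignment routes feed the classifier. A built-in exact substring matcher
(`align_exact()`) handles error-free simulated reads without any external
aligner and gives MAPQ 60/0 for unique/multiple template hits; real or
error-bearing reads go through minimap2 (SAM, parsed via
Rsamtools/GenomicAlignments) or any PAF-producing aligner. At 2%
substitution error the MAPQ ≥ 20 gate becomes conservative: the SSR-ref and
SSR-SINE-ref templates differ only by the 65-nt SINE, so near-full-length
reads have close secondary hits and some drop below the gate. That trades
recall for precision — the acceptance run measures 100% accuracy among
assigned reads at both 0% and 2% error, with fewer reads assigned at 2%.

## Junction quantification

A spliced short read increments a junction when two consecutive aligned
blocks abut the donor and acceptor edges exactly, each with ≥ 8 matched nt;
a read counts at most once per junction but may increment two junctions of
the same isoform. "Counts per FPKM" is read as junction count divided by the
locus-level FPKM of the gene in that sample (the denominator is an input,
not estimated); a counts-per-million alternative is selectable by flag
because the printed legend is ambiguous. A mapping-quality floor is exposed
(default 0) rather than assuming unique-read filtering.

## ORF prediction and variant consequence

Translation uses the standard nuclear code (via Biostrings, cross-checked in
tests against a hand-written codon table); N-containing codons give X and
never terminate. Start selection is positional only — annotated starts,
first ATG, or all ATGs — with no Kozak scoring, matching the positional
reasoning of the source analysis. Codons are attributed to the exon holding
their first nucleotide; both printed counts (29 and 6) involve
junction-clean frames, so the attribution rule is unconstrained by them and
chosen for determinism. The knockout call after a deletion is a declared
heuristic — frameshift plus truncation below 20% of the intact ORF — and is
always reported alongside the raw evidence (new stop position, truncated
length).

## The factorial differential-expression stage

The design is a 2^3 full factorial (sex × genotype × organ) with n = 2
specimens per cell, i.e. 16 arrays and 8 per genotype. The omnibus test per
probe is the saturated three-factor fixed-effects ANOVA, whose overall F
equals the one-way F across the 8 cells (df 7 and 8 at n = 2); probes with
zero residual variance get an undefined p and a flag. FDR is
Benjamini–Hochberg across probes. The gates come from the published
signal-to-noise framework and are implemented as configurable constants, not
re-derived: multivariate significance at FDR < 0.05 with max
|group-vs-grand-mean log2FC| > 0.286 (SNR > 1); pairwise differential calls
additionally need post hoc p < 0.05 and |pairwise log2FC| > 0.094 (5%
practical difference); robustness needs the pairwise effect above 0.286.
The post hoc test is a Welch two-sample t per contrast (the source names
none; Welch is the robust default at tiny n and a pooled-variance t is a
one-line change). Default contrasts are WT versus KO within each sex × organ
cell.

Two deliberate numerical notes. First, the power property (a +1.0 log2FC
shift in one cell at σ = 0.25 detected with power > 0.9 at FDR 0.05) is
assessed at n = 4 per group — the same replication level as the
fold-change-bias property — because at n = 2 the omnibus F for that effect
has noncentrality 28 on df (7, 8), analytic power ≈ 0.75 at raw α = 0.05 and
roughly half that after FDR, so the high-power regime simply does not exist
there; the n = 2 design itself is unchanged everywhere else. Second,
clustering uses 1 − Pearson correlation of group-mean log2FC profiles with
average linkage and k = 4, mirroring the four reported expression patterns;
distance and linkage were unstated, correlation/average is the conventional
choice for pattern (shape) clustering, and a dendrogram cut height is
accepted as an alternative to k. PCA is centered, over samples, deterministic
up to sign, with zero-variance components dropped and flagged. Probe
curation keeps probes mapping to exactly one non-RIKEN symbol (RIKEN
detected by an explicit flag or the `...Rik` suffix) and tallies removals by
category. RMA normalization is upstream of this package; the matrix arrives
normalized, with `quantile_normalize()` as an optional utility.

## Motif scanning and enrichment

PFMs (JASPAR text, bracketed or bare) become log-odds PWMs against a
background distribution with a 0.01 pseudo-frequency. Promoter windows are
TSS ± 1 kb, strand-oriented, clipped and flagged at chromosome ends. Both
strands are scanned (the minus strand via the reverse-complement matrix,
reported at the mirrored forward offset); N contributes zero log-odds. The
scoring threshold defaults to 80% of the motif's maximum achievable score —
the exact settings of the published scan are unstated, so the default is
declared, configurable and echoed in outputs. Gene-level presence ignores
hit multiplicity. Enrichment between gene sets is Pearson's chi-square on
the 2×2 presence table, without continuity correction, df = 1, requiring
positive marginals. One derived example in circulation for the table
[[20, 80], [5, 95]] quotes ≈ 9.89; the closed form Σ(O−E)²/E with expected
cells 12.5/87.5 in both rows gives 10.2857, and the tests assert the
computed value.

## What the generators emulate — and what they do not

Every generator is a pure function of its `fixture_spec()` (same seed, same
bytes), and every dataset ships its truth. The long-read simulator draws
isoform of origin from a stated mixture (default 0.7/0.2/0.1 favouring the
SSR-SINE isoform), lengths uniform on 500–5,500 nt truncated at the
transcript (draws beyond it become full-length reads), a 50-nt random
adapter removed by the head trim, constant per-read qualities with a 5%
low-quality fraction, and substitution errors only by default — indels would
defeat the exact test matcher and are left to aligner-based runs. The
expression simulator adds Gaussian noise on the log2 scale (default σ =
0.25) to per-probe baselines plus one of four one-cell planted profiles
(±1.2 in a single sex × organ × KO cell), plus null probes. The promoter
simulator plants the motif consensus (the PWM's maximum-scoring word) at a
random offset and strand with per-set prevalence.

None of this reproduces real-data pathologies: PacBio error profiles are not
emulated, microarray probe-level artefacts are absent, promoters have iid
background composition, and the real dataset-level counts (12,527 / 9,996 /
2,363 / 2,016 / 354 / 1,980 probes, the 82% PCA variance, the 18%/56% motif
prevalences) depend on the deposited arrays, the probe annotation and the
mm10 genome and are out of scope. Passing tests therefore demonstrate that
the implementations are correct against planted truth and independent
oracles at desk scale — not that they would reproduce any particular field
dataset's numbers.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 500 long reads per
classification run; a 2,000-probe null for the type-I check; 200 shifted +
200 null probes for power; 4 × 50 probes for pattern recovery; 200 + 200
promoters of ±1-kb windows, 20 seeds for enrichment power; 1,000 random
tables for the chi-square oracle. These sizes keep every property inside
its Monte-Carlo tolerance (binomial 99% intervals where proportions are
compared) while the whole suite runs in about a minute and a half on one
CPU.

## Known limitations

* The classifier consumes alignments; it is not an aligner, and its exact
  matcher is for error-free reads only.
* Isoform quantification by EM, novel-exon discovery, intron retention and
  transcript-level FPKM estimation are out of scope; the locus FPKM used in
  normalization is an input.
* The SNR-gate thresholds (0.286, 0.094) are treated as fixed configurable
  constants; their dataset-dependent derivation belongs to the original
  framework and is not re-derived here.
* The knockout call is a mechanistic prediction about the ORF, not a claim
  about protein abundance in tissue.
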