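---
title: "Methods: from transcript-level splicing to proteome evidence"
author: "spliceomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transcript-level splicing to proteome evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceomics)
```

# The question and the pipeline

Bulk RNA-seq of a plant such as *Physcomitrella patens* shows pervasive
alternative splicing (AS): a large fraction of multi-exon genes produce
several isoforms, with intron retention the dominant event class.
Shotgun proteomics of the same tissues, however, confirms very few
isoforms as proteins. `spliceomics` implements the computations needed to
quantify both sides of that comparison and the null model that connects
them, plus a screen for lncRNAs that could modulate splicing by
base-pairing with pre-mRNAs. The stages run in a fixed order
(`runPipeline()`): gene models and sequences → AS events and junctions →
isoform usage → ORFs and peptides → detectability resampling → lncRNA
interactome.

All internal coordinates are 1-based closed `IRanges`, the native
Bioconductor convention. GTF/GFF3 files use the same convention, so import
and export involve no coordinate shifting, and every interval operation
(union, gaps, containment) goes through `IRanges` rather than hand-written
arithmetic — this is how the package avoids off-by-one errors, not by
carrying a second convention internally.

# AS event classification

For each locus the *hypothetical pre-mRNA* is the interval union of all
isoform exons; its complement within the gene span is the intron set
(`buildPreMrna()`). Events are found by pairwise comparison of isoforms
and deduplicated by (type, interval):

* **intron retention** — an exon of one isoform fully covers an intron of
  the other; the event interval is the intron.
* **exon skipping** — an internal exon of one isoform lies wholly inside
  an intron of the other.
* **alternative donor / acceptor** — two overlapping introns differ at the
  5′ (donor) or 3′ (acceptor) boundary; naming is strand-aware, and the
  event interval is the stretch between the two boundary positions.
* **mutually exclusive exons** — each of two disjoint internal exons is
  skipped in the other's isoform; the interval spans both exons.
* **alternative TSS / TTS** — the transcription start or end coordinates
  differ.

Two disambiguation rules keep the calls non-redundant, and both are
applied identically in the independent brute-force comparator used by the
test-suite: a donor/acceptor difference is suppressed when the differing
region is explained by a complete exon of the other isoform inside the
intron (that situation *is* exon skipping), and exon-skipping calls whose
exon participates in a mutually-exclusive pair are absorbed into the MEE
event.

A junction is *alternative* iff some isoform whose genomic span covers the
intron does not splice it identically, or iff it borders an AS event
interval; retained-intron junctions are therefore always alternative.
`filterJunctions()` can additionally drop each isoform's first intron and
the junctions of retained introns, mirroring the usual exclusions applied
before splice-signal statistics.

# U2/U12 typing

Junctions are typed by log-odds PPM scoring,
score = Σ~i~ log2(p~i~(base~i~)/0.25), with ambiguous bases contributing
zero. The U2 score is donor (window −3..+10 around the 5′ splice site)
plus acceptor (−14..+3); the U12 score is donor plus the best branch-point
window scanned over −40..−10 upstream of the acceptor, because plant U12
branch points are positionally variable. The larger score wins; ties go to
U2 (the overwhelmingly dominant spliceosome), and a junction stays
`unclassified` when both scores fall below the floor (default 0 bits,
i.e. worse than random). The matrices ship as editable YAML
(`inst/extdata/ppm_default.yaml`), built from plant U2 GT–AG and U12
AT–AC consensus with probability floor ε = 0.01 — classification is fully
reproducible from configuration, with no hidden constants.

# Isoform usage, DAS and DE

Isoform fractions are percentages of the per-condition gene total
(condition means over replicates); a gene with zero FPKM in a condition
has *undefined* fractions, never zero. dIF is the percentage-point change
(the familiar "|dIF| > 20" rule only makes sense on this scale), and the
switch score is √JSD with base-2 logarithms, which confines it to [0, 1].

Significance is a permutation test on √JSD over replicate condition
labels, exhaustive whenever the number of label assignments is manageable
(C(10,5) = 252 for the default five replicates per condition). The p-value
is the proportion of assignments whose statistic is ≥ the observed one —
the standard valid convention, under which P(p ≤ α) ≤ α. One consequence
is worth stating plainly: because √JSD is symmetric, the complementary
assignment always ties the observed statistic, so the smallest attainable
p with *n* vs *n* replicates is 2/C(2n, n). With three replicates per
condition that is 0.1, and no 3v3 design can ever clear an FDR of 0.05;
this is why the synthetic generator defaults to five replicates per
condition (p~min~ = 2/252 ≈ 0.008), and why we did not adopt a looser
p-value convention instead. A gene is DAS when its BH-adjusted p is below
0.05 *and* some isoform moves by more than the dIF threshold (default 20);
without replicates the call degrades to threshold-only mode and says so.

DE calling clamps gene FPKM at the floor (default 0.2) before the
log-ratio — the floor is stated by the analysis convention, the clamping
is our choice of zero-handling — excludes genes below the floor in both
conditions, and flags |log2 FC| > 2.

# Proteogenomics and the detectability null

ORFs are the longest first-ATG-to-stop stretches per frame (default
minimum 100 codons), one primary ORF per transcript; the 5′-UTR length is
the ORF start offset. Homology-based rescue of short ORFs is deliberately
out of scope. Tryptic digestion cleaves after K/R except before P and
emits fragments with up to one missed cleavage. Peptide occurrence is
tested against *digests*, not raw protein substrings — an observed tryptic
peptide must be producible by digestion. Uniqueness is computed after
collapsing I and L (isobaric in MS; configurable), over peptides of 7–50
residues (the typically observable range; configurable). An
isoform-specific peptide (ISP) occurs in exactly one isoform ORF of
exactly one gene; a gene is AS-confirmed at the proteome level only when
observed ISPs cover ≥ 2 isoforms.

The in-silico detection experiment asks what that confirmation count
*should* be if all isoforms were translated equally: each gene's sampling
pool is the multiset concatenation of its isoform digests (a peptide
shared by k isoforms appears k times — equal molar abundance; a
distinct-peptide frame is available by flag), and per replicate the
observed number of peptides is drawn without replacement. The default is
100 replicates; the tests raise this to 2000 where Monte-Carlo error
matters and verify the rate against exact hypergeometric enumeration on a
toy pool. RNG substreams are derived per (replicate, gene) from a stable
hash of the gene id, so results are independent of gene ordering.

# lncRNA–(pre-)mRNA interactome

Candidates must exceed 200 nt, reach FPKM ≥ 0.5 in some condition, lack an
ORF of ≥ 100 codons (a deliberate coding-potential stand-in — full
coding-potential classifiers and Rfam screening are out of scope), and
belong to an unannotated assembly class; cis-NATs are lncRNAs overlapping
a coding locus on the opposite strand by ≥ 1 nt.

Hybridization is modelled as *antiparallel* local alignment: the lncRNA is
reversed (not complemented) and aligned to the target under the pairing
matrix G:C = +4, A:T = +2, G:U = +1, anything else −6, with affine gap
cost 20 + 8k for a k-base gap. Reversal-plus-pairing-matrix is physically
equivalent to reverse-complement-plus-identity-matching, but keeps the
wobble entry explicit; a parallel convention is available for comparison.
The search is an exhaustive affine-gap DP (Biostrings'
`pairwiseAlignment`) rather than a seeded heuristic: at desk scale the
heuristic seeding parameters of genome aligners have no analogue and
would only add a correctness variable. Multiple sites per pair come from
iterative masking of the optimal site until the score drops below the
threshold, which yields non-overlapping, locally optimal sites without
double counting. The default acceptance threshold (score ≥ 100,
length ≥ 25) equals a perfect 25-bp G:C duplex; an E-value calibration is
not attempted because no tractable null model is part of the scheme.

Sites are classified against the pre-mRNA structure: `junction_spanning`
iff the target interval covers an exon–intron boundary (both flanking
positions), `exonic`/`intronic` otherwise, with `spans_alternative_junction`
set from the junction catalogue. Enrichment of interactions at
alternative junctions is a two-sided Fisher exact test on the
{alternative, constitutive} × {interacted, not} table (odds ratio with
Haldane correction when a cell is zero). lncRNA–target co-expression uses
Spearman ρ with average ranks and an exact permutation p for ≤ 8 samples;
with 3 samples the exact two-sided p cannot fall below 1/3, and the
function warns rather than silently reporting untestable thresholds.

# The synthetic benchmark: what it emulates, and what it does not

`generateGenomeAndGenes()` builds each gene in transcription orientation —
a 5′ UTR free of ATG, a planted ORF of random sense codons, a 3′ UTR,
split across four exons with consensus-signal introns (U2 GT..AG or U12
AT..AC matching the shipped PPMs) — then writes it onto alternating
strands. Event variants are minimal edits (retain intron 2, skip the
frame-preserving exon 2, shift a boundary by 9 nt, truncate an end by
15 nt, or substitute a mutually exclusive exon), so planted event counts
are recovered exactly and CDS-internal edits yield clean deletion
proteins whose junction peptides become ISPs. The default event mix makes
intron retention the most common class, as observed in moss. Expression
plants isoform switches achieving an exact expected dIF, fold-changes of
2^3 for DE genes, and mean-preserving lognormal replicate noise (FPKM-like:
strictly positive, right-skewed). MS observations are multinomial draws
proportional to isoform abundance × peptide detectability, with an
`ispWeight` knob (0 = a proteome blind to isoform-specific peptides) and a
dominant-isoform mode (only the major isoform is translated). lncRNAs are
planted as reverse-complement windows — optionally with G:U wobble
substitutions — against exonic, intronic or junction-spanning positions
of target pre-mRNAs, written onto a dedicated chromosome, or as cis-NAT
antisense overlaps.

What passing tests on these data do **not** show: performance under
assembly artefacts, positionally biased coverage, incomplete gene models,
FPKM estimation error correlated between isoforms, PTMs or spectral
mis-identification on the MS side, or thermodynamics of RNA duplexes
(the pairing matrix is a score, not an energy model). The generator is a
correctness harness with planted truth, not a realism simulator.

# Numerical choices and degenerate inputs

* Zero-FPKM genes: isoform fractions undefined (NA) and excluded, never 0.
* √JSD of identical distributions is exactly 0; negative rounding is
  clamped before the square root.
* Tie between U2 and U12 scores → U2; intron < 4 nt → warning,
  dinucleotides and subtype unclassified.
* Digestion of a protein without K/R returns the protein itself; terminal
  cleavage sites produce no empty fragments.
* Sampling more peptides than a pool holds takes the whole pool.
* Empty sequences, empty site sets, zero-margin enrichment tables and
  constant expression vectors all return defined empty/NA results with a
  message rather than failing.
* All-tied expression in the UTR-length association is reported as ρ = 0
  (average-rank convention) rather than NA, so planted-null checks have a
  defined value.

# Problem sizes

The test-suite and the acceptance script run, per invocation, on 40–60
synthetic genes (~2 isoforms each, genome ≈ 100–200 kb), 500 random
proteins for digestion cross-checks, 200 random genes for classifier
oracle equivalence, 200 random sequence pairs (≤ 60 nt) for aligner oracle
equivalence, 2000 resampling replicates for the detectability toy, and
500 null genes for the permutation-test size check — chosen so the whole
pipeline exercises every code path in about a minute per block on a
single CPU while keeping Monte-Carlo error far below the asserted
tolerances.

# Known limitations

* ORF prediction is longest-ATG-ORF only; isoforms whose true product
  starts at a non-ATG codon or is rescued by homology are missed.
* The permutation DAS test needs ≥ 4–5 replicates per condition to have
  any resolution below FDR 0.05 (see above); with fewer replicates the
  package intentionally reports threshold-only calls.
* Junction typing scores only the configured windows; non-canonical
  splice sites shifted by alternative donor/acceptor events are left
  unclassified rather than forced into a class.
* The interactome stage scores complementarity, not binding energy, and
  treats each lncRNA–target pair independently.
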