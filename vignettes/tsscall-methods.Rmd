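---
title: "Methods: TSS detection, classification, and primary-transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS detection, classification, and primary-transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsscall)
```

This vignette is the package's account of its models and the decisions
behind them: what each stage assumes, which parameters matter and why
they default where they do, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## Data model and conventions

All in-memory coordinates are 1-based inclusive, the native R/Bioconductor
(IRanges) convention; BedGraph I/O converts from that format's 0-based
half-open standard. A TSS position is the +1 nucleotide itself — the first
transcribed base — and every distance below is measured from the +1 site
to the first base of a start codon, in transcribed nucleotides, so a UTR
length equals that distance and a TSS sitting on the A of ATG has UTR 0.
On the minus strand "upstream" means larger coordinates and all extracted
sequences are reverse-complemented. Replicons may be flagged circular, but
distance computations never wrap across the origin: every rule below is a
short-range rule (at most 600 nt) and the origin is a conventional, not
biological, discontinuity; wrapping would complicate every interval
operation for a vanishingly rare configuration.

The two signals are stranded per-base vectors: whole-transcriptome depth
and primary-library (5′-enriched) read-start counts. dRNA-seq libraries
enrich native 5′-triphosphate ends; processed 5′-monophosphate ends that
escape digestion are tagged during library preparation with a barcode
(default `TACCCTAG`), and reads carrying it are false-positive primary
ends. The filter is exact, 5′-anchored and case-insensitive with no
mismatch allowance — absent any stated tolerance, an exact rule is the
only reproducible choice. The pipeline reports the filter's counts but
does not subtract them from the read-start profile: the profile supplied
to detection is taken to be the post-filter signal, which is how such
profiles are produced in practice.

## TSS detection and curation

A position `p` is a candidate when `starts[p] >= min_read_starts`
(default 20) and the percent increase over the strand-aware upstream
neighbour `q` is at least `min_increase_percent` (default 250):

```
100 * (starts[p] - starts[q]) / max(starts[q], 1) >= 250
```

The denominator floor of 1 makes a zero upstream count yield a finite,
very large increase instead of an undefined one. The increase is computed
on the read-start signal by default; a depth-based variant is available
through `detection_config(signal = "depth")` because the exact signal
underlying "percent of coverage increase" in interactive TSS-detection
tools is not standardized.

Manual inspection of automatically detected TSSs is replaced by two
deterministic curation rules, each configurable and disableable:

* **Local maximum.** A candidate is removed when any position within ±3 nt
  has a higher read-start count (ties keep the smaller coordinate). This
  collapses the 1–3 nt "stutter" of initiation into a single +1 site and
  guarantees no two verified TSSs sit within the window on one strand.
* **Downstream support.** A candidate is removed when mean
  whole-transcriptome depth over the next 20 nt downstream is below 5 —
  a read-start spike with no transcript behind it (a processed end, a
  terminator pile-up) is not a TSS.

Both windows are small on purpose: they are meant to remove artifacts,
not to re-rank genuine alternative TSSs, which the primary/secondary
ranking handles later.

## Classification geometry

The category windows, with deliberate boundary semantics (the source
vocabulary of "maximal"/"more than" is loose, so the bounds here are
fixed and unit-tested at the exact boundaries):

| category | rule |
|---|---|
| sTSS | distance to nearest downstream same-strand ORF start in [0, 300] |
| pTSS | that distance in (300, 600] |
| revision route | inside a same-strand ORF, (0, 200] past its start |
| iTSS | inside a same-strand ORF, > 200 nt past its start |
| asTSS | inside an opposite-strand ORF, or a detected 5′-UTR |
| nTSS | none of the above |

Several labels can coexist on one TSS. An iTSS within 300 nt of its ORF's
end that is simultaneously the sTSS of the next gene loses the iTSS label
— it is read as the next gene's promoter firing inside the upstream gene.
Distal (pTSS) assignment uses the nearest downstream same-strand start;
whether intervening opposite-strand genes should block assignment is not
derivable from first principles, and "nearest same-strand start wins" is
the simplest rule that makes assignment unique. Antisense labels extend to
detected 5′-UTRs (not 3′-UTRs, whose extent the data do not delimit);
this is switchable off. TSSs belonging to rRNA/tRNA features are tagged
`structural` and excluded from classification and all downstream motif
and initiation statistics.

**Start-codon revision.** A TSS up to 200 nt past an annotated start
contradicts the annotation (transcription cannot start downstream of
translation). The revision scans from the TSS for the first codon in
{ATG, GTG, TTG, CTG} in frame with the annotated stop; if found, the gene
start moves there, the shortening in amino acids and the new UTR are
recorded, and an RBS check (motif 3′ end 3–14 nt upstream of the new
start, positive log-odds) is reported alongside. The revision is accepted
with or without an RBS hit — the RBS is corroborating evidence, not a
gate — and the flag lets users apply a stricter policy. With no in-frame
start codon downstream, the TSS is relabelled iTSS.

**Ranking.** Per gene, the TSS with the highest read-start count is
primary, the rest secondary; ties break toward the TSS closest to the
start codon (the biologically default promoter), then toward the smaller
coordinate for determinism. A transcript is leaderless when its UTR is
≤ 3 nt — too short to hold any ribosome binding site. The UTR histogram
uses 5-nt bins over primary plus secondary assignments.

## Motif discovery

Motifs are learned by expectation maximization under a ZOOPS model
(zero-or-one occurrence per sequence). The offset prior is uniform over
the *legal* window, so the documented spacer constraints do the
positional work: the −10 hexamer's 3′ end lies 3–11 nt upstream of the
+1 site within a 50-nt upstream window; the −35 hexamer is searched only
in sequences with a −10 call, its 3′ end 16–23 nt upstream of that
sequence's −10 5′ end; the width-5 RBS ends 3–14 nt upstream of the
start codon within a 20-nt window. RBS input is pre-filtered to
sequences whose mean purine (A+G) fraction over positions −15…−6
exceeds 0.55, UTRs shorter than 20 nt being excluded outright.

Numerical choices:

* Pseudocount 0.25 per base; background estimated from the input windows'
  overall composition. The objective reported and traced is the MAP
  objective — data log-likelihood plus the Dirichlet log-prior implied by
  the pseudocounts — which is exactly monotone under the EM updates (the
  plain likelihood is only approximately so once pseudocounts regularize
  the M-step). The trace is asserted monotone in the test suite.
* Five seeded restarts by default, each initialized from a random legal
  window; convergence at a gain below 1e-6 or 200 iterations.
* `N` bases score log-ratio 0 (background) and are skipped in
  re-estimation.
* Spacers are measured from the motif 3′ end to the +1 site (−10) or to
  the first start-codon base (RBS), and reported per call.

**Occurrence calls.** A sequence "has" the motif when its Bayes factor —
the mean per-offset motif-vs-background likelihood ratio at the converged
PWM — is at least 4 (an equal-prior posterior of 0.8). The ZOOPS
occurrence prior itself is not usable as a call threshold: on motif-free
input it drifts toward 1, at which point every sequence's posterior
exceeds 0.5 regardless of content. The Bayes-factor rule keeps calls
honest on weak or absent motifs (column-shuffled inputs drop far below
planted runs) while tracking the planted occurrence rate closely when a
real motif is present; the threshold of 4 is Jeffreys' conventional
"substantial evidence" cutoff. Consensus strings use uppercase at column
frequency ≥ 0.7, lowercase at ≥ 0.4, else `n`.

## Operons, sub-operons, and coverage-extension transcripts

Adjacent same-strand genes join into one transcript at ≥ 10 sense
spanning reads; maximal runs form operons, listed in transcription order.
Spanning counts are consumed as a table keyed by gene pairs: a spanning
read is a property of read alignments, not recoverable from per-base
coverage, so BedGraph-only inputs must provide the table. Only
annotation-adjacent genes can join — allowing joins across unexpressed
intervening genes would make operon membership depend on an expression
floor rather than on the spanning evidence. "Expressed", for the
monocistronic census only, means mean gene-body depth ≥ 5 (configurable);
the census partitions expressed genes exactly into monocistronic genes
and operon members.

A TSS assigned to an operon's first gene is the operon's primary TSS; a
TSS at gene *k* > 1 defines a sub-operon comprising genes *k* … end — a
contiguous suffix in transcription order, asserted as an invariant on
every output. Multiple TSSs on one internal gene collapse to a single
sub-operon keeping the strongest TSS.

Antisense and novel transcripts are called by coverage extension
downstream of the TSS on its own strand: extend while per-position depth
≥ 15, report at length ≥ 20 nt, and for long (> 500 nt), abundant
(mean > 40) calls require depth ≥ 80 at the TSS itself — a strong
transcript claimed from a weak start is more plausibly spurious
readthrough. The mean is the arithmetic mean over the called extent.
Overlapping extensions of intergenic TSSs merge into one transcript with
alternative TSSs. Within each novel transcript all three frames are
scanned for ORFs (start in {ATG, GTG, TTG, CTG}, in-frame stop inside the
transcript, ≥ 25 aa excluding the stop); the longest is reported with an
RBS presence flag, and transcripts without a qualifying ORF are putative
non-coding RNAs. Intragenic (iTSS) transcripts are reported without ORF
calls — their products (mRNA fragments, internal promoters, ncRNAs) are
an open question the data here cannot settle.

## Element statistics

**Readthrough.** For a predicted cis-regulatory element (e.g. a
riboswitch), the 5′-UTR region runs from the detected TSS (or, absent
one, the element start) to the base before the gene start; the
readthrough ratio is mean UTR depth over mean ORF depth (floored at 1e-6,
with zero-depth ORFs flagged). Ratios ≥ 10 are called termination-like:
terminating elements in these data sit at 20–100-fold, reading-through
ones near 1, so any cutoff in the wide gap between is equivalent and 10
leaves symmetric headroom.

**Enrichment.** Functional-category enrichment of long-UTR genes
(100–300 nt) uses two-sided Fisher exact tests per category, reporting
raw p-values (plus a Benjamini–Hochberg column); two-sided because
"over-representation" findings should survive the agnostic test. The test
suite checks the p-values against brute-force hypergeometric enumeration
for all margins ≤ 30.

**Initiation statistics.** Base frequencies at −1, +1, +2 (strand-aware)
per category, for all TSSs and for the top and bottom deciles by
read-start count; decile size is `ceiling(n/10)` with ties broken by
genome position for determinism, and categories under 10 members skip
the deciles. Intergenic TSSs are pooled with the sense group for these
statistics, as their transcripts behave like sense mRNAs once called.

## The synthetic-data generator

`generate_dataset()` lays out one 100 kb replicon with 80 genes — operon
runs with planted spanning counts straddling the joining threshold,
antisense host blocks, six riboswitch-like loci, standalone genes with
sense/distal/internal/revision-route TSSs, rRNA/tRNA features, and a gene
desert hosting novel transcripts and processed-end spikes. Fifty TSSs of
strength 40–200 are planted on both strands; every planted category is
enforced geometrically at planting time, so the classification rules can
re-derive each label exactly and the classification oracle test is a
genuine round trip. Promoter (TATAAT/TTGACA) and RBS (AGGAG) consensus
motifs are planted at legal spacers in 90% of eligible sites; 60.5% of
simulated primary reads carry the false-positive barcode, matching the
fraction such libraries typically discard.

Read-start noise is Poisson per position (mean 0.2): at that background,
the probability of a noise position reaching the 20-read-start floor is
negligible, so detection errors in tests reflect the rules, not the
noise model — raising the mean is the intended way to stress detection.
Depth is a block model: gently tapered plateaus (±5%) over planted
transcripts rather than per-read simulation, which is sufficient to
exercise every coverage threshold at desk scale. Riboswitch loci receive
exact UTR/ORF plateaus (6000/60, 3000/50, 2600/100, 2000/100 — ratios
100, 60, 26, 20 — plus two ratio-1 loci without TSSs), so the
readthrough verdicts have exact expected values. Processed-end spikes
(strength 35) sit in coverage deserts where the downstream-support rule
must remove them.

The generator does **not** emulate: sequencing error or quality
variation, mapping ambiguity, rRNA abundance and depletion, overlapping
genes, condition-dependent expression, or ragged transcript ends. Tests
passing on this data therefore demonstrate that the rules are implemented
exactly as stated and are recoverable under Poisson start noise — not
that the thresholds are optimal for any particular real library.

Default problem sizes (100 kb, 80 genes, 50 TSSs, 1000 reads) make a full
generate–run–score cycle take a few seconds, so the entire suite,
including the end-to-end acceptance properties, runs in well under a
minute.

## Known limitations

* Spanning-read counting from BAM is out of scope; counts arrive as a
  table.
* The EM uses a uniform offset prior within the legal window; tools with
  positional (e.g. Gaussian) offset priors can rank alternative
  placements differently in wide windows.
* Operon joining cannot bridge annotation gaps (unannotated genes break
  runs).
* The readthrough verdict is a two-class heuristic on one ratio; it does
  not model condition-dependent riboswitch states.
* Enrichment p-values depend on the annotation's category assignment;
  with few categorized genes the tests are underpowered.
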