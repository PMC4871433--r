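---
title: "chipscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipscan)
```

## The problem

Chromatin immunoprecipitation followed by sequencing (ChIP-seq) maps the
genomic binding sites of a DNA-associated protein. When the control is a
pre-immune serum pull-down rather than input chromatin, and sequencing
depth is modest, heavyweight statistical peak callers are often less
transparent than the classic windowed ratio analysis this package
implements: count reads in overlapping fixed-width windows, normalize for
library depth, take the IP/control ratio as an enrichment score, merge
and rank enriched windows, and then characterize each binding site by its
genomic context and shared sequence motif. `chipscan` packages that
procedure as tested, deterministic, reusable code, together with the
downstream ChIP-qPCR and RT-qPCR arithmetic used to validate binding
sites and measure knockdown effects, and a synthetic-data generator with
complete truth tables so every stage can be exercised against known
ground truth.

## Enrichment model

Reads are counted in windows of `window_width` bp every `step` bp
(defaults 100 and 50, i.e. a two-fold tiled grid). A read increments
every window it overlaps by at least one base; midpoint assignment was
rejected because 50 nt reads on a 50 bp step would never span two
windows, defeating the purpose of overlapping tiles.

Let $x_w$ and $y_w$ be the IP and control counts in window $w$, and
$s = N_{control}/N_{IP}$ the ratio of mapped-read totals. The window
score is

$$\mathrm{score}_w = \frac{\max(s\,x_w,\ [x_w = 0])}{\max(y_w, 1)}$$

i.e. the IP count is scaled to the control's depth, then zeros are
replaced by 1 **on both sides** before the ratio. The source procedure
replaces zeros "to allow the calculation of ratios"; that purpose forces
a nonzero denominator, hence the double-sided rule. The scale factor is
kept at full double precision internally; the conventional two-decimal
form (e.g. `1.62`) is display only, because rounding inside the pipeline
would make results depend on print precision.

Windows with score at or above `threshold` (default 2, the conventional
lowest reporting cut) are seeds. Seeds that overlap or abut are merged
into a single peak spanning their union — no gap tolerance, the simplest
rule consistent with peak widths of 100–550 bp on a 50 bp step. The
peak's final score is recomputed on the merged area, counting each read
once per area (not once per window), with the same scaling and
pseudocount rules. Peaks are ranked by descending score; ties break by
chromosome then start so ranking is a deterministic permutation.

Mapping statistics report mapped, unique and repeated (multi-mapping)
percentages **relative to the initial quality-filtered read count**.
Published tables of this kind sometimes footnote the unique row as a
percentage of mapped reads, but the printed values only reproduce with
the initial count as denominator; `mapping_stats()` follows the
arithmetic that reproduces the print and documents the discrepancy.

## Coordinates

Internally every interval is 0-based half-open. GFF3, the minimal SAM
dialect and the serialized peak table are converted at the I/O boundary
(1-based inclusive), so `end1 - start1 + 1 = end0 - start0` holds by
construction and off-by-one drift cannot accumulate. Whether published
peak tables of this style print half-open or inclusive pairs is usually
unstated; the 1-based inclusive reading is an assumption, applied only at
serialization. Chromosome names match by exact string equality (no "chr"
aliasing).

## Annotation classes

Each peak is annotated with the nearest catalog feature within 100 kb,
where distance is the gap between intervals (0 for overlap or abutment)
and ties break by smaller edge-to-TSS distance, then feature id. Location
classes follow the precedence TSS > O > DU/DD > I:

* **TSS** — a transcription start site within 2,500 bp of either peak
  edge (inclusive);
* **O** — overlapping a transcribed feature by at least 1 bp;
* **DU** / **DD** — distal, within 100 kb, 5' of the nearest feature's
  TSS (strand-aware) or 3' of its transcribed end;
* **I** — intergenic, no feature within 100 kb.

The TSS rule anchors on peak edges rather than midpoints because peaks
are short (100–550 bp) and midpoints would flip classes near the
boundary. TSS outranks O so that a peak overlapping a gene right at its
promoter is reported as promoter-proximal; the O class is then reserved
for body-overlapping sites far from the TSS. All "within" boundaries are
read inclusively (≤ 2,500, ≤ 5,000, ≤ 100,000 bp). lncRNA proximity
tiers use the same gap measure against lncRNA-biotype features only,
with the 5 kb tier taking precedence over the 100 kb tier.

## Motif discovery

`discover_motif()` is a greedy matrix-building search in the CONSENSUS
family: every word of the first sequence seeds a one-member count
matrix; each cycle extends every retained matrix with the word of the
next sequence (both strands by default) that maximizes Hertz–Stormo
information content

$$IC = \sum_w \sum_b f_{bw} \log_2 \frac{f_{bw}}{p_b}$$

keeping the `beam` (default 50) best distinct matrices per cycle.
Crucially, the first cycle is **not** pruned: under a uniform background
all one-word matrices tie on IC, so pruning there would discard candidate
sites arbitrarily. Frequencies are smoothed with a pseudocount of 0.25
per cell (avoids log 0 at 20-sequence counts); `information_content()`
itself defaults to pseudocount 0 so closed-form checks are exact. The
consensus string renders each column as its majority base at frequency
≥ 0.5, else `N`. Width defaults to 10 (the length of the degenerate
consensus the package's generator plants); the search is deterministic
given the input order — with both strands searched, the orientation of
the reported matrix is inherently arbitrary, so recovery is evaluated up
to reverse complement.

Match significance: each window of a sequence is scored by the
log-likelihood ratio against the background; the best-site p-value is the
exact single-window tail probability under the i.i.d. background,
computed by convolving the per-column score distributions after
discretizing scores into 0.01-bit bins (zero frequencies floored at −30
bits so impossible bases stay below any attainable match). The
discretization error is bounded by the bin size and the convolution is
validated against Monte-Carlo sampling in the test suite. A published
per-sequence p-value of this kind depends on the real peak sequences and
the original program's null, so no specific printed p-value is treated
as reproducible here.

## qPCR arithmetic

Relative expression uses the delta-delta-Ct method at assumed
amplification efficiency 2: replicates are averaged in Ct space, SEMs
combine in quadrature in Ct space and are exponentiated last. ChIP
enrichment is percent input, $100 \cdot 2^{(Ct_{input} -
\log_2(1/f)) - Ct_{IP}}$ with input dilution fraction $f$ (default 1 —
the source protocol does not state its dilution), and fold enrichment
over a non-binding reference locus, with optional pre-immune background
subtraction performed in percent space (clamped at zero: negative
enrichment is reported as no enrichment). Primer standard curves convert
slope to efficiency as $(10^{-1/slope} - 1) \cdot 100$, passing QC in
[90, 110]%.

## The synthetic world

The generator emulates the inputs the pipeline needs, with truth tables:

* **Genome** — i.i.d. uniform ACGT organized in blocks, one per planted
  peak: featured blocks (40 kb) carry one 8 kb gene placed with the
  geometry the intended location class requires (1 kb from the TSS for
  TSS-class, mid-body for O, a 10 kb gap for DU/DD); intergenic blocks
  (180 kb) hold the peak > 100 kb from every feature. Defaults plant 21
  peaks split 2 TSS / 8 O / 3 DD / 6 DU / 2 I at fold 8, width 300 bp.
  Every third featured gene is a lncRNA so proximity tiers are exercised.
* **Motif** — one concrete instantiation of the degenerate IUPAC string
  `ANAGAAGTGG` (N drawn per peak) written at each peak center.
* **Reads** — 50 nt, emitted directly as alignments (the pipeline
  consumes mapped reads; simulating FASTQ plus an aligner would add
  nothing testable). Control read starts are uniform with Poisson totals
  at rate $\rho = d/(W + r - 1)$ per bp, so the expected number of reads
  overlapping one full window of width $W$ equals the configured depth
  $d$; the IP track adds $(fold - 1)\rho$ across each planted peak. Reads
  originating inside a repeat copy are labelled `repeated` and re-placed
  at a uniformly drawn copy of the family (seeded multi-mapper
  randomization); the scorer itself stays deterministic. The repeat
  family defaults to 5 near-identical 500 bp copies at 2% divergence.
* **Ct tables** — $Ct = base - \log_2(q) + \mathcal{N}(0, sd)$ per
  replicate, three replicates per cell, sd 0.1 cycles by default.

Everything derives from one mandatory seed and regenerates
byte-identically. What the generator does **not** model: fragment-size
effects, GC bias, duplicate reads, mappability, sequencing error. A green
recovery test therefore establishes the pipeline's arithmetic and
geometry on an idealized library, not robustness to real-library
artifacts.

### Choosing the calibration depth

The recovery/calibration world is stated as "fold ≥ 4, control depth ≥ 20
reads/window" with a ≤ 1% bound on null windows scoring above 2. With
independent Poisson counts $X, Y$ at equal depth $d$ and realized scale
$s$ never exactly 1, the worst-case null fraction is
$P(X \ge 2\max(Y, 1))$ — ties count whenever $s$ lands marginally above
1. That quantity is 1.64% at $d = 20$ and 1.13% at $d = 25$, crossing the
1% bound only at $d \ge 26$ (0.78% at 28, 0.61% at 30). The calibration
world therefore runs at depth 30: inside the stated "≥ 20" condition,
with the bound met in closed form rather than by simulation tuning. At
depth exactly 20 the 1% bound is mathematically unattainable for this
scoring rule; the generator's own default stays at 20, the value the
recovery statements are phrased around.

## Numerical choices and degenerate inputs

* Empty files, empty peak sets and zero-depth simulations are valid and
  produce empty (header-only) outputs; the motif stage skips with a
  warning when no genome FASTA is configured or fewer than two peaks
  exist.
* Reads on chromosomes absent from the window grid are skipped and
  tallied, not errors; unknown chromosomes at parse time are not errors.
* Peak-table scores serialize at `%.17g` so write/read round-trips are
  lossless.
* All randomness flows through explicit seeds; the RNG state of the
  caller is saved and restored around every generator.

## Limitations

No statistical significance model for peaks (no FDR, no
Poisson/negative-binomial testing) — the score is a ratio, as in the
original desk procedure. No fragment-shift modelling or duplicate
removal. Motif search is exhaustive-greedy, not EM; motif databases and
logo rendering are out of scope. Efficiency-corrected delta-delta-Ct
variants are not implemented. Published peak counts, coordinates and
class tallies from any specific experiment depend on the underlying
genome build and annotation and are not reproduction targets of the test
suite.
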