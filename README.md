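# chipscan

Windowed ChIP-seq enrichment scoring, peak annotation, consensus motif
discovery and qPCR quantification — a small, deterministic, fully tested
pipeline for transcription-factor binding-site discovery when the control
is a pre-immune serum pull-down and sequencing depth is modest.

**Who it is for.** Labs running classic antibody-vs-preimmune ChIP-seq on
a handful of samples, who want the transparent windowed-ratio analysis
(the kind desk tools like SeqMonk popularized) as scriptable, testable R
code — plus the downstream arithmetic used to validate binding sites by
ChIP-qPCR and to measure knockdown effects by RT-qPCR.

## The method in brief

Reads from the IP and control libraries are counted in overlapping
fixed-width windows (100 bp, step 50 bp; any-overlap counting). With
$x_w, y_w$ the IP/control counts in window $w$ and
$s = N_{control}/N_{IP}$ the depth-normalization factor, each window is
scored

$$\mathrm{score}_w = \frac{\max(s\,x_w,\ [x_w{=}0])}{\max(y_w,\,1)}$$

(zeros pseudocounted to 1 on both sides). Windows scoring ≥ 2 are merged
into peaks when they overlap or abut; each peak is re-scored on its
merged area (reads counted once per area), ranked by descending score,
annotated with the nearest catalog feature within 100 kb, and classified
as TSS (within 2.5 kb of a transcription start site), O (overlapping a
feature), DU/DD (distal up/downstream) or I (intergenic), plus a
lncRNA-proximity tier (within 5 kb / within 100 kb / other). The top
peaks' sequences feed a CONSENSUS-style greedy information-content motif
search (Hertz–Stormo IC, exact convolution p-values). The qPCR module
implements delta-delta-Ct relative expression, percent input, background
subtraction, fold enrichment over a reference locus and primer-efficiency
QC. A seeded synthetic-data generator produces genomes, annotations,
repeat families, planted-peak read sets and Ct tables with truth tables
for end-to-end recovery testing.

## Worked example

Sequencing-QC arithmetic from published-style read counts, then a full
run on a bundled synthetic world (21 planted peaks, fold 8, split
2 TSS / 8 O / 3 DD / 6 DU / 2 I, with a planted `ANAGAAGTGG` motif):

```r
library(chipscan)

mapping_stats_from_counts(n_initial = 14746400,
                          n_unique = 11056749, n_repeated = 2312293)
#> initial reads: 14746400
#> mapped: 13369042 (90.66%)
#> unique: 11056749 (74.98%)
#> repeated: 2312293 (15.68%)

compute_scale_factor(21612138, 13369042)
#> scale factor 1.62 (= 21612138 / 13369042, exact 1.616581)

cfg <- simulation_config(seed = 17)
simulate_dataset(cfg, "demo")
rep <- run_pipeline(list(ip = "demo/ip.bed", control = "demo/control.bed",
                         features = "demo/features.tsv",
                         genome = "demo/genome.fa",
                         out_dir = "demo/out", top_k = 21))
head(as.data.frame(rep$peaks)[, c("rank", "chrom", "start", "end", "score",
                                  "feature", "location_class", "lnc_tier")], 5)
#>   rank chrom  start    end    score   feature location_class         lnc_tier
#> 1    1  chr2 453900 454400 7.350515   SynLnc5             DD lnc_within_100kb
#> 2    2  chr2 533900 534400 6.455444 SynGene19             DU lnc_within_100kb
#> 3    3  chr1 489750 490250 6.444205      <NA>              I            other
#> 4    4  chr2 399900 400400 6.415859 SynGene13              O lnc_within_100kb
#> 5    5  chr1  59900  60400 6.003827   SynLnc1              O   lnc_within_5kb

rep$motif
#> motif model: width 10, consensus ANAGAAGTGG, IC 15.662 bits, 21 sites
```

The run writes `peaks.tsv` (ranked 1-based-inclusive peak table),
`window_scores.bedGraph`, `class_summary.tsv`, `motif.txt` and
`run_report.json` into the output directory; the top-ranked peaks are the
planted sites (their fold-8 scores of ~6–7 stand clear of null
fluctuations around 1) and the recovered consensus is exactly the planted
degenerate word. Scores here are IP/control ratios — e.g. 7.35 means that
peak's area held 7.35-fold more depth-normalized IP than control reads.

qPCR arithmetic:

```r
percent_input(ct_ip = 24, ct_input = 20 + log2(10), input_fraction = 0.1)
#> [1] 6.25
primer_efficiency(-3.3219)   # slope of a standard curve, Ct per log10 dilution
#> $efficiency 100.0012  $pass TRUE
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "chipscan.R", package = "chipscan"))') \
    simulate -c sim.json -o demo          # sim.json: {"seed": 17}
# ... run -c config.json | qpcr ct.csv | stats reads.bed --initial N
```

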