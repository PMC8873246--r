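# regulocus

Locus-scale regulatory genomics in R: 4C-seq viewpoint contact tracks, a
G-test of differential enhancer–promoter contact, ROSE-style
super-enhancer calling, and single-nucleus ATAC quality control with
promoter-accessibility cell classification.

## The problem

Clustered gene loci under super-enhancer (SE) control — the fast-myosin
(*Myh*) locus is the paradigm — express exactly one gene of the cluster
per cell, selected by a chromatin loop between a distal SE and one
promoter. Establishing that architecture from data takes four analyses
that this package implements as composable, tested building blocks:

* **`digest_genome` / `annotate_blind`** — in-silico restriction
  digestion of a contig into the ordered fragment map that 4C reads are
  "translated back" to (first cutter `^GATC`, DpnII-style), with blind
  fragments (no secondary `CATG` site) flagged but retained.
* **`mask_viewpoint` → `normalize_to_region` → `running_mean` →
  `ratio_track`** — per-fragment 4C profiles: 2 kb viewpoint exclusion,
  one multiplicative factor equalizing signal over a reference region
  (the TADs around the locus) to 10⁶, an 11-fragment running mean, and
  between-condition log2 ratios.
* **`run_difftest`** — the significance procedure for differential
  contact: classify each fragment of the TAD as increased or decreased
  between conditions on *unsmoothed* normalized signal, tabulate
  directions for the SE region vs the remainder of the TAD, and test
  independence with the likelihood-ratio statistic
  `G = 2·Σ O·ln(O/E)` at 1 df (Williams correction optional).
* **`call_superenhancers`** — stitch peaks within 12.5 kb, rank by
  summed signal and apply the hockey-stick slope-1 cutoff on the
  unit-scaled rank curve.
* **`qc_filter` / `score_promoters` / `classify_fiber_type`** — keep
  nuclei passing the six strict QC inequalities (peak fragments in
  (3000, 100000), % reads in peaks > 15, blacklist ratio < 0.025,
  nucleosome signal < 10, TSS enrichment > 2), then assign each nucleus
  to the gene whose promoter dominates its accessibility.

A synthetic-locus generator (`sim_config`, `make_genome`, `simulate_4c`,
`simulate_enhancer_signal`, `simulate_nucleus_matrix`) emulates the
statistical structure every stage assumes — power-law contact decay with
a plantable loop, a plantable heavy 7-peak SE cluster, fiber-type
mixtures with QC covariates — so the whole pipeline runs and is tested
without any sequencing download. See the methods vignette
(`vignettes/regulocus-methods.Rmd`) for the model, parameter and
tie-break decisions.

## Worked example

```r
library(regulocus)

cfg <- sim_config(seed = 1L)               # the default synthetic world
gen <- make_genome(cfg)
map <- annotate_blind(digest_genome(gen$sequence, chrom = gen$chrom),
                      gen$sequence)
map
#> <fragment_map> 1031 fragments on chrS [0, 5e+05); cutter GATC / CATG

lm <- locus_model(cfg, map)
a <- simulate_4c(cfg, map, lm$viewpoint, condition = "quadriceps", seed = 2L)
b <- simulate_4c(cfg, map, lm$viewpoint, condition = "soleus",     seed = 3L)
a <- normalize_to_region(mask_viewpoint(a), lm$reference)
b <- normalize_to_region(mask_viewpoint(b), lm$reference)

res <- run_difftest(a, b, lm$se_region, lm$tad_region)
res$test
#> G-test of independence (df = 1)
#>           direction
#> region     increased decreased
#>   SE              79        13
#>   TAD_rest        37        66
#> G = 53.8047, p = 2.214e-13
```

86% of SE fragments gained contact in the loop-active condition versus
36% elsewhere in the TAD: the planted viewpoint–SE loop is detected
(`p = 2.2e-13`). The same world's enhancer landscape recovers the
planted cluster as the rank-1 super-enhancer:

```r
peaks <- simulate_enhancer_signal(cfg, seed = 4L)
st <- call_superenhancers(peaks[, c("chrom", "start", "end", "signal")])
head(st, 3)
#>   chrom  start    end n_peaks     signal rank is_super
#> 1  chrS 241000 274659       7 5091.24981    1     TRUE
#> 2  chrS  63660  64285       1   72.08594    2    FALSE
#> 3  chrS 177182 177522       1   66.31342    3    FALSE
```

and nucleus classification recovers every planted fiber-type class among
QC-passing nuclei:

```r
nm <- simulate_nucleus_matrix(cfg, seed = 5L)
labels <- classify_nuclei(nm$metrics, nm$counts)
table(labels$label[labels$qc_pass], nm$metrics$true_class[labels$qc_pass])
#>        Myh1 Myh2 Myh4 Myh7
#>   Myh1  225    0    0    0
#>   Myh2    0   49    0    0
#>   Myh4    0    0  451    0
#>   Myh7    0    0    0   60
```

Publication-style coordinates parse directly; the printed SE region is
the expected 42-kb element:

```r
interval_width(parse_region("chr11: 67,103,534–67,145,377"))
#> [1] 41844
```

## Command line

Every stage is scriptable through one entry point (`inst/exec/regulocus`
or `regulocus_cli()`): `simulate`, `digest`, `track`, `difftest`,
`se-call`, `classify`. Each subcommand logs its parameters to stderr,
writes results plus a JSON manifest, and exits non-zero with a one-line
diagnostic on any error:

```sh
regulocus simulate --seed 1 --out demo/
regulocus difftest --track-a demo/quad.normalized.bedgraph \
    --track-b demo/sol.normalized.bedgraph \
    --fragments demo/fragments.bed \
    --se "chrS:240,001-281,844" --tad "chrS:200,001-300,000" \
    --out demo/difftest
```

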