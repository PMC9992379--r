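# blastocall

Genotyping CRISPR/Cas9 editing outcomes in single cells of human
preimplantation embryos — and telling real loss of heterozygosity apart
from whole-genome-amplification artifacts.

## The problem

Editing outcomes in a 4–8-cell embryo are read per blastomere, and a single
cell's DNA must be whole-genome amplified (WGA/MDA) before sequencing. WGA
routinely drops one allele of a heterozygous locus (allelic dropout, ADO),
so the locus *looks* homozygous. That is a serious confounder, because
genuine homozygosity at the cut site — via interallelic gene conversion,
which copies a tract of the homologous chromosome across the double-strand
break — is precisely the repair outcome one wants to detect. blastocall is
for researchers analysing amplicon sequencing of edited single cells (or
clonal validation material such as ESC subclones) who need dropout-aware
genotype calls, edit classification, and conversion-tract inference from
one coherent toolkit.

## What it computes

Starting from allele-depth tables (`sample_id, locus_id, chrom, pos,
allele, depth`):

* **Genotype calls** — loci under 12× are *not amplified* and excluded;
  supported alleles need ≥ 3 reads and ≥ 10% of locus depth; FreeBayes-style
  record filters (`QUAL > 1 & QUAL/AO > 10 & SAF > 0 & SAR > 0 & RPR > 1 &
  RPL > 1`, clauses toggleable) and amplicon-length deletion sizing.
* **Edit taxonomy** — WT / Mut / Indel (< 100 bp) / Del (≥ 100 bp) / HDR
  (all ssODN markers), canonical cell labels (`WT/Indel`, `Del/Indel`,
  `homo-Indel`, …) with an LOH flag, and per-embryo mosaicism calls.
* **ADO rates** — per sample and per locus: homozygous / amplified among
  heterozygous-expected panel loci. With per-copy failure probability *q*,
  observed ADO among amplified loci is *2q/(1+q)*; pooling *k* clonal cells
  collapses it to *2qᵏ/(1+qᵏ)*. Observed homozygosity at an edited locus
  decomposes as *t + (1−t)·a* for true conversion rate *t* and dropout *a*.
* **Conversion tracts** — LOH segments around the cut site from phased
  flank variants, template-parent assignment by parental-incompatibility
  votes, and tract-length bounds: minimum across proven-converted sites
  (inclusive), maximum to the innermost heterozygous flanks (exclusive).
* **Cohort reports** — frequency tables, homozygosity fractions, one-tailed
  Fisher's exact tests (log-factorial, enumeration-exact), deterministic
  TSV/markdown/JSON reports.
* **Simulation** — mosaic embryo cohorts, WGA dropout, read depths and
  phased trio haplotypes with full ground truth (`sim_config()`,
  `load_preset()`), so every estimator above is testable offline.

## Worked example

Simulate a biallelic-editing cohort (16 embryos, 4–8 cells each), call
genotypes, label cells and embryos:

```r
library(blastocall)
library(dplyr)

preset <- load_preset("mybpc3_biallelic")
cfg <- preset$config
hp <- simulate_trio_haplotypes(cfg, preset$n_flank_variants)
truth <- simulate_embryo_cohort(cfg, hp)
evidence <- simulate_wga_evidence(truth, hp, cfg)

calls <- call_genotypes(evidence)
cells <- classify_cells(filter(calls, locus_id == "target"))
tabulate_genotype_frequencies(filter(cells, !is.na(label)), "simulated")
#> # A tibble: 8 × 4
#>   cohort_id label           n   pct
#>   <chr>     <chr>       <int> <dbl>
#> 1 simulated Indel/Indel    30 37.5
#> 2 simulated homo-Indel     21 26.2
#> 3 simulated homo-WT        10 12.5
#> 4 simulated homo-HDR        9 11.2
#> 5 simulated Del/Indel       4  5
#> 6 simulated WT/Indel        4  5
#> 7 simulated homo-Del        1  1.25
#> 8 simulated WT/HDR          1  1.25
```

Half the simulated cells show a homozygous (LOH-flagged) genotype — a
mixture of true gene conversion and WGA dropout, which is the point:

```r
labelled <- inner_join(cells, truth[, c("cell_id", "embryo_id")],
                       by = "cell_id")
classify_embryo_mosaicism(labelled) |> count(classification)
#>   classification     n
#> 1 mosaic            14
#> 2 uniform            2
```

Measure dropout itself on the 608-locus heterozygous panel (18
blastomere-like cells):

```r
p <- load_preset("ado_panel")
hpp <- simulate_trio_haplotypes(p$config, 4)
tr <- simulate_embryo_cohort(p$config, hpp)
evp <- simulate_wga_evidence(tr, hpp, p$config, include_target = FALSE)
est <- sample_ado_rate(call_genotypes(evp), ado_panel(p$config)$locus_id)
glance(est)
#>   scope      n n_undefined mean_rate min_rate max_rate
#> 1 sample    18           0     0.271    0.235    0.340
```

A mean per-cell ADO of 27% on pre-verified heterozygous loci is the scale
of artifact any single-cell LOH claim has to clear. `autoplot()` methods
exist for category tables and ADO estimates, `plot_tract_bounds()` for
tract calls, and `tidy()`/`glance()` for result objects.

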