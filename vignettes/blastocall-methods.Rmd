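---
title: "Methods: genotyping edited single cells under WGA artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping edited single cells under WGA artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastocall)
library(dplyr)
```

# The problem

CRISPR/Cas9 editing of human preimplantation embryos is read out in single
blastomeres of 4–8-cell embryos. A single cell carries picograms of DNA, so
every assay starts with whole-genome amplification (WGA, typically multiple
displacement amplification). WGA is biased: at a heterozygous locus one of
the two alleles frequently fails to amplify (allelic dropout, ADO), making
the locus look homozygous. Because loss of heterozygosity (LOH) at the cut
site is itself one of the biologically interesting repair outcomes —
interallelic gene conversion copies a tract of the homologous chromosome
across the break — ADO and true LOH are confounded in exactly the
measurement designed to detect LOH.

blastocall implements the computational side of this assessment as a
reusable, fully testable pipeline:

1. **genotype calling** from per-sample, per-locus allele-depth tables;
2. **on-target edit classification** into the taxonomy used in the field
   (WT, point mutant, indel, large deletion, HDR) with per-cell labels and
   embryo mosaicism calls;
3. **ADO estimation** at sample, locus and pool scope from a
   heterozygous-locus panel;
4. **conversion tract inference** from phased flanking variants;
5. **cohort reporting** with exact one-tailed Fisher comparisons; and
6. a **synthetic-data generator** that simulates all of the above with
   known ground truth, so every stage has an oracle.

# Genotype calling

Input is an allele-evidence table: `sample_id, locus_id, chrom, pos,
allele, depth`, one row per observed allele. Coordinates are 1-based
(VCF convention). A locus with total depth below `min_depth = 12` reads is
treated as **not amplified** and excluded from genotyping entirely — it
appears in neither the numerator nor the denominator of any dropout rate.
Above that threshold, an allele is **supported** when its depth reaches
both `min_allele_reads = 3` reads and `min_allele_frac = 10%` of the locus
depth. One supported allele is a homozygous call, two a heterozygous call,
more than two are reported as `multi_allelic` (contamination or WGA
chimera) and treated as an error state downstream, never silently
collapsed.

The 12× floor is the field's convention; the allele-support rule is this
package's own choice (no published rule exists for dismissing a minor
allele) and both thresholds are exposed as arguments. They were chosen so
that a locus at exactly 12× can still be called heterozygous (3 + 9, 4 + 8,
…), and so that under the default depth model (see below) a spurious
homozygous call at a truly heterozygous amplified locus has probability
~10⁻⁴ — negligible against the dropout rates of interest.

Record-level filtering of FreeBayes-style annotated variants implements the
six-clause high-confidence expression (`QUAL > 1`, `QUAL/AO > 10`,
`SAF > 0`, `SAR > 0`, `RPR > 1`, `RPL > 1`) with clauses individually
toggleable; the reduced three-clause form used for long-range amplicons is
`clauses = c("qual", "saf", "sar")`. Missing annotations raise an error —
a record never passes silently.

Large deletions screened by long-range PCR are sized by amplicon-length
subtraction (`estimate_deletion_from_amplicon()`); differences below the
100 bp class boundary are not deletions, and an observed amplicon longer
than expected is rejected (length screening cannot size insertions).

# Edit taxonomy and labels

A resolved on-target allele is one of:

| category | definition |
|---|---|
| `WT` | exact reference match |
| `Mut` | the known pathogenic base, nothing else |
| `Indel` | net length change, 1–99 bp |
| `LargeDel` | deletion ≥ 100 bp |
| `HDR` | **all** ssODN marker substitutions, no other change |

HDR requires every synonymous marker (4, 2 or 3 depending on the locus
design); partial marker presence is biologically interesting (incomplete
template conversion) but is not a category — it is returned as a
`partial_hdr` audit flag with `category = NA`, and labelling such an allele
is an error rather than a guess. Likewise an allele carrying all markers
*and* a ≥ 100 bp deletion raises a classification conflict.

A cell's label is built from its *distinct* observed alleles: two distinct
alleles give a compound label in the fixed order WT < Mut < Del < Indel <
HDR (so `"Del/Indel"`, never `"Indel/Del"`); a single distinct allele gives
`homo-<category>` and sets the LOH flag. An embryo is **uniform** when all
labelled sister cells share one label and **mosaic** otherwise (≥ 2
distinct labels; a stricter ≥ 3 reading is available via `min_distinct`).

# ADO estimation

Definitions follow the panel design: for each single cell, the
sample-specific ADO rate is the fraction of apparently homozygous loci
among the *amplified* heterozygous-expected panel loci; the locus-specific
rate swaps the roles of sample and locus. A sample (or locus) with zero
amplified loci has an undefined rate, flagged and excluded from cohort
means with a logged count — silent zeros would bias the mean downward.
Cohort means are unweighted across samples; weighting by amplified-locus
count recovers the pooled homozygous fraction exactly (a tested identity).

Under the generative model below, a heterozygous locus that amplified shows
one allele with probability

$$a \;=\; P(\text{exactly one copy drops} \mid \text{not both drop})
      \;=\; \frac{2q(1-q)}{1-q^2} \;=\; \frac{2q}{1+q},$$

where $q$ is the per-template-copy failure probability. For DNA pooled from
$k$ clonal cells each allele has $k$ template copies, so $q$ is replaced by
$q^k$ and observed ADO collapses as $2q^k/(1+q^k)$ — the quantitative form
of "pooling lowers ADO". Both closed forms are recovery targets in the test
suite. The same arithmetic decomposes observed homozygosity at an edited
locus: with true cell-level conversion rate $t$,

$$P(\text{observed homozygous} \mid \text{amplified}) \;=\; t + (1-t)\,a ,$$

which is why single-cell LOH frequencies exceed WGA-free validation
material, and why the package insists on carrying dropout estimates next to
every LOH claim.

# Conversion tract inference

Flank variants carry parental diploid genotypes and an informativeness
class: **informative** (parents homozygous for different alleles — the
offspring is obligate heterozygous, so observed homozygosity proves allele
loss and names the lost parent), **semi-informative** (at least one parent
heterozygous — homozygosity is detectable but only sometimes attributable),
**uninformative** (parents identical homozygous).

Per cell, the LOH segment is the maximal run of homozygous calls containing
the target (offset 0). Variants that did not amplify are transparent — they
neither break nor extend the run, but are counted and reported; a `strict`
mode breaks the segment at missing data instead. A heterozygous target
means no segment.

Within the segment each homozygous variant is scored against the parents:
if the observed allele is absent from one parent's genotype, that parent's
contribution was lost — the site is **converted** and votes for the other
(template) parent. This covers all informative sites and the determinable
subset of semi-informative sites; homozygosity compatible with both parents
remains **ambiguous**. A unanimous vote assigns the template parent;
disagreement is reported as a conflict (under dropout-free data conflicts
cannot arise, so a conflict is itself evidence of an artifact).

Tract length is bounded, not estimated:

* `min_tract_bp` spans the outermost *converted* sites (plus the target),
  inclusive of both endpoints. Ambiguous homozygous sites never extend the
  minimum — they prove nothing, and including them would break the
  guarantee that the true tract contains the minimum span.
* `max_tract_bp` spans the innermost heterozygous variants flanking the
  segment, exclusive, falling back to the panel edge (outermost assayed
  variant, inclusive) on sides with no heterozygous flank.

With the printed example offsets — converted sites at −2623 and +2963,
heterozygous flanks at −3324 and +8000 — these conventions give
min = 2963 − (−2623) + 1 = 5587 bp and max = 8000 − (−3324) − 1 = 11323 bp.

These bounds are *identifiable only inside the assayed window*: a tract
escaping the outermost variant on one side is right-censored by the panel
edge and its true length can exceed `max_tract_bp`. The recovery tests
therefore draw tract extents capped at 2.6 kb on a designed panel whose
innermost edge is at −2623 bp (`flank_panel_design()`: four informative
variants at −2623, −2551, −2069, +2963 and 23 semi-informative variants
scattered over −3324…+16185), which guarantees the bracketing property
`min ≤ true length ≤ max` deterministically; on fully random panels the
property holds whenever the tract stays inside the window.

# The synthetic-data generator

`sim_config()` collects the generative model; `simulate_trio_haplotypes()`,
`simulate_embryo_cohort()`, `simulate_wga_evidence()` and
`simulate_pooled_evidence()` produce phased parental context, per-cell
ground truth (`sim_truth`), and allele-depth evidence.

**Repair model.** Each target allele independently draws one of
intact / indel / large deletion / HDR / conversion. With probability
`p_zygote_edit` (default 0.125, the observed uniform-embryo fraction after
M-phase injection) the pair of outcomes resolves in the zygote and all
cells inherit it; otherwise two lineage branches at the 2-cell stage draw
independently — the minimal model that produces mosaic 4–8-cell embryos,
chosen because branching rates beyond "repair is delayed past the first
cleavage" are not identifiable from the published counts. A conversion
copies the homologous allele's resolved state plus a tract of flanking
alleles; tract extents left and right of the cut are drawn independently
(exponential, mean 4 kb, capped at 20 kb by default), so tracts always
cover the cut site but are asymmetric. If both alleles draw conversion, one
(random) acts as the intact template. NHEJ indel keys carry a realisation
tag (deletion start shift or inserted bases) so independently arising
indels of equal size remain distinct alleles — only conversion produces
truly identical allele pairs, apart from the small, real probability of
coincidentally identical NHEJ events.

**Outcome probabilities.** Defaults (intact 0.15, indel 0.55, large
deletion 0.05, HDR 0.05, conversion 0.20) are a plausible biallelic-editing
mix consistent with the observed category spread (deletions ~13%, HDR ~6%,
substantial homo-indel fraction); scenario presets override them per locus
design (`load_preset()`), e.g. HDR 0 where no ssODN incorporation was
observed, and allele-specific cleavage for the monoallelic design, where
only `Mut` alleles are cleavable and each embryo draws the sperm allele.

**WGA model.** Per locus, a blanket failure with probability
`f_locus_fail`; otherwise each of the two template copies fails
independently with probability `q_copy_fail`, and each surviving copy draws
a negative-binomial read depth (mean `depth_mean/2 = 71.5`, size
`depth_dispersion = 10`). Loci where nothing survives are emitted as a
depth-0 row — indistinguishable from blanket failure, as in real data. The
dropout and failure events are attached as attributes for recovery tests.
Defaults are calibrated analytically from the study conditions: mean panel
coverage 143×; `q = 0.1534` so that $2q/(1+q) = 26.6\%$ (the blastomere
ADO average; the fibroblast preset uses `q = 0.2285` for 37.2%); and
`f` such that $(1-f)(1-q^2) = 84.8\%$ of panel loci amplify. The
dispersion of 10 reflects typical amplicon overdispersion while keeping
threshold-related false homozygosity (~7 × 10⁻⁵ per locus) far below the
±0.01 tolerance of the closed-form recovery tests.

**What is deliberately not modelled:** raw reads and sequencing error, MDA
chimeras, per-locus dropout heterogeneity (a single scalar `q` per cell
type — which is why the simulated locus-wise ADO spread is narrower than
real panels show), cell-cycle DNA content differences (the G1-fibroblast
effect enters only through the preset's higher `q`), and >2-branch
mosaicism. Passing tests therefore demonstrate correctness of the
estimators and inference rules under the stated generative model, not
robustness to every artifact of real WGA data.

**Reproducibility.** Each simulation stage seeds its own RNG stream from
`config$seed` plus a fixed stage offset (haplotypes +0, cohort +1,
evidence +2, panel +3, reference window +4, panel design +6), with draw
order per embryo, then per cell, then per locus. One evidence call consumes
one stream: pass the whole cohort at once for reproducible per-cell draws.

# Statistics

`fisher_exact_one_tailed()` computes the exact hypergeometric tail by
log-binomial accumulation (log-sum-exp), tested against a full-enumeration
factorial oracle for every 2×2 table with total ≤ 24 and against
`stats::fisher.test()`. Degenerate margins return p = 1 with a flag. LOH
comparisons between cohorts state their direction explicitly, and which
labels count as LOH is a parameter (`homo-Indel` alone for a biallelic
design validated in WGA-free cell lines; `homo-WT` where LOH means loss of
the mutant allele) because the operationalisation genuinely differs per
locus design.

# Problem sizes used in the checks

The shipped tests and the acceptance script run entirely from simulation:
40,000 locus draws per dropout-recovery point, 10,000 cells for the
homozygosity decomposition, 1,000 dropout-free conversions for tract
bracketing/template recovery, the exhaustive Fisher sweep over all tables
with total ≤ 24, and the 608-locus panel with 18 + 33 single cells for the
cohort design. Preset fixture cohorts are scaled to ≤ 16 embryos (~100
cells), so cohort-level expectations are checked as distributions, not
exact counts.

# A worked run

```{r worked}
preset <- load_preset("mybpc3_biallelic")
cfg <- preset$config
hp <- simulate_trio_haplotypes(cfg, preset$n_flank_variants)
truth <- simulate_embryo_cohort(cfg, hp)
evidence <- simulate_wga_evidence(truth, hp, cfg)

calls <- call_genotypes(evidence)
cells <- classify_cells(filter(calls, locus_id == "target"))
tab <- tabulate_genotype_frequencies(filter(cells, !is.na(label)),
                                     "simulated blastomeres")
tab
homozygosity_fraction(tab)

labelled <- inner_join(cells, truth[, c("cell_id", "embryo_id")],
                       by = "cell_id")
classify_embryo_mosaicism(labelled) |> count(classification)
```

# Known limitations

* Tract bounds are censored by the flank panel; lengths near or beyond the
  outermost variants are lower bounds only.
* The generator's scalar dropout rate cannot reproduce locus-to-locus ADO
  heterogeneity; locus-scope summaries from simulation are narrower than
  real panels.
* Sequence-level classification assumes alleles aligned to the target
  window and recognises markers through substitution patterns; complex
  events (indel + markers, ≥ 100 bp insertions) are reported as errors for
  manual review rather than forced into a category.
* A sperm-only phasing mode (no maternal genotypes) is not implemented;
  variants lacking a parental genotype are treated as undetermined.
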