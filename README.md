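# capblood

Cell-type-resolved diurnal and subject-specific gene expression analysis
for repeated-measures single-cell RNA-seq of capillary blood.

## What problem this solves

Capillary sampling makes it cheap to profile the same people's immune
cells by scRNA-seq morning and afternoon over several days (4 subjects ×
3 days × AM/PM in the design this package targets). Three questions then
need careful statistics:

* **Which genes are diurnal, and in which immune cell type?** A gene can
  oscillate in NK or B cells alone and be invisible when all cells are
  pooled.
* **Which "population-level diurnal" genes are composition artifacts?**
  If B-cell abundance rises in the afternoon, every B-dominant gene looks
  diurnal in the pooled analysis without any per-cell expression change.
* **Which genes are stably different between individuals, per cell
  type?**

`capblood` implements the full path from a raw droplet barcode matrix to
those answers: debris removal via cluster-wise barcode dropoff traces,
two-stage gene filtering, per-cell fraction normalization, marker-based
cell typing on a pluggable embedding, a pseudobulk tensor, the AM/PM and
ANOVA tests with joint BH correction, abundance-shift disambiguation, and
weighted pathway enrichment. A synthetic-data generator with a planted
ground-truth registry validates every stage end to end.

## The statistics in brief

All tests run on the pseudobulk mean expression fraction
μ<sub>g,s,c,k</sub> of gene *g*, subject *s*, cell type *c*, session *k*
(groups under 3 cells are masked). Before the diurnal test each subject's
series is centered by the equally weighted mean of its AM and PM session
means,

> μ′ = μ − (mean<sub>AM</sub>μ + mean<sub>PM</sub>μ) / 2,

which removes subject baselines while weighting the two session classes
equally. Centered values are pooled across subjects and AM vs PM compared
with a two-tailed pooled-variance t-test per (gene, cell type),
BH-corrected jointly across the whole grid, with a signed normal-quantile
Z for display. The identical procedure on all cells pooled into one type
gives the population-level calls; cross-classifying the two yields
`celltype_specific` genes (missed by pooled analysis) and
`population_only_abundance_suspect` genes (candidate composition
artifacts), and a one-sided t-test on per-sample cell-type fractions
verifies abundance shifts directly. Subject and cell-type specificity use
one-way ANOVAs on the same tensor (log₂ F as the plotting magnitude), and
pathway enrichment uses a two-proportion z-test on 1/(pathway
multiplicity)-weighted gene counts for the top-250-per-axis gene set
against the background.

See `vignettes/capblood-methods.Rmd` for the full model, conventions, and
validation design.

## Worked example

Simulate a small study (300 genes, 40 cells per subject-session, planted
diurnal and subject effects, debris droplets) and run the whole pipeline:

```r
library(capblood)

cfg <- run_config(
  simulate = sim_config(n_genes = 300, cells_per_sample = 40,
                        n_diurnal_global = 4, n_diurnal_celltype = 4,
                        n_subject_specific = 4,
                        debris = debris_spec(n_debris_barcodes = 60),
                        seed = 17),
  output_dir = "run17",
  gmt = system.file("extdata", "toy_pathways.gmt", package = "capblood"),
  gmt_categories = system.file("extdata", "toy_pathway_categories.tsv",
                               package = "capblood"),
  top_n = 30, seed = 17)
summary <- run_pipeline(cfg)
```

The stage log prints, among others:

```
[debris] threshold=100 k=7 kept=960
[celltype] k=13 types=6
[diurnal] significant_celltype=38 significant_population=6
          classes=both:5,celltype_specific:17,none:269,population_only_abundance_suspect:1
```

All 960 simulated cells survive debris removal (the 360 debris barcodes
do not), all six PBMC types are found at k = 13, and the per-type diurnal
test recovers the planted genes. The top of `run17/diurnal_celltype.tsv`:

```
   gene       cell_type     t    z        p        q
 G00133     CD8 T cells 12.19 6.65 2.94e-11 5.15e-08
 G00090     CD8 T cells 10.74 6.29 3.24e-10 2.84e-07
 G00267     CD4 T cells 10.49 6.22 5.04e-10 2.94e-07
```

`t`/`p` are the pooled-variance AM-vs-PM test on centered pseudobulk
means, `z` the signed display statistic, `q` the grid-wide BH value; all
three genes shown are planted global diurnal genes. Of the 22 per-gene
diurnal calls, 17 are `celltype_specific` — detectable only inside a cell
type — and one gene is flagged `population_only_abundance_suspect`, the
composition-artifact class. `run17/abundance_shift.tsv` holds the
per-type one-sided shift test; with no planted shift at this seed, B
cells sit at p = 0.5 (identical AM/PM fractions) while NK cells drift to
p = 0.012 — a reminder that at 40 cells per sample one type in six can
drift past nominal 0.05 by chance. (At this toy scale the subject ANOVA
recovers 1 of 4 planted subject genes; the validation scenarios below use
400 cells per sample, where recovery is ≥ 80%.)

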