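# zipquant

Quantitative analysis of RNA "zipcode" elements and peripheral RNA
localization in migrating cells.

Many mRNAs — RAB13 prominently among them — are transported to cell
protrusions by cis-acting 3′UTR elements. In protrusion-localized,
APC-dependent transcripts these elements are GA-rich: short degenerate
`RGAAGRR` motifs (R = purine) embedded in longer stretches whose G+A content
exceeds 75% over at least 30 consecutive nucleotides. zipquant implements
the quantitative toolchain used to characterize such elements and their
functional consequences:

- **Sequence analysis** — degenerate IUPAC motif scanning (all overlapping
  occurrences), sliding-window %GA profiles (default 30-nt window), GA-rich
  region calling (GA fraction strictly > 0.75 sustained ≥ 30 nt),
  motif-in-region overlap summaries, two-group motif enrichment by Fisher's
  exact test with Bonferroni correction, deletion-construct arithmetic with
  coordinate remapping, and classification of 25-nt antisense probe
  intervals.
- **Spatial statistics on cell images** — per-cell Peripheral Distribution
  Index (PDI) from smFISH spot coordinates and cell/nucleus masks
  (PDI ≈ 1 diffuse, > 1 peripheral, < 1 perinuclear),
  peripheral/perinuclear intensity ratios, and proximity ligation assay
  (PLA) dot calling (strictly > 3 robust SDs above background) with
  peripheral/cell-body assignment.
- **Fractionation ratios** — protrusion/cell-body (Ps/CB) enrichment
  normalized to the geometric mean of a housekeeping set, and
  spike-normalized RIP enrichment of a target transcript over a reference
  gene, both reported as mean ± s.e.m. across replicates.
- **Synthetic data with ground truth** — generators for labeled UTR sets
  with planted motifs/regions, disk-cell geometries, radially biased spot
  patterns (weight ∝ (d/d_max)^β), PLA images with planted dots, and count
  matrices with known enrichment ratios, so every analysis stage is
  testable end to end.

## Core statistics

For spots *i* at distances *d<sub>i</sub>* from the nucleus centroid and
cell-mask pixels *p* at distances *d<sub>p</sub>*:

```
PDI = mean_i(d_i^2) / mean_p(d_p^2)
```

For a gene *g* with housekeeping set *H* in paired Ps/CB samples:

```
r_g = (Ps_g / geomean(Ps_H)) / (CB_g / geomean(CB_H))
```

For spike-corrected RIP with target *t*, reference *r* and spike *s*:

```
E_x = (eluate_x / eluate_s) / (input_x / input_s),   enrichment = E_t / E_r
```

## Worked example

```r
library(zipquant)

# two synthetic UTR groups; ~60% of the localized group carries the motif
sim  <- gen_utr_set(utr_sim_params(n_per_group = 30, seed = 42))
summ <- summarize_groups(sim$records)
summ$group_fraction
#>   control localized
#> 0.3333333 0.7333333

enr <- motif_enrichment(summ$per_utr$has_motif[summ$per_utr$group == "localized"],
                        summ$per_utr$has_motif[summ$per_utr$group == "control"])
#> Fisher p = 0.00403, odds ratio = 5.33

# PDI recovers the planted radial bias
cell <- gen_cell(cell_sim_params(cell_radius = 100, nucleus_radius = 30))
for (b in c(-2, 0, 4)) {
  s <- gen_spots(cell, spot_sim_params(n_spots = 500, bias_exponent = b, seed = 1))
  cat(sprintf("beta = %+d  PDI = %.3f\n", b, compute_pdi(cell, s)$pdi))
}
#> beta = -2  PDI = 0.168   (perinuclear)
#> beta = +0  PDI = 1.049   (diffuse)
#> beta = +4  PDI = 1.498   (peripheral)

# PLA dots: called at > 3 SD over robust background, assigned to compartments
pla  <- gen_pla_image(cell, pla_sim_params(n_dots = 20, dot_region_split = 0.7, seed = 2))
dots <- call_pla_dots(pla$image, cell)
unlist(classify_dots(cell, dots))
#>      n_total n_peripheral       n_body   n_excluded
#>           20           14            6            0

# fractionation ratios close the loop on planted truth (3 Poisson replicates)
fr <- gen_fraction_counts(fraction_sim_params(c(RAB13 = 3, NET1 = 2, CTRL = 1),
                                              n_replicates = 3, seed = 3))
ps_cb_enrichment(fr$counts)
#>    gene mean_ratio    sem n
#> 1 RAB13      3.034 0.1123 3
#> 2  NET1      2.043 0.0581 3
#> 3  CTRL      1.006 0.0210 3
#> ...
```

A configuration-driven end-to-end run (simulation → scanning → PDI → PLA →
fractions, with a checksummed manifest) is available as
`run_pipeline(config, outdir, seed)`, or from a shell via the thin wrapper
`inst/cli/zipquant.R run --config cfg.yaml --seed 1 --outdir out/`.

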