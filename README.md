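# erosionkit

Genomic-erosion analysis for collapsed, inbred populations, validated
end-to-end on simulated data with known truth.

## What it does, and for whom

Conservation and population genomicists who resequence an endangered
species alongside a stable relative keep re-deriving the same battery of
statistics: a post-calling variant filter cascade, windowed nucleotide
diversity and per-individual heterozygosity by genomic region, site
frequency spectra and Tajima's *D*, zero-fold/four-fold degenerate-site
classification, runs of homozygosity and F<sub>ROH</sub>, linkage-disequilibrium
decay and its half-maximum distance, and outgroup-polarized genetic-load
accounting over synonymous / tolerated / deleterious / loss-of-function
variant classes. erosionkit packages every one of those stages as a
tested R function, plus a forward Wright–Fisher simulator (selection,
dominance, selfing, recombination, annotated genome) that generates
stable-versus-collapsed population pairs with full truth tables — so the
entire pipeline can be validated without any sequencing data.

## The statistics at its core

* Per-site diversity uses the unbiased estimator
  π̂ = d(n−d)/C(n,2) (the mean pairwise haplotype difference), summed in
  50 kb sliding windows / 10 kb steps.
* Tajima's *D* = (π − S/a₁) / √(e₁S + e₂S(S−1)) with the standard
  constants; unfolded SFS over derived-allele counts after polarizing
  against three outgroup samples that must share an identical homozygous
  state.
* Zero-fold / four-fold classification substitutes all four bases at
  every CDS position and translates: zero-fold when the four amino acids
  are pairwise distinct (strict rule; the conventional rule is a flag),
  four-fold when they are identical.
* F<sub>ROH</sub> = (sum of ROH > 100 kb) / genome effective length, ROH called
  by a sliding heterozygote-density window.
* LD decay: r² = D²/(p_A p_a p_B p_b) from haplotype frequencies, binned
  by distance; the half-max distance is interpolated where the binned
  mean first falls to half its maximum.
* Load: each heterozygote counts once, each homozygous-derived genotype
  twice; missense variants are deleterious only when three effect
  predictors agree (intersection rule); group contrasts use an exact
  Mann–Whitney U test.
* An exact Hardy–Weinberg test (conditional enumeration of heterozygote
  counts) backs the filter cascade at P < 0.001.

## Worked example

```r
library(erosionkit)
cfg <- default_run_config(seed = 1, outdir = "erosion_run")
res <- run_all(cfg)
res$comparison$summary
```

```
                metric    stable collapsed collapsed_vs_stable as_expected
1              mean_pi  6.44e-04  1.12e-04               lower        TRUE
2  mean_heterozygosity  6.16e-04  1.01e-04               lower        TRUE
3            tajimas_d -3.41e-01  4.91e-01              higher        TRUE
4            mean_froh  1.87e-02  5.76e-01              higher        TRUE
5       ld_half_max_bp  2.43e+04  6.03e+04              higher        TRUE
6 mean_hom_derived_lof  2.00e-01  3.33e-01              higher       FALSE
7          n_fixed_del  6.00e+00  3.00e+01              higher        TRUE
```

Reading the table: the simulated collapse (two-stage decline to a
six-tree remnant with kin mating) loses ~85% of nucleotide diversity and
heterozygosity, flips Tajima's *D* from slightly negative to clearly
positive, drives mean F<sub>ROH</sub> from 0.02 to 0.58, more than doubles the LD
half-max distance, and fixes five times as many deleterious-missense
alleles — every contrast in the direction genomic erosion predicts. The
one flagged row is the homozygous-LoF count, where inbreeding exposure
outweighs purging at this simulation scale; the methods vignette
(`vignettes/genomic-erosion.Rmd`) derives why, and the allele-level
purging signal (fewer derived LoF alleles per haplotype in the collapsed
population) is reproduced. Per-population tables (windows,
heterozygosity by region, F<sub>ROH</sub> per individual, LD curve, load by
category) and `report.json` land in `outdir`.

A command-line front-end for the same two entry points lives at
`inst/scripts/erosionkit.R` (`simulate`, `run`).

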