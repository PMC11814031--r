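# lcnm — locus coeruleus neuromelanin quantification and permutation inference

The locus coeruleus (LC), the brain's main noradrenergic nucleus, loses
neuromelanin-bearing neurons in parkinsonian disorders, and that loss is
visible as fading hyperintensity on neuromelanin-sensitive MRI.  `lcnm`
implements, as a reusable R pipeline, the measurement and inference
chain used to study sub-regional LC degeneration and its relation to
cognition and cortical glucose metabolism in multiple system atrophy
(MSA), Parkinson's disease (PD) and healthy controls (HC):

1. **LC quantification** — slice-to-slice intensity normalization,
   tri-section of a bilateral LC search ROI into rostral/middle/caudal
   thirds, extraction of the five brightest *connected* voxels per third
   and side (exact branch-and-bound maximizer of mean intensity), and
   the neuromelanin contrast ratio

   contrast = (mean LC ROI intensity − mean background ROI intensity) / mean background ROI intensity

   with left/right averaging per third.
2. **FDG-PET SUVR** — voxel-wise division by the median uptake of a
   reference region, then 8-mm FWHM separable Gaussian smoothing
   (reflect boundary, per-axis sigma in voxel units).
3. **Scalar inference** — ANCOVA-type permutation omnibus per subregion
   (group factor, age covariate) using Freedman–Lane residual
   permutation; six one-tailed post hoc contrasts with Bonferroni
   family-wise correction (`p_FWER = min(1, 6p)`); Brown–Forsythe Levene
   test; Spearman correlations with education-adjusted MoCA (exact
   permutation p for small n); Kruskal–Wallis / chi-square /
   Mann–Whitney descriptives.
4. **Voxel-wise inference** — per-voxel regression t maps,
   cluster-forming thresholds (p < 0.001 primary, p < 0.01 exploratory),
   and cluster-extent family-wise error correction from the permutation
   null of the maximum cluster extent.
5. **Synthetic phantoms** — a seeded generator that renders cohorts of
   pontine-slab volumes with bright LC "tubes" of known sub-regional
   contrast, per-slice intensity drift, noise, covariate tables, and PET
   volumes with a planted cognition-linked cortical cluster, so the
   whole chain is testable end to end with known ground truth.

The package is aimed at neuroimaging methodologists who want a fully
inspectable, permutation-based re-implementation of this analysis style
that runs anywhere R runs, without MATLAB/SPM/FSL.

## Worked example

```r
library(lcnm)

cfg <- phantom_config(seed = 7)      # study-sized cohort: 18 HC, 11 MSA, 18 PD
cohort <- generate_cohort(cfg)
cohort
#> Phantom cohort: 47 subjects ( HC=18, MSA=11, PD=18 )
#>   grid 32x32x16 voxels @ 0.5x0.5x2.5 mm
#>   PET volumes: 11 (group MSA )

quantify_subject(cohort$nm[["S001"]], cohort$rois)
#> LC neuromelanin contrast (left/right averaged):
#> rostral  middle  caudal
#>  0.3473  0.2059  0.1638
#> background mean: 100.1505
```

The three numbers are this (healthy-control) subject's rostral, middle
and caudal neuromelanin contrast ratios — intensity of the five
brightest connected LC voxels relative to the pontine background, about
0.2–0.35 here, recovered from a volume carrying 2% noise and ±10%
per-slice gain drift.

```r
q <- quantify_cohort(cohort)
dat <- merge(cohort$subjects, q$wide, by = "subject_id")
dat$moca_adj <- adjust_moca(dat$moca_raw, dat$education_years)

permutation_ancova(dat$middle, dat$group, covariates = dat$age,
                   n_perm = 10000, seed = 7)
#> group omnibus (ANCOVA-type): F = 10.0484, permutation p = 0.0005999 (Monte-Carlo, 10000 permutations)

posthoc_pairwise(dat$middle, dat$group, covariates = dat$age,
                 n_perm = 10000, seed = 7)
#> One-tailed post hoc contrasts (FWER by Bonferroni x 6 ):
#>   contrast       t df      p p_fwer n_perm exhaustive
#> 1   HC>MSA  3.8016 43 0.0005 0.0030  10000      FALSE
#> 2   HC<MSA -3.8016 43 0.9996 1.0000  10000      FALSE
#> 3    HC>PD  3.8244 43 0.0003 0.0018  10000      FALSE
#> 4    HC<PD -3.8244 43 0.9998 1.0000  10000      FALSE
#> 5   MSA>PD -0.4906 43 0.6846 1.0000  10000      FALSE
#> 6   MSA<PD  0.4906 43 0.3155 1.0000  10000      FALSE
```

The phantom plants a 30% middle-LC contrast reduction in MSA and a 15%
reduction in PD; both one-tailed contrasts against controls survive the
six-fold family-wise correction (t(43) values with their permutation
p), while the MSA-vs-PD contrasts do not.  The cognition link planted in
the generator is recovered the same way:

```r
msa <- dat[dat$group == "MSA", ]
sp <- spearman_corr(msa$rostral, msa$moca_adj)
#> MSA rostral vs MoCA: rho = 0.821, p = 0.002 (t approximation)
```

For file-based workflows, `run_simulation()` writes a cohort as
NIfTI/TSV/YAML with an MD5 manifest, `validate_inputs()` checks a
directory, and `run_analysis()` produces contrast tables, a results
JSON, cluster tables and a plain-text report.  The same operations are
available from a shell via the thin front-end:

```sh
lcnm simulate --out cohort/ --seed 7
lcnm analyze  --in cohort/ --out report/ --seed 7 --n-perm 10000
lcnm all      --out run/   --seed 7        # simulate + validate + analyze
```

(after installation: `$(Rscript -e 'cat(system.file("exec/lcnm", package="lcnm"))')`,
or run `exec/lcnm` from the source tree.)

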