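---
title: "Lesion network mapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion network mapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Lesion network mapping treats a focal lesion not as a point of damage but
as a node of a distributed brain network, and reads that network off a
*normative connectome*: a large resting-state fMRI cohort of healthy
individuals, held fixed across analyses. The premise is that lesions in
different places that share a clinical phenotype may share a network, and
that the network — not the coordinates — carries the outcome signal.

For one lesion mask $L$ and one cohort subject $s$ with voxel time series
$Y_s(v, t)$:

1. the seed course is the unweighted mean
   $\bar{y}_s(t) = \frac{1}{|L|}\sum_{v \in L} Y_s(v, t)$;
2. the subject's $r$-map is the Pearson correlation of $\bar{y}_s$ with
   every brain-mask voxel's series;
3. $r$ is variance-stabilized by the Fisher transform $z = \mathrm{atanh}(r)$;
4. across the $n$ subjects, each voxel gets the one-sample statistic
   $t = \bar{z}\sqrt{n}/\mathrm{sd}(z)$ (sample SD, $n-1$);
5. the t-map is thresholded at $t \ge 5.1$ and binarized.

The binarized maps are summed within each outcome group ($V_P$, $V_C$ out
of $N_P$, $N_C$ lesions connected at a voxel), and contrasted with the
voxelwise odds ratio

$$\mathrm{VOR} = \frac{V_P\,(N_C - V_C)}{V_C\,(N_P - V_P)},$$

the odds ratio of the implicit 2×2 connected-by-group table; the opposite
direction swaps the group roles, so wherever all four cells are nonzero the
two directions are exact reciprocals. Binary "at least twice as likely"
maps keep voxels with $\mathrm{VOR} \ge 2$, and region tables summarize
mean/SD/max VOR over any labelled parcellation.

## Assumptions

* **One grid.** Masks, cohort, and atlases must share shape and affine
  (tolerance $10^{-4}$ mm elementwise). The package never resamples —
  spatial normalization is an upstream registration problem — and refuses
  mismatched grids instead.
* **Analysis-ready cohort.** No temporal preprocessing (filtering,
  nuisance regression, scrubbing) is applied; the cohort is taken as given.
* **Binary, nonempty seeds.** Masks are binarized at > 0.5 on read to shed
  interpolation dust from upstream nearest-neighbour registration; an
  empty mask (or an empty intersection with the brain mask) is an error,
  never a silent zero map.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `t_threshold` | 5.1 | t units | Bonferroni-corrected whole-brain level at family-wise $\alpha = 0.05$ for a ~1000-subject cohort: the two-tailed critical t at df = 998 over $10^5$–$2.3\times10^5$ brain voxels lies in [5.0, 5.3] (a property test asserts this band). Stored in config, never hard-coded. |
| `tail` | `two_sided` | — | The sign convention for "thresholded at t" is not standardly stated; two-sided is the conservative default, one-tailed positive is available. |
| `r_to_t_mode` | `group_ttest` | — | See design choices below. |
| `zero_cell_policy` | `exclude` | — | See design choices below. |
| `vor_cutoff` | 2.0 | odds ratio | "At least twice as likely", inclusive ($\ge$) to honour the wording. |
| `mask_threshold` | 0.5 | intensity | Binarization cut for masks on read. |
| `n_perm` | 999 | permutations | Dice group test resolution; p uses the add-one estimator so it is never 0. |

## What the synthetic generator emulates — and what it does not

`simulate_cohort` draws, per subject $s$ and network $k$, an independent
standard normal latent course $c_{k,s}(t)$ and sets

$$Y_s(v,t) = \sum_k a_k\, S_k(v)\, c_{k,s}(t) + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma^2),$$

with spherical supports $S_k$ shared across subjects. This is the simplest
model with a recoverable ground truth and a closed-form oracle: two voxels
sharing exactly one network have population correlation
$a^2/(a^2+\sigma^2)$, so loading 1 and noise SD 1 give exactly 0.5 (tested
to ±0.05 over 100 subjects). The bundled world — 20³ grid, 2 mm voxels, 50
subjects, 60 timepoints, loading 1, noise SD 0.5 — puts within-network
correlation at 0.8, which the t = 5.1 threshold recovers essentially
perfectly (Jaccard ≥ 0.9 planted-recovery criterion; in practice 1.0).

What it does **not** emulate: hemodynamics, autocorrelated noise, motion,
scanner drift, heteroscedastic noise, subject-specific network topography,
or anticorrelated networks. A green planted-recovery test therefore
establishes that the pipeline's algebra and thresholding chain are correct,
not that the statistical behaviour on real rs-fMRI (with its far lower SNR
and spatial autocorrelation) is characterized.

## Numerical choices

* **Validity sentinel.** Undefined voxels carry `NA` (written to NIfTI as
  IEEE NaN) and are excluded from every statistic — never stored as 0,
  which would silently deflate atlas means.
* **Fisher clip.** $|r| = 1$ is clipped to $1 - 10^{-7}$ before `atanh` so
  z stays finite while ordering is preserved.
* **Degenerate t voxels.** Where the across-subject sd of z is 0: mean 0 is
  a clean null (t = 0); mean ≠ 0 is unbounded and the voxel is flagged
  invalid (count recorded in the map's provenance) rather than set to ±∞,
  keeping downstream sums finite and auditable. A corollary found while
  testing: a literally noise-free cohort drives *every* within-support
  voxel into this path (all subjects' clipped z coincide), so the
  "noise → 0" limit is exercised at noise SD 0.05, below which the clip
  dominates.
* **Inclusive comparisons** at both the t threshold and the VOR cutoff.
* **Sample SD ($n-1$)** everywhere an SD is reported; a single pair/voxel
  reports SD 0 rather than NA, an undefined *region* reports NA and a
  voxel count of 0.
* **Dice of two empty volumes is an error**, not 0 or 1: empty seeds
  indicate an upstream fault.

## Design choices where the design was open

* **r→t construction.** "Converted to t-maps" admits two readings. Default:
  the one-sample t-test across subjects of Fisher-z values — with a
  ~1000-subject cohort this is the only construction under which a
  whole-brain Bonferroni threshold near t = 5.1 is meaningful (df ≈ 998).
  The per-map conversion $t = r\sqrt{df}/\sqrt{1-r^2}$ (df = timepoints −
  2, applied to the pooled z-mean) is available as `r_to_t_mode =
  "single_map"` but is not the default.
* **Zero-cell policy.** The VOR formula is undefined when $V_C = 0$ or
  $V_P = N_P$. Default `exclude` marks such voxels invalid: exclusion never
  fabricates odds, and published finite maxima are consistent with
  degenerate voxels being dropped. The Haldane–Anscombe +0.5 correction is
  provided as `haldane`. The bundled fixture's config selects `haldane`
  deliberately: its discriminative network is occupied by one group only,
  so every support voxel is a pure zero-cell and the `exclude` policy would
  mark the entire planted contrast invalid by construction — a degenerate
  world for exercising the contrast, not a flaw in the default.
* **Group Dice test.** Pairwise Dice values within a group are not
  independent (each mask enters many pairs), which invalidates a naive
  two-sample t-test; the implemented test permutes outcome labels over
  masks and recomputes the absolute difference of within-group mean
  pairwise Dice. Within-group pairs only; cross-group pairs are not mixed
  in.
* **Regional support.** Whether voxels with no thresholded connectivity in
  either group should contribute zeros to regional means is unspecified;
  default `valid_only` computes over defined voxels (structural zeros would
  deflate means toward 0), and every table row carries both the region and
  the valid voxel counts so the support is always visible.
* **Seeds and determinism.** One master seed; per-subject simulation
  streams are derived from it, the Dice permutation stream from the config
  seed. Identical config + seed reproduces bit-identical arrays and
  checksum-identical output files (gzip output carries no timestamps).

## Known limitations

* NIfTI-1 single-file volumes only (3-D/4-D, common datatypes, sform/qform);
  no NIfTI-2, no .hdr/.img pairs, no extensions.
* The whole cohort is held in memory; a 1000-subject full-resolution cohort
  would need a streaming subject loop (the per-lesion algebra already
  touches one subject at a time, so this is an I/O refactor, not a
  methods change).
* No confidence intervals or significance tests on voxelwise odds ratios;
  none are defined for the published approach.
* Surface-based analysis, probabilistic overlap metrics, and figure
  rendering are out of scope.
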