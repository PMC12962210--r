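# rsnr — tissue-independent relative SNR for parallel MRI

Comparing the SNR delivered by two MRI receive setups — say, a flexible
surface array with the patient supine versus a rigid breast coil with the
patient prone — is confounded by the object itself: breast MR signal varies
strongly between fibroglandular tissue and fat, and repositioning deforms
the tissue, so voxelwise SNR maps are not directly comparable. The
**relative SNR**

```
rSNR(r) = SNR_ext(r) / SNR_ref(r)
```

divides the SNR map of the coil under study by that of a fixed reference —
the scanner's transmit/receive body coil, acquired with the object in the
same position — so the object magnetization cancels voxelwise. What remains
is a tissue-independent map of relative coil noise performance that can be
compared across positions distributionally.

The package implements the full analysis as a tested simulation pipeline:

* **Synthetic inputs** — 3D Shepp-Logan phantoms with exchangeable contrast
  profiles, labeled digital breast subjects (breast / chest wall / axilla)
  in prone-like and supine-like geometries, loop-element coil models
  (conformal surface arrays, lateral paddle bars, uniform body coil), and
  multichannel Cartesian k-space with correlated complex Gaussian noise and
  a 2048-sample prescan noise block.
* **SENSE SNR/g-factor maps** — sensitivity estimation from windowed central
  k-space (24×24×12, Tukey), noise covariance from the prescan block, and
  (optionally retrospectively subsampled, e.g. 2× S/I × 4× R/L) SENSE
  reconstruction with analytic per-voxel noise propagation:
  `v = (S^H Ψ⁻¹ S)⁻¹ S^H Ψ⁻¹ a`, `g = sqrt(diag((S^H Ψ⁻¹S)⁻¹)·diag(S^H Ψ⁻¹S))`.
* **rSNR core** — rSNR maps with a reference-SNR validity floor, symmetric
  percent-difference maps between two rSNR maps, and histogram FWHM.
* **Region statistics** — five-number percentile summaries, the two-tailed
  bootstrapped percentile-difference test (p < 0.01), slicewise disk
  erosion robustness, breast-volume estimation and supine:prone
  median-ratio trend fits.
* **Distance-from-coil analysis** — exact nearest-element distance maps and
  median-rSNR-versus-distance profiles in 2 mm bins.

## Worked example

The two-contrast phantom experiment checks tissue independence end to end:
one geometry, two contrasts, two coils, four noisy acquisitions; if rSNR is
really tissue-independent, the two contrasts' rSNR maps agree up to noise,
and the width of their percent-difference histogram is pure noise
propagation.

```r
library(rsnr)

cfg <- tissue_independence_config()   # 64^3 phantom, 20-ch array, calibrated noise
ds  <- tissue_independence_dataset(cfg, seed = 1)
maps <- phantom_rsnr_maps(ds, cfg)
maps$rsnr_a
#> <rsnr_volume> 64x64x64, 30% valid, median rSNR 1.66
pd <- percent_difference_map(maps$rsnr_a, maps$rsnr_b)
median(pd$percent_diff[pd$valid_mask])
#> [1] 0.049
histogram_fwhm(pd)
#> [1] 13.2
```

The median rSNR of ~1.7 says the 20-channel array beats the body-coil
reference 1.7-fold at the median phantom voxel; the percent-difference
distribution is
centered at zero (no residual contrast) and its FWHM of ~13 is the noise
floor of the voxelwise metric at baseline noise. The three-condition
experiment (baseline, both noise variances ÷10, external variance only ÷10)
runs as:

```r
run_phantom_experiment(cfg, seed = 1, n_seeds = 5)
#> <phantom_experiment_report> percent-difference FWHM
#>   baseline        12.81 (sd 0.33 over 5 seeds)
#>   both_tenth      4.15 (sd 0.03 over 5 seeds)
#>   external_tenth  10.94 (sd 0.15 over 5 seeds)
```

The prone-versus-supine comparison on digital subjects
(`run_position_comparison(position_comparison_config(), seed = 1)`) runs
the same reconstruction machinery on both positions, tests 3 regions × 5
percentiles per acceleration with a seeded bootstrap, and emits tidy
CSV/JSON reports (`write_report()`).

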