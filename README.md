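# mttex

Quantitative texture analysis of plant cortical microtubule micrographs.

The arrangement of the cortical microtubule array — aligned transverse
bundles versus a disordered mesh — tracks the physiological state of a plant
cell, but is usually described qualitatively. `mttex` provides an objective
pipeline for single-channel fluorescence images (TIFF/PNG), aimed at plant
cell biologists and image analysts:

1. **Enhancement** — Bidimensional Empirical Mode Decomposition (BEMD):
   iterative sifting against upper/lower extrema envelope surfaces splits the
   image `x(m,n)` into intrinsic mode functions plus a residue,

   `x(m,n) = Σ_{l=1..L} c_l(m,n) + r_L(m,n)`,

   with `c_1` carrying the finest spatial detail.
2. **Selection** — the decomposition product with the highest grey-level
   co-occurrence (GLCM) *contrast* (direction-averaged) is taken as the
   enhanced image.
3. **Texture features** — from the normalized co-occurrence matrix `P(i,j)`
   at distance `d = 4` in four directions (0°, 45°, 90°, 135°):
   angular second moment `ΣP²`, entropy `−ΣP log₂P`,
   inverse difference moment `ΣP/(1+(i−j)²)`, variance `Σ(i−μ)²P`,
   and contrast `Σ n² P(|i−j| = n)`.
4. **Group comparison** — Welch's two-sided t-test per feature (ASM, entropy,
   IDM, variance; direction-averaged per image) between two image groups,
   reported as mean ± SD with significance flags.

A deterministic synthetic generator of microtubule-like fiber images
("ordered" κ = 8 vs "disordered" κ = 0 von Mises orientations) makes the
whole pipeline testable without micrographs.

## Worked example

```r
library(mttex)

img <- generate_fiber_image(fiber_params(orientation_mode = "ordered", seed = 1))
dec <- bemd(img)
dec
#> BEMD decomposition: 4 IMF(s) + residue (256 x 256)
#>   sift iterations: 3, 2, 3, 6
#>   stop reason: max_imfs

select_enhanced_image(dec)$table
#>      label contrast
#> 1     IMF1 40.43718
#> 2     IMF2 47.33284
#> 3     IMF3 46.52609
#> 4     IMF4 21.93856
#> 5  residue 17.61713
#> 6 original 91.27322

analyze_image(img)
#> GLCM texture features (G = 64 , d = 4 )
#>  direction         asm  entropy       idm variance contrast
#>          0 0.005480538 8.425506 0.2941585 31.97255 18.00504
#>         45 0.004168564 8.885815 0.1915099 31.41791 56.72208
#>         90 0.004186122 8.873456 0.1854537 31.25531 55.35300
#>        135 0.004225445 8.872704 0.1787079 31.41249 59.25123
#> direction means:
#>       asm   entropy       idm  variance  contrast
#>  0.004515  8.764370  0.212458 31.514565 47.332838
```

Reading the output: the decomposition stopped at the configured four IMFs;
the contrast criterion picked IMF2 (with this noise level the finest band is
noise-dominated, so the fiber-scale mode is the sharpest *informative*
product). In the per-direction table the 0° row stands out — fibers aligned
near 0° make that direction smooth (low contrast 18 vs ≈ 57 elsewhere, higher
IDM) — exactly the anisotropy signature of an ordered array.

Comparing ordered vs disordered groups (five images each here; `analyze_image`
per image, then Welch tests on the direction-averaged features):

```r
ga <- lapply(1:5, function(s) analyze_image(generate_fiber_image(
  fiber_params(orientation_mode = "ordered", seed = s))))
gb <- lapply(1:5, function(s) analyze_image(generate_fiber_image(
  fiber_params(orientation_mode = "disordered", seed = 100 + s))))
compare_groups(ga, gb)
#> Welch t two-sided comparison, alpha = 0.05
#>   feature     mean_a       sd_a n_a     mean_b       sd_b n_b       t     df
#>       asm  0.0033988 0.00078234   5  0.0022638 0.00034038   5  2.9747 5.4619
#>   entropy  9.1276000 0.28960000   5  9.5874000 0.16747000   5 -3.0731 6.4061
#>       idm  0.1894100 0.01830700   5  0.1629100 0.01031400   5  2.8199 6.3068
#>  variance 41.0760000 8.33680000   5 51.5770000 5.60550000   5 -2.3372 7.0030
#>  p_value significant
#>  0.02780        TRUE
#>  0.02011        TRUE
#>  0.02877        TRUE
#>  0.05204       FALSE
```

(The printed table wraps; the last column block belongs to the same rows.)
Ordered arrays score higher ASM and IDM (more uniform, more homogeneous
texture) and lower entropy and variance than disordered meshes.

## Command line

A thin Rscript front end ships in `inst/cli/mttex`:

```sh
mttex simulate --mode ordered --n 10 --seed 1 --out ordered/
mttex decompose ordered/ordered_01.tif --out dec/        # IMF TIFFs + JSON sidecar
mttex features ordered/*.tif --out features.csv          # per-direction CSV
mttex compare --group-a ordered/ --group-b disordered/ --out report/
```

Grayscale output is written as 32-bit float TIFF, so signed IMF images
round-trip losslessly. A YAML `--config` file can set `levels`, `distance`,
`sd_threshold`, `max_imfs`, `alpha`; flags override it.

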