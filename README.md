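# vfecm — quantitative microanatomy of the vocal-fold extracellular matrix

`vfecm` is an R package for quantifying the layered fibrillar architecture
of the vocal-fold lamina propria (LP) from label-free optical imaging. It
is aimed at laryngology / biophotonics groups who image the LP with
second-harmonic generation (SHG) microscopy and optical coherence
tomography (OCT) and want reproducible, windowed, per-region numbers
instead of manual measurements.

Two analysis branches share one windowing convention (50 × 50 px windows,
5 px apart so windows never overlap):

**SHG branch — fiber orientation, anisotropy, texture, morphometrics.**
Each window is converted to 8-bit gray scale and its structure tensor is
formed from cubic-spline image gradients smoothed with a Gaussian kernel
(σ = 2 px):

    S_T = [ Kσ*g_x²   Kσ*g_xy ]
          [ Kσ*g_yx   Kσ*g_y² ]

The dominant fiber orientation is θ = ½·atan2(2·J_xy, J_yy − J_xx),
counterclockwise-positive, θ = 0 for fibers parallel to the epithelium
surface; the anisotropy is the eigenvalue coherence
A = (λ_max − λ_min)/(λ_max + λ_min) ∈ [0, 1] (1 = perfectly aligned,
0 = isotropic). Texture is summarized by gray-level co-occurrence (GLCM)
contrast, entropy and inverse difference moment, averaged over 1- and 2-px
offsets along 0/45/90/135°. Morphometric operations measure fenestration
(void) fraction by Otsu binarization, fiber diameter by perpendicular FWHM
profiling, and centerline waviness (spatial period λ and amplitude a).

**OCT branch — relative attenuation and layer segmentation.** Five
consecutive B-scan frames are averaged, normalized, the epithelium surface
is detected, and a depth profile is extracted along the 45° midline from
the vocal-fold edge. Under the single-scattering Beer–Lambert model
⟨I(z)⟩ ∝ I₀·exp(−2·μ_t·z), so an ordinary least-squares fit of ln I
against physical depth (optical path × cos 45° / n, with n = 1.384) gives
the relative attenuation coefficient μ_t = −slope/2 per layer. Layers are
found by exact least-squares changepoint segmentation of the log profile;
segment lengths give layer thicknesses.

Region-level statistics (one-way ANOVA, Tukey pairwise comparisons with
the P < 0.001 "extremely significant" convention, per-region mean ± SD
tables) complete the pipeline. Because tissue images of this kind are
rarely shareable, the package ships seeded phantom generators —
fibrillar SHG scenes and layered speckled B-scans — with attached ground
truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(vfecm)

## SHG branch: fibers at +30 deg with additive noise
spec <- fiber_phantom_spec(size_px = c(160, 160), theta_deg = 30,
                           n_fibers = 30, noise_sd = 20, seed = 3)
ph <- make_fiber_phantom(spec)
orient <- orient_windows(ph$image, window_px = 50, gap_px = 5, sigma_px = 2)
aggregate_region(orient, region = "SLP")
#>   region n_windows n_flagged mean_theta_deg sd_theta_deg mean_anisotropy sd_anisotropy
#> 1    SLP         9         0           29.9        0.524           0.637         0.106

head(texture_windows(ph$image, 50, 5), 3)
#>   origin_row origin_col contrast entropy   idm n_offsets_averaged  flag
#> 1          1          1   0.0167    3.94 0.754                  8 FALSE
#> 2          1         56   0.0280    3.72 0.737                  8 FALSE
#> 3          1        111   0.0221    3.94 0.748                  8 FALSE

## OCT branch: 3-layer speckled B-scan, 45-degree midline protocol
ospec <- oct_phantom_spec(size_px = c(600, 1000), surface_row = 30, seed = 7)
oc    <- make_oct_phantom(ospec)          # truth: mu_t = 0.31/0.54/0.15 mm^-1
b     <- normalize_bscan(average_frames(oc$frames, k = 5))
surf  <- detect_surface(b)
aline <- extract_midline(b, surf, edge_col = 250, angle_deg = 45,
                         pixel_pitch_z_um = 4.8, n_avg = 100)
seg   <- segment_layers(aline, n_layers = 3)
sapply(seg$fits, function(f) f$mu_t_per_mm)
#> [1] 0.276 0.540 0.149
seg$thickness_um_physical
#> [1] 299.2 828.9 851.0
```

The region mean orientation (29.9° vs the generating 30°) and the
recovered attenuation coefficients (0.28/0.54/0.15 vs the generating
0.31/0.54/0.15 mm⁻¹) and layer thicknesses (299/829 µm vs 293.3/837.6 µm;
the last layer extends to the bottom of the scan) show each branch
recovering its phantom's ground truth. `summarize_tables()` then collects
such per-window records into per-region mean ± SD tables, and
`anova_oneway()` / `tukey_pairwise()` test for differences between LP
regions.

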