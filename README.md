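# grainscan

Backlight image analysis for rice grain phenotyping in R.

Rice breeders score panicles by total grain count, **filled** grain
count and grain size. Under backlight (a light panel behind a glass
stage) a filled grain — one with a developed endosperm — is opaque and
casts a dark silhouette, while an unfilled grain transmits light
through its empty hull: a bright interior inside a darker outline.
grainscan turns one 8-bit grayscale backlight image into per-grain
phenotypes and per-panicle counts, non-destructively and without
X-rays. It is aimed at phenotyping platforms and breeding labs that
image grains on a flatbed or rotating-stage backlight rig.

## The method

The pipeline runs fixed stages:

1. **Line-scan restoration** (optional). A line-scan camera over a
   turntable records a distorted image; source coordinates $(u, v)$ map
   to planar coordinates through
   $\rho = e^{u\ln(w)/w}$, $\theta = 2\pi v/S$,
   $x = w + \rho\cos\theta$, $y = w + \rho\sin\theta$,
   resampled by the analytic inverse with bilinear interpolation.
2. **Preprocessing**: 5×5 median filter, fixed-threshold binarization
   (grains are the dark phase), morphological closing (fills glume-gap
   holes), small-object removal (debris).
3. **Marker-based watershed**: sure-foreground seeds from thresholding
   the Euclidean distance transform per component, flooding of the
   contested band over the inverted distance transform — splits
   touching grains.
4. **Classification**: each grain's grays are split by exact 1-D
   2-means (globally optimal contiguous split of the sorted values);
   the **dark ratio** $DR = N_d/N_t$ is the dark-cluster pixel
   fraction, and a grain is filled iff $DR$ strictly exceeds the
   threshold (default 0.6; reference class means are 0.87 filled, 0.25
   unfilled).
5. **Size measurement**: minimum-area enclosing rectangle (rotating
   calipers), sides × resolution (default 0.086 mm/px) giving length
   and width in mm.
6. **Evaluation**: $R^2$, RMSE and MAPE comparing predicted vs actual
   counts or sizes, plus a dark-ratio threshold sweep.

Because no public backlight rice dataset exists, the package ships a
synthetic scene generator with exact ground truth (ellipse grains with
controlled dark fractions, glume-gap holes, debris specks, touching
pairs, optional turntable distortion) used by the test suite and the
acceptance script. See the methods vignette
(`vignettes/grainscan-methods.Rmd`) for the model, parameter rationale
and limitations.

## Worked example

```r
library(grainscan)

# a synthetic panicle: 150 filled + 50 unfilled grains, fixed seed
sc  <- generate_scene(scene_params(n_filled = 150, n_unfilled = 50, seed = 7))
res <- analyze_image(sc$image)
res$summary
#> <panicle_summary> total 200 | filled 150 | unfilled 50 | filled fraction 0.750

head(res$phenotypes[, c("label", "dark_ratio", "filled", "length_mm", "width_mm")], 5)
#>   label dark_ratio filled length_mm width_mm
#> 1     1  0.7995514   TRUE 10.946026 3.035878
#> 2     2  0.8012163   TRUE  9.343757 2.597362
#> 3     3  0.7305834   TRUE  9.932018 2.518783
#> 4     4  0.8514816   TRUE  9.038187 2.846067
#> 5     5  0.2408081  FALSE  9.278470 2.480619
```

The detected counts equal the generator's ground truth (200 grains,
150 filled). Each row is one segmented grain: its dark ratio (fraction
of pixels in the darker of its two gray clusters), the filled call at
the 0.6 threshold, and its enclosing-rectangle length and width in
millimeters. Comparing 50 measured lengths against the manifest:

```r
idx <- sapply(1:50, function(i) which.min((sc$manifest$cx - res$phenotypes$centroid_x[i])^2 +
                                          (sc$manifest$cy - res$phenotypes$centroid_y[i])^2))
evaluate_predictions(res$phenotypes$length_mm[1:50], sc$manifest$length_mm[idx])
#> <evaluation_report> n = 50 | R^2 = 0.9897 | RMSE = 0.07438 | MAPE = 0.71%
```

`analyze_image(..., out_dir = "out")` writes the per-grain CSV, a
summary JSON with full provenance (effective configuration, package
version, input checksum) and, with `overlay = TRUE`, an annotated PNG
(filled grains outlined red, unfilled blue). `analyze_batch()`
processes many images and aggregates counts. A command-line front end
with `analyze` / `simulate` / `evaluate` / `sweep` subcommands lives at
`inst/cli/grainscan.R`.

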