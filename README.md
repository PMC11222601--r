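# dsacolor

Color-coded parametric imaging for digital subtraction angiography (DSA),
aimed at interventional radiologists and imaging scientists who need
active bleeding to stand out from a grayscale cine run.

A DSA sequence records an iodine bolus travelling through vessels,
typically at 6 frames per second. Reading extravasation — contrast that
leaks out of a vessel, arrives late and clears slowly — off such a run is
subjective. `dsacolor` condenses the run into per-pixel perfusion
parameters and renders them in pseudo-color, so that the temporal
signature of a bleed becomes a spatial color contrast.

## The model

Every vessel pixel's time-intensity curve is fitted with a bolus model

$$I(t) = a_0 + a_1\,\frac{e^{-a_2 t}}{1 + e^{-a_3 (t - t_0)}}$$

(baseline $a_0$; increment $a_1$; washout rate $a_2$; rise slope $a_3$;
transition time $t_0$). $t_0$ and $a_0$ come from a frame-difference
estimator, then $(a_1, a_2, a_3)$ are fitted by bounded nonlinear least
squares. Five parameter maps are derived per pixel — AUC (area under the
enhancement curve), TTP (time to peak), TOA (time of arrival at a 15%
enhancement threshold), transit time (15% rise to 15% fall) and inflow
rate (maximum $dI/dt$) — and colored through a lookup table. The clinical
arrival scale runs red (earliest) through yellow to blue (latest), which
places bleeds at the blue end next to red/yellow feeding vessels.

The package also ships a synthetic angiography phantom (tube + optional
extravasation blob, with ground-truth masks and arrival times) and a
paired Likert reader-score module with an exact/approximate Wilcoxon
signed-rank test.

## Worked example

```r
library(dsacolor)

# a 128x128, 60-frame phantom at 6 fps with a breakpoint leak
ph <- generate_phantom(phantom_spec(seed = 1))
ph
#> <phantom_truth> 128 x 128 px, 60 frames at 6 fps; 960 vessel px, 201 leak px

save_sequence(ph$sequence, "seq.tif")
seq <- load_sequence("seq.tif")        # TIFF stack / PNG dir / DICOM
seq
#> <dsa_sequence> 60 frames of 128 x 128 px at 6 fps (9.83 s)
#>   intensity range [-9.764, 101.6]

sm   <- gaussian_lowpass(seq, 1)                       # denoise
mask <- segment_vessels(sm, segment_config(sigma_px = 0))
mask
#> <vessel_mask> 128 x 128 px, 1066 in-mask pixels (6.51% coverage)

px  <- which(ph$vessel_mask, arr.ind = TRUE)[200, ]
fit <- fit_tic(sm$frames[, px[1], px[2]], fps = seq$fps)
fit
#> <tic_fit> a0=-0.4224  a1=145.6  a2=0.2645/s  a3=14.87/s  t0=1.333 s
#>   rss=1931 over 60 frames at 6 fps

toa <- build_param_map(sm, mask, "TOA")
toa
#> <param_map> TOA (s), 128 x 128 px, 1066 valid pixels
#>   value range [0.1667, 6.333], median 3.5
plot(toa)   # red = contrast arrives first, yellow next, blue last
```

The fit says this pixel's contrast arrived at `t0 = 1.33` s with a steep
wash-in (`a3 ≈ 15`/s) and a washout half-life of a couple of seconds; on
the TOA map the leak blob shows up far later than its upstream tube. The
whole pipeline is one call:

```r
run_process(run_config(input = "seq.tif", out = "out", params = "all"))
# writes <kind>_map.tif + <kind>_color.png per parameter,
# vessel_mask.png and a reproducible run_config.json
```

Reader-score analysis on the bundled consensus tables:

```r
fx <- clinical_fixtures()
count_reinforced(fx$bleeding, "toward_bleeding")
#> $n_indeterminate 55   $n_reinforced 35   $n_downgraded 0   $n_unchanged 20
w <- wilcoxon_signed_rank(fx$bleeding$score_dsa, fx$bleeding$score_combined)
#> W = 630, p = 3.5e-09 (n_eff = 35)
```

Of the 55 bleeding cases the DSA-only reading left short of a definite
call, adding the arrival-time color rendering raised the confidence score
in 35 — a shift the paired signed-rank test finds highly significant.

## Command line

```sh
dsacolor process  --input run.tif --out out --param toa --lut toa-ryb
dsacolor phantom  --out ph --seed 7
dsacolor evaluate --scores scores.csv
dsacolor colorize --map out/toa_map.tif --out re.png --lut gray
```

(`dsacolor` is installed under the package's `exec/` directory; invoke as
`Rscript $(Rscript -e 'cat(system.file("exec","dsacolor",package="dsacolor"))') ...`
or add it to your `PATH`.)

## Layout

* `R/` — sequence I/O (TIFF/PNG/DICOM), preprocessing and segmentation,
  TIC fitting, parameter maps, pseudo-color, phantom, reader statistics,
  pipeline.
* `inst/extdata/` — bundled consensus score tables (CSV).
* `vignettes/parametric-color-dsa.Rmd` — the methods vignette: model,
  estimator design, parameter definitions, phantom rationale,
  statistical conventions, limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
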