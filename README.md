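# otoshape

Outline morphometrics for fish otoliths (sagittae, lapilli, asterisci), for
fisheries and fish-biology researchers who want a reproducible pipeline
from otolith photographs (or digitised outlines) to statistical tests of
side, sex and size-class structure.

## What it computes

Given a grayscale otolith image, the package binarises it (normalised
threshold, default 0.05), traces the outer contour as a sub-pixel
iso-contour, and measures it: maximum length OL, width OW, perimeter OP and
area OS, plus the six classical dimensionless shape indices

    C  = OP^2 / OS            (circularity;  4*pi for a circle)
    Re = OS / (OL * OW)       (rectangularity; 1 for a rectangle)
    E  = (OL - OW)/(OL + OW)  (ellipticity; signed)
    AR = OW / OL              (aspect ratio)
    FF = 4*pi*OS / OP^2       (form factor; FF * C = 4*pi identically)
    Ro = 4*OS / (pi * OL^2)   (roundness)

and the otolith-to-fish-length ratio OL/TL. Each outline is condensed into
two descriptor families: wavelet coefficients (periodized orthonormal
Daubechies-4 transform of the 512-point polar radius profile) and
normalised elliptic Fourier descriptors (translation-, scale-, rotation-
and start-point-invariant). After allometric adjustment (per-coefficient
regression on fish length, residuals kept where the slope is significant),
group structure is tested with a distance-based permutation pseudo-F
(PERMANOVA-style, seeded, block-aware for paired left/right otoliths) and
linear discriminant analysis with leave-one-out validation; group mean
shapes are reconstructed from averaged wavelet coefficients. A synthetic
generator produces specimen sets with the same design (3 TL-defined size
classes x 2 sexes, paired sides, allometric size, group shape effects), so
the entire pipeline is testable without specimen data.

## Worked example

```r
library(otoshape)
run <- run_pipeline(run_config(mode = "synthetic", seed = 1))
print(run)
```

```
<oto_run> mode=synthetic  120 specimens, 240 contours (0 quarantined)
  sides pooled: TRUE
  perm_side: pseudo-F = 0.520, p = 0.791
  perm_sex: pseudo-F = 2.719, p = 0.013 *
  perm_class: pseudo-F = 13.398, p = 0.001 *
  LDA side: LOO accuracy = 0.504
  LDA sex: LOO accuracy = 0.504
  LDA size_class: LOO accuracy = 1.000
```

Reading this: left and right otoliths do not differ (p = 0.79, LDA at
chance), so sides are pooled; the planted size-class shape effect is
recovered decisively (permutation p at its attainable minimum 0.001;
every fish correctly classified in leave-one-out). The generator plants no
sex effect — the LDA sits at chance and the occasional small sex p (here
0.013) reflects TL sampling imbalance between the sexes interacting with
the allometric adjustment, a caveat discussed in the methods vignette.
Morphometric summary tables, Tukey pairwise tables, Pearson correlations,
adjusted descriptor matrices, LDA scores, mean-shape overlays and
diagnostics are all in the returned object, and are written as a CSV/PNG
bundle when `out_dir` is set.

A command-line front end covers the common cases:

```sh
otoshape simulate --out data/ --seed 7
otoshape extract  --image oto.png --threshold 0.05 --px-per-mm 120 --out oto.csv
otoshape run      --mode synthetic --seed 7 --out report/
```

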