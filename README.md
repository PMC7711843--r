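# tomodock

Quantification of SUV–GUV vesicle docking sites in cryo-electron
tomograms of reconstituted SNARE/Synaptotagmin-1 fusion systems — for
researchers analysing in-vitro membrane-fusion intermediates by cryo-ET,
and for method developers who need a controlled synthetic benchmark for
such analyses.

## What it computes

At a docking site, an SUV (carrying VAMP2 and Syt1) is held near the
GUV membrane (carrying t-SNAREs) by protein densities. The package
measures, per site:

* the **membrane separation** *s* — distance from the SUV outer leaflet
  at the point of closest approach to the GUV outer leaflet;
* the **contact diameter** of flattened, zero-separation interfaces;
* a **GUV protrusion** flag and height (surface elevation toward the
  SUV above a baseline plane);
* the protein **density landmarks** and their count *n*;
* the **morphology class** from the density arrangement about the
  docking axis: with *n*ᵢ densities inside an exclusion cylinder of
  radius *r*ₑₓ and *n*ₒ outside,

  * clustered (code 0): *n*ᵢ ≥ 1, *n*ₒ = 0
  * ring-like (code 1): *n*ᵢ = 0, *n*ₒ ≥ 3
  * intermediate (code 0.5): otherwise,

  plus a ring-completeness fraction over angular bins.

Across sites it computes the 4×4 Pearson correlation matrix between
class code, separation, protrusion flag and density count (p-values from
*t* = *r*√((*n*−2)/(1−*r*²)), strength labels small/moderate/strong at
|*r*| = 0.1/0.3/0.5), summary tables, and landmark-aligned voxel
averages per morphology class.

Biophysical calculators cover reconstitution copy numbers
(copies = π*d*²/*a*ₗ · [protein]/[lipid], outward fraction 0.5),
the bridging span of a partially zippered SNAREpin
(span = *N*ᵤ · 0.365 nm), and the steric-exclusion predicate
(a complex of diameter *D* is excluded where *s* < *D*; presets
SNAREpin–CpxII = 3 nm, SNAREpin–CpxII–Syt1–Syt1 = 8 nm).

A synthetic scene generator (`generate_scene()`, `render_volume()`)
produces ground-truth docking scenes — class-conditional separations
(5–26 / 3–8 / 0–7 nm), SUV sizes (20–150 nm), density arrangements,
protrusions — rendered as bilayer-shell phantoms with a ±60° missing
wedge and noise, plus MRC and landmark-CSV I/O for real data.

## Worked example

```r
library(tomodock)

sc  <- generate_scene(scene_params(n_junctions = 1, seed = 42))
vol <- render_volume(sc, optics_params(), seed = 43)
res <- analyze_docking_volume(vol)
round(res$table[, c("separation_nm", "class_code", "protrusion_flag",
                    "n_densities")], 2)
#>   separation_nm class_code protrusion_flag n_densities
#> 1          4.25          0               1           1

sc$ground_truth[, c("separation_nm", "class_code", "protrusion_flag",
                    "n_densities")]
#>   separation_nm class_code protrusion_flag n_densities
#> 1      7.152238        0.5               1          25
```

This junction illustrates both what the pipeline gets right and where
resolution bites: the protrusion call matches the ground truth, the
separation is recovered to about a voxel (4.3 vs 7.2 nm, with the local
protrusion steepening the surface under the site), but of 25 generated
densities only the central merged cluster survives detection at
tomographic contrast, so an intermediate junction reads as clustered.
The vignette and the acceptance tests quantify these error modes over
hundreds of junctions.

```r
copy_number(140e-9, 50e-6, 80)$outward   # outward v-SNAREs per 80 nm SUV
#> [1] 43
bridging_span(38, 39)                    # nm; VAMP2 zippered to layer 0
#> [1] 28.105
is_excluded(snare_complex("SNAREpin-CpxII-Syt1-Syt1"), 7)
#> [1] TRUE
```

See `vignettes/docking-site-quantification.Rmd` for the measurement
model, generator assumptions, and known limitations.

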