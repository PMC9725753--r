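# MitoNodeQuant

Mitochondria divide and fuse at spots predefined by the endoplasmic
reticulum (ER): where an ER tubule crosses a mitochondrion, the organelle
constricts, and both the fission GTPase Drp1 and the fusion GTPase Mfn1 are
recruited to shared "nodes". Studies of this biology lean on a family of
live-cell quantifications — puncta densities, crossing co-occupancy
percentages, intensity-dip constriction calls, binary-mask contact overlap,
and photoconversion-based fusion/fission rates — that are usually performed
by hand in Fiji. MitoNodeQuant implements these measurements as an
automated, tested R pipeline for multi-channel fluorescence stacks, for
cell biologists who want the scoring to be reproducible and scriptable.

Because the underlying live-cell acquisitions of this kind are generally
not deposited, the package also ships a synthetic-microscopy generator
that builds ground-truth scenes (curvilinear mitochondria, ER tubule
fields, machinery puncta, Poisson-scheduled fusion/fission events, a
photoconvertible outer-membrane label) and renders them with a Gaussian
PSF and Poisson + Gaussian camera noise, so every stage of the analysis is
testable end-to-end without real data.

## The quantities

With `I` the matrix-marker intensity along a mitochondrion and `P` the
neighbouring fluorescence peak at a local minimum `m`, a constriction is
called when

    1 - I(m) / P >= 0.40        (confirmed in >= 2 z-planes)

and the constriction readout is `#constricted resolvable crossings /
#resolvable crossings`. Machinery recruitment is scored as persistent-
punctum density `n_puncta / L_mito` (per um of skeleton length), crossing
occupancy `n_occupied / n_crossings`, and node density (one-to-one matched
Drp1+Mfn1 pairs per um). Contact overlap is the Mander's fraction
`|A ∩ M| / |M|` of the mitochondrial mask `M` covered by the ER or ddFP
mask `A`. Event rates are `N_events / (N_mito x T_min)` per kind, with
fusion classed tip-to-tip vs tip-to-middle from the joint geometry.
Group comparisons use one-way ANOVA with Tukey HSD (two-tailed Student's t
for pairs), and proximity-proteomics tables are ranked by the WT/mutant
ratio of replicate-averaged LFQ intensities.

## A worked example

```r
library(MitoNodeQuant)

## one synthetic control-condition cell: Mfn1 programmed at 0.30 puncta/um,
## Drp1 at 47% of ER crossings, constrictions at 60% of crossings
p <- sceneParams(mfn1PerUm = 0.30, drp1AtCrossingProb = 0.47,
                 crossingConstrictionProb = 0.60, transientPerUm = 0.05)
scene <- buildScene(p, seed = 1)
movie <- renderMovie(scene, seed = 11)     # 24-frame 2-min movie, 4 channels

dens <- scoreDensities(movie)
round(c(mfn1PerUm = dens$mfn1Density,
        drp1Fraction = dens$drp1CrossingFraction,
        mitoLengthUm = dens$mitoLengthUm), 3)
#>    mfn1PerUm drp1Fraction mitoLengthUm
#>        0.217        0.600       32.294

zstack <- renderZStack(scene, seed = 21)   # 12 slices, 0.2 um apart
round(scoreConstrictions(zstack)$fractionConstricted, 2)
#> [1] 0.62

## a 5-min photoconversion movie at the control rates
pd <- sceneParams(nMito = 5, nErTubules = 0, fovUm = c(17, 17),
                  durationS = 300, fusionRatePerMitoMin = 0.25,
                  fissionRatePerMitoMin = 0.17, photoconvert = TRUE)
dyn <- scoreDynamics(renderMovie(buildScene(pd, seed = 2), seed = 12,
                                 channels = c("native", "converted")))
dyn$rates
#>      kind         class n rate
#> 1  fusion         total 5 0.20
#> 2  fusion tip_to_middle 4 0.16
#> 3  fusion    tip_to_tip 1 0.04
#> 4  fusion  unclassified 0 0.00
#> 5 fission         total 4 0.16
```

For this cell the pipeline reads an Mfn1 density of 0.22 puncta/um over
32.3 um of mitochondria against a programmed 0.30 (the per-cell count is
Poisson), finds Drp1 at 60% of the five resolvable crossings (programmed
probability 0.47), calls constrictions at 62% of crossings (programmed
0.60), and recovers a fusion rate of 0.20 events per mitochondrion per
minute against this movie's realized ground-truth rate of 0.24. Means over
many cells, not single-cell values, are the quantities the recovery tests
hold to tolerance.

The methods vignette
(`vignettes/scoring-er-mitochondria-dynamics.Rmd`) documents the model
behind the generator, every analysis parameter with its default and
rationale, and the known limitations.

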