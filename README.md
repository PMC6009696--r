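# ctRadial

Quantitative analysis of chromosome territory (CT) radial positioning in
interphase nuclei from multichannel 3D confocal stacks, with companion
summaries for per-chromosome transcriptional deregulation and
nuclear-envelope line-scan profiling.

## The problem and the statistic

Interphase chromosomes occupy discrete territories whose radial position
in the nucleus is non-random: gene-poor territories (human chromosome 18)
sit near the nuclear periphery, gene-rich ones (chromosome 19) toward the
interior. 3D-FISH experiments probe whether perturbations — substrate
stiffness, lamin levels, nuclear-envelope signalling — shift these
positions. `ctRadial` implements the measurement those experiments rely
on, end to end, for anisotropic confocal voxel grids.

For each segmented territory the package computes the **percent radial
distance**:

- *N* — geometric centre of the DAPI-stained nucleus (unweighted mask
  centroid, physical µm),
- *C* — geometric centre of the territory,
- *B* — the point where the ray from *N* through *C* crosses the nuclear
  boundary (sub-voxel ray marching over the nucleus mask),
- *R* = |NC|, *Y* = |NB|, and

  **%RD = (R / Y) × 100**,

so 0% is the nuclear centre and 100% the periphery. Per condition and
chromosome, values are pooled across replicates and summarized as the
sample median, a 20-point binned distribution
([0,20) [20,40) [40,60) [60,80) [80,100]), two-sided Mann–Whitney
comparisons between conditions, and median shift tables
(Δ = median − median(reference), `+` meaning movement toward the
periphery; optionally Δ(CT_a − CT_b) within each condition).

Because real acquisitions are not required to exercise any of this, the
package ships a ground-truthed simulator: ellipsoidal nuclei with
territory blobs planted at exact fractional radial positions, rendered
under Gaussian PSF blur, background and noise at the acquisition
geometry of a typical 63× confocal stack (voxel 0.105 × 0.105 × 0.34 µm,
8-bit channels); expression tables with planted per-chromosome
deregulation; and 2D envelope-stained sections with controlled
rim-to-interior contrast.

## Worked example

```r
library(ctRadial)

# a nucleus with a peripheral (CT18-like) and an interior (CT19-like)
# territory planted at fractional positions 0.66 and 0.49
p <- sceneParams(territories = list(
  territorySpec("green", 0.66, direction = c(1, 0, 0)),
  territorySpec("red",   0.49, direction = c(0, 1, 0))), seed = 7)
scene <- renderScene(p)
measureScene(scene, "nucleus01")[, c("channel", "R", "Y", "percent_rd")]
#>   channel     R     Y percent_rd
#> 1   green 3.959 5.906      67.02
#> 2     red 2.209 4.489      49.20
```

The green territory, planted at 66% of the centre-to-boundary distance,
is recovered at 67.0 %RD (R = 3.96 µm from the nucleus centre, boundary
at Y = 5.91 µm along the same ray); the red one, planted at 49%, reads
49.2 %RD. Pooled values are then summarized and compared:

```r
su <- summarizeRD(c(62.1, 70.4, 55.9, 68.2, 71.6, 60.3), "glass", "CT18")
su
#> RDSummary: CT18 | glass | n = 6
#>   median %RD: 65.15
#>   bin frequencies [0-20,20-40,40-60,60-80,80-100]: 0 0 0.167 0.833 0
```

`compareRD()` runs the Mann–Whitney test between two such summaries, and
`shiftTable()` turns a set of condition medians into the Δ table. The
whole chain — simulate, measure, summarize, shift table (plus `dereg`
and `linescan` stages) — runs from one configuration via
`runPipeline(defaultPipelineConfig(), "out/")`, or from a shell through
`inst/cli/ctradial.R`.

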