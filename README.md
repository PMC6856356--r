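# NeutroTrack

Quantitative analysis of neutrophil behaviour at wounds from time-lapse
fluorescence microscopy, for researchers studying inflammation and its
resolution in live-imaging models such as larval zebrafish.

Neutrophils are recruited to tissue damage, cluster at the wound, and
later disperse (reverse migration). Both arms of this response are shaped
by chemokine receptor trafficking: a receptor that is internalized after
ligand binding stops signalling, while one that stays at the plasma
membrane keeps driving motility. NeutroTrack implements the two
measurement chains needed to study this in vivo:

- **Receptor internalization per cell.** Intensities of a GFP-tagged
  receptor inside a segmented cell surface are quantized to N = 8 gray
  levels and summarized by the co-occurrence contrast

  C = Σᵢⱼ |i − j|² p(i, j),

  where p(i, j) is the gray-level co-occurrence matrix at the
  right-neighbour offset. Punctate (internalized, endosomal) receptor
  gives high C; smooth membrane-localized receptor gives low C. The
  package provides seeded Chan–Vese and whole-image threshold
  segmentation, reference (CHT-mean) and per-movie-maximum
  normalizations, distance-binned gradient profiles against a wound
  margin, the membrane GFP/CFP ratio, and a chemokine-uptake score.

- **Migration statistics against the occupied wound area (owa).** Tracks
  are classified into forward segments (before first owa entry) and
  reverse segments (after last owa residence). Per step the package
  computes speed v_t (µm/min), distance to the owa d_t, and the
  approach-angle cosine cos θ_t; per cohort it computes speed–distance
  and speed–cosine profiles, track straightness (net / cumulative
  displacement within 50 µm of the owa), net reverse traffic
  (reverse / forward-intersecting track counts), recruitment counts in a
  200 × 200 µm wound square, and filtered cluster sizes.

A synthetic-scene generator — fluorescence phantoms with a tunable
membrane/vesicular split, wound-gradient scenes with an exponential
internalization gradient (decay length 200 µm), and biased persistent
random walkers with ground-truth forward/reverse labels — makes every
stage testable without microscopy data.

## Worked example

```r
library(NeutroTrack)

# Two single-cell phantoms at identical total fluorescence: one with the
# receptor on the membrane, one fully internalized.
mem <- renderCellImage(scenePhantomParams(vesicularFraction = 0, seed = 1))
ves <- renderCellImage(scenePhantomParams(vesicularFraction = 1, seed = 1))
glcmContrast(coocMatrix(mem$image, mem$surfaceMask))
#> [1] 0.2843137
glcmContrast(coocMatrix(ves$image, ves$surfaceMask))
#> [1] 2.385621
```

The internalized cell scores ~9× higher contrast at matched flux — the
separation the internalization readout relies on.

```r
# A wound-recruitment cohort: walkers biased toward the owa, 30% of
# entrants later disperse.
fin <- owaPolygon(cbind(c(-300, 300, 300, -300), c(-300, -300, 300, 300)))
owa <- owaPolygon(cbind(c(-20, 20, 20, -20), c(-20, -20, 20, 20)))
tr  <- simulateTracks(walkerParams(nTracks = 100, nFrames = 120,
                                   pReverse = 0.3, startDistance = 80,
                                   finPolygon = fin, seed = 2), owa)
cl  <- classifyTracks(loadTracks(tr), owa)
netReverseTraffic(cl)
#> $n_forward_intersecting
#> [1] 100
#> $n_reverse
#> [1] 35
#> $ratio
#> [1] 0.35
```

All 100 walkers reached the wound cluster and 35 later left it: a net
reverse traffic of 0.35, recovering the simulated dispersal probability.

End-to-end runs (simulate → segment → score → summarize) are driven by a
YAML configuration through `runSimulate()`, `runInternalization()`,
`runTrajectories()`, `runClusters()` and `runAll()`; a thin command-line
wrapper lives at `inst/scripts/neutrotrack.R`. Outputs are deterministic
for a fixed configuration and seed.

See the methods vignette (`vignettes/neutrotrack-methods.Rmd`) for the
model details, parameter defaults and their rationale, and known
limitations.

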