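# leaftex

Quantifying and ranking the texture complexity of leaf epidermal surfaces
from scanning electron micrographs.

## What it does

The lower (abaxial) leaf surface carries species-typical micro-structure —
wax papillae, folds, plates — that shapes how fungi, bacteria and lichens
colonize the leaf. `leaftex` turns stomata-annotated 8-bit grayscale
micrographs into a quantitative, species-level **surface texture
complexity score**:

1. **Sampling** — 80 µm sub-images are drawn around annotated stomata and
   resized to 512 × 512 px; the dataset is balanced per species.
2. **Features** — per patch: isotropic gray-level co-occurrence (GLCM)
   statistics (64 levels, offsets {1,2,4} × four angles), a radially
   averaged log Fourier power spectrum reduced to 25 principal components,
   Sobel gradient statistics, and lossless compression density (bits per
   pixel).
3. **Classification** — k-nearest neighbours (k = 3) under grouped
   leave-image-out cross-validation verifies that the features carry
   species-level signal.
4. **Ranking** — a pairwise comparison game: patches of different species
   duel on the complexity triplet (compression density, 1 − ASM, gradient
   standard deviation), one point per feature. Species-level win counts
   are fitted with a Bradley–Terry model,

   P(i beats j) = π<sub>i</sub> / (π<sub>i</sub> + π<sub>j</sub>),

   and log-abilities (Σ log π = 0) are min–max scaled to the complexity
   score in [0, 1].
5. **Grouping** — pairwise Kruskal–Wallis tests on per-patch win
   fractions (BH-adjusted) feed average-linkage clustering cut at
   −log₁₀(α); statistically indistinguishable species share a complexity
   group.
6. **Stability** — bootstrap resampling (20 replicates, 80 % of patches
   per species) and feature leave-one-out reruns report Spearman
   correlations against the full-data ranking.

A synthetic micrograph generator with a single ground-truth complexity
parameter (spectral slope + papilla density, plus a species-typical
striation frequency) makes the whole pipeline testable end to end without
any image download.

## Worked example

```r
library(leaftex)

# a small synthetic cohort: 6 species, 2 micrographs each
bench <- generate_benchmark(out_dir = tempfile(), n_species = 6,
                            images_per_species = 2, size_px = 768,
                            seed = 42)
ann <- load_annotations(file.path(bench$dir, "annotations.csv"),
                        bench$manifest)

cfg <- leaftex_config(manifest = file.path(bench$dir, "manifest.csv"),
                      annotations = file.path(bench$dir, "annotations.csv"),
                      out_dir = tempfile(), seed = 7,
                      sampling = list(n_per_image = 15, per_species = 24),
                      classifier = list(n_folds = 2),
                      features = list(n_components = 10),
                      tournament = list(pairs_per_species_pair = 150),
                      stability = list(n_boot = 3))
res <- run_pipeline(cfg)

res$report
#> <leaftex_classification_report> accuracy 0.9271 on 96 patches
#>   per-fold: 0.896 0.958
res$scores[, c("species", "score", "rank", "group")]
#>      species     score rank group
#> 1 species_01 0.0000000    1     1
#> 2 species_02 0.4397726    2     2
#> 3 species_03 0.8698793    3     3
#> 4 species_04 1.0000000    4     4
res$stability
#> <leaftex_stability_report> n_boot 3, frac 0.80: rho 1.0000 +/- 0.0000;
#>   4/4 species with zero rank variance
```

(Output from a 4-species run of the same configuration.) The score table
says species_01 has the least complex surface texture (rank 1, score 0)
and species_04 the most complex (score 1); each species lands in its own
complexity group, and the ranking is identical in every bootstrap
replicate. `run_pipeline()` writes all artifacts (feature table, confusion
matrix, win matrix, score/group tables, stability JSON, resolved config,
run log) into `out_dir`, and reruns with the same seed are byte-identical.

A thin command-line wrapper ships in `inst/cli/leaftex.R`:

```sh
Rscript inst/cli/leaftex.R simulate --out-dir bench --seed 42
Rscript inst/cli/leaftex.R run --manifest bench/manifest.csv \
    --annotations bench/annotations.csv --out-dir results
```

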