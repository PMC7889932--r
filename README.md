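# netage

**Network age** is a one-dimensional daily descriptor of an individual's
role in an animal society, computed purely from its position in the
colony's multimodal social-interaction network. In honey bee colonies,
workers progress through tasks as they age (temporal polyethism:
nursing → food handling → foraging), but same-aged bees can follow very
different developmental paths. Network age separates those paths where
biological age cannot: it predicts task allocation, mortality, circadian
activity, and future behavior better than the number of days since
emergence.

`netage` implements the full pipeline for R, together with a synthetic
colony simulator with known ground truth, so every stage can be validated
end to end without the original tracking data.

## The method

For every day *t* and interaction mode *m* (proximity contact counts,
trophallaxis counts, two spatial-distance similarities, and four directed
movement-effect networks), the bees alive on *t* form an affinity matrix
**A**<sup>(m,t)</sup>:

1. **Rank transform.** Each matrix's affinities are replaced by tie-aware
   ranks rescaled to [0, 1].
2. **Spectral embedding.** For symmetric modes, Laplacian-eigenmap
   coordinates: the first 8 nontrivial eigenvectors of the symmetric
   normalized adjacency D<sup>-1/2</sup>AD<sup>-1/2</sup>. Directed modes
   use the bispectral (SVD) co-embedding of the degree-normalized matrix,
   giving separate row (focal) and column (partner) coordinate sets. With
   8 symmetric-plus-directed modes this yields 12 embedding sets and an
   F = 96-dimensional daily factor vector per bee.
3. **Temporal sign alignment.** Eigenvector signs are arbitrary; a
   dimension is flipped on day *t* when its Spearman correlation with day
   *t* − 1 over shared bees is negative.
4. **CCA.** Canonical correlation analysis between the standardized pooled
   factors and the four-area task descriptor (fractions of time in brood
   nest, dance floor, honey storage, exit) yields a linear projection;
   its first dimension is network age. Unsupervised (PCA) and targeted
   (CCA against any scalar property, e.g. days until death) variants are
   included.
5. **Scaling and orientation.** Per day, an affine map sends the 5th/95th
   percentiles to 0/40 — so 90% of values fall in [0, 40], a range
   comparable to a worker's summer lifespan in days — and the sign is
   fixed so that low network age corresponds to biologically younger bees.

Supporting models, all implemented here:

- a **Bayesian changepoint model** for death dates from daily detection
  counts (alive days *l* ~ N(35, 50) truncated, detection probability
  *p* ~ Beta(5, 1), count threshold *t* with an informative prior just
  above the false-positive floor), with an exact enumeration backend and
  an MCMC backend;
- **Otsu thresholding** to remove erroneously decoded tag ids;
- trajectory-level primitives: median-filtered velocities, proximity
  events (< 2 cm, ≥ 3 frames), the stage-1 trophallaxis geometry
  classifier (head offset d = 3.19 mm, thorax-distance gate
  0.731–1.204 cm), and per-contact velocity-change records;
- **evaluation machinery**: weighted multinomial/binomial/Gaussian task
  models (GLM and a small tanh network), McFadden's pseudo R²
  (R² = 1 − ℓ₁/ℓ₀), likelihood-ratio χ² tests, 128-replicate bootstrap
  effect CIs, repeatability R = Var_p/(Var_i + Var_p), Ward clustering of
  developmental trajectories, per-day 2-means mode splits, and a
  future-prediction protocol (12-day training windows, 1–11-day horizons)
  against a persistence null.

## Worked example

```r
library(netage)

cfg <- colony_config(seed = 1)        # 200 bees, 25 days, heterogeneous development
p   <- run_colony_pipeline(cfg)       # affinities -> embeddings -> CCA -> network age

head(as.data.frame(p$series)[, c("bee_id", "day", "network_age")], 3)
#>   bee_id day network_age
#> 1  b0001   1    8.327182
#> 2  b0002   1   37.166469
#> 3  b0003   1   68.015962

p$map$cor1                            # first canonical correlation: 0.881

m <- merge(as.data.frame(p$series),
           p$ground_truth$roles[, c("bee_id", "day", "rho")])
cor(m$network_age, m$rho, method = "spearman")
#> 0.833  — network age recovers the latent developmental role

feat_na <- as.data.frame(p$series)[, c("bee_id", "day", "network_age")]
feat_ba <- p$bio_age; names(feat_ba)[3] <- "bio_age"
fit_task_model(feat_na, p$descriptors)$r2   # 0.398
fit_task_model(feat_ba, p$descriptors)$r2   # 0.127
```

The two McFadden scores show the core claim on a colony whose ground truth
we control: network age explains task allocation about three times better
than biological age, because the simulated bees transition to forager-like
roles at different ages. Bee `b0001` on day 1 sits near 8 (nurse-like
network position), `b0003` near 68 (well beyond the 95th percentile —
strongly forager-like).

A thin command-line wrapper is installed with the package
(`system.file("exec", "netage", package = "netage")`), with subcommands
`simulate`, `events`, `lifetimes`, and `pipeline`.

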