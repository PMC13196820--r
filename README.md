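# pdmdiffuse

Generative modelling of **point distribution models** (PDMs) — ordered point
sets in which index *i* marks the same anatomical locus in every subject —
with a **correspondence-preserving denoising diffusion model**. The package
is aimed at shape analysts (e.g. hippocampal morphometry in Alzheimer's
disease) who need generated shapes that keep the training data's point
correspondences, so that per-index group difference maps, conditional
generation and counterfactual "disease progression" maps remain meaningful.

## What is inside

A shape is $X^{(0)} = (x_1,\dots,x_N)$, $x_i \in \mathbb{R}^3$, with row
order semantic. The diffusion model corrupts shapes with the Gaussian kernel
$q(X^{(t)}\mid X^{(t-1)}) = \mathcal{N}(\sqrt{1-\beta_t}\,X^{(t-1)},\ \beta_t I)$
and learns the reverse chain
$p_\theta(X^{(t-1)}\mid X^{(t)}) = \mathcal{N}(\mu_\theta(X^{(t)},t),\ \beta_t I)$
by minimizing the noise-prediction loss
$\lVert\epsilon - \epsilon_\theta(X^{(t)},t)\rVert^2$ with
$X^{(t)} = \sqrt{\bar\alpha_t}X^{(0)} + \sqrt{1-\bar\alpha_t}\,\epsilon$.
The backbone applies shared per-point linear maps (row-wise feature
transformation blocks) in a U-Net layout with **learned correspondence
embeddings** ($y_i' = y_i + e_i$, the component that encodes point identity)
and a **masked self-attention** bottleneck whose mask is the k-nearest-
neighbour graph of the training mean shape (k = 50 by default).

Also included, all exercised on a bundled synthetic shape-population
generator with exact ground truth:

* ShapeWorks-style `.particles` + CSV-manifest I/O, lateral flipping,
  normalization, mean shapes (`read_particles()`, `flip_lateral()`, ...);
* a PCA shape-model baseline (`pca_fit()`, `pca_sample()`);
* generation metrics — MMD, coverage, density (k = 7) under Chamfer, exact
  assignment-based earth mover's, and ordered-L2 distances
  (`evaluate_generation()`), with the EMD solver and pairwise kernels in C++;
* per-index group difference maps, a small shape classifier,
  classifier-guided counterfactual generation, correspondence colour maps
  and a correspondence score (`group_mean_difference()`,
  `counterfactual_generate()`, `correspondence_score()`);
* a CLI (`pdm_cli()`, wrapper script in `inst/cli/`) with `synth`, `train`,
  `sample`, `evaluate`, `baseline-pca` and `counterfactual` subcommands.

See the methods vignette (`vignettes/correspondence-diffusion.Rmd`) for the
model, conventions and design decisions.

## Worked example

Generate the benchmark population (400 shapes of 64 points; the "AD" class
has an inward radial displacement of 0.3 at a contiguous 8-index patch),
map the class difference, and evaluate the PCA baseline:

```r
library(pdmdiffuse)
pop <- generate_population(synthetic_config(seed = 1))
pop
#> <synthetic_population: 400 shapes x 64 points, seed 1>
#> <shape_dataset: 400 shapes x 64 points>
#>   labels: AD=200, healthy=200

ds <- pop$dataset
gd <- group_mean_difference(ds[ds$labels == "AD"], ds[ds$labels == "healthy"])
head(as.data.frame(gd)[c("point", "signed", "se_signed", "magnitude")], 4)
#>   point     signed   se_signed magnitude
#> 1     1 -0.2923352 0.004973930 0.2996560
#> 2     2 -0.2891618 0.004479114 0.3023201
#> 3     3 -0.2953150 0.004639074 0.3002417
#> 4     4 -0.2904628 0.004008597 0.3056575
```

Indices 1–8 show a signed (outward-projected) displacement of about −0.29 —
the injected atrophy, recovered with the right sign and location — while
off-patch indices sit near zero (index 9: −0.004 ± 0.006). `autoplot(gd)`
draws the map with a 3-SE band.

```r
m <- pca_fit(ds, 20)
glance(m)
#>   n_components n_points n_train explained_variance_ratio
#> 1           20       64     400                    0.906
set.seed(2)
gen <- pca_sample(m, 200)
evaluate_generation(ds, gen, k = 7)
#>   distance     mmd coverage density k n_real n_gen
#> 1       CD 0.00486    0.965    1.30 7    400   200
#> 2      EMD 0.04453    0.970    1.52 7    400   200
#> 3       L2 0.04863    0.965    1.30 7    400   200
correspondence_score(ds, gen)
#> [1] 0.9999
```

PCA keeps correspondence trivially (score ≈ 1) but over-concentrates
(density well above 1) — the classic low-diversity behaviour of a linear
shape model.

Training the diffusion model on the same population (CPU-scale profile,
about 4 minutes) and sampling:

```r
net <- train_diffusion(
  ds,
  net_config  = network_config(64, level_widths = c(32, 64), attention_k = 50),
  diff_config = diffusion_config(n_steps = 100, beta_start = 1e-3, beta_end = 0.2),
  epochs = 150, batch_size = 32, lr = 2e-3, seed = 7)
set.seed(99)
gen <- sample_shapes(net, 200)
correspondence_score(ds, gen)
#> [1] 0.9982155
mmd(ds, gen, "l2"); mmd(ds, gen, "emd")
#> [1] 0.08487683
#> [1] 0.07793284
```

The ordered-L2 MMD is within ~9% of the permutation-invariant EMD MMD: the
model places each index at its anatomical locus, so matching by index is
nearly as good as the optimal matching. Re-running the same pipeline with
`use_correspondence_embeddings = FALSE` (the ablation) collapses the
correspondence score to ≈ 0.

From a shell, the same workflow:

```sh
Rscript inst/cli/pdmdiffuse synth --n-points 64 --seed 1 --out data/
Rscript inst/cli/pdmdiffuse train --manifest data/manifest.csv --steps 100 \
    --beta-end 0.2 --widths 32,64 --epochs 150 --out model.rds
Rscript inst/cli/pdmdiffuse sample --model model.rds --n-samples 200 --seed 99 --out gen/
Rscript inst/cli/pdmdiffuse evaluate --real data/manifest.csv --gen gen/manifest.csv --k 7
```

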