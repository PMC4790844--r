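# isocolony

Can stable isotopes tell you which breeding colony a bird came from?

`isocolony` is an R package for movement ecologists working on colonial
birds (the motivating system is the American white pelican, a species that
is genetically panmictic across North America, so genetic assignment carries
no signal). It implements the complete feather-isotope assignment pipeline:

* **Synthetic data** — seeded generators for colony isotope tables
  (trivariate-normal colonies) and microsatellite genotype tables with
  planted duplicate individuals, so every stage is testable without raw
  field data.
* **Assignment core** — per-colony trivariate-normal fits over
  (δ²H, δ¹³C, δ¹⁵N) and a maximum-likelihood assignment test with
  error-incorporated resampling and leave-one-out cross-validation.
* **Clustering** — k-means over isotope triplets with within-cluster
  sum-of-squares model selection, per-colony cluster composition, and a
  MANOVA across clusters.
* **Basemaps** — ordinary kriging of colony-mean isotope values with a
  stable variogram model (ESRI ASCII rasters, GeoJSON contours).
* **Duplicate screening** — an allele-mismatch rule for shed feathers
  ("unique unless mismatched at >1 locus by >2 bp") and the probability of
  identity.

## The model in brief

Colony $c$ has feather isotope distribution
$x \sim \mathcal{N}_3(\mu_c, \Sigma_c)$, fitted by maximum likelihood.
Measurement error is propagated by resampling: each of 100 perturbed data
sets (per-value Gaussian noise with lab-standard SDs of 3 / 0.2 / 0.3 ‰ for
H / C / N) defines the colony parameters, and 100 perturbed copies of the
focal feather are each assigned to $\arg\max_c \log f(x \mid \mu_c,
\Sigma_c)$, giving 10,000 outcomes per feather. The assignment is the modal
colony; confidence is its share of outcomes. Under cross-validation the
focal feather is excluded from all parameter fits. The probability of
identity is $P_{ID} = \prod_\ell \left( \sum_i p_i^4 + \sum_{i<j}
(2 p_i p_j)^2 \right)$, and the kriging variogram is the stable model
$\gamma(h) = c_0 + c_1(1 - e^{-(h/a)^s})$, $s \in (0,2]$.

See `vignettes/isotope-assignment.Rmd` for assumptions, parameter meanings
and the design decisions behind every module.

## Worked example

```r
library(isocolony)

config   <- default_scenario(seed = 42, duplicate_rate = 0.08)
feathers <- generate_feathers(config)                  # 189 feathers, 17 colonies
feathers <- filter_min_colony_size(feathers, min_n = 5)

cv <- cross_validate(feathers, lab_sd = c(3, 0.2, 0.3),
                     n_param_reps = 25, n_noise = 25, seed = 42)
print(cv)
#> Leave-one-out cross-validation of colony assignment
#>  colony_id  n n_correct proportion_correct
#>        C01 15         9          0.6000000
#>        C02  9         3          0.3333333
#>        ...
#>        C17 10         8          0.8000000
#> Overall: 47 / 189 correct (24.9%)

rs <- range_vs_success(feathers, cv, "d2H")
#> d2H range vs success: r = -0.27, p = 0.304 (n = 17 colonies)

gen <- generate_genotypes(config, feathers)
dd  <- match_individuals(gen$genotypes, colony_of = feathers)
print(dd)
#> Duplicate screen (colony scope, tol 2 bp, <= 1 mismatching locus/loci):
#> 15 of 189 feathers are repeat samples of another individual

kept <- select_representatives(dd$groups, seed = 42)
probability_of_identity(allele_frequencies(gen$genotypes, samples = kept))
#> Probability of identity over 10 locus/loci: 1.19e-12

choose_k(generate_cluster_scenario(n_per_cluster = 50, seed = 42),
         k_max = 12, n_restarts = 20, seed = 42)$k
#> [1] 4

vg <- fit_variogram(colony_means(feathers), "d2H")
#> stable variogram: nugget 109, partial sill 1.47e+03, range 3012.0 km, shape 2.00
surf <- krige(colony_means(feathers), "d2H", vg, n_max = 5, n_min = 2)
```

Reading the output: the default scenario deliberately has very high
within-colony isotopic variance, so only a quarter of known-origin feathers
assign back to their colony — chance would be ~6% across 17 colonies, so
there is signal, but nowhere near enough for a usable basemap. The one
enriched coastal colony (C17) assigns at 80%, the analogue of an isotopically
distinct outlier colony. The duplicate screen recovers exactly the 8%
planted repeat feathers, and with ten polymorphic loci the probability that
two random birds share a genotype is ~10⁻¹², so matching genotypes really do
mean the same bird.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/isocolony.R simulate --seed 5 --duplicate-rate 0.08 --out-dir out/
Rscript inst/cli/isocolony.R crossval --feathers out/feathers.csv --out-dir out/
Rscript inst/cli/isocolony.R krige    --feathers out/feathers.csv --isotope d2H --out-dir out/
```

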