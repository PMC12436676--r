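# cnmix — robust model-based clustering with contaminated Gaussian mixtures

`cnmix` identifies latent groups in multivariate continuous data in the
presence of mild outliers and uninformative variables. It was built for
two-group cognitive-skill cohorts — children screened for dyslexia with a
battery of reading, phonology, naming-speed, attention and auditory tests —
where simple clustering heuristics are misled by correlated scores, noise
variables and atypical observations.

Each cluster is modelled as a *contaminated Gaussian*: a two-part mixture
sharing a mean,

    f(x; θ_g) = α_g φ(x; μ_g, Σ_g) + (1 − α_g) φ(x; μ_g, η_g Σ_g),

with good-point proportion α_g ∈ (0.5, 1) and inflation η_g > 1, embedded in
a finite mixture p(x) = Σ_g π_g f(x; θ_g). Covariances range over the
14-member parsimonious family Σ_g = λ_g D_g A_g D_gᵀ (volume / shape /
orientation each equal, variable, or identity). The package provides:

* **`fit_ecm()`** — multi-start ECM estimation under any of the 14
  structures, with MAP classification, per-observation good-point
  probabilities, and outlier flags (`v < 0.5` at the assigned cluster);
* **`sweep_models()`** — fits over a grid of structures and cluster counts,
  scored by eight information criteria (AIC, AICc, AIC3, AICu, CAIC, BIC,
  AWE, ICL; smaller is better);
* **`vscc_select()`** — stepwise variable selection: variables enter by
  ascending within-group variance W_j subject to |ρ_jr| < 1 − W_j^i for
  i = 1..5, and the candidate subset minimising mean clustering uncertainty
  wins;
* **`comparison_table()`**, **`adjusted_rand_index()`** — a benchmarking
  harness against hierarchical linkages, k-means, k-medoids and univariate
  mixtures;
* **`simulate_mixture()`**, **`dyslexia_preset()`**, **`recovery_preset()`**,
  **`unclassified_preset()`** — synthetic generators with ground truth,
  including a 122-child two-group cohort preset (71/51) and its extension
  with 81 borderline units.

See `vignettes/contaminated-mixture-clustering.Rmd` for the model, the
algorithmic choices and the limits of what the synthetic studies show.

## Worked example

```r
library(cnmix)

sim <- dyslexia_preset(seed = 7)          # 122 x 9 cohort with ground truth
fit <- fit_ecm(sim$data, G = 2, "EVI", fit_config(n_init = 10, seed = 7))
print(fit)
#> <cnmix_fit> EVI, G = 2, loglik = -1733.521 (converged, 19 iterations)
#>   BIC = 3659.20 | cluster sizes: 71/51 | flagged bad: 11

adjusted_rand_index(fit$labels, sim$truth$labels)
#> [1] 0.6964104
```

The fit recovers the two groups (ARI 0.70 against the generating labels —
the preset's clusters overlap deliberately), assigns each child a cluster
and flags observations whose good-point probability at their cluster drops
below one half. Variable selection then strips the battery down to the
scores that drive the separation:

```r
st <- vscc_select(sim$data, G = 2, fit_config(n_init = 10, seed = 7))
st$chosen_vars
#> [1] "Reading"   "RAN"       "Phonology" "Tone"      "Rhythm"    "VAS1"
```

Here the three variables that truly separate the groups (Reading, RAN,
Phonology) head the list, followed by the weakly informative Tone; the
uncertainty-minimising rule also admits two uninformative scores on this
seed — selection by clustering confidence is deliberately greedy, and its
behaviour across many seeds is characterised in the test suite.

The `analysis/` directory chains these steps as a numbered workflow
(simulate → fit → select variables → model selection with borderline units
→ method comparison), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit.R
Rscript analysis/03_select_variables.R
Rscript analysis/04_model_selection.R
Rscript analysis/05_compare.R
```

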