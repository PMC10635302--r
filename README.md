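# pdheat

Spectral heat-kernel representation of persistence diagrams and fast
transposition-based permutation inference, with a topological clustering
scheme and a key-shape simulation test surface.

## Who this is for

Statistical comparison of persistence diagrams (PDs) — e.g. of functional
brain connectivity matrices, or of point clouds sampled from shapes — is
awkward: diagrams are multisets of (birth, death) points with no
correspondence across subjects, and they do not form a vector space.
`pdheat` is for analysts who want group inference and clustering directly
on PDs without point matching or ad-hoc dimensionality reduction.

## The method

Pooled birth/death coordinates are standardized into the triangle
𝒯 = {0 ≤ x ≤ y ≤ 1} and each diagram D = {(aᵢ, bᵢ)}ᵢ₌₁..P is represented
by Fourier coefficients over the Laplace–Beltrami eigenbasis of 𝒯
(Neumann boundary, P1 finite elements):

    f_k = Σᵢ ψ_k(aᵢ, bᵢ),   Δψ_k = λ_k ψ_k,   k = 0..κ.

The degree-κ heat-kernel estimate of the diagram at bandwidth σ is
h_σ(p) = Σ_k e^(−λ_k σ) f_k ψ_k(p), and all inference uses the squared
distance ‖f − g‖² = Σ_k e^(−λ_k σ)(f_k − g_k)².

Inference is by *transpositions*: random walks of single label swaps whose
statistics update incrementally —

* `two_sample_test()`: statistic ‖f̄ − ḡ‖² between group mean coefficient
  vectors, O(κ) per swap;
* `t_anova()`: multi-group ratio φ = TSSB/TSSW of between- to
  within-group sums of pairwise squared distances over a precomputed
  distance matrix, O(N) per swap, with periodic full re-randomization;
* `permanova_baseline()`: classical distance-based pseudo-F with
  whole-label permutations, as the reference method;
* `fit_clusters()`: Lloyd k-centroids whose centroids are the functional
  means of the heat-kernel estimates, plus `consistency_over_repeats()`
  and `select_k()` diagnostics.

Rips persistence (dimensions 0/1) for point clouds and weighted networks
is built in (`rips_diagram()`, `network_diagram()`), as is the key-shape
synthetic generator (`sample_key_cloud()`, `make_two_sample_setting()`,
`make_anova_setting()`, `run_simulation_study()`) used for power and
robustness studies.

## Worked example

Two groups of five 100-point clouds: rectangle-only vs the key shape with
its hole.

```r
library(pdheat)

basis <- lb_basis(kappa = 100)          # eigenbasis of the triangle, once
spec  <- key_shape_spec()

set.seed(1)
g1 <- lapply(1:5, function(i) sample_key_cloud(spec, 100, frac_on_shape = 0))
g2 <- lapply(1:5, function(i) sample_key_cloud(spec, 100, frac_on_shape = 1))

pds <- lapply(c(g1, g2), function(cl) rips_diagram(cl, max_dimension = 1)$dim1)
dom <- fit_standardization(pds, basis$domain)     # pooled min-max map
cs  <- lapply(pds, function(pd)
  fourier_coefficients(standardize_diagram(pd, dom), basis))

two_sample_test(cs[1:5], cs[6:10], sigma = 0.1, eigenvalues = basis,
                n_transpositions = 20000, seed = 2)
```

```
Two-sample spectral transposition test
  groups: m = 5, n = 5; sigma = 0.1
  observed ||f.bar - g.bar||^2 = 395.277
  transpositions: 20000;  p-value = 0.00424979
```

The observed statistic sits far outside the transposition null (the
rectangle clouds carry many short-lived cycles, the key clouds one
dominant hole), and the p-value ~0.003 is at the resolution limit of a
tie-conservative permutation test with five subjects per group.  The same
coefficients feed `t_anova()` for three or more groups and
`fit_clusters()` for subtyping.

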