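# pammotif

Data-driven recognition of atomic-scale motifs — hydrogen bonds and
backbone conformations — in protein crystal structures.

Heuristic definitions of structural motifs (distance–angle hydrogen-bond
criteria, DSSP/STRIDE secondary-structure rules) encode the answer into
the question: they list the motifs known to occur and test for them.
`pammotif` takes the opposite route. It estimates the probability density
of simple geometric descriptors over many experimental structures and
lets the *modes* of that density define the motifs. The package is aimed
at structural bioinformaticians and molecular modellers who want
motif definitions that transfer to unusual conformations, non-protein
polymers, or descriptor spaces where no heuristic exists.

## The method

The engine is PAMM (probabilistic analysis of molecular motifs), a
density-based mode clustering:

1. **Sparse grid** — a few thousand configurations are selected from the
   data by farthest-point sampling (greedy max–min).
2. **Adaptive KDE** — each grid point gets a kernel whose covariance is
   the local sample covariance of the nearest fraction of the data,
   shrunk by a bandwidth scale; the density is the Voronoi-weighted
   mixture of these kernels. Dihedral dimensions are treated as periodic
   (minimum-image distances, wrapped moments).
3. **Quick shift** — every grid point links to its nearest
   higher-density neighbour within a local radius; link roots are modes,
   and each basin becomes one Gaussian of a mixture model
   `P(x) = Σ_k p_k G(x | μ_k, Σ_k)`, pruned of clusters with weight
   below 1e-5.
4. **Probabilistic motif identifiers (PMIs)** — the degree of confidence
   that a configuration `x` belongs to mode `k`:

   ```
   f_k(x) = p_k G(x | μ_k, Σ_k) / (P(x) + ζ)
   ```

   with a small background `ζ` (default 1e-5) so the identifier decays
   to zero far from every mode. With `ζ = 0` the identifiers are
   posterior responsibilities and sum to one everywhere.

Around the engine the package provides the full benchmarking pipeline:

- **Hydrogen bonds** — enumeration of donor–H–acceptor triplets of the
  four flavors (N–H···N, N–H···O, O–H···O, O–H···N) with the
  `d_DH + d_AH ≤ 4.5 Å`, `d_DH < d_AH` pre-filter; the conventional
  distance–angle identifier; the Kabsch–Sander electrostatic energy
  `E = 27.888 (1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN)` kcal/mol with the
  `E < −0.5` bond criterion and its density-based identifier; and the
  normalized agreement score `δ_AB` between any two identifiers.
- **Secondary structure** — backbone (φ, ψ) extraction, 2/6/10-dimensional
  windows over consecutive residues, joint tables `P(A, y)` between
  cluster assignments and DSSP/STRIDE labels, and Q3/Q8 accuracy scores.
- **SOAP descriptors** — Cα-centered smooth-overlap power spectra
  (rotation/translation/permutation invariant), farthest-point component
  selection and PCA reduction.
- **Supervised baseline** — a one-vs-one RBF SVM (γ = 1/N_f, C = 1) on
  the same features, separating representation insufficiency from
  heuristic/data mismatch.
- **Synthetic generators** — seeded planted Gaussian mixtures, ideal
  polypeptide backbones at prescribed dihedrals, and PDB-format toy
  structures with prescribed hydrogen-bond geometries, so every stage is
  testable with known ground truth and no database download.

## Worked example

Cluster a planted two-mode hydrogen-bond geometry distribution and read
off the motifs:

```r
library(pammotif)

x <- sample_mixture(
  means  = list(c(1.82, 2.74), c(3.1, 2.3)),   # bond mode, adjacent-residue mode
  sigmas = list(0.12, 0.15),
  weights = c(0.6, 0.4), n = 8000, seed = 2
)
names(x)[1:2] <- c("d_AH", "d_DA")

fit <- pamm(x[, c("d_AH", "d_DA")], n_grid = 400, seed = 5)
tidy(fit)
#> # A tibble: 2 × 5
#>    mode weight mean_d_AH mean_d_DA  det_cov
#>   <int>  <dbl>     <dbl>     <dbl>    <dbl>
#> 1     1  0.593      1.82      2.74 0.000218
#> 2     2  0.407      3.10      2.30 0.000556
```

The two Gaussians sit on the planted centers with the planted weights:
mode 1 is the hydrogen bond (its mean is nearest the reference point
(d_AH, d_DA) = (1.82, 2.74) Å), mode 2 the spurious adjacent-residue
correlation. Its identifier is essentially 1 at the bond center and
vanishes at the other mode:

```r
hb <- pmi_pamm(fit)     # selects the hydrogen-bond mode automatically
pmi_evaluate(hb, tibble::tibble(d_AH = c(1.82, 3.10), d_DA = c(2.74, 2.30)))
#> [1] 1.00e+00 1.84e-27
```

Compare the data-driven identifier with the conventional distance–angle
definition over a pooled geometry sample:

```r
set.seed(42)
geo <- tibble::tibble(
  d_AH = runif(1e4, 1.2, 4.2), d_DA = runif(1e4, 1.8, 4.6),
  d_DH = runif(1e4, 0.9, 2.2), angle_ADH = runif(1e4, 0, 60)
)
pmi_similarity(geo, hb, pmi_distance_angle())
#> # A tibble: 1 × 3
#>   delta lambda n_samples
#>   <dbl>  <dbl>     <int>
#> 1 0.201  0.931     10000
```

`delta` is the probability that the two definitions agree a point is a
hydrogen bond relative to either flagging it, normalized so that
identical definitions score exactly 1. On this deliberately diffuse
uniform sample the two agree on only a fifth of the flagged
configurations: the geometric box is far broader than the density mode —
precisely the transferability gap the score is designed to expose.

A thin command-line wrapper over the same functions lives in
`inst/cli/pammotif.R` (subcommands `make-fixtures`, `extract-hb`,
`fit-pamm`, `eval-pmi`, `extract-dihedrals`, `ss-bench`).

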